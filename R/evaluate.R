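#' Adjudicate two reviewer labels into a gold standard
#'
#' Two masked specialist reviewers independently label each record urgent
#' or non-urgent; where they disagree, a third clinician's casting vote
#' decides. Vectorized over records: `tiebreak` must be supplied (non-NA)
#' exactly for the disagreeing records and must be absent (`NA`) where
#' the reviewers agree.
#'
#' @param reviewer1,reviewer2 logical vectors of urgent labels.
#' @param tiebreak logical vector of casting votes, `NA` where the
#'   reviewers agree; may be omitted when they agree everywhere.
#' @return a data frame with columns `reviewer1`, `reviewer2`,
#'   `tiebreak`, `adjudicated`.
#' @export
adjudicate <- function(reviewer1, reviewer2, tiebreak = NULL) {
  n <- length(reviewer1)
  if (length(reviewer2) != n) {
    triage_error("length_mismatch", "reviewer vectors differ in length")
  }
  if (is.null(tiebreak)) tiebreak <- rep(NA, n)
  if (length(tiebreak) != n) {
    triage_error("length_mismatch", "tiebreak vector differs in length")
  }
  disagree <- reviewer1 != reviewer2
  if (any(disagree & is.na(tiebreak))) {
    triage_error("missing_tiebreak",
                 sprintf("reviewers disagree without a casting vote at record(s): %s",
                         paste(which(disagree & is.na(tiebreak)),
                               collapse = ", ")))
  }
  if (any(!disagree & !is.na(tiebreak))) {
    triage_error("spurious_tiebreak",
                 sprintf("casting vote supplied where reviewers agree at record(s): %s",
                         paste(which(!disagree & !is.na(tiebreak)),
                               collapse = ", ")))
  }
  data.frame(reviewer1 = reviewer1, reviewer2 = reviewer2,
             tiebreak = as.logical(tiebreak),
             adjudicated = ifelse(disagree, as.logical(tiebreak), reviewer1))
}

#' Confusion counts against a gold standard
#'
#' @param predicted logical vector of urgent labels from a triage arm.
#' @param gold logical vector of adjudicated gold-standard labels,
#'   aligned record-by-record (if both vectors are named, the names must
#'   agree element-wise).
#' @return an object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` (summing to the cohort size).
#' @export
confusion_counts <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    triage_error("length_mismatch",
                 "predicted and gold label vectors differ in length")
  }
  if (!is.null(names(predicted)) && !is.null(names(gold)) &&
      !identical(names(predicted), names(gold))) {
    triage_error("key_mismatch",
                 "predicted and gold labels are keyed by different order references")
  }
  if (anyNA(predicted) || anyNA(gold)) {
    triage_error("missing_label", "labels must not contain NA")
  }
  structure(list(tp = sum(predicted & gold),
                 fp = sum(predicted & !gold),
                 fn = sum(!predicted & gold),
                 tn = sum(!predicted & !gold)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d): tp=%d fp=%d fn=%d tn=%d\n",
              x$tp + x$fp + x$fn + x$tn, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity and specificity (percent)
#'
#' Sensitivity is `100 * tp / (tp + fn)`; specificity is
#' `100 * tn / (tn + fp)`. An empty positive (or negative) class is an
#' error, not zero. Values are returned unrounded; display rounding is
#' one decimal by convention.
#'
#' @param counts a `confusion_counts` object.
#' @return a percentage in `[0, 100]`.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0L) {
    triage_error("undefined_metric",
                 "sensitivity undefined: no gold-positive records")
  }
  100 * counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  if (counts$tn + counts$fp == 0L) {
    triage_error("undefined_metric",
                 "specificity undefined: no gold-negative records")
  }
  100 * counts$tn / (counts$tn + counts$fp)
}

#' Continuity-corrected McNemar test
#'
#' Paired test on the discordant counts `b` and `c` with the
#' continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)` referred to
#' a chi-square distribution with 1 degree of freedom. When `b + c = 0`
#' there are no discordant pairs and the conventional result
#' (statistic 0, p = 1) is returned with a `message()`.
#'
#' @param b,c non-negative discordant pair counts.
#' @return an object of class `mcnemar_cc` with fields `b`, `c`,
#'   `statistic`, `p_value`.
#' @export
mcnemar_cc <- function(b, c) {
  if (b < 0 || c < 0) {
    triage_error("negative_count", "discordant counts must be non-negative")
  }
  if (b + c == 0) {
    message("no discordant pairs (b + c = 0); returning statistic 0, p = 1 by convention")
    stat <- 0
    p <- 1
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = c, statistic = stat, p_value = p),
            class = "mcnemar_cc")
}

#' @export
print.mcnemar_cc <- function(x, ...) {
  cat(sprintf("McNemar (continuity-corrected): b=%d c=%d chi-sq=%.4g p=%.4g\n",
              x$b, x$c, x$statistic, x$p_value))
  invisible(x)
}

#' A-priori interpretation band of a kappa value
#'
#' The agreed cut-points: values <= 0 no agreement; 0.01-0.20 none to
#' slight; 0.21-0.40 fair; 0.41-0.60 moderate; 0.61-0.80 substantial;
#' 0.81-1.00 almost perfect.
#'
#' @param kappa numeric kappa value(s).
#' @return character vector of band names.
#' @export
kappa_band <- function(kappa) {
  vapply(kappa, function(k) {
    if (k <= 0) "no agreement"
    else if (k <= 0.20) "none to slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between
#' two raters over the same records, with `p_e` from the marginal label
#' frequencies. The 95% CI uses the large-sample standard error of
#' Fleiss, Cohen and Everitt (1969), truncated to `[-1, 1]`. Both raters
#' agreeing on a single constant label leaves `p_e = 1` and kappa
#' undefined (an error).
#'
#' @param labels_a,labels_b aligned label vectors (logical or factor-like)
#'   of length >= 2.
#' @param conf_level confidence level for the interval.
#' @return an object of class `kappa_result` with fields `kappa`, `se`,
#'   `ci_low`, `ci_high`, `band`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(labels_a, labels_b, conf_level = 0.95) {
  n <- length(labels_a)
  if (length(labels_b) != n) {
    triage_error("length_mismatch", "label vectors differ in length")
  }
  if (n < 2L) {
    triage_error("too_few_records", "kappa requires at least 2 records")
  }
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  p <- table(a, b) / n                 # joint proportions p_ij
  pi_ <- rowSums(p)                    # marginals of rater a
  p_j <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(pi_ * p_j)
  if (isTRUE(all.equal(p_e, 1))) {
    triage_error("kappa_undefined",
                 "both raters constant and identical: p_e = 1, kappa undefined")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss-Cohen-Everitt large-sample variance of kappa-hat
  k <- length(lev)
  A <- sum(vapply(seq_len(k), function(i) {
    p[i, i] * (1 - (pi_[i] + p_j[i]) * (1 - kappa))^2
  }, numeric(1)))
  B <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) B <- B + p[i, j] * (p_j[i] + pi_[j])^2
  }
  B <- (1 - kappa)^2 * B
  C <- (kappa - p_e * (1 - kappa))^2
  se <- sqrt(max(0, A + B - C)) / ((1 - p_e) * sqrt(n))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 ci_low = max(-1, kappa - z * se),
                 ci_high = min(1, kappa + z * se),
                 band = kappa_band(kappa),
                 p_o = p_o, p_e = p_e, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen kappa = %.2f (95%% CI %.2f-%.2f), %s agreement (n = %d)\n",
              x$kappa, x$ci_low, x$ci_high, x$band, x$n))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups of ordinal scores. The
#' U statistic for each group is computed from midranks (ties counted
#' one half). The two-sided p-value uses the exact distribution when
#' both groups have at most 20 observations and there are no ties, and a
#' tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param group_a_scores,group_b_scores numeric score vectors (non-empty).
#' @return an object of class `mann_whitney` with fields `U_a`, `U_b`,
#'   `statistic` (= `U_a`), `p_value`, `exact`.
#' @export
mann_whitney_u <- function(group_a_scores, group_b_scores) {
  na <- length(group_a_scores); nb <- length(group_b_scores)
  if (na == 0L || nb == 0L) {
    triage_error("empty_group", "both groups must be non-empty")
  }
  pooled <- c(group_a_scores, group_b_scores)
  r <- rank(pooled)                    # midranks
  U_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  U_b <- na * nb - U_a
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && max(na, nb) <= 20L
  if (exact) {
    U <- min(U_a, U_b)
    p <- min(1, 2 * stats::pwilcox(U, na, nb))
  } else {
    N <- na + nb
    tie_sizes <- table(pooled)
    sigma2 <- na * nb / 12 * ((N + 1) -
                sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
    mu <- na * nb / 2
    if (sigma2 <= 0) {
      p <- 1                            # all observations identical
    } else {
      z <- (U_a - mu - sign(U_a - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(U_a = U_a, U_b = U_b, statistic = U_a,
                 p_value = p, exact = exact),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (%s), two-sided p = %.4g\n",
              x$statistic, if (x$exact) "exact" else "normal approximation",
              x$p_value))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a * d) / (b * c)` for the 2x2 table `[a b; c d]`, with a
#' log-scale (Woolf) confidence interval. Any zero cell triggers the
#' Haldane-Anscombe correction (0.5 added to every cell), logged via
#' `message()`.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf_level confidence level.
#' @return a list with `estimate`, `ci_low`, `ci_high`, `corrected`.
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  if (any(c(a, b, c, d) < 0)) {
    triage_error("negative_count", "cell counts must be non-negative")
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    message("zero cell: applying Haldane-Anscombe 0.5 correction")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est,
       ci_low = exp(log(est) - z * se),
       ci_high = exp(log(est) + z * se),
       corrected = corrected)
}

#' Descriptive summary of a cohort table
#'
#' Computes the descriptive statistics reported for a triage evaluation
#' cohort: mean/SD/range of age and questionnaire duration, the
#' presenting-complaint and age-band frequency tables, and the voluntary
#' Likert feedback summary (response rate, top-2 proportion, mean, SD).
#'
#' @param cohort a data frame with (any of) columns `age`,
#'   `duration_seconds`, `complaint_category`, `likert`, `mode`.
#' @return a list of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  if (!nrow(cohort)) triage_error("empty_cohort", "cohort is empty")
  out <- list(n = nrow(cohort))
  num_summary <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x),
         sd = if (length(x) > 1L) stats::sd(x) else 0,
         min = min(x), max = max(x))
  }
  if (!is.null(cohort$age)) {
    out$age <- num_summary(cohort$age)
    bands <- cut(cohort$age, c(-Inf, 19, 29, 39, 49, 59, 69, 79, Inf),
                 labels = c("<20", "20-29", "30-39", "40-49", "50-59",
                            "60-69", "70-79", ">79"))
    out$age_bands <- table(bands)
  }
  if (!is.null(cohort$duration_seconds)) {
    out$duration <- num_summary(cohort$duration_seconds)
  }
  if (!is.null(cohort$complaint_category)) {
    out$complaint <- sort(table(cohort$complaint_category),
                          decreasing = TRUE)
  }
  if (!is.null(cohort$likert)) {
    resp <- cohort$likert[!is.na(cohort$likert)]
    out$feedback <- list(
      n_respondents = length(resp),
      response_rate = length(resp) / nrow(cohort),
      top2_n = sum(resp >= 4),
      top2_pct = if (length(resp)) 100 * sum(resp >= 4) / length(resp)
                 else NA_real_,
      mean = if (length(resp)) mean(resp) else NA_real_,
      sd = if (length(resp) > 1) stats::sd(resp) else NA_real_
    )
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d records\n", x$n))
  if (!is.null(x$age)) {
    cat(sprintf("  Age: mean %.1f (SD %.1f; range %d-%d)\n",
                x$age$mean, x$age$sd, x$age$min, x$age$max))
  }
  if (!is.null(x$duration)) {
    cat(sprintf("  Duration: mean %.0f s (SD %.0f; range %.0f-%.0f)\n",
                x$duration$mean, x$duration$sd,
                x$duration$min, x$duration$max))
  }
  if (!is.null(x$complaint)) {
    cat("  Presenting complaint:\n")
    for (i in seq_along(x$complaint)) {
      cat(sprintf("    %-40s %d (%.1f%%)\n", names(x$complaint)[i],
                  x$complaint[i], 100 * x$complaint[i] / x$n))
    }
  }
  if (!is.null(x$feedback)) {
    cat(sprintf("  Feedback: %d/%d responded (%.0f%%); top-2 %d (%.0f%%); mean %.2f (SD %.2f)\n",
                x$feedback$n_respondents, x$n, 100 * x$feedback$response_rate,
                x$feedback$top2_n, x$feedback$top2_pct,
                x$feedback$mean, x$feedback$sd))
  }
  invisible(x)
}

#' Full accuracy evaluation of a triage study table
#'
#' Runs the study's accuracy analysis on a record-level table: gold
#' standard adjudication from the two reviewer labels (plus casting
#' votes), confusion counts and sensitivity/specificity of the automated
#' tool and of optometry triage against the adjudicated gold standard,
#' paired comparison of the two arms' sensitivity (McNemar on the
#' discordant structure among gold-positives) and specificity (among
#' gold-negatives), and the inter-rater kappa table.
#'
#' Both arms are compared against the same adjudicated vector (no
#' re-adjudication between arms), and only observed columns are read:
#' `tool_urgent`, `optometry_urgent`, `reviewer1_urgent`,
#' `reviewer2_urgent`, `tiebreak_urgent`.
#'
#' @param records a data frame with the five logical columns above
#'   (plus anything else, which is ignored), one row per patient.
#' @return an object of class `triage_accuracy`.
#' @export
evaluate_cohort <- function(records) {
  need <- c("tool_urgent", "optometry_urgent", "reviewer1_urgent",
            "reviewer2_urgent", "tiebreak_urgent")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    triage_error("schema_violation",
                 sprintf("records lack column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  gs <- adjudicate(records$reviewer1_urgent, records$reviewer2_urgent,
                   records$tiebreak_urgent)
  gold <- gs$adjudicated
  tool <- records$tool_urgent
  opto <- records$optometry_urgent

  cc_tool <- confusion_counts(tool, gold)
  cc_opto <- confusion_counts(opto, gold)

  # paired comparison restricted to gold-positives (sensitivity) and
  # gold-negatives (specificity): b = optometry right / tool wrong,
  # c = tool right / optometry wrong
  pos <- gold
  mc_sens <- mcnemar_cc(sum(pos & opto & !tool), sum(pos & !opto & tool))
  mc_spec <- mcnemar_cc(sum(!pos & !opto & tool), sum(!pos & opto & !tool))

  structure(list(
    n = nrow(records),
    gold_urgent_n = sum(gold),
    tool = list(counts = cc_tool,
                sensitivity = sensitivity(cc_tool),
                specificity = specificity(cc_tool)),
    optometry = list(counts = cc_opto,
                     sensitivity = sensitivity(cc_opto),
                     specificity = specificity(cc_opto)),
    mcnemar_sensitivity = mc_sens,
    mcnemar_specificity = mc_spec,
    kappa = list(
      optometry_tool = cohens_kappa(opto, tool),
      reviewer1_tool = cohens_kappa(records$reviewer1_urgent, tool),
      reviewer2_tool = cohens_kappa(records$reviewer2_urgent, tool),
      reviewers = cohens_kappa(records$reviewer1_urgent,
                               records$reviewer2_urgent)
    )
  ), class = "triage_accuracy")
}

#' @export
print.triage_accuracy <- function(x, ...) {
  cat(sprintf("Triage accuracy evaluation (N = %d; gold-urgent n = %d)\n\n",
              x$n, x$gold_urgent_n))
  cat(sprintf("%-22s %10s %10s\n", "", "Optometry", "Tool"))
  cat(sprintf("%-22s %9.1f%% %9.1f%%   McNemar p = %.3g\n", "Sensitivity",
              x$optometry$sensitivity, x$tool$sensitivity,
              x$mcnemar_sensitivity$p_value))
  cat(sprintf("%-22s %9.1f%% %9.1f%%   McNemar p = %.3g\n\n", "Specificity",
              x$optometry$specificity, x$tool$specificity,
              x$mcnemar_specificity$p_value))
  cat("Inter-rater agreement (Cohen kappa, 95% CI):\n")
  labels <- c(optometry_tool = "Optometrist and tool",
              reviewer1_tool = "Reviewer 1 and tool",
              reviewer2_tool = "Reviewer 2 and tool",
              reviewers = "Reviewer 1 and reviewer 2")
  for (nm in names(labels)) {
    k <- x$kappa[[nm]]
    cat(sprintf("  %-28s %.2f (%.2f-%.2f) %s\n", labels[[nm]],
                k$kappa, k$ci_low, k$ci_high, k$band))
  }
  invisible(x)
}
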