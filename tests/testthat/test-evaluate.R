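test_that("adjudication follows the casting-vote protocol", {
  one <- adjudicate(TRUE, TRUE)
  expect_true(one$adjudicated)
  expect_true(is.na(one$tiebreak))
  two <- adjudicate(TRUE, FALSE, FALSE)
  expect_false(two$adjudicated)
  expect_error(adjudicate(TRUE, FALSE), class = "missing_tiebreak")
  expect_error(adjudicate(TRUE, TRUE, TRUE), class = "spurious_tiebreak")
  # vectorized: agreement keeps the shared label, disagreement the vote
  g <- adjudicate(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
                  c(NA, TRUE, NA))
  expect_identical(g$adjudicated, c(TRUE, TRUE, FALSE))
})

test_that("confusion counts reconstruct the paired-arm arithmetic", {
  # perfect agreement at the study's gold prevalence
  perfect <- expand_labels(53, 0, 0, 156)
  cc <- confusion_counts(perfect$pred, perfect$gold)
  expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                   list(tp = 53L, fp = 0L, fn = 0L, tn = 156L))

  # tool-arm reconstruction: 40/53 gold-urgent predicted urgent,
  # 67 urgent predictions overall, N = 209
  arm <- expand_labels(40, 27, 13, 129)
  cc2 <- confusion_counts(arm$pred, arm$gold)
  expect_identical(cc2$tp + cc2$fp, 67L)
  expect_identical(unclass(cc2)[c("tp", "fp", "fn", "tn")],
                   list(tp = 40L, fp = 27L, fn = 13L, tn = 129L))

  empty <- confusion_counts(logical(0), logical(0))
  expect_identical(empty$tp + empty$fp + empty$fn + empty$tn, 0L)
  expect_error(confusion_counts(c(TRUE, FALSE), TRUE),
               class = "length_mismatch")
  expect_error(confusion_counts(c(a = TRUE), c(b = TRUE)),
               class = "key_mismatch")
})

test_that("sensitivity and specificity match the reported accuracy figures", {
  tool <- confusion_counts(expand_labels(40, 27, 13, 129)$pred,
                           expand_labels(40, 27, 13, 129)$gold)
  expect_equal(round(sensitivity(tool), 1), 75.5)
  expect_equal(round(specificity(tool), 1), 82.7)
  opto <- structure(list(tp = 41L, fp = 0L, fn = 12L, tn = 0L),
                    class = "confusion_counts")
  expect_equal(sensitivity(opto), 100 * 41 / 53)
  expect_equal(round(sensitivity(opto), 1), 77.4)
  none <- structure(list(tp = 0L, fp = 2L, fn = 0L, tn = 3L),
                    class = "confusion_counts")
  expect_error(sensitivity(none), class = "undefined_metric")
  allpos <- structure(list(tp = 2L, fp = 0L, fn = 3L, tn = 0L),
                      class = "confusion_counts")
  expect_error(specificity(allpos), class = "undefined_metric")
})

test_that("McNemar statistic and tail follow the continuity-corrected form", {
  m <- mcnemar_cc(5, 5)
  expect_equal(m$statistic, 0.1)
  expect_equal(m$p_value, oracle_chisq_tail(0.1), tolerance = 1e-10)
  expect_equal(round(m$p_value, 3), 0.752)

  m2 <- mcnemar_cc(20, 0)
  expect_equal(m2$statistic, 18.05)
  expect_lt(m2$p_value, 0.001)
  expect_equal(m2$p_value, oracle_chisq_tail(18.05), tolerance = 1e-10)

  expect_message(m0 <- mcnemar_cc(0, 0), "convention")
  expect_equal(m0$p_value, 1)
  expect_error(mcnemar_cc(-1, 2), class = "negative_count")

  # cross-check against the reference implementation on random counts
  # (mcnemar.test zeroes the corrected statistic when b = c, instead of
  # the study's (|b-c|-1)^2/(b+c); compare only where the forms agree)
  set.seed(5)
  for (i in 1:20) {
    b <- sample(0:30, 1); c <- sample(0:30, 1)
    if (b + c == 0 || b == c) next
    ref <- stats::mcnemar.test(matrix(c(10, b, c, 10), 2), correct = TRUE)
    m <- mcnemar_cc(b, c)
    expect_equal(m$statistic, unname(ref$statistic))
    expect_equal(m$p_value, unname(ref$p.value))
  }
})

test_that("kappa, its bands and its CI behave as specified", {
  x <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  k1 <- cohens_kappa(x, x)
  expect_equal(k1$kappa, 1)
  expect_identical(k1$band, "almost perfect")

  # 2x2 agreement table [[40,13],[27,129]] at n = 209:
  # p_o = 169/209, p_e = (67*53 + 142*156)/209^2, kappa ~ 0.535
  lab <- expand_labels(40, 27, 13, 129)
  k2 <- cohens_kappa(lab$pred, lab$gold)
  expect_equal(k2$p_o, 169 / 209)
  expect_equal(k2$p_e, (67 * 53 + 142 * 156) / 209^2)
  expect_equal(k2$kappa, (k2$p_o - k2$p_e) / (1 - k2$p_e))
  expect_equal(round(k2$kappa, 3), 0.535)
  expect_identical(k2$band, "moderate")

  expect_identical(kappa_band(0.26), "fair")
  expect_identical(kappa_band(0.75), "substantial")

  expect_error(cohens_kappa(rep(TRUE, 4), rep(TRUE, 4)),
               class = "kappa_undefined")
  expect_error(cohens_kappa(TRUE, logical(0)), class = "length_mismatch")

  # oracle equivalence on random binary vectors
  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    a <- runif(n) < runif(1, 0.2, 0.8)
    b <- runif(n) < runif(1, 0.2, 0.8)
    ok <- tryCatch(cohens_kappa(a, b), triage_error = function(e) NULL)
    if (is.null(ok)) next
    expect_equal(ok$kappa, oracle_kappa(a, b), tolerance = 1e-12)
  }
})

test_that("kappa of independent random labelers is centered at zero", {
  set.seed(2026)
  n <- 200L
  ks <- vapply(seq_len(10000L), function(i) {
    a <- runif(n) < 0.5
    b <- runif(n) < 0.5
    cohens_kappa(a, b)$kappa
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("Mann-Whitney U matches brute-force pairwise enumeration", {
  # ties counted one half: identical vectors share the pairs evenly
  m <- mann_whitney_u(1:4, 1:4)
  expect_equal(m$U_a, 8)
  expect_equal(m$U_b, 8)
  expect_gt(m$p_value, 0.95)

  sep <- mann_whitney_u(c(1, 1, 1), c(5, 5, 5))
  expect_equal(sep$U_a, 0)
  expect_equal(sep$U_b, 9)

  expect_error(mann_whitney_u(numeric(0), 1), class = "empty_group")

  set.seed(31)
  for (i in 1:60) {
    a <- sample(1:5, sample(2:12, 1), replace = TRUE)
    b <- sample(1:5, sample(2:12, 1), replace = TRUE)
    m <- mann_whitney_u(a, b)
    expect_equal(m$U_a, oracle_U(a, b))
    expect_equal(m$U_b, oracle_U(b, a))
    # p agrees with the reference rank-sum implementation
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = m$exact,
                                               correct = TRUE))
    expect_equal(m$p_value, ref$p.value, tolerance = 1e-8)
  }
  # exact branch (no ties, small n) against the exact reference
  for (i in 1:20) {
    a <- sample(1:100, 8); b <- setdiff(sample(1:100, 20), a)[1:7]
    m <- mann_whitney_u(a, b)
    expect_true(m$exact)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(m$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("odds ratios use the Woolf interval and zero-cell correction", {
  expect_equal(odds_ratio(10, 10, 10, 10)$estimate, 1)
  expect_equal(odds_ratio(20, 10, 10, 20)$estimate, 4)
  o <- odds_ratio(13, 39, 40, 117)
  expect_equal(o$estimate, (13 * 117) / (39 * 40))
  se <- sqrt(1 / 13 + 1 / 39 + 1 / 40 + 1 / 117)
  expect_equal(o$ci_low, exp(log(o$estimate) - qnorm(0.975) * se))
  expect_equal(o$ci_high, exp(log(o$estimate) + qnorm(0.975) * se))
  expect_message(oz <- odds_ratio(5, 0, 3, 7), "Haldane")
  expect_true(oz$corrected)
  expect_equal(oz$estimate, (5.5 * 7.5) / (0.5 * 3.5))
})

test_that("cohort summaries reproduce the descriptive layout", {
  one <- summarize_cohort(data.frame(age = 40))
  expect_equal(one$age$mean, 40)
  expect_equal(one$age$sd, 0)
  expect_equal(c(one$age$min, one$age$max), c(40, 40))

  fb <- data.frame(likert = c(rep(5L, 70), rep(4L, 51), rep(3L, 26),
                              rep(NA_integer_, 62)))
  s <- summarize_cohort(fb)
  expect_identical(s$feedback$n_respondents, 147L)
  expect_identical(s$feedback$top2_n, 121L)
  expect_equal(round(s$feedback$top2_pct), 82)
  expect_error(summarize_cohort(data.frame()), class = "empty_cohort")
})

test_that("urgency dichotomizes exactly at the 24-hour boundary", {
  expect_identical(urgent_label(acuity_levels()),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # changing any sub-48-h disposition never flips a non-urgent label
  for (lvl in c("SOON_48H", "ROUTINE_WEEK", "SELF_CARE")) {
    expect_false(urgent_label(lvl))
  }
})

test_that("both triage arms are evaluated against one adjudicated vector", {
  set.seed(8)
  n <- 120L
  truth <- runif(n) < 0.3
  records <- data.frame(
    tool_urgent = simulate_raters(truth, 0.8, 0.9),
    optometry_urgent = simulate_raters(truth, 0.8, 0.6),
    reviewer1_urgent = simulate_raters(truth, 0.9, 0.9),
    reviewer2_urgent = simulate_raters(truth, 0.9, 0.9)
  )
  disagree <- records$reviewer1_urgent != records$reviewer2_urgent
  records$tiebreak_urgent <- ifelse(disagree,
                                    simulate_raters(truth, 0.9, 0.9), NA)
  res <- evaluate_cohort(records)
  # same gold-positive total in both arms: no re-adjudication drift
  expect_identical(res$tool$counts$tp + res$tool$counts$fn,
                   res$optometry$counts$tp + res$optometry$counts$fn)
  expect_identical(res$tool$counts$tp + res$tool$counts$fn,
                   res$gold_urgent_n)
  # the paired McNemar uses only gold-positive discordance for sensitivity
  gold <- adjudicate(records$reviewer1_urgent, records$reviewer2_urgent,
                     records$tiebreak_urgent)$adjudicated
  b <- sum(gold & records$optometry_urgent & !records$tool_urgent)
  c_ <- sum(gold & !records$optometry_urgent & records$tool_urgent)
  expect_identical(res$mcnemar_sensitivity$b, b)
  expect_identical(res$mcnemar_sensitivity$c, c_)
})
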