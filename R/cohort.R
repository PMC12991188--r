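#' Vignette archetypes for the synthetic cohort
#'
#' The archetype pool drives the synthetic cohort generator: each
#' archetype is a clinically plausible presentation with a complaint
#' category, a complete answer script for the default questionnaire, a
#' ground-truth acuity level, and an emergency-class flag. The pool
#' spans all five acuity levels, covers every complaint category with at
#' least two archetypes, and contains exactly three emergency-class
#' presentations (a chemical splash triggering the trauma fast-path,
#' acute angle-closure, and orbital cellulitis). At zero answer noise
#' each archetype's script reproduces its ground-truth level through the
#' engine and the default acuity table (checked in the test suite).
#'
#' @return a named list of archetypes, each a list with `id`,
#'   `category`, `script`, `truth_level`, `emergency_class`.
#' @export
default_archetypes <- function() {
  arch <- function(id, category, script, truth_level, emergency = FALSE) {
    list(id = id, category = category, script = script,
         truth_level = truth_level, emergency_class = emergency)
  }
  pool <- list(
    # --- red and/or painful eye ---
    arch("angle_closure", "red_painful",
         list(q_filter = "red_painful",
              q_red_symptoms = c("redness", "pain_severe"),
              q_red_assoc = c("nausea_vomiting", "halos")),
         "EMERGENCY_SAME_DAY", emergency = TRUE),
    arch("cl_keratitis", "red_painful",
         list(q_filter = "red_painful",
              q_red_symptoms = c("redness", "pain_severe",
                                 "light_sensitivity"),
              q_red_assoc = "contact_lens"),
         "URGENT_24H"),
    arch("episcleritis", "red_painful",
         list(q_filter = "red_painful",
              q_red_symptoms = c("redness", "pain_mild"),
              q_red_assoc = "none"),
         "SOON_48H"),
    arch("conjunctivitis", "red_painful",
         list(q_filter = "red_painful",
              q_red_symptoms = c("redness", "discharge", "gritty"),
              q_red_assoc = "none"),
         "ROUTINE_WEEK"),
    arch("dry_eye", "red_painful",
         list(q_filter = "red_painful",
              q_red_symptoms = "dryness",
              q_red_assoc = "none"),
         "SELF_CARE"),
    # --- painless visual disturbance ---
    arch("retinal_detachment", "vision",
         list(q_filter = "vision", q_vis_onset = "curtain",
              q_vis_pain = "painless"),
         "URGENT_24H"),
    arch("pvd_floaters", "vision",
         list(q_filter = "vision", q_vis_onset = "flashes_floaters"),
         "URGENT_24H"),
    arch("cataract", "vision",
         list(q_filter = "vision", q_vis_onset = "gradual_loss"),
         "ROUTINE_WEEK"),
    arch("refractive_blur", "vision",
         list(q_filter = "vision", q_vis_onset = "mild_blur"),
         "SOON_48H"),
    # --- eyelid problems ---
    arch("orbital_cellulitis", "eyelid",
         list(q_filter = "eyelid", q_lid_main = "swelling_fever"),
         "EMERGENCY_SAME_DAY", emergency = TRUE),
    arch("preseptal_swelling", "eyelid",
         list(q_filter = "eyelid", q_lid_main = "swelling_no_fever"),
         "SOON_48H"),
    arch("chalazion", "eyelid",
         list(q_filter = "eyelid", q_lid_main = "lump"),
         "ROUTINE_WEEK"),
    arch("blepharitis", "eyelid",
         list(q_filter = "eyelid", q_lid_main = "itchy_crusty"),
         "SELF_CARE"),
    # --- eye injury ---
    arch("chemical_splash", "injury",
         list(q_filter = "injury", q_injury_type = "chemical"),
         "EMERGENCY_SAME_DAY", emergency = TRUE),
    arch("corneal_abrasion", "injury",
         list(q_filter = "injury", q_injury_type = "minor",
              q_injury_assoc = "vision_reduced"),
         "SOON_48H"),
    arch("minor_foreign_body", "injury",
         list(q_filter = "injury", q_injury_type = "minor",
              q_injury_assoc = "none"),
         "SOON_48H")
  )
  stats::setNames(pool, vapply(pool, `[[`, character(1), "id"))
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the structure of the analyzed evaluation cohort:
#' N = 209 patients; the four presenting-complaint categories at weights
#' 95:82:22:12; a 25% prevalence of gold-standard-urgent presentations;
#' age drawn from a truncated normal with mean 53.5 and SD 17.5 bounded
#' to 13-90 years; 19/136 telephone completion; 147/209 voluntary Likert
#' feedback with 82% of respondents in the top 2 points; an
#' optometry-triager error model with sensitivity 0.77 and specificity
#' 0.80 against ground truth; and two independent expert reviewers at
#' sensitivity = specificity = 0.85 (which yields a between-reviewer
#' kappa of about 0.4 at this prevalence), with an identically
#' distributed third rater casting the vote on disagreements.
#'
#' @param n cohort size.
#' @param category_weights positive weights over the four complaint
#'   categories (normalized internally).
#' @param urgent_prevalence probability a patient's true acuity is in the
#'   urgent (within 24 h) band.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model
#'   (years).
#' @param telephone_fraction probability a session is completed by
#'   telephone.
#' @param feedback_rate probability a patient leaves Likert feedback.
#' @param top2_rate probability a respondent rates 4 or 5.
#' @param answer_noise per-question probability that a scripted choice is
#'   resampled uniformly among the question's options.
#' @param optometry_sens,optometry_spec error model of the simulated
#'   optometry triager against ground truth.
#' @param reviewer_sens,reviewer_spec length-2 vectors: error models of
#'   the two gold-standard reviewers.
#' @param tiebreak_sens,tiebreak_spec error model of the casting-vote
#'   clinician.
#' @param mode_missing_rate probability the completion mode is recorded
#'   as missing (the study observed mode for only 136/209 records;
#'   default off).
#' @param seed integer seed making the cohort fully reproducible.
#' @return a validated list of class `cohort_params`.
#' @export
cohort_params <- function(n = 209,
                          category_weights = c(red_painful = 95,
                                               vision = 82,
                                               eyelid = 22,
                                               injury = 12),
                          urgent_prevalence = 0.25,
                          age_mean = 53.5, age_sd = 17.5,
                          age_min = 13, age_max = 90,
                          telephone_fraction = 19 / 136,
                          feedback_rate = 147 / 209,
                          top2_rate = 0.82,
                          answer_noise = 0,
                          optometry_sens = 0.77, optometry_spec = 0.80,
                          reviewer_sens = c(0.85, 0.85),
                          reviewer_spec = c(0.85, 0.85),
                          tiebreak_sens = 0.85, tiebreak_spec = 0.85,
                          mode_missing_rate = 0,
                          seed = 1L) {
  if (n < 1) triage_error("parameter_error", "n must be >= 1")
  if (any(category_weights <= 0) || length(category_weights) != 4L) {
    triage_error("parameter_error",
                 "category_weights must be 4 positive weights")
  }
  probs <- c(urgent_prevalence, telephone_fraction, feedback_rate,
             top2_rate, answer_noise, optometry_sens, optometry_spec,
             reviewer_sens, reviewer_spec, tiebreak_sens, tiebreak_spec,
             mode_missing_rate)
  if (any(probs < 0 | probs > 1)) {
    triage_error("parameter_error", "probabilities must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "cohort_params")
}

# exact truncated-normal sampling via the inverse CDF
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Perturb an answer script
#'
#' Re-walks the questionnaire graph applying answer noise: at each
#' question on the (possibly diverging) path, the scripted choice is
#' kept with probability `1 - noise_rate` and otherwise resampled
#' uniformly among the question's other admissible choices (a different
#' option for single-select, a different non-empty subset for
#' multiple-select), so `noise_rate = 1` always changes every visited
#' choice. Questions entered that the original script never visited are
#' answered uniformly at random. The result is always a valid traversal
#' of the graph.
#'
#' @param script named list: question id -> option ids.
#' @param graph a `triage_graph`.
#' @param noise_rate per-question resampling probability in `[0, 1]`.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return a perturbed script (named list).
#' @export
perturb_answers <- function(script, graph, noise_rate, seed = NULL) {
  if (noise_rate < 0 || noise_rate > 1) {
    triage_error("parameter_error", "noise_rate must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  random_choice <- function(q, avoid = NULL) {
    ids <- names(q$options)
    if (q$select == "single") {
      pool <- setdiff(ids, avoid)
      if (!length(pool)) pool <- ids
      return(pool[sample.int(length(pool), 1L)])
    }
    repeat {
      sub <- ids[stats::runif(length(ids)) < 0.5]
      if (!length(sub)) sub <- ids[sample.int(length(ids), 1L)]
      if (is.null(avoid) || !setequal(sub, avoid)) return(sub)
    }
  }
  out <- list()
  qid <- graph$entry
  repeat {
    q <- graph$questions[[qid]]
    choice <- script[[qid]]
    if (is.null(choice)) {
      choice <- random_choice(q)
    } else if (stats::runif(1) < noise_rate) {
      choice <- random_choice(q, avoid = choice)
    }
    out[[qid]] <- choice
    succ <- graph_successor(graph, qid, choice)
    if (identical(succ, "TERMINAL")) break
    qid <- succ
  }
  out
}

#' Simulate noisy urgent/non-urgent raters
#'
#' Each truly urgent record is labeled urgent with probability `sens`;
#' each truly non-urgent record is labeled non-urgent with probability
#' `spec`; records are independent.
#'
#' @param truth logical vector of true urgent labels.
#' @param sens,spec rater sensitivity and specificity in `[0, 1]`.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return logical vector of simulated labels.
#' @export
simulate_raters <- function(truth, sens, spec, seed = NULL) {
  if (any(c(sens, spec) < 0 | c(sens, spec) > 1)) {
    triage_error("parameter_error", "sens and spec must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth)
  u <- stats::runif(n)
  ifelse(truth, u < sens, u >= spec)
}

#' Generate a synthetic evaluation cohort
#'
#' Samples a full record-level cohort: for each patient a complaint
#' category (multinomial at the category weights) and a vignette
#' archetype (urgent-band archetypes with probability
#' `urgent_prevalence`, uniformly within the band), whose answer script
#' — perturbed at `answer_noise` — is executed through the questionnaire
#' engine to produce the session and the automated disposition; a
#' simulated optometry triage outcome and two reviewer labels (plus
#' casting votes) from the respective error models against ground truth;
#' and age, completion mode, duration, and voluntary Likert feedback.
#'
#' Ground-truth columns (`true_archetype`, `true_level`, `true_urgent`)
#' are retained for recovery tests only and are clearly segregated from
#' the observed columns; the evaluation functions never read them.
#'
#' @param params a `cohort_params` object (carries the seed).
#' @param graph a `triage_graph` (default: the shipped questionnaire).
#' @param table a `triage_acuity_table` (default: the shipped rules).
#' @param archetypes archetype pool (default: [default_archetypes()]).
#' @param keep_sessions logical; attach the session objects as an
#'   attribute (`attr(x, "sessions")`).
#' @return a data frame of class `cohort_table`, one row per order
#'   reference, with observed columns (`date`, `pseudonym`, `age`,
#'   `mode`, `complaint_category`, `duration_seconds`, `tool_service`,
#'   `tool_urgency`, `tool_urgent`, `fast_path`, `optometry_service`,
#'   `optometry_urgency`, `optometry_urgent`, `reviewer1_urgent`,
#'   `reviewer2_urgent`, `tiebreak_urgent`, `likert`) followed by the
#'   truth columns.
#' @export
sample_cohort <- function(params, graph = default_graph(),
                          table = default_acuity_table(),
                          archetypes = default_archetypes(),
                          keep_sessions = FALSE) {
  stopifnot(inherits(params, "cohort_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)

  cats <- names(params$category_weights)
  urgent_pool <- lapply(stats::setNames(cats, cats), function(cc) {
    Filter(function(a) a$category == cc &&
             urgent_label(a$truth_level), archetypes)
  })
  nonurgent_pool <- lapply(stats::setNames(cats, cats), function(cc) {
    Filter(function(a) a$category == cc &&
             !urgent_label(a$truth_level), archetypes)
  })
  if (any(!vapply(urgent_pool, length, integer(1))) ||
      any(!vapply(nonurgent_pool, length, integer(1)))) {
    triage_error("parameter_error",
                 "archetype pool cannot meet the urgent-prevalence target in every category")
  }

  n <- params$n
  category <- sample(cats, n, replace = TRUE,
                     prob = params$category_weights / sum(params$category_weights))
  is_urgent_truth <- stats::runif(n) < params$urgent_prevalence
  age <- as.integer(round(rtruncnorm(n, params$age_mean, params$age_sd,
                                     params$age_min, params$age_max)))
  age <- pmin(pmax(age, params$age_min), params$age_max)
  mode <- ifelse(stats::runif(n) < params$telephone_fraction,
                 "telephone", "online")
  mode_recorded <- stats::runif(n) >= params$mode_missing_rate
  # duration: lognormal matched to a ~5-minute mean with wide spread,
  # bounded to the plausible 90 s - 16 min range
  duration <- stats::rlnorm(n, meanlog = 5.62, sdlog = 0.40)
  duration <- round(pmin(pmax(duration, 90), 975))
  start0 <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")

  rows <- vector("list", n)
  sessions <- if (keep_sessions) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pool <- if (is_urgent_truth[i]) urgent_pool[[category[i]]]
            else nonurgent_pool[[category[i]]]
    a <- pool[[sample.int(length(pool), 1L)]]
    script <- if (params$answer_noise > 0) {
      perturb_answers(a$script, graph, params$answer_noise)
    } else a$script
    started <- start0 + (i - 1) * 1800
    sess <- run_answers(graph, script, age = age[i],
                        mode = mode[i],
                        order_reference = sprintf("ORD-%05d", i),
                        started_at = started,
                        finished_at = started + duration[i])
    disp <- triage(sess, table)
    if (keep_sessions) sessions[[i]] <- sess
    rows[[i]] <- data.frame(
      order_reference = sess$order_reference,
      date = format(started, "%Y-%m-%d"),
      pseudonym = sprintf("patient_%05d", i),
      age = age[i],
      mode = if (mode_recorded[i]) mode[i] else NA_character_,
      complaint_category = category[i],
      duration_seconds = duration[i],
      tool_service = disp$service,
      tool_urgency = disp$urgency,
      fast_path = disp$fast_path,
      true_archetype = a$id,
      true_level = a$truth_level,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$tool_urgent <- urgent_label(out$tool_urgency)
  out$true_urgent <- urgent_label(out$true_level)

  truth <- out$true_urgent
  out$optometry_urgent <- simulate_raters(truth, params$optometry_sens,
                                          params$optometry_spec)
  out$optometry_urgency <- simulate_optometry_urgency(out$optometry_urgent)
  out$optometry_service <- ifelse(
    out$optometry_urgency == "EMERGENCY_SAME_DAY", "ED_EEC",
    ifelse(out$optometry_urgent, "MECS_CUES",
           ifelse(out$optometry_urgency == "SELF_CARE", "PHARMACIST",
                  "COMMUNITY_OPTOMETRY")))
  out$reviewer1_urgent <- simulate_raters(truth, params$reviewer_sens[1],
                                          params$reviewer_spec[1])
  out$reviewer2_urgent <- simulate_raters(truth, params$reviewer_sens[2],
                                          params$reviewer_spec[2])
  cast <- simulate_raters(truth, params$tiebreak_sens,
                          params$tiebreak_spec)
  disagree <- out$reviewer1_urgent != out$reviewer2_urgent
  out$tiebreak_urgent <- ifelse(disagree, cast, NA)

  responded <- stats::runif(n) < params$feedback_rate
  out$likert <- ifelse(responded,
                       sample_likert(n, params$top2_rate), NA_integer_)

  # observed columns first, truth columns clearly segregated at the end
  obs <- c("order_reference", "date", "pseudonym", "age", "mode",
           "complaint_category", "duration_seconds", "tool_service",
           "tool_urgency", "tool_urgent", "fast_path",
           "optometry_service", "optometry_urgency", "optometry_urgent",
           "reviewer1_urgent", "reviewer2_urgent", "tiebreak_urgent",
           "likert")
  out <- out[, c(obs, "true_archetype", "true_level", "true_urgent")]
  class(out) <- c("cohort_table", "data.frame")
  if (keep_sessions) attr(out, "sessions") <- sessions
  out
}

# urgent labels split between same-day and 24-h bands; non-urgent labels
# across the three sub-24-h bands, loosely following the observed
# outcome mix (few same-day hospital referrals, mostly less urgent
# optometry appointments, some advice-only)
simulate_optometry_urgency <- function(urgent) {
  n <- length(urgent)
  u <- character(n)
  u[urgent] <- sample(c("EMERGENCY_SAME_DAY", "URGENT_24H"),
                      sum(urgent), replace = TRUE, prob = c(0.08, 0.92))
  u[!urgent] <- sample(c("SOON_48H", "ROUTINE_WEEK", "SELF_CARE"),
                       sum(!urgent), replace = TRUE,
                       prob = c(0.35, 0.50, 0.15))
  u
}

# 5-point Likert mix with the top-2 mass parameterized; within-band
# splits fixed so that top2_rate = 0.82 gives a mean near 4.3
sample_likert <- function(n, top2_rate) {
  p <- c(0.02, 0.04, 0.12) * (1 - top2_rate) / 0.18       # 1,2,3 rescaled
  q <- c(0.341, 0.659) * top2_rate                        # 4,5
  probs <- c(p, q)
  sample.int(5L, n, replace = TRUE, prob = probs / sum(probs))
}

#' Write a synthetic cohort to disk
#'
#' Writes the record-level CSV consumed by the evaluation functions, the
#' study-table and feedback CSVs in their standard dialects, and a JSON
#' manifest recording the generator parameters and seed.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @param params the `cohort_params` used (stored in the manifest).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort),
                   file.path(dir, "records.csv"), row.names = FALSE)
  write_study_table(cohort[, c("date", "pseudonym", "order_reference",
                               "optometry_service", "optometry_urgency")],
                    file.path(dir, "study-table.csv"))
  write_feedback(cohort[, c("order_reference", "likert")],
                 file.path(dir, "feedback.csv"))
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
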