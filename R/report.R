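#' Generate a structured symptom report
#'
#' Compiles the clinician-facing symptom report from a finished session
#' and its automated disposition. With `mask = TRUE` the disposition
#' block (service, urgency, fired rules with their levels, fast-path
#' flag, patient notice) is replaced by a masked marker while all symptom
#' content is retained — this is how reports are delivered when the
#' receiving clinician must not be biased by the automated disposition.
#' Report content is a pure function of `(session, disposition, mask)`.
#'
#' @param session a finished `triage_session` (a trauma fast-path session
#'   may be unfinished at the point its questionnaire terminated early;
#'   it must still have reached the terminal state).
#' @param disposition the `triage_disposition` computed from that session.
#' @param mask logical; `TRUE` removes the disposition block and nothing
#'   else.
#' @return an object of class `triage_report`.
#' @export
generate_report <- function(session, disposition, mask = FALSE) {
  if (!identical(session$order_reference, disposition$order_reference)) {
    triage_error("order_reference_mismatch",
                 sprintf("session '%s' vs disposition '%s'",
                         session$order_reference,
                         disposition$order_reference))
  }
  complaint <- if (length(session$answers)) {
    unname(session$answers[[1L]]$option_labels[1L])
  } else NA_character_
  duration <- if (is.null(session$finished_at)) NA_real_
              else session_duration(session)
  disp <- if (mask) {
    list(status = "masked")
  } else {
    list(status = "present",
         service = disposition$service,
         urgency = disposition$urgency,
         fast_path = disposition$fast_path,
         rules = disposition$triggered_rules,
         patient_notice = disposition$patient_notice)
  }
  structure(
    list(order_reference = session$order_reference,
         age = session$age,
         mode = session$mode,
         laterality = session$laterality,
         complaint_category = complaint,
         duration_seconds = duration,
         transcript = lapply(session$answers, function(a) {
           list(question_id = a$question_id,
                question_text = a$question_text,
                option_ids = a$option_ids,
                option_labels = unname(a$option_labels))
         }),
         symptom_codes = session$codes,
         free_text = session$free_text,
         disposition = disp),
    class = "triage_report"
  )
}

#' Render a symptom report as plain text
#'
#' Stable, templated rendering with a fixed section order: header,
#' presenting complaint, transcript, asserted symptoms, patient comments,
#' disposition. Masked reports contain no urgency or service wording; an
#' empty symptom set is stated explicitly.
#'
#' @param report a `triage_report`.
#' @return a single character string (lines joined with `"\n"`).
#' @export
render_report <- function(report) {
  lines <- c(
    "=== EYE SYMPTOM REPORT ===",
    sprintf("Order reference: %s", report$order_reference),
    sprintf("Age: %d   Completion: %s   Laterality: %s",
            report$age, report$mode, report$laterality),
    if (!is.na(report$duration_seconds))
      sprintf("Questionnaire duration: %.0f s", report$duration_seconds),
    sprintf("Presenting complaint: %s", report$complaint_category),
    "",
    "--- Questionnaire transcript ---"
  )
  for (a in report$transcript) {
    lines <- c(lines,
               sprintf("Q [%s] %s", a$question_id, a$question_text),
               sprintf("   A: %s", paste(a$option_labels, collapse = "; ")))
  }
  lines <- c(lines, "", "--- Asserted symptoms ---",
             if (length(report$symptom_codes))
               paste(" -", sort(report$symptom_codes))
             else "No red-flag symptoms asserted.")
  if (!is.null(report$free_text) && nzchar(report$free_text)) {
    lines <- c(lines, "", "--- Patient comments ---", report$free_text)
  }
  lines <- c(lines, "", "--- Automated triage disposition ---")
  d <- report$disposition
  if (identical(d$status, "masked")) {
    lines <- c(lines, "[withheld from this copy of the report]")
  } else {
    lines <- c(lines,
               sprintf("Service: %s", d$service),
               sprintf("Urgency: %s", d$urgency))
    if (isTRUE(d$fast_path)) {
      lines <- c(lines, "TRAUMA FAST-PATH: attend emergency services now.",
                 sprintf("First-aid notice: %s", d$patient_notice))
    }
    if (nrow(d$rules)) {
      lines <- c(lines, "Fired rules:",
                 sprintf(" - %s (%s)", d$rules$rule_id, d$rules$level))
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(render_report(x), "\n")
  invisible(x)
}

#' Session serialization
#'
#' Sessions round-trip losslessly through JSON (timestamps are stored as
#' seconds since the epoch, UTC).
#'
#' @param session a `triage_session`.
#' @param path file path.
#' @return `read_session()` returns the restored `triage_session`;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  x <- unclass(session)
  x$started_at <- as.numeric(x$started_at)
  x$finished_at <- if (is.null(x$finished_at)) NULL
                   else as.numeric(x$finished_at)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  x <- jsonlite::read_json(path)
  s <- list(
    order_reference = x$order_reference,
    age = as.integer(x$age),
    consent = isTRUE(x$consent),
    mode = x$mode,
    laterality = x$laterality,
    free_text = x$free_text,
    answers = lapply(x$answers, function(a) {
      list(question_id = a$question_id,
           question_text = a$question_text,
           option_ids = as_chr(a$option_ids),
           option_labels = as_chr(a$option_labels))
    }),
    codes = if (length(x$codes)) as_chr(x$codes) else character(0),
    trauma = if (length(x$trauma)) as_chr(x$trauma) else character(0),
    started_at = as.POSIXct(as.numeric(x$started_at),
                            origin = "1970-01-01", tz = "UTC"),
    finished_at = if (is.null(x$finished_at)) NULL
                  else as.POSIXct(as.numeric(x$finished_at),
                                  origin = "1970-01-01", tz = "UTC")
  )
  structure(s, class = "triage_session")
}

STUDY_TABLE_HEADER <- c("date", "pseudonym", "order_reference",
                        "optometry_service", "optometry_urgency")

#' Read and write the study record spreadsheet
#'
#' The study table is the per-practice spreadsheet linking each order
#' reference to the optometry triage outcome: a CSV with header
#' `date,pseudonym,order_reference,optometry_service,optometry_urgency`,
#' ISO-8601 dates, and outcome tokens drawn from [services()] and
#' [acuity_levels()]. Rows with a blank or unknown outcome are not
#' silently dropped: they are collected into an exclusion report
#' (mirroring the study's exclusion of incomplete optometry triage
#' outcome records) available via `attr(x, "excluded")`. Duplicate order
#' references and malformed dates are errors.
#'
#' @param path CSV file path.
#' @param rows a data frame with the five study columns (e.g. as returned
#'   by `read_study_table()`).
#' @return `read_study_table()` returns a data frame of the valid rows
#'   with an `excluded` attribute (data frame of `row`, `reason`);
#'   `write_study_table()` returns `path` invisibly. Write-then-read
#'   round-trips valid rows identically.
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!identical(names(df), STUDY_TABLE_HEADER)) {
    triage_error("schema_violation",
                 sprintf("study table header must be: %s",
                         paste(STUDY_TABLE_HEADER, collapse = ",")))
  }
  bad_date <- which(is.na(as.Date(df$date, format = "%Y-%m-%d")))
  if (length(bad_date)) {
    triage_error("malformed_date",
                 sprintf("malformed date(s) in row(s): %s",
                         paste(bad_date, collapse = ", ")))
  }
  dup <- which(duplicated(df$order_reference))
  if (length(dup)) {
    triage_error("duplicate_order_reference",
                 sprintf("duplicate order_reference in row(s): %s",
                         paste(dup, collapse = ", ")))
  }
  bad_service <- !df$optometry_service %in% services()
  bad_urgency <- !df$optometry_urgency %in% acuity_levels()
  excl <- bad_service | bad_urgency
  excluded <- data.frame(
    row = which(excl),
    order_reference = df$order_reference[excl],
    reason = ifelse(
      !nzchar(df$optometry_service[excl]) | !nzchar(df$optometry_urgency[excl]),
      "blank optometry outcome", "unknown outcome token"),
    stringsAsFactors = FALSE
  )
  out <- df[!excl, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' @rdname read_study_table
#' @export
write_study_table <- function(rows, path) {
  rows <- as.data.frame(rows)[, STUDY_TABLE_HEADER, drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write voluntary patient feedback
#'
#' Feedback is a 5-point visual Likert rating converted to the integers
#' 1 (least favorable) to 5 (most favorable); patients who declined are
#' recorded with an empty rating.
#'
#' @param path CSV file path (header `order_reference,likert`).
#' @param rows data frame with columns `order_reference` and `likert`
#'   (integer 1-5 or `NA`).
#' @return `read_feedback()` returns the validated data frame;
#'   `write_feedback()` returns `path` invisibly.
#' @export
read_feedback <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "integer"))
  if (!identical(names(df), c("order_reference", "likert"))) {
    triage_error("schema_violation",
                 "feedback header must be: order_reference,likert")
  }
  bad <- which(!is.na(df$likert) & (df$likert < 1L | df$likert > 5L))
  if (length(bad)) {
    triage_error("schema_violation",
                 sprintf("likert out of 1-5 range in row(s): %s",
                         paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname read_feedback
#' @export
write_feedback <- function(rows, path) {
  rows <- as.data.frame(rows)[, c("order_reference", "likert"), drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
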