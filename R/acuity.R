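#' Load and validate a symptom acuity table
#'
#' The acuity table is the declarative rule set that rates asserted
#' symptom codes. Each rule has a trigger over symptom codes (an `all_of`
#' conjunction, optionally combined with an `any_of` disjunction), an
#' acuity level, an optional service hint, and an `emergency_class` flag
#' marking triggers that encode an emergency presentation per the
#' national emergency eye-care guidance.
#'
#' Load-time invariants: every trigger code is in the declared
#' vocabulary; every vocabulary code is covered by at least one rule;
#' every `emergency_class` rule maps to `EMERGENCY_SAME_DAY` with an
#' `ED_EEC` service; rules at the two most acute levels may only hint
#' `ED_EEC` or `MECS_CUES`.
#'
#' @param definition path to a YAML (or JSON) rule file, or a parsed list
#'   with keys `version`, `vocabulary`, `rules`.
#' @return an object of class `triage_acuity_table`.
#' @seealso [default_acuity_table()], [rate_acuity()], [assign_disposition()]
#' @export
load_acuity_table <- function(definition) {
  doc <- read_definition(definition)
  for (key in c("vocabulary", "rules")) {
    if (is.null(doc[[key]])) {
      triage_error("schema_violation",
                   sprintf("acuity table lacks key '%s'", key))
    }
  }
  vocab <- as_chr(doc$vocabulary)
  rules <- list()
  for (r in doc$rules) {
    rid <- as.character(r$id)
    if (rid %in% names(rules)) {
      triage_error("schema_violation",
                   sprintf("duplicate rule id '%s'", rid))
    }
    trig <- r$trigger
    unknown_comb <- setdiff(names(trig), c("all_of", "any_of"))
    if (length(unknown_comb)) {
      triage_error("unknown_combinator",
                   sprintf("rule '%s': unknown combinator(s) %s",
                           rid, paste(unknown_comb, collapse = ", ")))
    }
    all_of <- if (length(trig$all_of)) as_chr(trig$all_of) else character(0)
    any_of <- if (length(trig$any_of)) as_chr(trig$any_of) else character(0)
    if (!length(all_of) && !length(any_of)) {
      triage_error("schema_violation",
                   sprintf("rule '%s' has an empty trigger", rid))
    }
    bad <- setdiff(c(all_of, any_of), vocab)
    if (length(bad)) {
      triage_error("unknown_symptom_code",
                   sprintf("rule '%s': unknown symptom code(s) %s",
                           rid, paste(bad, collapse = ", ")))
    }
    level <- as.character(r$level)
    acuity_rank(level)  # validates
    hint <- r$service_hint
    if (!is.null(hint) && !hint %in% services()) {
      triage_error("schema_violation",
                   sprintf("rule '%s': unknown service '%s'", rid, hint))
    }
    emergency <- isTRUE(r$emergency_class)
    if (emergency &&
        (!identical(level, "EMERGENCY_SAME_DAY") ||
         !identical(hint %||% "ED_EEC", "ED_EEC"))) {
      triage_error("emergency_rule_misclassified",
                   sprintf("emergency-class rule '%s' must map to EMERGENCY_SAME_DAY + ED_EEC",
                           rid))
    }
    if (acuity_rank(level) <= 2L && !is.null(hint) &&
        !hint %in% c("ED_EEC", "MECS_CUES")) {
      triage_error("schema_violation",
                   sprintf("rule '%s': urgent-band rules may only hint ED_EEC or MECS_CUES",
                           rid))
    }
    rules[[rid]] <- list(id = rid, all_of = all_of, any_of = any_of,
                         level = level, service_hint = hint,
                         emergency_class = emergency)
  }
  covered <- unique(unlist(lapply(rules, function(r) c(r$all_of, r$any_of)),
                           use.names = FALSE))
  uncovered <- setdiff(vocab, covered)
  if (length(uncovered)) {
    triage_error("uncovered_symptom_code",
                 sprintf("vocabulary code(s) not covered by any rule: %s",
                         paste(uncovered, collapse = ", ")))
  }
  structure(list(version = as.character(doc$version %||% "1"),
                 vocabulary = vocab, rules = rules),
            class = "triage_acuity_table")
}

#' @rdname default_graph
#' @export
default_acuity_table <- function() {
  load_acuity_table(system.file("extdata", "acuity-table-default.yaml",
                                package = "eyetriage", mustWork = TRUE))
}

#' @export
print.triage_acuity_table <- function(x, ...) {
  cat(sprintf("Symptom acuity table (version %s)\n", x$version))
  lv <- table(factor(vapply(x$rules, `[[`, character(1), "level"),
                     levels = acuity_levels()))
  cat(sprintf("  %d rules over %d symptom codes (%s)\n",
              length(x$rules), length(x$vocabulary),
              paste(sprintf("%s: %d", names(lv), lv), collapse = ", ")))
  invisible(x)
}

# monotone predicate: all all_of present AND (no any_of list, or >= 1 present)
rule_fires <- function(rule, codes) {
  all(rule$all_of %in% codes) &&
    (length(rule$any_of) == 0L || any(rule$any_of %in% codes))
}

#' Trauma fast-path check
#'
#' A history of potentially severe chemical, blunt or high-velocity
#' trauma bypasses the remaining questionnaire and acuity rating: the
#' patient receives an immediate same-day emergency disposition together
#' with a first-aid notice and advice to attend emergency services.
#'
#' @param session a `triage_session` (need not be finished; the trauma
#'   screen may terminate the questionnaire early).
#' @return a `triage_disposition` with `fast_path = TRUE`, or `NULL` when
#'   no trauma flag was asserted.
#' @export
trauma_fast_path <- function(session) {
  if (!any(session$trauma %in% TRAUMA_FLAGS)) return(NULL)
  new_disposition(
    order_reference = session$order_reference,
    service = "ED_EEC", urgency = "EMERGENCY_SAME_DAY",
    triggered_rules = data.frame(rule_id = character(0),
                                 level = character(0)),
    fast_path = TRUE,
    patient_notice = "nhs-eye-first-aid"
  )
}

#' Rate the acuity of a finished session
#'
#' Evaluates every rule of the acuity table against the session's
#' asserted symptom codes. Triggers are monotone (supersets of a
#' triggering code set still trigger), so adding symptoms can only add
#' rule firings.
#'
#' @param session a finished `triage_session`.
#' @param table a `triage_acuity_table`.
#' @return a data frame with columns `rule_id` and `level`, one row per
#'   fired rule (zero rows when no rule fires).
#' @export
rate_acuity <- function(session, table) {
  if (is.null(session$finished_at)) {
    triage_error("unfinished_session",
                 "acuity is rated on finished sessions only")
  }
  fired <- Filter(function(r) rule_fires(r, session$codes), table$rules)
  data.frame(rule_id = vapply(fired, `[[`, character(1), "id"),
             level = vapply(fired, `[[`, character(1), "level"),
             stringsAsFactors = FALSE, row.names = NULL)
}

new_disposition <- function(order_reference, service, urgency,
                            triggered_rules, fast_path, patient_notice) {
  structure(list(order_reference = order_reference, service = service,
                 urgency = urgency, triggered_rules = triggered_rules,
                 fast_path = fast_path, patient_notice = patient_notice),
            class = "triage_disposition")
}

#' Assign the automated triage disposition
#'
#' The trauma fast-path takes precedence. Otherwise the disposition
#' urgency is the maximum (most acute) level over the fired rules —
#' `SELF_CARE` when no rule fired — and the service is taken from the
#' service hints of the maximal rules, defaulting by urgency band
#' (emergency: ED/EEC; urgent: MECS/CUES; 48-hour and routine: community
#' optometry; self-care: pharmacist). Conflicting hints at the maximal
#' level are resolved by the fixed precedence
#' `ED_EEC > MECS_CUES > COMMUNITY_OPTOMETRY > PHARMACIST` and logged via
#' `message()`.
#'
#' @param ratings the data frame returned by [rate_acuity()] on the same
#'   session.
#' @param session the rated `triage_session`.
#' @param table the `triage_acuity_table` the ratings came from.
#' @return a `triage_disposition`: `order_reference`, `service`,
#'   `urgency`, `triggered_rules`, `fast_path`, `patient_notice`.
#' @export
assign_disposition <- function(ratings, session, table) {
  fp <- trauma_fast_path(session)
  if (!is.null(fp)) return(fp)
  if (nrow(ratings) == 0L) {
    return(new_disposition(session$order_reference, "PHARMACIST",
                           "SELF_CARE", ratings, FALSE, NULL))
  }
  ranks <- acuity_rank(ratings$level)
  urgency <- acuity_levels()[min(ranks)]
  maximal <- ratings$rule_id[ranks == min(ranks)]
  hints <- unlist(lapply(table$rules[maximal], function(r) r$service_hint),
                  use.names = FALSE)
  service <- if (length(hints)) {
    hints <- unique(hints)
    if (length(hints) > 1L) {
      chosen <- services()[min(match(hints, services()))]
      message(sprintf("conflicting service hints (%s) at level %s; using %s",
                      paste(hints, collapse = ", "), urgency, chosen))
      chosen
    } else hints
  } else {
    switch(urgency,
           EMERGENCY_SAME_DAY = "ED_EEC",
           URGENT_24H = "MECS_CUES",
           SOON_48H = "COMMUNITY_OPTOMETRY",
           ROUTINE_WEEK = "COMMUNITY_OPTOMETRY",
           SELF_CARE = "PHARMACIST")
  }
  new_disposition(session$order_reference, service, urgency,
                  ratings[order(acuity_rank(ratings$level)), , drop = FALSE],
                  FALSE, NULL)
}

#' One-call triage of a session
#'
#' Runs the trauma fast-path check, acuity rating and disposition
#' assignment in sequence. Computing a disposition never mutates the
#' session, so masked and unmasked report generation agree on content.
#'
#' @param session a `triage_session`; must be finished unless a trauma
#'   fast-path applies.
#' @param table a `triage_acuity_table`.
#' @return a `triage_disposition`.
#' @export
triage <- function(session, table) {
  fp <- trauma_fast_path(session)
  if (!is.null(fp)) return(fp)
  assign_disposition(rate_acuity(session, table), session, table)
}

#' @export
print.triage_disposition <- function(x, ...) {
  cat(sprintf("Disposition for %s: %s / %s%s\n",
              x$order_reference %||% "<no order>", x$service, x$urgency,
              if (x$fast_path) " [trauma fast-path]" else ""))
  if (nrow(x$triggered_rules)) {
    cat(sprintf("  rules: %s\n",
                paste(sprintf("%s (%s)", x$triggered_rules$rule_id,
                              x$triggered_rules$level), collapse = ", ")))
  }
  invisible(x)
}
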