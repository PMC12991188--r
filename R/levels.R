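#' Acuity levels and services
#'
#' The disposition vocabulary of the triage engine. Acuity is an ordinal
#' scale from most to least acute; services are the four destinations a
#' disposition can point to. The "within a week" and "routine" bands are
#' collapsed into a single ordinal level, and the self-care band carries
#' the pharmacist service.
#'
#' @return `acuity_levels()` returns the five urgency levels ordered from
#'   most to least acute; `services()` returns the four services in
#'   fixed precedence order (used to break ties between conflicting
#'   service hints).
#' @examples
#' acuity_levels()
#' services()
#' @export
acuity_levels <- function() {
  c("EMERGENCY_SAME_DAY", "URGENT_24H", "SOON_48H", "ROUTINE_WEEK",
    "SELF_CARE")
}

#' @rdname acuity_levels
#' @export
services <- function() {
  c("ED_EEC", "MECS_CUES", "COMMUNITY_OPTOMETRY", "PHARMACIST")
}

TRAUMA_FLAGS <- c("chemical", "blunt", "high_velocity")

# rank 1 = most acute; all level comparisons in the package go through this
acuity_rank <- function(level) {
  r <- match(level, acuity_levels())
  if (anyNA(r)) {
    triage_error("unknown_level",
                 sprintf("unknown acuity level(s): %s",
                         paste(level[is.na(r)], collapse = ", ")))
  }
  r
}

#' Dichotomize an urgency level at the 24-hour boundary
#'
#' A disposition is "urgent" in the study sense when it calls for hospital
#' or community specialist assessment within 24 hours, i.e. its urgency is
#' one of the two most acute levels.
#'
#' @param urgency character vector of acuity levels (see [acuity_levels()]).
#' @return logical vector, `TRUE` for `EMERGENCY_SAME_DAY` and
#'   `URGENT_24H`, `FALSE` for the sub-24-hour levels.
#' @examples
#' urgent_label(c("URGENT_24H", "ROUTINE_WEEK"))
#' @export
urgent_label <- function(urgency) {
  acuity_rank(urgency) <= 2L
}

# classed conditions so callers/tests can distinguish failure modes
triage_error <- function(class, message) {
  stop(structure(
    class = c(class, "triage_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_chr <- function(x) {
  vapply(x, as.character, character(1), USE.NAMES = FALSE)
}
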