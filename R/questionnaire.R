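#' Load and validate a conditional-logic questionnaire
#'
#' A questionnaire is a directed acyclic graph of multiple-choice
#' questions. Each answer option may assert controlled-vocabulary symptom
#' codes and/or a trauma flag; conditional edges route the patient from
#' question to question depending on the options chosen, and every
#' complete traversal reaches a terminal state within 25 questions.
#'
#' The definition document has top-level keys `version`, `vocabulary`,
#' `questions` and `edges`. Each question carries an `id`, display `text`,
#' a `select` mode (`single` or `multiple`) and at least two options; each
#' option has an `id`, a `label`, optional `codes` (drawn from
#' `vocabulary`) and an optional `trauma` flag (`chemical`, `blunt`,
#' `high_velocity` or `none`). Edges are declared as
#' `{from, when: {any_of: [...]}, to}` with `to` a question id or
#' `TERMINAL`; every question must also declare a `default: true` edge.
#' The first question in the document is the entry (complaint filter)
#' question. Edge order is significant: the first edge whose predicate
#' holds on the chosen options decides the successor.
#'
#' All structural invariants are checked at load time: unique ids, known
#' symptom codes, at least two options per question, acyclicity, presence
#' of a default edge on every question, reachability of every question
#' from the entry, and a maximum path length of 25 questions.
#'
#' @param definition path to a YAML (or JSON) definition file, or an
#'   already-parsed list with the same structure.
#' @return an object of class `triage_graph`.
#' @seealso [default_graph()] for the questionnaire shipped with the
#'   package, [start_session()] to begin a patient session.
#' @export
load_graph <- function(definition) {
  doc <- read_definition(definition)
  for (key in c("version", "vocabulary", "questions", "edges")) {
    if (is.null(doc[[key]])) {
      triage_error("schema_violation",
                   sprintf("questionnaire definition lacks key '%s'", key))
    }
  }
  vocab <- as_chr(doc$vocabulary)

  questions <- list()
  for (q in doc$questions) {
    if (is.null(q$id) || is.null(q$text) || is.null(q$options)) {
      triage_error("schema_violation",
                   "each question needs id, text and options")
    }
    qid <- as.character(q$id)
    if (qid %in% names(questions)) {
      triage_error("schema_violation",
                   sprintf("duplicate question id '%s'", qid))
    }
    select <- q$select %||% "single"
    if (!select %in% c("single", "multiple")) {
      triage_error("schema_violation",
                   sprintf("question '%s': select must be single or multiple",
                           qid))
    }
    if (length(q$options) < 2L) {
      triage_error("schema_violation",
                   sprintf("question '%s' has fewer than 2 options", qid))
    }
    opts <- list()
    for (o in q$options) {
      oid <- as.character(o$id)
      if (oid %in% names(opts)) {
        triage_error("schema_violation",
                     sprintf("question '%s': duplicate option id '%s'",
                             qid, oid))
      }
      codes <- if (length(o$codes)) as_chr(o$codes) else character(0)
      bad <- setdiff(codes, vocab)
      if (length(bad)) {
        triage_error("unknown_symptom_code",
                     sprintf("question '%s', option '%s': unknown symptom code(s) %s",
                             qid, oid, paste(bad, collapse = ", ")))
      }
      trauma <- o$trauma %||% "none"
      if (!trauma %in% c(TRAUMA_FLAGS, "none")) {
        triage_error("schema_violation",
                     sprintf("question '%s', option '%s': invalid trauma flag '%s'",
                             qid, oid, trauma))
      }
      opts[[oid]] <- list(id = oid, label = as.character(o$label %||% oid),
                          codes = codes, trauma = trauma)
    }
    questions[[qid]] <- list(id = qid, text = as.character(q$text),
                             select = select, options = opts)
  }

  edges_by_from <- stats::setNames(vector("list", length(questions)),
                                   names(questions))
  for (e in doc$edges) {
    from <- as.character(e$from)
    to <- as.character(e$to)
    if (!from %in% names(questions)) {
      triage_error("schema_violation",
                   sprintf("edge from unknown question '%s'", from))
    }
    if (!identical(to, "TERMINAL") && !to %in% names(questions)) {
      triage_error("schema_violation",
                   sprintf("edge from '%s' to unknown question '%s'", from, to))
    }
    default <- isTRUE(e$default)
    when <- NULL
    if (!default) {
      when <- as_chr(e$when$any_of %||% list())
      if (!length(when)) {
        triage_error("schema_violation",
                     sprintf("edge from '%s' has neither a predicate nor default: true",
                             from))
      }
      bad <- setdiff(when, names(questions[[from]]$options))
      if (length(bad)) {
        triage_error("schema_violation",
                     sprintf("edge from '%s' references unknown option(s) %s",
                             from, paste(bad, collapse = ", ")))
      }
    }
    edges_by_from[[from]] <- c(edges_by_from[[from]],
                               list(list(from = from, when = when,
                                         default = default, to = to)))
  }

  graph <- structure(
    list(version = as.character(doc$version), vocabulary = vocab,
         questions = questions, edges = edges_by_from,
         entry = names(questions)[1L]),
    class = "triage_graph"
  )
  validate_graph_structure(graph)
  graph
}

read_definition <- function(definition) {
  if (is.character(definition) && length(definition) == 1L) {
    if (!file.exists(definition)) {
      triage_error("schema_violation",
                   sprintf("definition file not found: %s", definition))
    }
    if (grepl("\\.json$", definition)) {
      jsonlite::read_json(definition)
    } else {
      yaml::read_yaml(definition)
    }
  } else if (is.list(definition)) {
    definition
  } else {
    triage_error("schema_violation",
                 "definition must be a file path or a parsed list")
  }
}

# DFS over the question-level edge graph: cycles, default-edge coverage,
# reachability and the 25-question path cap are all checked here.
validate_graph_structure <- function(graph) {
  for (qid in names(graph$questions)) {
    edges <- graph$edges[[qid]]
    if (is.null(edges) || !any(vapply(edges, `[[`, logical(1), "default"))) {
      triage_error("graph_incomplete",
                   sprintf("question '%s' declares no default edge", qid))
    }
  }
  visited <- character(0)
  longest <- 0L
  walk <- function(qid, path) {
    if (qid %in% path) {
      triage_error("cycle_detected",
                   sprintf("cycle through question '%s' (path: %s)",
                           qid, paste(c(path, qid), collapse = " -> ")))
    }
    path <- c(path, qid)
    if (length(path) > 25L) {
      triage_error("path_too_long",
                   sprintf("path exceeds 25 questions: %s ...",
                           paste(path, collapse = " -> ")))
    }
    longest <<- max(longest, length(path))
    visited <<- union(visited, qid)
    for (e in graph$edges[[qid]]) {
      if (!identical(e$to, "TERMINAL")) walk(e$to, path)
    }
  }
  walk(graph$entry, character(0))
  unreachable <- setdiff(names(graph$questions), visited)
  if (length(unreachable)) {
    triage_error("unreachable_question",
                 sprintf("question(s) unreachable from entry: %s",
                         paste(unreachable, collapse = ", ")))
  }
  invisible(graph)
}

#' @export
print.triage_graph <- function(x, ...) {
  cat(sprintf("Triage questionnaire graph (version %s)\n", x$version))
  cat(sprintf("  %d questions, %d symptom codes, entry: '%s'\n",
              length(x$questions), length(x$vocabulary), x$entry))
  invisible(x)
}

#' Paths and successor structure of a questionnaire graph
#'
#' Enumerates every question-level path from the entry question to the
#' terminal state, following all declared edges. Used for structural
#' audits (every path terminates, no path exceeds 25 questions).
#'
#' @param graph a `triage_graph`.
#' @return a list of character vectors of question ids, one per path.
#' @export
graph_paths <- function(graph) {
  out <- list()
  walk <- function(qid, path) {
    path <- c(path, qid)
    for (e in graph$edges[[qid]]) {
      if (identical(e$to, "TERMINAL")) out[[length(out) + 1L]] <<- path
      else walk(e$to, path)
    }
  }
  walk(graph$entry, character(0))
  out
}

#' Start a triage session
#'
#' Creates an empty patient session positioned at the entry (complaint
#' filter) question. Patients must be at least 13 years old and must have
#' accepted the data-use consent gate before a session is created.
#' Timestamps are injected by the caller so that duration logic is
#' testable; they default to the wall clock.
#'
#' @param age patient age in whole years; must be >= 13.
#' @param consent logical; `FALSE` refuses session creation.
#' @param mode `"online"` or `"telephone"` (receptionist proxy entry).
#' @param order_reference unique order token linking the session to the
#'   practice's study record.
#' @param started_at session start time (`POSIXct`).
#' @param laterality which eye is affected: `"left"`, `"right"`, `"both"`
#'   or `"unknown"`.
#' @param free_text optional free-text clarification from the patient.
#' @return an object of class `triage_session` with an empty transcript.
#' @export
start_session <- function(age, consent, mode = c("online", "telephone"),
                          order_reference = NULL,
                          started_at = Sys.time(),
                          laterality = c("unknown", "left", "right", "both"),
                          free_text = NULL) {
  mode <- match.arg(mode)
  laterality <- match.arg(laterality)
  if (!isTRUE(consent)) {
    triage_error("consent_refused",
                 "consent was not given; session not created")
  }
  age <- as.integer(age)
  if (is.na(age) || age < 13L) {
    triage_error("ineligible_age",
                 "patients must be aged 13 years or older")
  }
  structure(
    list(order_reference = order_reference %||%
           sprintf("ORD-%08X", sample.int(.Machine$integer.max, 1L)),
         age = age, consent = TRUE, mode = mode, laterality = laterality,
         free_text = free_text,
         answers = list(),         # ordered transcript, append-only
         codes = character(0),     # accumulated asserted symptom codes
         trauma = character(0),    # accumulated trauma flags (!= "none")
         started_at = started_at, finished_at = NULL),
    class = "triage_session"
  )
}

graph_successor <- function(graph, question_id, chosen) {
  for (e in graph$edges[[question_id]]) {
    if (e$default || any(chosen %in% e$when)) return(e$to)
  }
  triage_error("graph_incomplete",
               sprintf("no edge matches at question '%s'", question_id))
}

#' Next pending question of a session
#'
#' Deterministic traversal: the first declared edge whose predicate holds
#' on the transcript decides the successor of each answered question.
#'
#' @param session a `triage_session`.
#' @param graph the `triage_graph` the session is traversing.
#' @return the pending `Question` (a list with `id`, `text`, `select`,
#'   `options`), or the string `"TERMINAL"` when the traversal is
#'   complete.
#' @export
next_question <- function(session, graph) {
  n <- length(session$answers)
  if (n == 0L) return(graph$questions[[graph$entry]])
  last <- session$answers[[n]]
  succ <- graph_successor(graph, last$question_id, last$option_ids)
  if (identical(succ, "TERMINAL")) "TERMINAL" else graph$questions[[succ]]
}

is_terminal <- function(x) identical(x, "TERMINAL")

#' Record an answer in a session transcript
#'
#' Transcripts are append-only and must follow the graph traversal order:
#' only the currently pending question may be answered, a single-select
#' question accepts exactly one option, and a multiple-select question
#' accepts one or more. Symptom codes and trauma flags of the chosen
#' options are accumulated into the session.
#'
#' @inheritParams next_question
#' @param question_id id of the currently pending question.
#' @param option_ids chosen option id(s) of that question.
#' @return the extended `triage_session`.
#' @export
record_answer <- function(session, graph, question_id, option_ids) {
  if (!is.null(session$finished_at)) {
    triage_error("out_of_order_answer", "session already finished")
  }
  pending <- next_question(session, graph)
  if (is_terminal(pending)) {
    triage_error("out_of_order_answer",
                 "traversal already complete; no question pending")
  }
  if (!identical(question_id, pending$id)) {
    triage_error("out_of_order_answer",
                 sprintf("pending question is '%s', got answer for '%s'",
                         pending$id, question_id))
  }
  option_ids <- as.character(option_ids)
  bad <- setdiff(option_ids, names(pending$options))
  if (length(bad)) {
    triage_error("unknown_option",
                 sprintf("question '%s': unknown option(s) %s",
                         question_id, paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(option_ids)) {
    triage_error("unknown_option",
                 sprintf("question '%s': duplicated option ids", question_id))
  }
  n_opt <- length(option_ids)
  if (pending$select == "single" && n_opt != 1L) {
    triage_error("cardinality_error",
                 sprintf("question '%s' is single-select; got %d options",
                         question_id, n_opt))
  }
  if (n_opt < 1L) {
    triage_error("cardinality_error",
                 sprintf("question '%s': at least one option required",
                         question_id))
  }
  chosen <- pending$options[option_ids]
  entry <- list(
    question_id = question_id,
    question_text = pending$text,
    option_ids = option_ids,
    option_labels = unname(vapply(chosen, `[[`, character(1), "label"))
  )
  session$answers[[length(session$answers) + 1L]] <- entry
  session$codes <- union(session$codes,
                         unlist(lapply(chosen, `[[`, "codes"), use.names = FALSE))
  flags <- vapply(chosen, `[[`, character(1), "trauma")
  session$trauma <- union(session$trauma, setdiff(flags, "none"))
  session
}

#' Close a finished session
#'
#' Marks the session finished once the traversal has reached the terminal
#' state, recording the finish timestamp. The finish time must not
#' precede the start time.
#'
#' @inheritParams next_question
#' @param finished_at finish time (`POSIXct`).
#' @return the finished `triage_session`.
#' @export
finish_session <- function(session, graph, finished_at = Sys.time()) {
  if (!is_terminal(next_question(session, graph))) {
    triage_error("unfinished_session",
                 "traversal has not reached the terminal state")
  }
  if (as.numeric(finished_at) < as.numeric(session$started_at)) {
    triage_error("invalid_timestamps",
                 "finished_at precedes started_at")
  }
  session$finished_at <- finished_at
  session
}

#' Session duration in seconds
#'
#' @param session a finished `triage_session`.
#' @return elapsed seconds between start and finish (non-negative).
#' @export
session_duration <- function(session) {
  if (is.null(session$finished_at)) {
    triage_error("unfinished_session",
                 "duration is defined only for finished sessions")
  }
  as.numeric(session$finished_at) - as.numeric(session$started_at)
}

#' Execute a scripted traversal
#'
#' Convenience driver: walks the graph from the entry question, answering
#' each pending question from `script` (a named list mapping question id
#' to chosen option ids), and closes the session. Used by the synthetic
#' cohort generator and by batch (non-interactive) runs.
#'
#' @inheritParams start_session
#' @param graph a `triage_graph`.
#' @param script named list: question id -> character vector of option ids.
#' @param finished_at finish time.
#' @return a finished `triage_session`.
#' @export
run_answers <- function(graph, script, age = 50L, consent = TRUE,
                        mode = "online", order_reference = NULL,
                        started_at = Sys.time(),
                        finished_at = started_at,
                        laterality = "unknown", free_text = NULL) {
  s <- start_session(age, consent, mode, order_reference, started_at,
                     laterality, free_text)
  repeat {
    q <- next_question(s, graph)
    if (is_terminal(q)) break
    if (is.null(script[[q$id]])) {
      triage_error("incomplete_script",
                   sprintf("script has no answer for pending question '%s'",
                           q$id))
    }
    s <- record_answer(s, graph, q$id, script[[q$id]])
  }
  finish_session(s, graph, finished_at)
}

#' @export
print.triage_session <- function(x, ...) {
  cat(sprintf("Triage session %s (age %d, %s)\n",
              x$order_reference, x$age, x$mode))
  cat(sprintf("  %d answers, %d symptom codes%s, %s\n",
              length(x$answers), length(x$codes),
              if (length(x$trauma)) paste0(", trauma: ",
                                           paste(x$trauma, collapse = "/"))
              else "",
              if (is.null(x$finished_at)) "in progress" else "finished"))
  invisible(x)
}

#' Default questionnaire and acuity table
#'
#' Loads the representative questionnaire graph and symptom acuity table
#' shipped with the package. The entry question is the complaint filter
#' with the four presenting-complaint categories (red and/or painful eye,
#' painless visual disturbance, eyelid problems, eye injury); follow-up
#' questions cover the symptom vocabulary of the default acuity table,
#' which spans all five acuity levels.
#'
#' @return `default_graph()` returns a `triage_graph`;
#'   `default_acuity_table()` returns a `triage_acuity_table`.
#' @export
default_graph <- function() {
  load_graph(system.file("extdata", "questionnaire-default.yaml",
                         package = "eyetriage", mustWork = TRUE))
}
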