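test_that("shipped questionnaire loads with the four complaint filter categories", {
  g <- the_graph
  entry <- g$questions[[g$entry]]
  expect_length(entry$options, 4L)
  expect_setequal(names(entry$options),
                  c("red_painful", "vision", "eyelid", "injury"))
  expect_identical(entry$select, "single")
  # every option code is in the declared vocabulary
  for (q in g$questions) {
    for (o in q$options) expect_true(all(o$codes %in% g$vocabulary))
  }
})

test_that("structural load errors name the offending element", {
  base_q <- function(id) {
    list(id = id, text = id, select = "single",
         options = list(list(id = "a", label = "a"),
                        list(id = "b", label = "b")))
  }
  # 26-question linear chain exceeds the 25-question cap
  qs <- lapply(paste0("q", 1:26), base_q)
  edges <- lapply(1:26, function(i) {
    list(from = paste0("q", i), default = TRUE,
         to = if (i < 26) paste0("q", i + 1) else "TERMINAL")
  })
  def <- list(version = "t", vocabulary = list("x"),
              questions = qs, edges = edges)
  expect_error(load_graph(def), class = "path_too_long")

  # a single-option question is rejected
  def1 <- list(version = "t", vocabulary = list("x"),
               questions = list(list(
                 id = "q1", text = "q1", select = "single",
                 options = list(list(id = "a", label = "a")))),
               edges = list(list(from = "q1", default = TRUE,
                                 to = "TERMINAL")))
  expect_error(load_graph(def1), class = "schema_violation")

  # cycle detection
  def2 <- list(version = "t", vocabulary = list("x"),
               questions = list(base_q("q1"), base_q("q2")),
               edges = list(
                 list(from = "q1", default = TRUE, to = "q2"),
                 list(from = "q2", default = TRUE, to = "q1")))
  expect_error(load_graph(def2), class = "cycle_detected")

  # unreachable question
  def3 <- list(version = "t", vocabulary = list("x"),
               questions = list(base_q("q1"), base_q("q2")),
               edges = list(
                 list(from = "q1", default = TRUE, to = "TERMINAL"),
                 list(from = "q2", default = TRUE, to = "TERMINAL")))
  expect_error(load_graph(def3), class = "unreachable_question")
  expect_error(load_graph(def3), "q2")

  # unknown symptom code
  def4 <- list(version = "t", vocabulary = list("x"),
               questions = list(list(
                 id = "q1", text = "q1", select = "single",
                 options = list(list(id = "a", label = "a",
                                     codes = list("nope")),
                                list(id = "b", label = "b")))),
               edges = list(list(from = "q1", default = TRUE,
                                 to = "TERMINAL")))
  expect_error(load_graph(def4), class = "unknown_symptom_code")
  expect_error(load_graph(def4), "nope")

  # missing default edge
  def5 <- list(version = "t", vocabulary = list("x"),
               questions = list(base_q("q1")),
               edges = list(list(from = "q1",
                                 when = list(any_of = list("a")),
                                 to = "TERMINAL")))
  expect_error(load_graph(def5), class = "graph_incomplete")
})

test_that("session eligibility and consent gates are enforced", {
  s <- start_session(53, TRUE, "online", started_at = T0)
  expect_s3_class(s, "triage_session")
  expect_identical(next_question(s, the_graph)$id, the_graph$entry)
  expect_error(start_session(12, TRUE, "online"), class = "ineligible_age")
  expect_error(start_session(53, FALSE, "online"),
               class = "consent_refused")
  # upper end of the observed study range is eligible
  s90 <- start_session(90, TRUE, "telephone", started_at = T0)
  expect_identical(s90$mode, "telephone")
})

test_that("transcripts are append-only and respect traversal order", {
  g <- the_graph
  s <- start_session(53, TRUE, "online", order_reference = "X-1",
                     started_at = T0)
  # answering a question that is not pending
  expect_error(record_answer(s, g, "q_red_symptoms", "redness"),
               class = "out_of_order_answer")
  # two options on the single-select filter question
  expect_error(record_answer(s, g, "q_filter", c("vision", "eyelid")),
               class = "cardinality_error")
  expect_error(record_answer(s, g, "q_filter", "not_an_option"),
               class = "unknown_option")
  s <- record_answer(s, g, "q_filter", "red_painful")
  expect_length(s$answers, 1L)
  # re-answering an already-answered question
  expect_error(record_answer(s, g, "q_filter", "vision"),
               class = "out_of_order_answer")
  s <- record_answer(s, g, "q_red_symptoms", c("redness", "pain_mild"))
  expect_setequal(s$codes, c("red_eye", "eye_pain_mild"))
  # cannot finish before the terminal state
  expect_error(finish_session(s, g, T0 + 60),
               class = "unfinished_session")
  s <- record_answer(s, g, "q_red_assoc", "none")
  expect_identical(next_question(s, g), "TERMINAL")
  # transcript completeness: every question on the taken path answered
  expect_identical(vapply(s$answers, `[[`, character(1), "question_id"),
                   c("q_filter", "q_red_symptoms", "q_red_assoc"))
  expect_error(finish_session(s, g, T0 - 1), class = "invalid_timestamps")
  s <- finish_session(s, g, T0 + 297)
  expect_equal(session_duration(s), 297)
})

test_that("trauma answers terminate the questionnaire early", {
  g <- the_graph
  s <- start_session(40, TRUE, "online", started_at = T0)
  s <- record_answer(s, g, "q_filter", "injury")
  s <- record_answer(s, g, "q_injury_type", "chemical")
  expect_identical(next_question(s, g), "TERMINAL")
  expect_identical(s$trauma, "chemical")
})

test_that("identical scripts yield identical traversals and durations", {
  script <- the_pool$cl_keratitis$script
  s1 <- run_answers(the_graph, script, age = 60, order_reference = "D-1",
                    started_at = T0, finished_at = T0 + 150)
  s2 <- run_answers(the_graph, script, age = 60, order_reference = "D-1",
                    started_at = T0, finished_at = T0 + 150)
  expect_identical(s1, s2)
  expect_equal(session_duration(s1), 150)
  s0 <- run_answers(the_graph, script, started_at = T0, finished_at = T0)
  expect_equal(session_duration(s0), 0)
  expect_error(session_duration(start_session(50, TRUE, "online")),
               class = "unfinished_session")
})

test_that("accepted graphs always terminate within 25 questions", {
  # exhaustive path enumeration on the shipped graph
  paths <- graph_paths(the_graph)
  expect_gt(length(paths), 0L)
  expect_true(all(lengths(paths) <= 25L))
  # property: random forward-edge graphs either fail validation with a
  # classed error or terminate on every random walk
  set.seed(42)
  for (rep in 1:25) {
    def <- random_graph_def(sample(2:10, 1))
    g <- tryCatch(load_graph(def),
                  triage_error = function(e) NULL)
    if (is.null(g)) next
    expect_true(all(lengths(graph_paths(g)) <= 25L))
    s <- random_session(g)
    expect_identical(next_question(s, g), "TERMINAL")
  }
})

test_that("sessions round-trip losslessly through JSON", {
  s <- run_answers(the_graph, the_pool$angle_closure$script, age = 67,
                   order_reference = "RT-1", started_at = T0,
                   finished_at = T0 + 200, laterality = "left",
                   free_text = "worse at night")
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  expect_identical(read_session(path), s)
})
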