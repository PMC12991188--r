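# Shared fixtures and independent oracles, built in code.

the_graph <- default_graph()
the_table <- default_acuity_table()
the_pool <- default_archetypes()

T0 <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")

# random complete traversal of a graph using the current RNG stream
random_session <- function(graph, order_reference = "R-1") {
  s <- start_session(age = sample(13:90, 1), consent = TRUE,
                     mode = "online", order_reference = order_reference,
                     started_at = T0)
  repeat {
    q <- next_question(s, graph)
    if (identical(q, "TERMINAL")) break
    ids <- names(q$options)
    pick <- if (q$select == "single") ids[sample.int(length(ids), 1L)]
            else sample(ids, sample.int(length(ids), 1L))
    s <- record_answer(s, graph, q$id, pick)
  }
  finish_session(s, graph, T0 + 120)
}

# a synthetic finished session carrying an arbitrary asserted-code set,
# for rating-level property tests
session_with_codes <- function(codes, trauma = character(0)) {
  structure(list(order_reference = "SYN-1", age = 50L, consent = TRUE,
                 mode = "online", laterality = "unknown", free_text = NULL,
                 answers = list(), codes = codes, trauma = trauma,
                 started_at = T0, finished_at = T0 + 60),
            class = "triage_session")
}

# --- independent oracles -----------------------------------------------

# accuracy metrics recomputed directly from raw label vectors
oracle_sensitivity <- function(pred, gold) 100 * mean(pred[gold])
oracle_specificity <- function(pred, gold) 100 * mean(!pred[!gold])

oracle_kappa <- function(a, b) {
  tab <- table(factor(a, levels = c(FALSE, TRUE)),
               factor(b, levels = c(FALSE, TRUE)))
  e1071::classAgreement(tab)$kappa
}

# Mann-Whitney U by brute-force pairwise comparison, ties counted 1/2
oracle_U <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# chi-square(1) upper tail by numerical integration of the density
oracle_chisq_tail <- function(stat) {
  if (stat == 0) return(1)
  stats::integrate(function(x) stats::dchisq(x, df = 1),
                   lower = stat, upper = Inf,
                   rel.tol = 1e-13)$value
}

# expand confusion counts into aligned label vectors
expand_labels <- function(tp, fp, fn, tn) {
  list(pred = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fp, fn, tn)),
       gold = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fp, fn, tn)))
}

# random forward-edge questionnaire definitions for termination
# property tests (forward edges only, so accepted graphs are DAGs)
random_graph_def <- function(nq) {
  qs <- lapply(seq_len(nq), function(i) {
    nopt <- sample(2:4, 1)
    list(id = paste0("q", i), text = paste("question", i),
         select = "single",
         options = lapply(seq_len(nopt), function(j) {
           list(id = paste0("o", j), label = paste("option", j))
         }))
  })
  edges <- list()
  for (i in seq_len(nq)) {
    if (i < nq && stats::runif(1) < 0.6) {
      edges <- c(edges, list(list(
        from = paste0("q", i),
        when = list(any_of = list("o1")),
        to = paste0("q", sample((i + 1):nq, 1))
      )))
    }
    def_to <- if (i < nq && stats::runif(1) > 0.15) paste0("q", i + 1)
              else "TERMINAL"
    edges <- c(edges, list(list(from = paste0("q", i), default = TRUE,
                                to = def_to)))
  }
  list(version = "t", vocabulary = list("x"), questions = qs,
       edges = edges)
}
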