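tp <- test_params()

test_that("the new-representation rule needs rejection plus a clear margin", {
  expect_true(remfear:::creation_due(-6, -12, tp))    # margin 6 > delta
  expect_false(remfear:::creation_due(-6, -8, tp))    # margin 2: blocked
  expect_false(remfear:::creation_due(-4, -20, tp))   # winner above B_new
  expect_true(remfear:::creation_due(-7, NA, tp))     # no runner-up
  expect_true(remfear:::creation_due(-Inf, -Inf, tp)) # all hopeless
  expect_true(remfear:::creation_due(NA, NA, tp))     # no candidates
})

test_that("a naive agent creates a representation at the first interval", {
  set.seed(41)
  w <- make_world(tp)
  w <- add_category(w, "X")
  w <- add_context(w, "A", "X")
  agent <- make_agent(w, known_categories = character(0))
  res <- run_session(agent, session_spec("A", 5))
  expect_equal(res$summary$rep_created_at, 1)
  expect_equal(nrow(res$trace), 5)
  # the new representation is immediately active and stays so
  expect_equal(unique(res$trace$active_rep), res$trace$active_rep[1])
  expect_true(all(res$trace$kind == "hipp"))
})

test_that("a single live representation always wins the decision", {
  set.seed(42)
  w <- make_world(tp)
  w <- add_category(w, "X")
  w <- add_context(w, "A", "X")
  agent <- make_agent(w, known_categories = character(0))
  r1 <- run_session(agent, session_spec("A", 40))
  r2 <- run_session(r1$agent, session_spec("A", 40))
  expect_equal(length(unique(r2$trace$active_rep)), 1)
  expect_true(all(diff(r2$trace$z_com) >= 0))
})

test_that("a novel context in a known category is first mistaken for an established one", {
  set.seed(43)
  w <- remfear:::standard_world(tp)
  agent <- remfear:::standard_agent(w, "expected_value")
  res <- run_session(agent, remfear:::conditioning_session("A"))
  first <- res$trace[1, ]
  expect_equal(first$kind, "cort")
  expect_equal(agent$reps[[first$active_rep]]$ctx, "EX")  # same category
  # ... until the evidence collapses and a representation of A is created
  expect_false(is.na(res$summary$rep_created_at))
  expect_gt(res$summary$rep_created_at, 40)
})

test_that("session traces have the documented shape and summary", {
  set.seed(44)
  w <- remfear:::standard_world(tp)
  agent <- remfear:::standard_agent(w, "expected_value")
  res <- run_session(agent, remfear:::conditioning_session("A"))
  tr <- res$trace
  expect_equal(nrow(tr), 76)
  expect_equal(tr$z_cur, 1:76)
  expect_true(all(c("active_rep", "kind", "b_rep", "cnd", "fear",
                    "created") %in% names(tr)))
  expect_equal(res$summary$mean_fear, mean(tr$fear))
  expect_true(all(tr$fear >= 0 & tr$fear <= 1))
  path <- tempfile(fileext = ".csv"); on.exit(unlink(path))
  write_trace(tr, path)
  expect_equal(nrow(read.csv(path)), 76)
})

test_that("conditioning requires a representation above the threshold", {
  set.seed(45)
  w <- remfear:::standard_world(tp)
  agent <- remfear:::standard_agent(w, "expected_value")
  # an immediate shock (interval 5) falls on a low-confidence established
  # representation: conditionability is ~0 and no fear is ever learned
  res <- run_session(agent, session_spec("A", 76, us_interval = 5))
  test <- run_session(res$agent, session_spec("A", 95))
  expect_lt(test$summary$mean_fear, 0.05)
  # a late shock (interval 75, after the representation of A exists)
  # produces strong fear in a later test
  res2 <- run_session(agent, remfear:::conditioning_session("A"))
  test2 <- run_session(res2$agent, session_spec("A", 95))
  expect_gt(test2$summary$mean_fear, 0.8)
})

test_that("hippocampal inactivation silences recent fear and blocks creation", {
  set.seed(46)
  w <- remfear:::standard_world(tp)
  agent <- remfear:::standard_agent(w, "expected_value")
  res <- run_session(agent, remfear:::conditioning_session("A"))
  inact <- run_session(res$agent,
                       session_spec("A", 95, hippocampus_inactivated = TRUE))
  expect_lt(inact$summary$mean_fear, 0.01)
  expect_true(is.na(inact$summary$rep_created_at))
  expect_true(all(inact$trace$kind %in% c("cort", NA)))
})

test_that("stochastic and expected-value modes agree qualitatively", {
  set.seed(47)
  w <- remfear:::standard_world(tp)
  agent_s <- remfear:::standard_agent(w, "stochastic")
  res <- run_session(agent_s, remfear:::conditioning_session("A"))
  expect_false(is.na(res$summary$rep_created_at))
  expect_gt(res$summary$rep_created_at, 30)
  test <- run_session(res$agent, session_spec("A", 95))
  expect_gt(test$summary$mean_fear, 0.6)
})

test_that("unknown experiment names are rejected with the registry", {
  expect_error(run_experiment("nope", tp), "should be one of")
  expect_setequal(list_experiments(),
                  c("novel_context_known_category",
                    "novel_context_unknown_category", "pre_exposure",
                    "hyper_generalization", "stage2_similarity",
                    "familiar_test_context", "cross_category",
                    "well_known_context", "reminder"))
})
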