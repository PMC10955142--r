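# Behavioural properties of the scripted protocols, all at the reduced DG
# profile (event coordinates do not depend on N_dg; fear magnitudes only
# through CA3 overlap tails).

test_that("remote fear hyper-generalizes to an unfamiliar same-category context", {
  r <- cached_experiment("hyper_generalization")
  a <- function(arm, col = "mean_fear") arm_value(r, arm, col)
  # fear of the conditioned context is high at both stages
  expect_gt(a("recent-A"), 0.85)
  expect_gt(a("remote-A"), 0.85)
  # generalization to unfamiliar B is substantially higher remote than recent
  expect_gt(a("remote-B"), a("recent-B") + 0.15)
  # remote fear of B approaches fear of A itself
  expect_gt(a("remote-B"), 0.75 * a("remote-A"))
  # the un-feared representation of B is created much later remote than recent
  expect_gt(a("remote-B", "rep_created_at"), a("recent-B", "rep_created_at") + 15)
})

test_that("hippocampal inactivation abolishes recent but not remote fear", {
  r <- cached_experiment("hyper_generalization")
  a <- function(arm) arm_value(r, arm)
  expect_lt(a("recent-A-inact"), 0.05)
  expect_gt(a("remote-A-inact"), 0.85)
  expect_lt(abs(a("remote-A-inact") - a("remote-A")), 0.05)
  expect_lt(a("recent-B-inact"), 0.05)
  expect_gt(a("remote-B-inact"), 0.5)
})

test_that("no hyper-generalization when the test context is familiar", {
  r <- cached_experiment("familiar_test_context")
  hg <- cached_experiment("hyper_generalization")
  recent <- arm_value(r, "recent-B"); remote <- arm_value(r, "remote-B")
  # cortical-cortical generalization slightly exceeds hippocampal overlap
  expect_gt(remote, recent)
  # but nothing like the unfamiliar-context case: fear of familiar B stays
  # far below fear of the conditioned context
  expect_lt(remote, arm_value(hg, "remote-B") - 0.2)
  expect_lt(remote, 0.6 * arm_value(hg, "remote-A"))
})

test_that("cross-category generalization is hypo, not hyper", {
  r <- cached_experiment("cross_category")
  expect_lte(arm_value(r, "remote-C"), arm_value(r, "recent-C"))
})

test_that("no hyper-generalization when the conditioned context is extremely well-known", {
  r <- cached_experiment("well_known_context")
  hg <- cached_experiment("hyper_generalization")
  recent <- arm_value(r, "recent-B"); remote <- arm_value(r, "remote-B")
  expect_gte(remote, recent - 0.02)                 # at most slightly above
  expect_lt(remote - recent, 0.15)
  expect_lt(remote, arm_value(hg, "remote-B") - 0.3)
})

test_that("stage II activates the hippocampal version for similar and the cortical for dissimilar test contexts", {
  r <- cached_experiment("stage2_similarity")
  expect_equal(r$events$similar_active, "hippocampal")
  expect_equal(r$events$dissimilar_active, "cortical")
  # fear is hippocampus-dependent throughout Stage II
  expect_gt(arm_value(r, "stageII-Bsim"), 0.5)
})

test_that("a reminder restores specificity and hippocampus-dependence", {
  r <- cached_experiment("reminder")
  hg <- cached_experiment("hyper_generalization")
  a <- function(arm) arm_value(r, arm)
  expect_true(r$events$updated_after_reminder)
  expect_equal(r$events$post_reminder_stage, "I")
  # generalization to B drops from the hyper level back near the recent level
  expect_gt(a("pre-reminder-B"), 0.75)
  expect_lt(a("post-reminder-B"), a("pre-reminder-B") - 0.2)
  expect_lt(abs(a("post-reminder-B") - arm_value(hg, "recent-B")), 0.1)
  # fear is hippocampus-dependent again after the reminder
  expect_gt(a("pre-reminder-B-inact"), 0.5)
  expect_lt(a("post-reminder-B-inact"), 0.05)
  # fear of the conditioned context itself is preserved
  expect_gt(a("post-reminder-A"), 0.9)
})

test_that("blocking new learning during the reminder prevents the effect", {
  r <- cached_experiment("reminder")
  expect_lt(abs(arm_value(r, "blocked-reminder-B") -
                arm_value(r, "pre-reminder-B")), 0.05)
})

test_that("representations form sooner in unknown categories and after pre-exposure", {
  known <- cached_experiment("novel_context_known_category")
  unknown <- cached_experiment("novel_context_unknown_category")
  pre <- cached_experiment("pre_exposure")
  # unknown category: creation much earlier (shorter immediate shock deficit)
  expect_lt(unknown$events$rep_created_at,
            known$events$rep_created_at - 20)
  # pre-exposure: conditioning becomes possible within a few intervals
  expect_lt(pre$events$b_cnd_cross, 10)
  expect_lt(pre$events$half_cnd_cross, 20)
  expect_lt(pre$events$half_cnd_cross, known$events$rep_created_at)
  # remote representations condition more slowly than recent ones
  expect_gt(pre$events$remote_b_cnd_cross, pre$events$b_cnd_cross)
  expect_gt(pre$events$remote_half_cnd_cross, pre$events$half_cnd_cross)
})

test_that("expected-value runs are reproducible and reports serializable", {
  r1 <- run_experiment("novel_context_unknown_category", test_params(),
                       seed = 5)
  r2 <- run_experiment("novel_context_unknown_category", test_params(),
                       seed = 5)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$sessions$conditioning$b_rep,
                   r2$sessions$conditioning$b_rep)
  skip_if_not_installed("jsonlite")
  dir <- tempfile(); on.exit(unlink(dir, recursive = TRUE))
  write_report(r1, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "trace_conditioning.csv")))
})
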