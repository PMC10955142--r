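# One conditioned preparation shared by the stage-machine tests: standard
# world, conditioning session in A (US at interval 75).
tp <- test_params()
set.seed(31)
base_world <- remfear:::standard_world(tp)
base_agent <- remfear:::standard_agent(base_world, "expected_value")
cond <- run_session(base_agent, remfear:::conditioning_session("A"))
conditioned <- cond$agent

test_that("stage I to II builds the cortical version on the progenitor CA3 set", {
  a <- advance_stage(conditioned, "A")
  expect_equal(record_stage(a, "A"), "II")
  ri <- remfear:::record_index(a, "A")
  rec <- a$records[[ri]]
  hipp <- a$reps[[rec$hipp]]; cort <- a$reps[[rec$cort]]
  expect_identical(cort$ca3, hipp$ca3)
  expect_equal(cort$category, "X")
  expect_false(hipp$erased)
  # advancing a Stage III record errors
  a3 <- advance_stage(a, "A")
  expect_error(advance_stage(a3, "A"), "Stage III")
})

test_that("stage II to III transfers fear and erases the hippocampal version", {
  a <- advance_stage(conditioned, "A")
  ri <- remfear:::record_index(a, "A")
  rec <- a$records[[ri]]
  w_before <- remfear:::sum_w_hipp(a$amy, a$reps[[rec$hipp]]$ca3)
  expect_equal(w_before, 1)          # one maximal US with alpha = 1/K
  fear_before <- express_fear(
    remfear:::fear_drive(a, a$reps[[rec$hipp]]), 4, tp)$fear
  a <- advance_stage(a, "A")
  expect_equal(record_stage(a, "A"), "III")
  expect_equal(remfear:::w_cort_of(a$amy, rec$cort), w_before)
  hipp <- a$reps[[rec$hipp]]
  expect_true(hipp$erased)
  expect_length(hipp$ca3, tp$K)      # progenitor links survive erasure
  expect_equal(remfear:::sum_w_hipp(a$amy, hipp$ca3), 0)
  # fear conservation: the cortical version expresses the same fear at the
  # same weight of evidence as its fully active progenitor did
  fear_after <- express_fear(
    remfear:::fear_drive(a, a$reps[[rec$cort]]), 4, tp)$fear
  expect_equal(fear_after, fear_before)
})

test_that("an unconditioned record transfers zero weight", {
  # the established contexts went through the full stage sequence without
  # ever being conditioned
  for (ctx in c("EX", "EY")) {
    rj <- remfear:::record_index(conditioned, ctx)
    expect_equal(record_stage(conditioned, ctx), "III")
    expect_equal(
      remfear:::w_cort_of(conditioned$amy, conditioned$records[[rj]]$cort), 0)
  }
})

test_that("amygdala NMDA block prevents fear transfer but not replacement", {
  a <- advance_stage(conditioned, "A")
  blocked <- set_nmda_block(a, amygdala = TRUE)
  blocked <- advance_stage(blocked, "A")
  unblocked <- advance_stage(a, "A")
  ri <- remfear:::record_index(blocked, "A")
  rec <- blocked$records[[ri]]
  expect_equal(record_stage(blocked, "A"), "III")
  expect_true(blocked$reps[[rec$hipp]]$erased)
  expect_equal(remfear:::w_cort_of(blocked$amy, rec$cort), 0)
  # remote fear abolished at any confidence
  fear <- express_fear(
    remfear:::fear_drive(blocked, blocked$reps[[rec$cort]]), 20, tp)$fear
  expect_equal(fear, 0)
  # the cortical representation's content is unaffected by the block
  expect_identical(blocked$reps[[rec$cort]]$know,
                   unblocked$reps[[rec$cort]]$know)
})

test_that("updating returns a remote record to Stage I with fear retained", {
  a <- advance_stage(conditioned, "A")
  a <- advance_stage(a, "A")
  rem <- run_session(a, session_spec("A", 60))     # reminder exposure
  expect_true(rem$summary$updated)
  a2 <- rem$agent
  expect_equal(record_stage(a2, "A"), "I")
  ri <- remfear:::record_index(a2, "A")
  rec <- a2$records[[ri]]
  hipp <- a2$reps[[rec$hipp]]
  expect_false(hipp$erased)
  expect_gte(remfear:::know_zrec(hipp$know), 60)
  # reconstructed on the stored progenitor CA3 set
  expect_identical(hipp$ca3, a2$reps[[rec$cort]]$ca3)
  # cortical fear weight retained and expressible through the CA3 route
  expect_equal(remfear:::w_cort_of(a2$amy, rec$cort), 1)
  fear <- express_fear(remfear:::fear_drive(a2, hipp), 4, tp)$fear
  expect_equal(fear, 1)
})

test_that("updating a hippocampal record unions attributes without a stage change", {
  a <- conditioned                                  # Stage I record for A
  z0 <- remfear:::know_zrec(
    a$reps[[a$records[[remfear:::record_index(a, "A")]]$hipp]]$know)
  res <- run_session(a, session_spec("A", 95))      # long re-exposure
  expect_true(res$summary$updated)
  a2 <- res$agent
  expect_equal(record_stage(a2, "A"), "I")
  z1 <- remfear:::know_zrec(
    a2$reps[[a2$records[[remfear:::record_index(a2, "A")]]$hipp]]$know)
  expect_gte(z1, z0)
})

test_that("a learning NMDA block makes updating a no-op", {
  a <- advance_stage(conditioned, "A")
  a <- advance_stage(a, "A")
  blocked <- set_nmda_block(a, learning = TRUE)
  rem <- run_session(blocked, session_spec("A", 60))
  expect_equal(record_stage(rem$agent, "A"), "III")   # still remote
  ri <- remfear:::record_index(rem$agent, "A")
  expect_equal(remfear:::w_cort_of(rem$agent$amy, rem$agent$records[[ri]]$cort), 1)
})
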