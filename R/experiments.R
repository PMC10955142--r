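## ---- Standard experimental worlds -----------------------------------------

## The canonical single-agent preparation: a to-be-conditioned context A in
## category X, plus one long-established context in the same category (EX)
## and one in a different category (EY), with the standard unrelated-context
## overlaps. Generalization-test contexts are added per protocol.
standard_world <- function(params) {
  w <- make_world(params)
  w <- add_category(w, "X")
  w <- add_category(w, "Y", anchor = "X", o_cat = params$O_catHet)
  w <- add_context(w, "A", "X")
  w <- add_context(w, "EX", "X", anchor = "A", o_ptc = params$O_ptcHom)
  w <- add_context(w, "EY", "Y", anchor = "A", o_ptc = params$O_ptcHet)
  w
}

standard_agent <- function(world, mode, known_categories = c("X", "Y"),
                           established = c("EX", "EY")) {
  agent <- make_agent(world, mode, known_categories)
  for (ctx in established) agent <- establish_context(agent, ctx)
  agent
}

conditioning_session <- function(context)
  session_spec(context, length = 76, us_interval = 75)

test_session <- function(context, inactivated = FALSE)
  session_spec(context, length = 95,
               hippocampus_inactivated = inactivated)

run_test_arm <- function(agent, context, stage, inactivated = FALSE,
                         arm = NULL) {
  res <- run_session(agent, test_session(context, inactivated))
  s <- res$summary
  if (is.null(arm))
    arm <- paste0(stage, "-", context, if (inactivated) "-inact" else "")
  data.frame(arm = arm, test_context = context, stage = stage,
             inactivated = inactivated, mean_fear = s$mean_fear,
             rep_created_at = s$rep_created_at,
             decline_onset = s$decline_onset,
             stringsAsFactors = FALSE)
}

#' Registered experiments
#' @return Character vector of experiment names accepted by
#'   \code{\link{run_experiment}}.
#' @export
list_experiments <- function() {
  c("novel_context_known_category", "novel_context_unknown_category",
    "pre_exposure", "hyper_generalization", "stage2_similarity",
    "familiar_test_context", "cross_category", "well_known_context",
    "reminder")
}

#' Run a scripted experiment
#'
#' Each experiment is a fixed session protocol over a synthetic context
#' world built to the package's standard overlap structure. Conditioning
#' sessions are 76 intervals with the unconditioned stimulus at interval
#' 75; test sessions are 95 intervals. The protocols:
#' \describe{
#'   \item{novel_context_known_category}{A naive-to-A agent with
#'     established remote contexts in categories X and Y is placed in a
#'     novel context A of known category X and conditioned. Reports when
#'     the new representation is created (the immediate shock deficit is
#'     long because A is first mistaken for the established same-category
#'     context).}
#'   \item{novel_context_unknown_category}{Same, but the agent knows only
#'     category Y; the representation is created much earlier.}
#'   \item{pre_exposure}{A representation-creating pre-exposure session in
#'     A, then a conditioning session. Reports the conditioning-threshold
#'     and half-conditionability coordinates (much earlier than without
#'     pre-exposure). A remote arm repeats the conditioning session after
#'     consolidating A to Stage III (slower evidence growth).}
#'   \item{hyper_generalization}{Condition A; test in A and in an
#'     unfamiliar same-category context B (particular overlap 0.6),
#'     recent (Stage I) versus remote (Stage III), each intact versus
#'     hippocampus-inactivated.}
#'   \item{stage2_similarity}{Condition A, advance to Stage II, test in a
#'     very similar and in a dissimilar unfamiliar context; reports which
#'     version (hippocampal or cortical) of A's representation is active.}
#'   \item{familiar_test_context}{Pre-expose B, condition A, test in B
#'     recent versus remote (both representations consolidated); no
#'     hyper-generalization.}
#'   \item{cross_category}{Condition A, test in an unfamiliar context of a
#'     different category (particular overlap 0.75, categorical 0.2):
#'     remote generalization is at most the recent level
#'     (hypo-generalization).}
#'   \item{well_known_context}{Pre-expose A to Z_cur = 98 before
#'     conditioning; remote generalization to B (particular overlap 0.8)
#'     barely exceeds recent.}
#'   \item{reminder}{Condition A, consolidate to Stage III, then a
#'     60-interval reminder exposure to A triggers updating; tests in B
#'     show generalization back near the recent level and fear again
#'     hippocampus-dependent. A learning-block arm shows the reminder has
#'     no effect when new learning is prevented.}
#' }
#'
#' @param name one of \code{\link{list_experiments}}.
#' @param params a \code{\link{fear_params}} object.
#' @param seed integer seed for all randomness in the run.
#' @param mode \code{"expected_value"} (deterministic trajectories) or
#'   \code{"stochastic"}.
#' @param n_mc_g Monte-Carlo replicates for the generalization table, when
#'   the protocol needs one.
#' @return A list with \code{name}, \code{arms} (data frame of mean fear
#'   and event coordinates per arm), \code{events} (named key coordinates)
#'   and \code{sessions} (traces of the protocol's formative sessions).
#' @export
run_experiment <- function(name, params = fear_params(), seed = 1,
                           mode = c("expected_value", "stochastic"),
                           n_mc_g = 8) {
  mode <- match.arg(mode)
  name <- match.arg(name, list_experiments())
  set.seed(seed)
  fn <- switch(name,
    novel_context_known_category = exp_novel_known,
    novel_context_unknown_category = exp_novel_unknown,
    pre_exposure = exp_pre_exposure,
    hyper_generalization = exp_hyper_generalization,
    stage2_similarity = exp_stage2_similarity,
    familiar_test_context = exp_familiar_test,
    cross_category = exp_cross_category,
    well_known_context = exp_well_known,
    reminder = exp_reminder)
  out <- fn(params, mode, n_mc_g)
  out$name <- name
  out$seed <- seed
  out$mode <- mode
  out
}

exp_novel_known <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  agent <- standard_agent(w, mode)
  res <- run_session(agent, conditioning_session("A"))
  list(arms = NULL,
       events = list(rep_created_at = res$summary$rep_created_at),
       sessions = list(conditioning = res$trace))
}

exp_novel_unknown <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  agent <- standard_agent(w, mode, known_categories = "Y",
                          established = "EY")
  res <- run_session(agent, conditioning_session("A"))
  list(arms = NULL,
       events = list(rep_created_at = res$summary$rep_created_at),
       sessions = list(conditioning = res$trace))
}

exp_pre_exposure <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  agent <- standard_agent(w, mode)
  pre <- run_session(agent, session_spec("A", 76))
  agent <- pre$agent
  recent <- run_session(agent, conditioning_session("A"))
  remote_agent <- agent
  remote_agent <- advance_stage(remote_agent, "A")
  remote_agent <- advance_stage(remote_agent, "A")
  remote <- run_session(remote_agent, conditioning_session("A"))
  list(arms = NULL,
       events = list(
         rep_created_at = pre$summary$rep_created_at,
         b_cnd_cross = recent$summary$b_cnd_cross,
         half_cnd_cross = recent$summary$half_cnd_cross,
         remote_b_cnd_cross = remote$summary$b_cnd_cross,
         remote_half_cnd_cross = remote$summary$half_cnd_cross),
       sessions = list(pre_exposure = pre$trace,
                       conditioning = recent$trace,
                       remote_conditioning = remote$trace))
}

exp_hyper_generalization <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  w <- add_context(w, "B", "X", anchor = "A", o_ptc = 0.6)
  agent <- standard_agent(w, mode)
  cond <- run_session(agent, conditioning_session("A"))
  recent_agent <- cond$agent
  remote_agent <- advance_stage(recent_agent, "A")
  remote_agent <- advance_stage(remote_agent, "A")
  remote_agent <- build_g_table(remote_agent, n_mc_g)
  arms <- list()
  for (ctx in c("A", "B")) for (inact in c(FALSE, TRUE)) {
    arms[[length(arms) + 1]] <- run_test_arm(recent_agent, ctx, "recent", inact)
    arms[[length(arms) + 1]] <- run_test_arm(remote_agent, ctx, "remote", inact)
  }
  arms <- do.call(rbind, arms)
  t4 <- arms$decline_onset[arms$arm == "recent-B"]
  list(arms = arms,
       events = list(recent_B_decline_onset = t4),
       sessions = list(conditioning = cond$trace))
}

exp_stage2_similarity <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  w <- add_context(w, "Bsim", "X", anchor = "A", o_ptc = 0.8)
  w <- add_context(w, "Bdis", "X", anchor = "A", o_ptc = 0.2)
  agent <- standard_agent(w, mode)
  cond <- run_session(agent, conditioning_session("A"))
  agent <- advance_stage(cond$agent, "A")   # Stage II: both versions live
  ri <- record_index(agent, "A")
  hipp_id <- agent$records[[ri]]$hipp
  cort_id <- agent$records[[ri]]$cort
  active_version <- function(trace) {
    ids <- trace$active_rep
    n_h <- sum(ids == hipp_id, na.rm = TRUE)
    n_c <- sum(ids == cort_id, na.rm = TRUE)
    if (n_h >= n_c) "hippocampal" else "cortical"
  }
  sim <- run_session(agent, test_session("Bsim"))
  dis <- run_session(agent, test_session("Bdis"))
  arms <- rbind(run_test_arm(agent, "Bsim", "stageII"),
                run_test_arm(agent, "Bdis", "stageII"))
  list(arms = arms,
       events = list(similar_active = active_version(sim$trace),
                     dissimilar_active = active_version(dis$trace)),
       sessions = list(similar = sim$trace, dissimilar = dis$trace))
}

exp_familiar_test <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  w <- add_context(w, "B", "X", anchor = "A", o_ptc = 0.6)
  agent <- standard_agent(w, mode)
  preB <- run_session(agent, session_spec("B", 76))
  cond <- run_session(preB$agent, conditioning_session("A"))
  recent_agent <- cond$agent
  remote_agent <- recent_agent
  for (ctx in c("A", "B")) {
    remote_agent <- advance_stage(remote_agent, ctx)
    remote_agent <- advance_stage(remote_agent, ctx)
  }
  remote_agent <- build_g_table(remote_agent, n_mc_g)
  arms <- rbind(run_test_arm(recent_agent, "B", "recent"),
                run_test_arm(remote_agent, "B", "remote"))
  list(arms = arms, events = list(),
       sessions = list(pre_exposure_B = preB$trace,
                       conditioning = cond$trace))
}

exp_cross_category <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  w <- add_category(w, "Z", anchor = "X", o_cat = params$O_catHet)
  w <- add_context(w, "C", "Z", anchor = "A", o_ptc = 0.75)
  agent <- standard_agent(w, mode)   # category Z itself is not known
  cond <- run_session(agent, conditioning_session("A"))
  recent_agent <- cond$agent
  remote_agent <- advance_stage(recent_agent, "A")
  remote_agent <- advance_stage(remote_agent, "A")
  remote_agent <- build_g_table(remote_agent, n_mc_g)
  arms <- rbind(run_test_arm(recent_agent, "C", "recent"),
                run_test_arm(remote_agent, "C", "remote"))
  list(arms = arms, events = list(),
       sessions = list(conditioning = cond$trace))
}

exp_well_known <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  w <- add_context(w, "B", "X", anchor = "A", o_ptc = 0.8)
  agent <- standard_agent(w, mode)
  pre <- run_session(agent, session_spec("A", 98))
  cond <- run_session(pre$agent, conditioning_session("A"))
  recent_agent <- cond$agent
  remote_agent <- advance_stage(recent_agent, "A")
  remote_agent <- advance_stage(remote_agent, "A")
  remote_agent <- build_g_table(remote_agent, n_mc_g)
  arms <- rbind(run_test_arm(recent_agent, "B", "recent"),
                run_test_arm(remote_agent, "B", "remote"))
  list(arms = arms, events = list(),
       sessions = list(pre_exposure = pre$trace,
                       conditioning = cond$trace))
}

exp_reminder <- function(params, mode, n_mc_g) {
  w <- standard_world(params)
  w <- add_context(w, "B", "X", anchor = "A", o_ptc = 0.6)
  agent <- standard_agent(w, mode)
  cond <- run_session(agent, conditioning_session("A"))
  remote_agent <- advance_stage(cond$agent, "A")
  remote_agent <- advance_stage(remote_agent, "A")
  remote_agent <- build_g_table(remote_agent, n_mc_g)
  pre_arms <- rbind(
    run_test_arm(remote_agent, "B", "remote", arm = "pre-reminder-B"),
    run_test_arm(remote_agent, "B", "remote", TRUE,
                 arm = "pre-reminder-B-inact"))
  rem <- run_session(remote_agent, session_spec("A", 60))
  post_agent <- rem$agent
  post_arms <- rbind(
    run_test_arm(post_agent, "B", "post-reminder", arm = "post-reminder-B"),
    run_test_arm(post_agent, "B", "post-reminder", TRUE,
                 arm = "post-reminder-B-inact"),
    run_test_arm(post_agent, "A", "post-reminder", arm = "post-reminder-A"))
  blocked_agent <- set_nmda_block(remote_agent, learning = TRUE)
  remb <- run_session(blocked_agent, session_spec("A", 60))
  blocked_arms <- run_test_arm(remb$agent, "B", "blocked-reminder",
                               arm = "blocked-reminder-B")
  arms <- rbind(pre_arms, post_arms, blocked_arms)
  list(arms = arms,
       events = list(updated_after_reminder = rem$summary$updated,
                     post_reminder_stage = record_stage(post_agent, "A")),
       sessions = list(conditioning = cond$trace, reminder = rem$trace))
}

#' Write an experiment report to a directory
#'
#' Writes \code{summary.json} (arms and events) and one
#' \code{trace_<session>.csv} per stored session.
#'
#' @param report a list from \code{\link{run_experiment}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required to write reports")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(name = report$name, seed = report$seed, mode = report$mode,
         arms = report$arms, events = report$events),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (nm in names(report$sessions))
    utils::write.csv(report$sessions[[nm]],
                     file.path(dir, paste0("trace_", nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
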