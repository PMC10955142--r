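#' Specify a session
#'
#' @param context context id the agent is placed in.
#' @param length session length in computational intervals (one new
#'   attribute observed per interval; must not exceed \code{N_atr}).
#' @param us_interval interval at which an unconditioned stimulus occurs,
#'   or \code{NA} for none.
#' @param hippocampus_inactivated if \code{TRUE}, hippocampal
#'   representations neither compete for activation nor contribute to
#'   fear expression during the session.
#' @return A list of class \code{"session_spec"}.
#' @export
session_spec <- function(context, length, us_interval = NA,
                         hippocampus_inactivated = FALSE) {
  stopifnot(length >= 1, is.na(us_interval) || us_interval <= length)
  structure(list(context = context, length = length,
                 us_interval = us_interval,
                 hippocampus_inactivated = hippocampus_inactivated),
            class = "session_spec")
}

## ---- Decision phase -------------------------------------------------------

## candidate representations: every cortical representation of a record in
## Stage II or III, plus the single hippocampal representation that the
## current observations activate (content-addressable recall) among records
## in Stage I or II. A cortical version under revision (Stage I record
## after updating) does not compete.
decision_phase <- function(agent, spec, z_cur, observed_set = NULL) {
  p <- agent$params
  w <- agent$world
  hipp_ids <- character(0); cort_ids <- character(0)
  for (rec in agent$records) {
    if (rec$stage %in% c("I", "II") && !agent$reps[[rec$hipp]]$erased)
      hipp_ids <- c(hipp_ids, rec$hipp)
    if (rec$stage %in% c("II", "III") && !is.na(rec$cort))
      cort_ids <- c(cort_ids, rec$cort)
  }
  if (spec$hippocampus_inactivated) hipp_ids <- character(0)
  recalled <- character(0)
  if (length(hipp_ids)) {
    ov <- vapply(hipp_ids, function(id) {
      r <- agent$reps[[id]]
      if (is.null(observed_set)) know_shared(r$know, w, spec$context)
      else length(intersect(r$know$set, observed_set))
    }, numeric(1))
    recalled <- hipp_ids[which.max(ov)]
  }
  ids <- c(recalled, cort_ids)
  if (!length(ids))
    return(list(candidates = NULL, winner = NULL, runner_up_b = NA_real_))
  cand <- lapply(ids, function(id) {
    r <- agent$reps[[id]]
    z_rec <- know_zrec(r$know)
    n_shared <- know_shared(r$know, w, spec$context)
    z_com <- if (is.null(observed_set)) {
      min(expected_common(z_cur, n_shared, p$N_atr), z_rec, z_cur)
    } else {
      length(intersect(r$know$set, observed_set))
    }
    b <- b_rep(z_cur, z_rec, z_com, p$N_atr, p$N_ctx)
    data.frame(id = id, kind = r$kind, z_rec = z_rec, n_shared = n_shared,
               z_com = z_com, b = b, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  ## winner: highest evidence; ties favor the hippocampal version, then
  ## registry order
  ord <- order(-cand$b, cand$kind != "hipp", seq_len(nrow(cand)))
  winner <- ord[1]
  runner <- if (nrow(cand) >= 2) cand$b[ord[2]] else NA_real_
  list(candidates = cand, winner = cand[winner, , drop = FALSE],
       runner_up_b = runner)
}

## New-representation rule: the winner is rejected (b below B_new) and
## there is no close runner-up (margin above delta, or no runner-up at
## all; a -Inf runner-up is maximally rejected and cannot block creation).
creation_due <- function(b_winner, b_runner_up, params) {
  if (is.na(b_winner)) return(TRUE)      # no candidates at all
  if (b_winner >= params$B_new) return(FALSE)
  if (is.na(b_runner_up)) return(TRUE)
  if (is.infinite(b_runner_up) && b_runner_up < 0) return(TRUE)
  (b_winner - b_runner_up) > params$delta
}

## ---- Fear expression ------------------------------------------------------

## conditioned drive g reaching the amygdala when `rep` is the active
## representation. Routes:
##  - active hippocampal: its CA3 synapses' weights, plus (via the
##    permanent CA3-cortical links) each conditioned cortical cell's
##    weight scaled by the CA3 overlap with that cell's progenitor.
##  - active cortical: its own synapse weight, plus its progenitor CA3
##    synapses' weights, plus other conditioned cortical cells' weights
##    scaled by the tabulated generalization G of context similarity.
## All CA3-routed terms vanish when the hippocampus is inactivated.
fear_drive <- function(agent, rep, hipp_inactivated = FALSE) {
  p <- agent$params
  amy <- agent$amy
  conditioned_cort <- names(amy$w_cort)[amy$w_cort > 0]
  g <- 0
  if (rep$kind == "hipp") {
    if (hipp_inactivated) return(0)
    g <- g + sum_w_hipp(amy, rep$ca3)
    for (id in conditioned_cort) {
      cr <- agent$reps[[id]]
      g <- g + (length(intersect(rep$ca3, cr$ca3)) / p$K) * amy$w_cort[[id]]
    }
  } else {
    g <- g + w_cort_of(amy, rep$id)
    if (!hipp_inactivated) g <- g + sum_w_hipp(amy, rep$ca3)
    for (id in setdiff(conditioned_cort, rep$id)) {
      cr <- agent$reps[[id]]
      ov <- context_overlap(agent$world, rep$ctx, cr$ctx)
      s <- similarity(ov$o_ptc, ov$o_cat, p$gamma,
                      both_categorized = !is.na(rep$category) &&
                        !is.na(cr$category),
                      o_atr = ov$o_atr)
      if (is.null(agent$g_table))
        stop("cortical-cortical generalization requires a G table; ",
             "call build_g_table() on the agent first")
      g <- g + cortical_generalization(s, agent$g_table) * amy$w_cort[[id]]
    }
  }
  g
}

## ---- Running a session ----------------------------------------------------

#' Run one session of the computational cycle
#'
#' Iterates the Decision and Execution phases over the session's
#' intervals: at each interval one new attribute of the context is
#' observed, every candidate representation is scored by its weight of
#' evidence, the winner is activated, and the execution rules fire (new
#' representation creation when the winner is rejected with a clear
#' margin; conditioning if the unconditioned stimulus occurs; fear
#' expression). At session end, if the final winner's evidence exceeds
#' \code{B_add}, the active representation is updated with the session's
#' observations (see the consolidation machinery).
#'
#' @param agent a \code{"fear_agent"}.
#' @param spec a \code{\link{session_spec}}.
#' @return A list with the updated \code{agent}, the per-interval
#'   \code{trace} data frame (interval, z_cur, active representation and
#'   kind, z_rec, n_shared, z_com, b_rep, cnd, fear, created flag), and a
#'   \code{summary} list (mean fear; creation interval; conditioning-
#'   threshold, half-conditionability and evidence-decline coordinates of
#'   the initially active representation, read off the continuous
#'   relaxation of its expected trajectory).
#' @export
run_session <- function(agent, spec) {
  p <- agent$params
  w <- agent$world
  agent$session_no <- agent$session_no + 1L
  stream <- NULL
  if (agent$mode == "stochastic")
    stream <- observation_stream(w, spec$context, spec$length, "stochastic")
  n <- spec$length
  trace <- data.frame(interval = seq_len(n), z_cur = seq_len(n),
                      active_rep = NA_character_, kind = NA_character_,
                      z_rec = NA_real_, n_shared = NA_real_,
                      z_com = NA_real_, b_rep = NA_real_, cnd = NA_real_,
                      fear = NA_real_, created = FALSE,
                      stringsAsFactors = FALSE)
  last_active <- NULL; last_b <- NA_real_
  for (z in seq_len(n)) {
    observed <- if (is.null(stream)) NULL else stream$order[seq_len(z)]
    dp <- decision_phase(agent, spec, z, observed)
    active <- dp$winner
    create <- creation_due(if (is.null(active)) NA_real_ else active$b,
                           dp$runner_up_b, p)
    ## a new representation is hippocampal; none can form while the
    ## hippocampus is inactivated
    if (spec$hippocampus_inactivated) create <- FALSE
    if (create) {
      know <- if (is.null(observed))
        know_from_observation(w, spec$context, z)
      else know_from_observation(w, spec$context, z, observed)
      agent <- add_hipp_rep(agent, spec$context, know,
                            born_session = agent$session_no)
      id <- agent$records[[length(agent$records)]]$hipp
      r <- agent$reps[[id]]
      z_rec <- know_zrec(r$know)
      n_shared <- know_shared(r$know, w, spec$context)
      z_com <- if (is.null(observed))
        min(expected_common(z, n_shared, p$N_atr), z_rec, z)
      else z
      active <- data.frame(id = id, kind = "hipp", z_rec = z_rec,
                           n_shared = n_shared, z_com = z_com,
                           b = b_rep(z, z_rec, z_com, p$N_atr, p$N_ctx),
                           stringsAsFactors = FALSE)
      trace$created[z] <- TRUE
    }
    cnd <- if (is.null(active)) 0 else conditionability(active$b, p)
    if (!is.na(spec$us_interval) && z == spec$us_interval &&
        !is.null(active)) {
      agent$amy <- condition_rep(agent$amy, agent$reps[[active$id]], cnd, p)
    }
    fear <- 0
    if (!is.null(active)) {
      g <- fear_drive(agent, agent$reps[[active$id]],
                      spec$hippocampus_inactivated)
      fear <- express_fear(g, active$b, p)$fear
      trace$active_rep[z] <- active$id
      trace$kind[z] <- active$kind
      trace$z_rec[z] <- active$z_rec
      trace$n_shared[z] <- active$n_shared
      trace$z_com[z] <- active$z_com
      trace$b_rep[z] <- active$b
    }
    trace$cnd[z] <- cnd
    trace$fear[z] <- fear
    last_active <- active; last_b <- if (is.null(active)) NA else active$b
  }
  ## end-of-session updating
  updated <- FALSE
  if (!is.null(last_active) && is.finite(last_b) && last_b > p$B_add) {
    observed <- if (is.null(stream)) NULL else stream$order
    ctx_of_active <- agent$reps[[last_active$id]]$ctx
    agent <- update_representation(agent, ctx_of_active, n, observed)
    updated <- TRUE
  }
  summary <- session_summary(trace, p)
  summary$updated <- updated
  list(agent = agent, trace = trace, summary = summary)
}

## Event coordinates of a session. Threshold crossings and the evidence-
## decline onset of the initially active representation are read off the
## continuous (log-gamma) relaxation of its expected trajectory, which is
## free of the +-1 integer-rounding ripple of the pointwise trajectory.
session_summary <- function(trace, p) {
  created_at <- if (any(trace$created)) trace$interval[trace$created][1]
    else NA_integer_
  first <- which(!is.na(trace$active_rep))[1]
  b_cnd_cross <- half_cnd_cross <- decline <- NA_integer_
  tracked <- NA_character_
  if (!is.na(first)) {
    tracked <- trace$active_rep[first]
    z_rec <- trace$z_rec[first]
    n_shared <- trace$n_shared[first]
    bs <- smooth_trajectory(z_rec, n_shared, p$N_atr, p$N_ctx,
                            nrow(trace))
    b_cnd_cross <- first_crossing(bs, p$B_cnd)
    half_cnd_cross <- first_crossing(bs, (p$B_cnd + p$B_mxCnd) / 2)
    decline <- decline_onset(bs)
  }
  list(mean_fear = mean(trace$fear), rep_created_at = created_at,
       b_cnd_cross = b_cnd_cross, half_cnd_cross = half_cnd_cross,
       decline_onset = decline, tracked_rep = tracked)
}

#' Write a session trace as CSV
#' @param trace a trace data frame from \code{\link{run_session}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
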