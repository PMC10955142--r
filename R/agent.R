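#' Create a simulated agent
#'
#' The agent holds everything that constitutes one simulated individual:
#' its DG wiring (fixed for life), its known categories (assumed fully
#' learned), its context representations and consolidation records, its
#' amygdala weight state, and the tabulated cortical generalization
#' function (built on demand by \code{\link{build_g_table}}).
#'
#' In \code{"expected_value"} mode, evidence is computed from expected
#' match counts given the agent's prior experience (deterministic
#' trajectories); in \code{"stochastic"} mode attribute sampling and
#' association sets are concrete random draws.
#'
#' @param world a \code{"fear_world"}.
#' @param mode \code{"expected_value"} or \code{"stochastic"}.
#' @param known_categories character vector of category ids the agent
#'   knows (attribute knowledge of a known category is complete).
#' @return A list of class \code{"fear_agent"}.
#' @export
make_agent <- function(world, mode = c("expected_value", "stochastic"),
                       known_categories = names(world$categories)) {
  mode <- match.arg(mode)
  p <- world$params
  agent <- list(
    world = world, params = p, mode = mode,
    wiring = make_wiring(p$N_dg, p$F, p$N_ctx),
    categories = world$categories[known_categories],
    reps = list(), records = list(),
    amy = amygdala_state(), g_table = NULL,
    nmda_amygdala_block = FALSE, nmda_learning_block = FALSE,
    next_rep = 1L, session_no = 0L
  )
  class(agent) <- "fear_agent"
  agent
}

#' @export
print.fear_agent <- function(x, ...) {
  cat("<fear_agent> mode:", x$mode, "\n",
      " categories known:", paste(names(x$categories), collapse = ", "), "\n",
      " representations:", length(x$reps),
      " records:", length(x$records), "\n")
  invisible(x)
}

new_rep_id <- function(agent) sprintf("r%d", agent$next_rep)

## add a fresh hippocampal representation (and Stage I record) built from
## the given knowledge; a concrete attribute realization drives the DG
## competition
add_hipp_rep <- function(agent, ctx, know, born_session = NA_integer_) {
  realized <- know_realize(know, agent$world)
  hr <- create_representation(realized, agent$wiring, agent$params$K)
  id <- new_rep_id(agent)
  know$born_session <- born_session
  agent$reps[[id]] <- list(id = id, kind = "hipp", ctx = ctx, know = know,
                           ca3 = hr$ca3, z_o = know_zrec(know),
                           category = NA_character_, erased = FALSE)
  agent$next_rep <- agent$next_rep + 1L
  agent$records[[length(agent$records) + 1L]] <-
    list(ctx = ctx, stage = "I", hipp = id, cort = NA_character_)
  agent
}

## index of the (latest) consolidation record for a context, or NA
record_index <- function(agent, ctx) {
  idx <- which(vapply(agent$records, function(r) r$ctx == ctx, logical(1)))
  if (length(idx)) idx[length(idx)] else NA_integer_
}

#' Install a long-established remote context
#'
#' Simulates a context the agent came to know well long ago: a
#' representation with \code{z_o} known attributes is created and driven
#' through the full consolidation sequence to Stage III (without any fear
#' conditioning), leaving a remote cortical representation with a
#' permanent link to its hippocampal progenitor's CA3 cells.
#'
#' @param agent a \code{"fear_agent"}.
#' @param ctx context id.
#' @param z_o number of attributes known prior to consolidation (default
#'   \code{Z_oRec}).
#' @return The updated agent.
#' @export
establish_context <- function(agent, ctx, z_o = agent$params$Z_oRec) {
  w <- agent$world
  know <- if (agent$mode == "stochastic") {
    attrs <- context_attrs(w, ctx)
    know_from_set(ctx, attrs[sample.int(length(attrs), z_o)])
  } else {
    know_from_observation(w, ctx, z_o)
  }
  agent <- add_hipp_rep(agent, ctx, know)
  agent <- advance_stage(agent, ctx)   # I -> II (builds cortical version)
  agent <- advance_stage(agent, ctx)   # II -> III (erases hippocampal)
  agent
}

#' Build the agent's cortical generalization table
#'
#' Tabulates the generalization function G on the agent's own wiring (see
#' \code{\link{make_g_table}}) and stores it in the agent. Needed before
#' fear can generalize between two cortical representations.
#'
#' @param agent a \code{"fear_agent"}.
#' @param n_mc Monte-Carlo replicates.
#' @return The updated agent.
#' @export
build_g_table <- function(agent, n_mc = 20) {
  agent$g_table <- make_g_table(agent$params, n_mc = n_mc,
                                wiring = agent$wiring)
  agent
}

#' Set pharmacological-block flags
#'
#' \code{amygdala = TRUE} models NMDA-receptor block within the amygdala:
#' the Stage II to III transition still replaces the hippocampal
#' representation, but the conditioned weight is not transferred to the
#' cortical pathway. \code{learning = TRUE} models block of new Hebbian
#' learning: end-of-session updating becomes a no-op while fear expression
#' is unaffected.
#'
#' @param agent a \code{"fear_agent"}.
#' @param amygdala,learning logical flags (NULL leaves a flag unchanged).
#' @return The updated agent.
#' @export
set_nmda_block <- function(agent, amygdala = NULL, learning = NULL) {
  if (!is.null(amygdala)) agent$nmda_amygdala_block <- amygdala
  if (!is.null(learning)) agent$nmda_learning_block <- learning
  agent
}
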