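#' Advance a context's consolidation record by one stage
#'
#' Stage transitions are explicit experiment-driver events (the biological
#' Stage II duration is highly variable, so protocols specify recent /
#' Stage II / remote conditions directly):
#' \describe{
#'   \item{I to II}{The cortical version is built: the category is
#'     identified (if possible) and linked, a capped random subset of
#'     unclassified attributes is retained (see \code{\link{unc_ceiling}}),
#'     and the cortical cell keeps a permanent link to the hippocampal
#'     progenitor's CA3 cells. During Stage II both versions compete for
#'     activation.}
#'   \item{II to III}{Conditioned fear is transferred: the cortical
#'     representation-cell synapse gains the cumulative weight of the K
#'     hippocampal CA3 synapses (so the cortical version evokes the same
#'     fear as its progenitor did), those CA3 synapses are cleared, and
#'     the hippocampal representation is erased. Under an amygdala NMDA
#'     block (\code{\link{set_nmda_block}}) the replacement still happens
#'     but no weight is transferred.}
#' }
#'
#' @param agent a \code{"fear_agent"}.
#' @param ctx context id with an active record.
#' @return The updated agent.
#' @export
advance_stage <- function(agent, ctx) {
  ri <- record_index(agent, ctx)
  if (is.na(ri)) stop("no consolidation record for context ", ctx)
  rec <- agent$records[[ri]]
  if (rec$stage == "I") {
    hipp <- agent$reps[[rec$hipp]]
    res <- consolidate_knowledge(hipp$know, agent$world, agent$categories,
                                 agent$params)
    if (is.na(rec$cort)) {
      id <- new_rep_id(agent)
      agent$next_rep <- agent$next_rep + 1L
      rec$cort <- id
    } else {
      id <- rec$cort   # updating cycle: revise the existing cortical cell
    }
    agent$reps[[id]] <- list(id = id, kind = "cort", ctx = ctx,
                             know = res$know, ca3 = hipp$ca3,
                             z_o = hipp$z_o, category = res$category,
                             erased = FALSE)
    rec$stage <- "II"
  } else if (rec$stage == "II") {
    hipp <- agent$reps[[rec$hipp]]
    transferred <- sum_w_hipp(agent$amy, hipp$ca3)
    if (!agent$nmda_amygdala_block && transferred > 0) {
      old <- w_cort_of(agent$amy, rec$cort)
      agent$amy$w_cort[[rec$cort]] <- old + transferred
    }
    agent$amy$w_hipp[as.character(hipp$ca3)] <- 0
    hipp <- erase(hipp)
    hipp$know <- know_from_counts(hipp$ctx, 0, 0)
    agent$reps[[rec$hipp]] <- hipp
    rec$stage <- "III"
  } else {
    stop("record for ", ctx, " is already at Stage III")
  }
  agent$records[[ri]] <- rec
  agent
}

#' Stage of a context's consolidation record
#' @param agent a \code{"fear_agent"}.
#' @param ctx context id.
#' @return \code{"I"}, \code{"II"}, \code{"III"}, or \code{NA} if the
#'   context has no record.
#' @export
record_stage <- function(agent, ctx) {
  ri <- record_index(agent, ctx)
  if (is.na(ri)) NA_character_ else agent$records[[ri]]$stage
}

## End-of-session updating: called when the agent is confident the active
## representation was valid (B_Rep > B_add).
##
## Hippocampal locus (Stage I or II): newly observed attributes join the
## hippocampal representation's associated set. Stage II cortical winners
## also route here (updating always goes through the hippocampal version).
##
## Cortical locus (Stage III): the representation returns to Stage I. The
## hippocampal version is reconstructed on the stored progenitor CA3 set,
## associated with everything known (cortical attributes, the category's
## attributes if identified, and the session's observations), and the
## consolidation process starts over. Fear previously conditioned to the
## cortical representation remains on it and stays expressible through the
## CA3-cortical pathway.
##
## Under a learning NMDA block the whole operation is a no-op.
update_representation <- function(agent, ctx, z_end, observed_set = NULL) {
  if (agent$nmda_learning_block) return(agent)
  ri <- record_index(agent, ctx)
  if (is.na(ri)) return(agent)
  rec <- agent$records[[ri]]
  w <- agent$world
  if (rec$stage %in% c("I", "II")) {
    hipp <- agent$reps[[rec$hipp]]
    nested <- identical(hipp$know$born_session, agent$session_no)
    hipp$know <- know_union_observation(hipp$know, w, z_end, observed_set,
                                        nested = nested)
    agent$reps[[rec$hipp]] <- hipp
  } else {
    cort <- agent$reps[[rec$cort]]
    know <- cort$know
    if (!is.na(cort$category))
      know <- know_add_category(know, w, agent$categories[[cort$category]])
    know <- know_union_observation(know, w, z_end, observed_set,
                                   nested = FALSE)
    know$born_session <- NA_integer_
    hipp <- agent$reps[[rec$hipp]]
    hipp$erased <- FALSE
    hipp$know <- know
    hipp$z_o <- know_zrec(know)
    ## CA3-CA3 associations re-established from the progenitor links: the
    ## reconstructed representation reuses the original CA3 set
    agent$reps[[rec$hipp]] <- hipp
    rec$stage <- "I"
    agent$records[[ri]] <- rec
  }
  agent
}
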