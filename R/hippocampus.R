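#' Dentate gyrus wiring
#'
#' Each of the \code{n_dg} DG cells is innervated by a uniformly drawn set
#' of \code{f} of the \code{n_ctx} attribute (Cur) cells. Each DG cell
#' drives a single dedicated CA3 partner through an innately effective
#' synapse, so DG index = CA3 index. The wiring is stored as a sparse
#' \code{n_dg x n_ctx} incidence matrix so that many observation sets can
#' be scored in one multiplication.
#'
#' @param n_dg number of DG cells.
#' @param f afferents per DG cell.
#' @param n_ctx number of attribute cells.
#' @return A list of class \code{"dg_wiring"} with the sparse incidence
#'   matrix \code{m} and a fixed tie-break permutation \code{tie} (so that
#'   identical observation sets always select identical winners under a
#'   given wiring).
#' @export
make_wiring <- function(n_dg, f, n_ctx) {
  stopifnot(f <= n_ctx)
  cols <- integer(n_dg * f)
  for (i in seq_len(n_dg))
    cols[((i - 1L) * f + 1L):(i * f)] <- sample.int(n_ctx, f)
  m <- Matrix::sparseMatrix(i = rep(seq_len(n_dg), each = f), j = cols,
                            x = 1, dims = c(n_dg, n_ctx))
  structure(list(m = m, tie = sample.int(n_dg)), class = "dg_wiring")
}

## innervation score of every DG cell for one or more observation sets
## (columns of the result correspond to sets)
wiring_scores <- function(wiring, sets) {
  if (!is.list(sets)) sets <- list(sets)
  ind <- matrix(0, ncol(wiring$m), length(sets))
  for (j in seq_along(sets)) ind[sets[[j]], j] <- 1
  as.matrix(wiring$m %*% ind)
}

#' Create a hippocampal (DG/CA3) representation
#'
#' The \code{k} DG cells most richly innervated by the currently active
#' attribute cells win the competition and their CA3 partners form the
#' representation; ties among equally innervated cells are broken by the
#' wiring's fixed random permutation, so identical observation sets under
#' the same wiring always yield identical winners. The observed attributes
#' become the representation's associated set.
#'
#' @param observed_attrs nonempty integer vector of observed attribute
#'   indices.
#' @param wiring a wiring matrix from \code{\link{make_wiring}}.
#' @param k number of winners.
#' @return List of class \code{"hipp_rep"} with \code{ca3} (integer vector
#'   of length \code{k}), \code{assoc_attrs}, \code{z_o} (attributes
#'   observed at creation) and \code{erased = FALSE}.
#' @export
create_representation <- function(observed_attrs, wiring, k) {
  stopifnot(length(observed_attrs) > 0)
  scores <- wiring_scores(wiring, observed_attrs)[, 1]
  ca3 <- order(-scores, wiring$tie)[seq_len(k)]
  structure(list(ca3 = as.integer(ca3),
                 assoc_attrs = sort(as.integer(observed_attrs)),
                 z_o = length(observed_attrs), erased = FALSE),
            class = "hipp_rep")
}

#' Content-addressable recall among live hippocampal representations
#'
#' Returns the index (within \code{reps}) of the live representation whose
#' associated attributes overlap the observed set most; ties go to the
#' lowest index, and erased representations never win.
#'
#' @param observed_attrs observed attribute indices.
#' @param reps list of \code{"hipp_rep"} objects.
#' @return Integer index into \code{reps}, or \code{NULL} if no live
#'   representation exists.
#' @export
recall_candidate <- function(observed_attrs, reps) {
  live <- which(!vapply(reps, function(r) isTRUE(r$erased), logical(1)))
  if (!length(live)) return(NULL)
  ov <- vapply(live, function(i)
    length(intersect(reps[[i]]$assoc_attrs, observed_attrs)), integer(1))
  live[which.max(ov)]
}

#' Associate newly observed attributes with a representation
#'
#' Used when the agent is confident the representation is valid (weight of
#' evidence above \code{B_add}); the CA3 cell set never changes.
#'
#' @param rep a live \code{"hipp_rep"}.
#' @param new_attrs attribute indices to add.
#' @return The updated representation.
#' @export
associate_attributes <- function(rep, new_attrs) {
  if (isTRUE(rep$erased)) stop("cannot associate attributes with an erased representation")
  rep$assoc_attrs <- sort(union(rep$assoc_attrs, as.integer(new_attrs)))
  rep
}

#' Overlap of two hippocampal representations
#'
#' @param rep_a,rep_b \code{"hipp_rep"} objects (or anything with a
#'   \code{ca3} field of equal length).
#' @return Fraction of shared CA3 cells in [0, 1].
#' @export
rep_overlap <- function(rep_a, rep_b) {
  k <- length(rep_a$ca3)
  stopifnot(k == length(rep_b$ca3))
  length(intersect(rep_a$ca3, rep_b$ca3)) / k
}

#' Erase a hippocampal representation
#'
#' Clears the attribute associations and marks the representation erased so
#' it can never win a recall competition again. The CA3 cell set is
#' retained: cortical descendants keep permanent links to their
#' progenitor's CA3 cells. Idempotent.
#'
#' @param rep a \code{"hipp_rep"}.
#' @return The erased representation.
#' @export
erase <- function(rep) {
  rep$erased <- TRUE
  rep$assoc_attrs <- integer(0)
  rep
}

#' Monte-Carlo expected overlap of two representations
#'
#' Estimates the mean CA3 overlap of representations of two contexts whose
#' total attribute overlap proportion is \code{o_atr}, when \code{z_oA} and
#' \code{z_oB} attributes respectively had been observed at creation time.
#' Each replicate draws fresh DG wiring (unless a fixed wiring is
#' supplied), fresh contexts with exactly \code{round(o_atr * N_atr)}
#' shared attributes, fresh observation subsets, builds both
#' representations and records their overlap.
#'
#' @param o_atr total attribute overlap proportion in [0, 1].
#' @param z_oA,z_oB attributes observed at creation for each context.
#' @param params a \code{\link{fear_params}} object (\code{N_dg}, \code{F},
#'   \code{K}, \code{N_ctx}, \code{N_atr} are used).
#' @param n_mc number of Monte-Carlo replicates.
#' @param wiring optional fixed wiring matrix reused across replicates
#'   (one individual's brain); if \code{NULL}, wiring is redrawn each
#'   replicate.
#' @return List with \code{mean}, \code{sd}, \code{n}.
#' @export
expected_overlap <- function(o_atr, z_oA, z_oB, params = fear_params(),
                             n_mc = 20, wiring = NULL) {
  stopifnot(n_mc >= 1, o_atr >= 0, o_atr <= 1,
            z_oA <= params$N_atr, z_oB <= params$N_atr)
  p <- params
  ov <- vapply(seq_len(n_mc), function(r) {
    w <- if (is.null(wiring)) make_wiring(p$N_dg, p$F, p$N_ctx) else wiring
    n_shared <- round(o_atr * p$N_atr)
    n_own <- p$N_atr - n_shared
    pool <- sample.int(p$N_ctx)
    shared <- pool[seq_len(n_shared)]
    a <- c(shared, pool[n_shared + seq_len(n_own)])
    b <- if (n_own == 0) a else
      c(shared, pool[n_shared + n_own + seq_len(n_own)])
    obs_a <- a[sample.int(p$N_atr, z_oA)]
    obs_b <- b[sample.int(p$N_atr, z_oB)]
    rep_overlap(create_representation(obs_a, w, p$K),
                create_representation(obs_b, w, p$K))
  }, numeric(1))
  list(mean = mean(ov), sd = stats::sd(ov), n = n_mc)
}
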