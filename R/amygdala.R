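#' Linear sigmoid ("linsig") ramp
#'
#' Rises linearly from zero starting at \code{thrs} and plateaus at unity
#' at \code{mxat}. This is the model's activation/conditionability
#' nonlinearity.
#'
#' @param x input value.
#' @param thrs threshold (output 0 at or below).
#' @param mxat plateau point (output 1 at or above); must exceed
#'   \code{thrs}.
#' @return Value in [0, 1]. Vectorized over \code{x}.
#' @examples
#' linsig(7, 2, 12)   # 0.5
#' @export
linsig <- function(x, thrs, mxat) {
  if (mxat <= thrs) stop("mxat must exceed thrs")
  pmin(1, pmax(0, (x - thrs) / (mxat - thrs)))
}

#' Conditionability as a function of the weight of evidence
#'
#' The synaptic weight increment caused by an unconditioned stimulus is
#' scaled by how confident the agent is in the active representation:
#' \code{Cnd = linsig(B, B_cnd, B_mxCnd)}, zero at or below \code{B_cnd}
#' and maximal at \code{B_mxCnd}.
#'
#' @param b weight of evidence of the active representation.
#' @param params a \code{\link{fear_params}} object.
#' @return Conditionability in [0, 1].
#' @export
conditionability <- function(b, params) {
  ## linsig maps -Inf to 0 and +Inf to 1, so sentinels saturate correctly
  linsig(b, params$B_cnd, params$B_mxCnd)
}

## fresh amygdala state: sparse weight maps, CA3 index -> weight and
## cortical rep id -> weight
amygdala_state <- function() {
  list(w_hipp = numeric(0), w_cort = numeric(0))
}

## add cnd * alpha to each CA3 synapse of a hippocampal representation, or
## K * cnd * alpha to a cortical representation-cell synapse (so a single
## maximal US produces the same cumulative drive in both cases)
condition_rep <- function(amy, rep, cnd, params) {
  if (cnd <= 0) return(amy)
  if (rep$kind == "hipp") {
    keys <- as.character(rep$ca3)
    old <- amy$w_hipp[keys]
    old[is.na(old)] <- 0
    amy$w_hipp[keys] <- old + cnd * params$alpha
  } else {
    key <- rep$id
    old <- if (key %in% names(amy$w_cort)) amy$w_cort[[key]] else 0
    amy$w_cort[[key]] <- old + params$K * cnd * params$alpha
  }
  amy
}

sum_w_hipp <- function(amy, ca3) {
  w <- amy$w_hipp[as.character(ca3)]
  sum(w, na.rm = TRUE)
}

w_cort_of <- function(amy, id) {
  if (id %in% names(amy$w_cort)) amy$w_cort[[id]] else 0
}

#' Fear expression from synaptic drive and confidence
#'
#' The conditioned synaptic drive \code{g} (in units of the amygdala
#' cell's leakage conductance) depolarizes the cell to
#' \code{V = E g / (1 + g)} (single-compartment conductance divider with
#' excitatory equilibrium potential \code{E}); the activation is
#' \code{A_F = linsig(V, 0, E/2)}, calibrated so that one maximal
#' unconditioned stimulus (total weight 1, hence g = 1, V = E/2) yields
#' full activation. Expressed fear is the activation multiplied by the
#' fear expression factor \code{Fef = linsig(B, 0, B_mxF)}.
#'
#' @param g conditioned drive (nonnegative).
#' @param b weight of evidence of the active representation.
#' @param params a \code{\link{fear_params}} object.
#' @return List with \code{g}, \code{v}, \code{a_f}, \code{fef},
#'   \code{fear}.
#' @examples
#' express_fear(1, 4, fear_params())$fear   # 1
#' @export
express_fear <- function(g, b, params) {
  stopifnot(g >= 0)
  v <- params$E * g / (1 + g)
  a_f <- linsig(v, 0, params$E / 2)
  fef <- if (!is.finite(b) && b < 0) 0 else linsig(b, 0, params$B_mxF)
  list(g = g, v = v, a_f = a_f, fef = fef, fear = a_f * fef)
}
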