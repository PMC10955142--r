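#' Bayesian weight of evidence for a context representation
#'
#' After observing \code{z_cur} attributes of the current context, with
#' \code{z_com} of them matching the \code{z_rec} attributes recalled by a
#' candidate representation, the weight of evidence that the current
#' context \emph{is} the recalled one is the log (base 10) likelihood
#' ratio of two hypergeometric sampling models:
#' \deqn{B = \log_{10} \frac{P(z_{com} \mid \mathrm{same\ context})}
#'                          {P(z_{com} \mid \mathrm{random\ place})}}
#' Under the "same context" hypothesis the \code{z_cur} draws come without
#' replacement from the context's \code{n_atr} attributes of which
#' \code{z_rec} are recalled; under the "random place" null they come from
#' the full universe of \code{n_ctx} representable attributes of which
#' \code{z_rec} are recalled.
#'
#' With no observations (\code{z_cur = 0}) the evidence is 0. If the match
#' count is impossible under the same-context hypothesis the function
#' returns \code{-Inf}; if impossible only under the null it returns
#' \code{+Inf}. These sentinels saturate comparisons but are never used in
#' weight arithmetic. A match count impossible under both hypotheses is an
#' error.
#'
#' @param z_cur attributes observed this session.
#' @param z_rec attributes associated with the representation.
#' @param z_com matches between observed and recalled sets.
#' @param n_atr attributes per context.
#' @param n_ctx representable attributes in the universe.
#' @return The weight of evidence in log10 units (a "ban" scale).
#' @examples
#' b_rep(0, 85, 0, 100, 1000)              # 0: no observations
#' b_rep(100, 100, 100, 100, 1000)         # log10 choose(1000, 100)
#' @export
b_rep <- function(z_cur, z_rec, z_com, n_atr, n_ctx) {
  stopifnot(z_cur >= 0, z_rec >= 0, z_com >= 0,
            z_com <= min(z_cur, z_rec), z_cur <= n_atr, n_atr <= n_ctx)
  if (z_cur == 0) return(0)
  num <- stats::dhyper(z_com, z_rec, n_atr - z_rec, z_cur, log = TRUE)
  den <- stats::dhyper(z_com, z_rec, n_ctx - z_rec, z_cur, log = TRUE)
  if (!is.finite(num) && !is.finite(den))
    stop("match count impossible under both hypotheses")
  if (!is.finite(num)) return(-Inf)
  if (!is.finite(den)) return(Inf)
  (num - den) / log(10)
}

## continuous log-binomial coefficient, defined for real b in [-1, a+1]
lchoose_cont <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)

## Continuous relaxation of b_rep: z_com may be non-integer (the expected
## match count before rounding). Used for reading event coordinates off
## expected-value trajectories without integer-rounding ripple.
b_rep_smooth <- function(z_cur, z_rec, z_com, n_atr, n_ctx) {
  if (z_cur == 0) return(0)
  if (z_com > z_rec || z_cur - z_com > n_atr - z_rec) return(-Inf)
  num <- lchoose_cont(z_rec, z_com) +
    lchoose_cont(n_atr - z_rec, z_cur - z_com) - lchoose_cont(n_atr, z_cur)
  den <- lchoose_cont(z_rec, z_com) +
    lchoose_cont(n_ctx - z_rec, z_cur - z_com) - lchoose_cont(n_ctx, z_cur)
  (num - den) / log(10)
}

#' Expected weight-of-evidence trajectory over a session
#'
#' Composes \code{\link{expected_common}} with \code{\link{b_rep}} for
#' \code{Z_cur = 1..length}: at each interval the expected match count is
#' \code{round(Z_cur * true_overlap_count / n_atr)}. For a valid
#' representation (\code{true_overlap_count = z_rec} and all attributes in
#' the current context) the trajectory rises monotonically; for a
#' mismatched representation it rises, peaks and collapses (eventually to
#' \code{-Inf} when the observed mismatch becomes impossible under the
#' same-context hypothesis).
#'
#' @param z_rec attributes associated with the representation.
#' @param true_overlap_count attributes shared between the recalled set and
#'   the current context's true attribute set.
#' @param n_atr,n_ctx world sizes.
#' @param length number of intervals.
#' @return Data frame with columns \code{z_cur}, \code{z_com}, \code{b_rep}.
#' @export
expected_brep_curve <- function(z_rec, true_overlap_count, n_atr, n_ctx,
                                length) {
  stopifnot(length >= 1, length <= n_atr,
            true_overlap_count <= z_rec || true_overlap_count <= n_atr)
  z <- seq_len(length)
  zc <- vapply(z, expected_common, numeric(1),
               n_shared = true_overlap_count, n_atr = n_atr)
  b <- vapply(seq_along(z), function(i)
    b_rep(z[i], z_rec, zc[i], n_atr, n_ctx), numeric(1))
  data.frame(z_cur = z, z_com = zc, b_rep = b)
}

## Event read-offs on the continuous relaxation of a candidate's expected
## trajectory (constant z_rec and n_shared within a session). The integer
## trajectory carries a +-1 rounding ripple and a feasibility-boundary
## spike; the smooth curve gives unambiguous coordinates.
smooth_trajectory <- function(z_rec, n_shared, n_atr, n_ctx, length) {
  vapply(seq_len(length), function(z)
    b_rep_smooth(z, z_rec, z * n_shared / n_atr, n_atr, n_ctx), numeric(1))
}

first_crossing <- function(b, threshold) {
  i <- which(b >= threshold)
  if (length(i)) i[1] else NA_integer_
}

decline_onset <- function(b) {
  mx <- which.max(b)
  i <- which(seq_along(b) > mx & c(FALSE, diff(b) < 0))
  if (length(i)) i[1] else NA_integer_
}

#' Export a weight-of-evidence curve as CSV
#'
#' @param curve a data frame from \code{\link{expected_brep_curve}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_brep_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
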