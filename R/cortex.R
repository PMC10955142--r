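#' Identify the category of a set of known attributes
#'
#' For each known category the weight of evidence that the context belongs
#' to it is computed with \code{\link{b_rep}}: the recalled set is the
#' category's known attributes, the "observed" set is everything known
#' about the context, and the match count is their intersection. The
#' best-scoring category is returned if its evidence exceeds \code{B_cat};
#' ties go to the first category in registry order.
#'
#' @param know internal knowledge object (or an integer attribute vector,
#'   which is converted).
#' @param world a \code{"fear_world"}.
#' @param categories named list of known-category attribute sets.
#' @param params a \code{\link{fear_params}} object.
#' @return \code{NULL} if no category qualifies, else a list with
#'   \code{category} (id) and \code{b} (its weight of evidence).
#' @export
identify_category <- function(know, world, categories, params) {
  if (!length(categories)) return(NULL)
  if (is.numeric(know)) know <- know_from_set(ctx = NA, set = know)
  z_cur <- know_zrec(know)
  b <- vapply(categories, function(cat_attrs) {
    z_rec <- length(cat_attrs)
    z_com <- min(know_shared_set(know, world, cat_attrs), z_cur, z_rec)
    b_rep(z_cur, z_rec, z_com, params$N_atr, params$N_ctx)
  }, numeric(1))
  best <- which.max(b)
  if (b[best] > params$B_cat)
    list(category = names(categories)[best], b = b[[best]])
  else NULL
}

#' Retention ceiling for unclassified attributes
#'
#' When a representation consolidates, only a capped proportion of the
#' \code{N_ptc} unclassified (Unc) attributes -- those not known to be
#' categorical -- is retained by the cortical version:
#' \deqn{ceiling = \kappa + (1 - \kappa) (Z_{rec}/N_{atr})^{\epsilon}}
#' With the default \eqn{\epsilon = 20} the ceiling is essentially
#' \eqn{\kappa} unless nearly everything is known about the context. If
#' the context's category cannot be determined the caller uses the fixed
#' high ceiling \code{kappa_o} instead.
#'
#' @param z_rec attributes associated with the hippocampal representation.
#' @param params a \code{\link{fear_params}} object.
#' @param categorized if \code{FALSE}, returns \code{kappa_o}.
#' @return Proportion in [0, 1].
#' @examples
#' unc_ceiling(85, fear_params())   # ~0.327
#' unc_ceiling(0, fear_params())    # kappa = 0.3
#' @export
unc_ceiling <- function(z_rec, params, categorized = TRUE) {
  if (z_rec > params$N_atr) stop("z_rec exceeds N_atr")
  if (!categorized) return(params$kappa_o)
  params$kappa + (1 - params$kappa) * (z_rec / params$N_atr)^params$epsilon
}

## Build the knowledge content of a cortical representation from its
## hippocampal precursor's knowledge. Returns list(know, category).
consolidate_knowledge <- function(know, world, categories, params) {
  p <- params
  idc <- identify_category(know, world, categories, params)
  z_rec <- know_zrec(know)
  if (!is.null(idc)) {
    cat_attrs <- categories[[idc$category]]
    ceil <- unc_ceiling(z_rec, p, categorized = TRUE)
    cap <- floor(ceil * p$N_ptc)
    if (know_is_set(know)) {
      pool <- setdiff(know$set, cat_attrs)
      u <- min(length(pool), cap)
      uncs <- if (u > 0) pool[sample.int(length(pool), u)] else integer(0)
      new_know <- know_from_set(know$ctx, union(cat_attrs, uncs))
    } else {
      pool <- know$k_ptc           # category knows all categorical attrs
      u <- min(round(pool), cap)
      new_know <- know_from_counts(know$ctx, p$N_cat, u)
    }
    list(know = new_know, category = idc$category)
  } else {
    cap <- floor(p$kappa_o * p$N_ptc)
    if (know_is_set(know)) {
      u <- min(length(know$set), cap)
      uncs <- know$set[sample.int(length(know$set), u)]
      new_know <- know_from_set(know$ctx, uncs)
    } else {
      pool <- know$k_cat + know$k_ptc
      u <- min(round(pool), cap)
      frac <- if (pool > 0) u / pool else 0
      new_know <- know_from_counts(know$ctx, know$k_cat * frac,
                                   know$k_ptc * frac)
    }
    list(know = new_know, category = NA_character_)
  }
}

#' Effective recalled-attribute count of a cortical representation
#'
#' A cortical representation cell drives the recalled-attribute cells of
#' its retained unclassified attributes and, through its category cell,
#' all of the category's known attributes; this sum is the \code{Z_rec}
#' entering the evidence computation.
#'
#' @param rep an agent representation of kind \code{"cort"}.
#' @param categories named list of known-category attribute sets.
#' @return Integer count.
#' @export
cortical_zrec <- function(rep, categories) {
  know_zrec(rep$know)
}

#' Similarity of two contexts for cortical generalization
#'
#' When both representations are categorized the similarity weighs the
#' particular- and categorical-attribute overlaps:
#' \deqn{S_{AB} = \gamma O_{ptcAB} + (1 - \gamma) O_{catAB}}
#' When the pair is not both categorized, similarity is simply the overlap
#' of the totality of their attributes, \code{o_atr}.
#'
#' @param o_ptc,o_cat,o_atr overlap proportions in [0, 1].
#' @param gamma weighting of particular-attribute similarity.
#' @param both_categorized logical flag.
#' @return Similarity in [0, 1].
#' @examples
#' similarity(0.6, 1, 0.6, TRUE, o_atr = 0.68)   # 0.76
#' @export
similarity <- function(o_ptc, o_cat, gamma, both_categorized, o_atr) {
  stopifnot(o_ptc >= 0, o_ptc <= 1, o_cat >= 0, o_cat <= 1,
            o_atr >= 0, o_atr <= 1)
  if (both_categorized) gamma * o_ptc + (1 - gamma) * o_cat else o_atr
}

#' Tabulate the cortical generalization function G
#'
#' Generalization between two remote representations equals the expected
#' CA3 overlap of hippocampal representations of contexts with the same
#' total attribute overlap, when all \code{N_atr} attributes are known at
#' creation. The table is a Monte-Carlo estimate of that curve on a grid
#' of overlap values; \code{\link{cortical_generalization}} interpolates
#' it. A single wiring may be supplied (one individual's brain, contexts
#' redrawn per replicate) which is much faster; otherwise wiring is
#' redrawn per replicate.
#'
#' @param params a \code{\link{fear_params}} object.
#' @param n_mc Monte-Carlo replicates per grid point.
#' @param grid overlap grid in [0, 1].
#' @param wiring optional \code{"dg_wiring"} reused across replicates.
#' @return Data frame with columns \code{o_atr}, \code{mean}, \code{sd},
#'   \code{n}, usable as the \code{g_table} of an agent or exportable with
#'   \code{write.csv}.
#' @export
make_g_table <- function(params = fear_params(), n_mc = 20,
                         grid = seq(0, 1, length.out = 21), wiring = NULL) {
  p <- params
  if (!is.null(wiring)) {
    ## batch all (replicate x grid) context pairs through one wiring
    res <- matrix(NA_real_, length(grid), n_mc)
    for (r in seq_len(n_mc)) {
      sets <- list()
      for (gi in seq_along(grid)) {
        n_shared <- round(grid[gi] * p$N_atr)
        n_own <- p$N_atr - n_shared
        pool <- sample.int(p$N_ctx)
        a <- pool[seq_len(p$N_atr)]
        b <- c(a[seq_len(n_shared)],
               pool[p$N_atr + seq_len(n_own)])
        sets[[2 * gi - 1]] <- a
        sets[[2 * gi]] <- b
      }
      sc <- wiring_scores(wiring, sets)
      for (gi in seq_along(grid)) {
        ka <- order(-sc[, 2 * gi - 1], wiring$tie)[seq_len(p$K)]
        kb <- order(-sc[, 2 * gi], wiring$tie)[seq_len(p$K)]
        res[gi, r] <- length(intersect(ka, kb)) / p$K
      }
    }
    data.frame(o_atr = grid, mean = rowMeans(res),
               sd = apply(res, 1, stats::sd), n = n_mc)
  } else {
    rows <- lapply(grid, function(o) {
      eo <- expected_overlap(o, p$N_atr, p$N_atr, p, n_mc = n_mc)
      data.frame(o_atr = o, mean = eo$mean, sd = eo$sd, n = n_mc)
    })
    do.call(rbind, rows)
  }
}

#' Cortical generalization between two remote representations
#'
#' Monotone piecewise-linear interpolation of the tabulated G curve; the
#' table's means are made nondecreasing (cumulative maximum) before
#' interpolation and G(1) = 1 by construction (identical attribute sets
#' select identical winners).
#'
#' @param s_ab similarity in [0, 1] from \code{\link{similarity}}.
#' @param g_table a table from \code{\link{make_g_table}}.
#' @return Generalized response fraction in [0, 1].
#' @export
cortical_generalization <- function(s_ab, g_table) {
  if (s_ab < 0 || s_ab > 1) stop("similarity outside [0, 1]")
  y <- cummax(g_table$mean)
  stats::approx(g_table$o_atr, y, xout = s_ab, rule = 2)$y
}
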