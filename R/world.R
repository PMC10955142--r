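#' Create a synthetic context world
#'
#' A world is the attribute universe of \code{N_ctx} representable
#' attributes plus a registry of categories and contexts. Every context has
#' exactly \code{N_atr} attributes: \code{N_cat} categorical attributes
#' shared bit-identically by all contexts in its category, and \code{N_ptc}
#' particular attributes specific to the context. Overlaps between contexts
#' are constructed exactly (shared attributes are chosen, not rejection
#' sampled), so a requested overlap proportion is realized as its rounded
#' count.
#'
#' @param params a \code{\link{fear_params}} object.
#' @param seed optional integer; if given, \code{set.seed} is called so the
#'   world is reproducible on its own. Otherwise the ambient RNG is used.
#' @return A list of class \code{"fear_world"} with elements
#'   \code{params}, \code{categories} (named list of attribute vectors),
#'   \code{contexts} (named list; each has \code{id}, \code{category},
#'   \code{cat_attrs}, \code{ptc_attrs}) and an internal fresh-attribute
#'   cursor.
#' @seealso \code{\link{add_category}}, \code{\link{add_context}}
#' @export
make_world <- function(params = fear_params(), seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  w <- list(params = params, categories = list(), contexts = list(),
            used = integer(0))
  class(w) <- "fear_world"
  w
}

## draw n attribute indices never used by any existing category/context
fresh_attrs <- function(world, n) {
  pool <- setdiff(seq_len(world$params$N_ctx), world$used)
  if (length(pool) < n)
    stop("attribute pool exhausted: cannot draw ", n, " fresh attributes")
  if (n == 0) return(integer(0))
  pool[sample.int(length(pool), n)]
}

#' Add a category to a world
#'
#' A category is a fixed set of \code{N_cat} attributes shared by all its
#' member contexts. With an \code{anchor} category, exactly
#' \code{round(o_cat * N_cat)} attributes are shared with the anchor and the
#' rest are fresh (never used elsewhere), so the categorical overlap between
#' the two categories equals the requested proportion exactly.
#'
#' @param world a \code{"fear_world"}.
#' @param id character id for the category.
#' @param anchor optional id of an existing category to overlap with.
#' @param o_cat target categorical overlap proportion with the anchor.
#' @return The updated world.
#' @export
add_category <- function(world, id, anchor = NULL, o_cat = NULL) {
  p <- world$params
  if (id %in% names(world$categories)) stop("category already exists: ", id)
  if (is.null(anchor)) {
    attrs <- fresh_attrs(world, p$N_cat)
  } else {
    base <- world$categories[[anchor]]
    if (is.null(base)) stop("unknown anchor category: ", anchor)
    if (is.null(o_cat)) o_cat <- p$O_catHet
    n_shared <- round(o_cat * p$N_cat)
    shared <- base[sample.int(length(base), n_shared)]
    attrs <- c(shared, fresh_attrs(world, p$N_cat - n_shared))
  }
  world$categories[[id]] <- sort(attrs)
  world$used <- union(world$used, attrs)
  world
}

#' Add a context to a world
#'
#' The context's categorical attributes are those of its category. Its
#' particular attributes share exactly \code{round(o_ptc * N_ptc)}
#' attributes with the anchor context's particulars (when an anchor is
#' given) and are otherwise fresh, so realized overlaps equal their rounded
#' targets. Without an anchor the particulars are entirely fresh.
#'
#' @param world a \code{"fear_world"}.
#' @param id character id for the context.
#' @param category id of an existing category.
#' @param anchor optional id of an existing context whose particulars are
#'   partially shared.
#' @param o_ptc target particular-attribute overlap proportion with the
#'   anchor (defaults to \code{O_ptcHom} for a same-category anchor and
#'   \code{O_ptcHet} otherwise).
#' @return The updated world.
#' @export
add_context <- function(world, id, category, anchor = NULL, o_ptc = NULL) {
  p <- world$params
  if (id %in% names(world$contexts)) stop("context already exists: ", id)
  cat_attrs <- world$categories[[category]]
  if (is.null(cat_attrs)) stop("unknown category: ", category)
  if (is.null(anchor)) {
    ptc <- fresh_attrs(world, p$N_ptc)
  } else {
    a <- world$contexts[[anchor]]
    if (is.null(a)) stop("unknown anchor context: ", anchor)
    if (is.null(o_ptc))
      o_ptc <- if (identical(a$category, category)) p$O_ptcHom else p$O_ptcHet
    n_shared <- round(o_ptc * p$N_ptc)
    shared <- a$ptc_attrs[sample.int(length(a$ptc_attrs), n_shared)]
    ptc <- c(shared, fresh_attrs(world, p$N_ptc - n_shared))
  }
  stopifnot(length(intersect(cat_attrs, ptc)) == 0)
  world$contexts[[id]] <- list(id = id, category = category,
                               cat_attrs = cat_attrs, ptc_attrs = sort(ptc))
  world$used <- union(world$used, ptc)
  world
}

#' All attributes of a context
#' @param world a \code{"fear_world"}.
#' @param id context id.
#' @return Integer vector of length \code{N_atr}.
#' @export
context_attrs <- function(world, id) {
  ctx <- world$contexts[[id]]
  if (is.null(ctx)) stop("unknown context: ", id)
  c(ctx$cat_attrs, ctx$ptc_attrs)
}

#' Pairwise overlap structure of two contexts
#'
#' @param world a \code{"fear_world"}.
#' @param a,b context ids.
#' @return List with realized overlap proportions \code{o_cat},
#'   \code{o_ptc}, \code{o_atr} and the raw shared-attribute count
#'   \code{n_shared} (computed on the full attribute sets, so incidental
#'   cross-stratum sharing is included in \code{o_atr}).
#' @export
context_overlap <- function(world, a, b) {
  p <- world$params
  ca <- world$contexts[[a]]; cb <- world$contexts[[b]]
  if (is.null(ca) || is.null(cb)) stop("unknown context id")
  n_cat <- length(intersect(ca$cat_attrs, cb$cat_attrs))
  n_ptc <- length(intersect(ca$ptc_attrs, cb$ptc_attrs))
  n_all <- length(intersect(context_attrs(world, a), context_attrs(world, b)))
  list(o_cat = n_cat / p$N_cat, o_ptc = n_ptc / p$N_ptc,
       o_atr = n_all / p$N_atr, n_shared = n_all)
}

#' Observation stream for a session in a context
#'
#' The agent samples one new attribute of the context per computational
#' interval, in random order without replacement. In \code{"stochastic"}
#' mode the stream is a seeded uniform permutation prefix of the context's
#' attributes; in \code{"expected_value"} mode only the cumulative count
#' \code{Z_cur} per interval is defined and expected match counts are
#' computed downstream.
#'
#' @param world a \code{"fear_world"}.
#' @param id context id.
#' @param length number of intervals (must not exceed \code{N_atr}).
#' @param mode \code{"expected_value"} or \code{"stochastic"}.
#' @return List of class \code{"observation_stream"} with \code{context_id},
#'   \code{mode}, \code{z_cur} (1..length) and, in stochastic mode,
#'   \code{order} (the sampled attribute order).
#' @export
observation_stream <- function(world, id,
                               length,
                               mode = c("expected_value", "stochastic")) {
  mode <- match.arg(mode)
  attrs <- context_attrs(world, id)
  if (length > length(attrs))
    stop("session length ", length, " exceeds N_atr = ", length(attrs))
  out <- list(context_id = id, mode = mode, z_cur = seq_len(length))
  if (mode == "stochastic")
    out$order <- attrs[sample.int(length(attrs), length)]
  class(out) <- "observation_stream"
  out
}

#' Expected number of matches after partial observation
#'
#' When \code{Z_cur} of a context's \code{N_atr} attributes have been
#' sampled without replacement and \code{n_shared} of those attributes are
#' in a representation's associated set, the expected number of matches is
#' \code{Z_cur * n_shared / N_atr}, rounded to the nearest integer (the
#' model works with integer match counts).
#'
#' @param z_cur attributes observed so far.
#' @param n_shared attributes shared between the context's true set and the
#'   representation's associated set.
#' @param n_atr attributes per context.
#' @return Integer expected match count \code{Z_com}.
#' @examples
#' expected_common(45, 68, 100)  # 31
#' @export
expected_common <- function(z_cur, n_shared, n_atr) {
  stopifnot(z_cur >= 0, z_cur <= n_atr, n_shared >= 0, n_shared <= n_atr)
  round(z_cur * n_shared / n_atr)
}
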