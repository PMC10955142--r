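#' Model parameters
#'
#' Returns the full parameter set of the simulator, with defaults set to the
#' standard calibration used throughout the package's experiments. Any
#' parameter can be overridden by name.
#'
#' The parameters fall into three groups:
#' \describe{
#'   \item{World / coding}{\code{N_ctx} representable attributes (cortical
#'     attribute cell kinds); \code{N_atr} attributes per context, split into
#'     \code{N_cat} categorical and \code{N_ptc} particular attributes;
#'     \code{F} attribute cells innervating each dentate gyrus (DG) cell;
#'     \code{K} DG/CA3 winners per representation; \code{N_dg} DG cells.}
#'   \item{Weight-of-evidence thresholds}{All on the \code{b_rep} (log10
#'     likelihood-ratio) scale: \code{B_new} (below which a new
#'     representation is made), \code{B_add} (above which end-of-session
#'     updating occurs), \code{B_cnd} / \code{B_mxCnd} (conditionability
#'     ramp), \code{B_mxF} (fear-expression ramp plateau), \code{B_cat}
#'     (category identification), and the winner margin \code{delta}.}
#'   \item{Systems consolidation}{\code{O_catHet}, \code{O_ptcHet},
#'     \code{O_ptcHom} overlap proportions for unrelated contexts;
#'     \code{P_oCat} and \code{Z_oRec} describing how much is known about
#'     long-established contexts; the unclassified-attribute retention
#'     ceilings \code{kappa}, \code{kappa_o} and exponent \code{epsilon};
#'     the similarity weighting \code{gamma}; the learning-rate
#'     \code{alpha}; and the amygdala equilibrium potential \code{E}
#'     (arbitrary units; only ratios to \code{E} matter).}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class \code{"fear_params"}.
#' @examples
#' p <- fear_params()
#' p$N_atr            # 100 attributes per context
#' fear_params(N_dg = 20000)$N_dg
#' @export
fear_params <- function(...) {
  p <- list(
    N_ctx   = 1000,
    N_atr   = 100,
    N_cat   = 20,
    N_ptc   = 80,
    F       = 60,
    K       = 60,
    N_dg    = 100000,
    B_new   = -5,
    B_add   = 15,
    B_cnd   = 2,
    B_mxCnd = 12,
    B_mxF   = 4,
    B_cat   = 5,
    alpha   = 1 / 60,
    O_catHet = 0.2,
    O_ptcHet = 0.2,
    O_ptcHom = 0.2,
    P_oCat  = 0.85,
    Z_oRec  = 85,
    kappa   = 0.3,
    kappa_o = 0.8,
    epsilon = 20,
    gamma   = 0.6,
    delta   = 5,
    E       = 1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
  class(p) <- "fear_params"
  p
}

validate_params <- function(p) {
  stopifnot(
    p$N_atr == p$N_cat + p$N_ptc,
    p$N_atr <= p$N_ctx,
    p$F <= p$N_ctx,
    p$K <= p$N_dg,
    p$B_new < 0, p$B_cnd > 0, p$B_cnd < p$B_mxCnd, p$B_add > p$B_cnd,
    p$kappa >= 0, p$kappa <= p$kappa_o, p$kappa_o <= 1,
    p$gamma >= 0, p$gamma <= 1,
    p$epsilon > 0,
    p$alpha > 0, p$E > 0, p$delta >= 0,
    p$Z_oRec <= p$N_atr
  )
  for (nm in c("O_catHet", "O_ptcHet", "O_ptcHom", "P_oCat"))
    stopifnot(p[[nm]] >= 0, p[[nm]] <= 1)
  invisible(p)
}

#' Read parameters from a YAML configuration file
#'
#' The file holds \code{key: value} pairs named exactly as in
#' \code{\link{fear_params}} (e.g. \code{N_ctx}, \code{kappa_o},
#' \code{alpha}); keys that are absent keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A \code{"fear_params"} list.
#' @export
read_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(fear_params, cfg)
}

#' @export
print.fear_params <- function(x, ...) {
  cat("<fear_params>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
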