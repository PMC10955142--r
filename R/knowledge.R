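## Internal bookkeeping of the attributes associated with a representation.
##
## Two interchangeable forms, both tied to the context the representation
## was built from:
##   - set form (stochastic mode): a concrete attribute index vector.
##   - count form (expected-value mode): expected counts (k_cat, k_ptc) of
##     associated attributes per stratum, each assumed uniform within its
##     stratum. Counts may be fractional; integers are produced only where
##     the model needs them (Z_rec, n_shared), by rounding.
##
## The count form implements the convention that the weight of evidence is
## based on expected values of Z_rec and Z_com given prior experience:
## the expected overlap of a uniform k-subset of stratum S with any target
## attribute set D is k * |S intersect D| / |S|.

know_from_set <- function(ctx, set) {
  list(ctx = ctx, set = as.integer(set), k_cat = NA_real_, k_ptc = NA_real_,
       born_session = NA_integer_)
}

know_from_counts <- function(ctx, k_cat, k_ptc) {
  list(ctx = ctx, set = NULL, k_cat = k_cat, k_ptc = k_ptc,
       born_session = NA_integer_)
}

## expected (or exact) counts from observing z attributes of the context
know_from_observation <- function(world, ctx, z, observed_set = NULL) {
  p <- world$params
  if (!is.null(observed_set)) return(know_from_set(ctx, observed_set))
  know_from_counts(ctx, z * p$N_cat / p$N_atr, z * p$N_ptc / p$N_atr)
}

know_is_set <- function(know) !is.null(know$set)

know_zrec <- function(know) {
  if (know_is_set(know)) length(know$set) else round(know$k_cat + know$k_ptc)
}

## shared attribute count between the associated set and target context's
## full attribute set (exact for set form; rounded stratified expectation
## for count form)
know_shared <- function(know, world, target_ctx) {
  d <- context_attrs(world, target_ctx)
  if (know_is_set(know)) return(length(intersect(know$set, d)))
  p <- world$params
  c_ctx <- world$contexts[[know$ctx]]
  s_cat <- length(intersect(c_ctx$cat_attrs, d)) / p$N_cat
  s_ptc <- length(intersect(c_ctx$ptc_attrs, d)) / p$N_ptc
  round(know$k_cat * s_cat + know$k_ptc * s_ptc)
}

## shared count with an arbitrary attribute set (used for category
## identification)
know_shared_set <- function(know, world, target_attrs) {
  if (know_is_set(know)) return(length(intersect(know$set, target_attrs)))
  p <- world$params
  c_ctx <- world$contexts[[know$ctx]]
  s_cat <- length(intersect(c_ctx$cat_attrs, target_attrs)) / p$N_cat
  s_ptc <- length(intersect(c_ctx$ptc_attrs, target_attrs)) / p$N_ptc
  round(know$k_cat * s_cat + know$k_ptc * s_ptc)
}

## union with this session's observations in the representation's own
## context. `nested` marks that the existing associations are a subset of
## the session's observed set (the representation was created or rebuilt
## from this very session), in which case the union is a stratum-wise max;
## otherwise the two samples are independent uniform draws and the union
## count is n * (1 - (1 - k1/n)(1 - k2/n)).
know_union_observation <- function(know, world, z, observed_set = NULL,
                                   nested = FALSE) {
  p <- world$params
  if (know_is_set(know)) {
    stopifnot(!is.null(observed_set))
    know$set <- union(know$set, as.integer(observed_set))
    return(know)
  }
  z_cat <- z * p$N_cat / p$N_atr
  z_ptc <- z * p$N_ptc / p$N_atr
  if (nested) {
    know$k_cat <- max(know$k_cat, z_cat)
    know$k_ptc <- max(know$k_ptc, z_ptc)
  } else {
    know$k_cat <- p$N_cat * (1 - (1 - know$k_cat / p$N_cat) * (1 - z_cat / p$N_cat))
    know$k_ptc <- p$N_ptc * (1 - (1 - know$k_ptc / p$N_ptc) * (1 - z_ptc / p$N_ptc))
  }
  know
}

## make the full categorical stratum known (category attributes recalled
## through the category cell)
know_add_category <- function(know, world, cat_attrs) {
  if (know_is_set(know)) {
    know$set <- union(know$set, cat_attrs)
    return(know)
  }
  know$k_cat <- world$params$N_cat
  know
}

## realize a concrete attribute set consistent with the counts (for DG
## scoring in expected-value mode; uses the ambient RNG)
know_realize <- function(know, world) {
  if (know_is_set(know)) return(know$set)
  c_ctx <- world$contexts[[know$ctx]]
  kc <- min(round(know$k_cat), length(c_ctx$cat_attrs))
  kp <- min(round(know$k_ptc), length(c_ctx$ptc_attrs))
  c(c_ctx$cat_attrs[sample.int(length(c_ctx$cat_attrs), kc)],
    c_ctx$ptc_attrs[sample.int(length(c_ctx$ptc_attrs), kp)])
}
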