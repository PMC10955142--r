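# Reduced dentate-gyrus profile for fast tests. The evidence trajectories,
# decision rules and all event coordinates are independent of N_dg (it only
# shapes CA3 overlap tails of the fear readout), so the qualitative
# behaviour is unchanged.
test_params <- function(...) fear_params(N_dg = 20000, ...)

# Memoized experiment runs shared across test files (all deterministic in
# expected-value mode under the fixed seed).
.exp_cache <- new.env(parent = emptyenv())

cached_experiment <- function(name, seed = 1) {
  key <- paste(name, seed, sep = "#")
  if (is.null(.exp_cache[[key]]))
    .exp_cache[[key]] <- run_experiment(name, test_params(), seed = seed)
  .exp_cache[[key]]
}

arm_value <- function(report, arm, col = "mean_fear") {
  report$arms[[col]][report$arms$arm == arm]
}
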