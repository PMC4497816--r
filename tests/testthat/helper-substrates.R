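# small shared substrates, built once per test run
small_wt <- function(n = 200, seed = 101) {
  build_substrate("wild_type", n_r = n, n_sc = n, seed = seed)
}

tiny_wt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- small_wt(60, seed = 77)
    cache
  }
})

# medium substrate reused by analysis-oracle tests (fixture analyses want
# realistic point densities)
medium_wt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_substrate("wild_type", n_r = 1500,
                                                  n_sc = 1500, seed = 55)
    cache
  }
})
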