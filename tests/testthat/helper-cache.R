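# The full default-cohort pipeline run is shared across test files.
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(seed = 20240317L)
    cache
  }
})
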