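# The default synthetic study (seed 42) and its full pipeline run are
# shared across test files; both are computed once per test session.

sim42 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateLibraries(simulationConfig(seed = 42))
    cache
  }
})

run42 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- sim42()
      od <- file.path(tempdir(), "run42out")
      cfg <- pipelineConfig(fastq = sim$reads, genome = sim$genome,
                            matureRef = sim$matureRef,
                            precursorRef = sim$precursorRef,
                            decoys = sim$decoys, seed = 42, outdir = od)
      cache <<- runPipeline(cfg)
    }
    cache
  }
})
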