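# Shared simulated studies, built once per test run.

.studyCache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 11L, depth = 6000L, ...) {
  simulationConfig(seed = seed, nChromosomes = 2L,
                   chromosomeLength = 200000L, nPrecursors = 4L,
                   nClusters = 1L, libraryDepth = as.integer(depth), ...)
}

smallStudy <- function() {
  if (is.null(.studyCache$small)) {
    cfg <- smallConfig()
    .studyCache$small <- c(simulateStudy(cfg), list(cfg = cfg))
  }
  .studyCache$small
}

# Full-size study under the default generator conditions (three libraries,
# 1e5 reads each), with the complete pipeline run once and shared.
fullStudy <- function() {
  if (is.null(.studyCache$full)) {
    cfg <- simulationConfig(seed = 20260927L)
    st <- simulateStudy(cfg)
    res <- runProfiling(st, cfg)
    .studyCache$full <- c(st, list(cfg = cfg, res = res))
  }
  .studyCache$full
}
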