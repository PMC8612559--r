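# models are expensive to discretize only once per session
.cache <- new.env(parent = emptyenv())

ball_model <- function() {
  if (is.null(.cache$ball)) .cache$ball <- buildModel(ballMorphology())
  .cache$ball
}

bs_model <- function() {
  if (is.null(.cache$bs)) .cache$bs <- buildModel(ballAndStickMorphology())
  .cache$bs
}

small_synth_model <- function() {
  if (is.null(.cache$synth)) {
    spec <- SyntheticMorphologySpec(nDendrites = 10, segRange = c(2, 40),
                                    segLength = 7, branchDepth = 2, seed = 7)
    .cache$synth <- buildModel(generateSyntheticMorphology(spec))
  }
  .cache$synth
}

passive_cfg <- function(tstop, ...) SolverConfig(tstop = tstop,
                                                 apMechanism = FALSE, ...)
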