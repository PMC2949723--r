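# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Fixed per-stage seed offsets: one global seed reproduces each stage
# independently.
stage_seed <- function(seed, stage) {
  offsets <- c(expression = 101L, refdb = 211L, permutation = 307L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
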