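# RNG discipline: functions taking a seed must not perturb the caller's
# random stream, so the global state is saved and restored around the draw.
.seedRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# deterministic small sub-seed derived from a base seed and a salt,
# kept well below .Machine$integer.max
.deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt * 104729) %% 2147483587)
}
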