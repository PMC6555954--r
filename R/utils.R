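# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a pipeline stage, kept within 32-bit range.
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

# Uniform draw of n integers from [a, b]; safe for a == b (unlike sample()).
sample_int_range <- function(a, b, n) {
  v <- seq.int(a, b)
  v[sample.int(length(v), n, replace = TRUE)]
}

# Uniform random DNA of given lengths, as character vector.
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}
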