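# Internal helpers: seeded evaluation, deterministic seed derivation,
# truncated-normal draws.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
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
  code
}

# Deterministic 31-bit seed from a master seed and a string key.
# Polynomial rolling hash mod 2^31 - 1; exact in double arithmetic.
deriveSeed <- function(master, key) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(as.character(key))) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Truncated-normal draws by rejection; at most `maxAttempts` resamples per
# value before erroring (degenerate configurations should fail loudly).
rtruncnorm <- function(n, mean, sd, lo, maxAttempts = 100L) {
  if (sd <= 0) {
    if (mean < lo) stop("truncated normal: mean below lower bound with sd = 0")
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(maxAttempts)) {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lo) {
        out[i] <- x
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("truncated normal: no admissible draw after ", maxAttempts, " attempts")
  }
  out
}

# md5 of an R object via its serialization (no binary artifacts kept).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}
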