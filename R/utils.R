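# Internal helpers: seeded evaluation, seed derivation, sample skewness.

# Evaluate `expr` under a local RNG stream started at `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of
# (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic polynomial hash of a stage label folded into the master
#' seed, kept below 2^31 so it is a valid R integer seed.  Adding a stage
#' never perturbs the seeds of existing stages.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. "simulate:panel".
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(master, label) {
  stopifnot(length(label) == 1, is.character(label))
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# Sample skewness (moment estimator m3 / m2^{3/2}).
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Pearson correlation that returns NA (not an error) on degenerate input.
safeCor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) return(NA_real_)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}
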