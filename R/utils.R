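# Run code under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Smooth band-correlated noise: iid Gaussian filtered with a Gaussian kernel
# whose weights are normalised to unit sum of squares, so each band keeps
# marginal standard deviation `sd` while neighbouring bands are correlated.
.correlatedNoise <- function(n, nsig, sd, corr_halfwidth = 2L) {
  if (sd == 0) return(matrix(0, n, nsig))
  kw <- dnorm(seq(-3L * corr_halfwidth, 3L * corr_halfwidth),
              sd = corr_halfwidth)
  kw <- kw / sqrt(sum(kw^2))
  pad <- length(kw) - 1L
  Z <- matrix(rnorm((n + pad) * nsig), n + pad, nsig)
  out <- matrix(0, n, nsig)
  for (j in seq_along(kw)) {
    out <- out + kw[j] * Z[j:(j + n - 1L), , drop = FALSE]
  }
  out * sd
}
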