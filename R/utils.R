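# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps field generation and cell sampling
# deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Reflection (symmetric, edge included) index vector covering 1-k .. n+k.
reflect_idx <- function(n, k) {
  i <- seq.int(1L - k, n + k)
  j <- (i - 1L) %% (2L * n)            # R's %% is always non-negative
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Mirror-pad a matrix by `k` pixels on every side; reflection includes the
# edge row/col so constant images stay exactly constant and any k works.
pad_reflect <- function(m, k) {
  m[reflect_idx(nrow(m), k), reflect_idx(ncol(m), k), drop = FALSE]
}

# Gaussian blur of a plain matrix with reflective boundary handling.
# EBImage::filter2 uses circular (FFT) boundaries, so we mirror-pad by the
# kernel half-width first; the kernel is truncated at 4 sigma so that the
# mass of an interior impulse is conserved to well under 0.1%.
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  half <- as.integer(ceiling(4 * sigma))
  size <- 2L * half + 1L
  brush <- EBImage::makeBrush(size = size, shape = "Gaussian", sigma = sigma)
  mp <- pad_reflect(m, half)   # padded dims are always >= kernel size
  out <- EBImage::filter2(mp, brush)
  out[(half + 1L):(half + nrow(m)), (half + 1L):(half + ncol(m)), drop = FALSE]
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
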