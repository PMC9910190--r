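# Independent brute-force Otsu oracle: for every candidate split t it
# recomputes the class probabilities and means directly from the definition
# sums (no cumulative-sum shortcuts) and scores the split with the
# two-term form of the between-class variance. Ties resolve to smallest t,
# matching the package convention.
oracle_otsu <- function(probs, mids) {
  L <- length(probs)
  mu_T <- sum(probs * mids)
  best_t <- NA_integer_
  best_sigma <- -Inf
  for (t in seq_len(L - 1L)) {
    w0 <- sum(probs[1:t])
    w1 <- sum(probs[(t + 1):L])
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(probs[1:t] * mids[1:t]) / w0
    mu1 <- sum(probs[(t + 1):L] * mids[(t + 1):L]) / w1
    sigma <- w0 * (mu0 - mu_T)^2 + w1 * (mu1 - mu_T)^2
    if (sigma > best_sigma) {
      best_sigma <- sigma
      best_t <- t
    }
  }
  list(t = best_t, sigma_b2 = best_sigma)
}

random_histogram <- function(bins) {
  counts <- rpois(bins, lambda = runif(1, 0.5, 20))
  if (sum(counts > 0) < 2L) {
    counts[1L] <- counts[1L] + 1L
    counts[bins] <- counts[bins] + 1L
  }
  edges <- seq(0, 1, length.out = bins + 1L)
  structure(list(edges = edges, mids = (edges[-1L] + edges[-(bins + 1L)]) / 2,
                 counts = counts, n = sum(counts),
                 probs = counts / sum(counts)),
            class = "otsu_histogram")
}

grid_of <- function(values, pixel_m = 10) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  raster_grid(values, pixel_m = pixel_m)
}

# Scene with constant-valued bands, for hand-arithmetic index checks.
const_scene <- function(..., n = 2L, pixel_m = 10) {
  vals <- list(...)
  bands <- lapply(vals, function(v) raster_grid(matrix(v, n, n), pixel_m = pixel_m))
  scene(bands)
}

# Level rasters with prescribed (pre, post) pair counts, for transfer tests.
levels_from_counts <- function(pairs, pixel_m = 10) {
  pre <- rep(pairs$pre, pairs$n)
  post <- rep(pairs$post, pairs$n)
  n <- length(pre)
  nr <- ceiling(sqrt(n))
  pad <- nr * nr - n
  list(pre = raster_grid(matrix(c(pre, rep(NA, pad)), nr, nr), pixel_m = pixel_m),
       post = raster_grid(matrix(c(post, rep(NA, pad)), nr, nr), pixel_m = pixel_m))
}
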