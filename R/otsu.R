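#' Histogram of a continuous raster
#'
#' Discretizes the valid (unmasked) values of a grid into `bins` equal-width
#' gray levels over the data min-max range (or an explicit `range`). Values
#' falling exactly on the top edge are assigned to the last bin; with an
#' explicit range, values outside it are dropped.
#'
#' @param grid A [raster_grid], or a numeric vector of values.
#' @param bins Number of gray levels L (>= 2); default 256, the native 8-bit
#'   formulation of Otsu thresholding.
#' @param range Optional `c(lo, hi)` histogram support.
#' @return An object of class `otsu_histogram`: `edges` (L+1 ascending
#'   breaks), `mids`, `counts` (n_i), `n` (N) and `probs` (P_i = n_i / N,
#'   summing to 1).
#' @export
build_histogram <- function(grid, bins = 256, range = NULL) {
  x <- if (is_raster_grid(grid)) valid_values(grid) else grid[!is.na(grid)]
  if (bins < 2) stop("`bins` must be >= 2", call. = FALSE)
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] < range[2])
    x <- x[x >= range[1] & x <= range[2]]
    lo <- range[1]; hi <- range[2]
  } else {
    if (length(unique(x)) < 2L)
      stop("degenerate input: histogram needs >= 2 distinct valid values",
           call. = FALSE)
    lo <- min(x); hi <- max(x)
  }
  if (length(x) < 2L || lo >= hi)
    stop("degenerate input: histogram needs >= 2 distinct valid values",
         call. = FALSE)
  w <- (hi - lo) / bins
  idx <- pmin(floor((x - lo) / w) + 1L, bins)  # top edge joins the last bin
  counts <- tabulate(idx, nbins = bins)
  edges <- lo + w * (0:bins)
  structure(list(edges = edges, mids = (edges[-1L] + edges[-(bins + 1L)]) / 2,
                 counts = counts, n = length(x), probs = counts / length(x)),
            class = "otsu_histogram")
}

#' Otsu threshold of a histogram
#'
#' Selects the gray-level split maximizing the between-class variance
#' `sigma_b^2(t) = omega0 * omega1 * (mu0 - mu1)^2`, where class C0 holds
#' bins 1..t with probability mass omega0 and mean mu0, and class C1 the
#' rest (equivalently, the split minimizing within-class variance). Class
#' means are computed over bin midpoints. Candidates are all t with
#' 0 < omega0 < 1; ties break to the smallest t for reproducibility.
#'
#' @param hist An `otsu_histogram` with mass in at least two bins.
#' @return An object of class `otsu_result`: `threshold_value` (the upper
#'   edge of bin t; the classification rule is value >= threshold_value ->
#'   C1), `threshold_bin` (t), class probabilities `omega0`/`omega1`, class
#'   means `mu0`/`mu1`, global mean `mu_t`, and `sigma_b2`. The full
#'   candidate scan is attached as attribute `"candidates"` (a data frame)
#'   for diagnostics.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "otsu_histogram"))
  p <- hist$probs
  m <- hist$mids
  L <- length(p)
  if (sum(p > 0) < 2L)
    stop("degenerate input: histogram has mass in fewer than 2 bins", call. = FALSE)
  cw <- cumsum(p)
  cm <- cumsum(p * m)
  mu_t <- cm[L]
  t_all <- seq_len(L - 1L)
  omega0 <- cw[t_all]
  omega1 <- 1 - omega0
  ok <- omega0 > 0 & omega0 < 1
  mu0 <- ifelse(ok, cm[t_all] / omega0, NA_real_)
  mu1 <- ifelse(ok, (mu_t - cm[t_all]) / omega1, NA_real_)
  sigma <- ifelse(ok, omega0 * omega1 * (mu0 - mu1)^2, -Inf)
  t <- which.max(sigma)  # first maximum = smallest t on ties
  res <- structure(
    list(threshold_value = hist$edges[t + 1L], threshold_bin = t,
         omega0 = omega0[t], omega1 = omega1[t],
         mu0 = mu0[t], mu1 = mu1[t], mu_t = mu_t,
         sigma_b2 = sigma[t], bins = L),
    class = "otsu_result"
  )
  attr(res, "candidates") <- data.frame(
    t = t_all, omega0 = omega0, omega1 = omega1, mu0 = mu0, mu1 = mu1,
    sigma_b2 = ifelse(is.finite(sigma), sigma, NA_real_)
  )
  res
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> threshold = %g (bin %d of %d)\n",
              x$threshold_value, x$threshold_bin, x$bins))
  cat(sprintf("  omega0 = %.4f  mu0 = %.4f | omega1 = %.4f  mu1 = %.4f | sigma_b2 = %.6g\n",
              x$omega0, x$mu0, x$omega1, x$mu1, x$sigma_b2))
  invisible(x)
}

#' Otsu threshold of a raster
#'
#' Convenience composition of [build_histogram()] and [otsu_threshold()]
#' restricted to valid pixels, optionally further restricted by a domain
#' mask (e.g. the complement of a water mask).
#'
#' @param grid A [raster_grid].
#' @param bins Number of gray levels (default 256).
#' @param domain_mask Optional logical matrix; only `TRUE` pixels enter the
#'   histogram.
#' @return An `otsu_result`.
#' @export
otsu_on_raster <- function(grid, bins = 256, domain_mask = NULL) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  if (!is.null(domain_mask)) {
    stopifnot(identical(dim(domain_mask), dim(v)))
    v[!domain_mask] <- NA_real_
  }
  x <- v[!is.na(v)]
  if (length(unique(x)) < 2L)
    stop("degenerate input: masked raster has < 2 distinct valid values",
         call. = FALSE)
  otsu_threshold(build_histogram(x, bins = bins))
}

#' Serialize an Otsu result for provenance logs
#'
#' @param x An `otsu_result`.
#' @return A JSON string with the threshold and its omega/mu/sigma
#'   diagnostics.
#' @export
otsu_to_json <- function(x) {
  stopifnot(inherits(x, "otsu_result"))
  jsonlite::toJSON(unclass(x)[c("threshold_value", "threshold_bin", "bins",
                                "omega0", "omega1", "mu0", "mu1", "mu_t",
                                "sigma_b2")],
                   auto_unbox = TRUE, digits = NA)
}
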