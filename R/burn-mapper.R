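#' Two-stage Otsu severity classification of a dNBR raster
#'
#' The decision-tree classifier: an Otsu threshold over all valid (non-water)
#' dNBR pixels separates the heavily burned class (forest loss; dNBR >=
#' threshold1); the heavy pixels are then masked out and a second Otsu
#' threshold over the remainder separates the mildly burned class (fire
#' traced; threshold2 <= dNBR < threshold1) from unburned land. A dNBR value
#' exactly equal to a threshold joins the more-burned class.
#'
#' @param dnbr_grid A [raster_grid] of dNBR values (see [dnbr()]).
#' @param bins Gray levels for each Otsu stage (default 256).
#' @param water_mask Optional logical matrix, `TRUE` over water; water pixels
#'   are excluded from both histograms and left nodata in the output.
#' @param min_patch Optional sieve: burned patches (4-connected components of
#'   a single class) smaller than this many pixels are reverted to unburned.
#'   Default 0 (off).
#' @return An object of class `severity_map`: `classes` (categorical
#'   [raster_grid], 0 unburned / 1 mild / 2 heavy, nodata outside the
#'   domain), `threshold1` (heavy cut), `threshold2` (mild cut,
#'   < threshold1), `bins`, and the two stage `otsu_result`s under
#'   `diagnostics`.
#' @examples
#' sim <- make_burn_pair(scene_spec(shape = c(48, 48), seed = 7))
#' d <- dnbr(nbr(sim$pre), nbr(sim$post))
#' sev <- classify_severity(d)
#' sev$threshold1 > sev$threshold2
#' @export
classify_severity <- function(dnbr_grid, bins = 256, water_mask = NULL,
                              min_patch = 0) {
  stopifnot(is_raster_grid(dnbr_grid))
  v <- dnbr_grid$values
  domain <- !is.na(v)
  if (!is.null(water_mask)) {
    stopifnot(identical(dim(water_mask), dim(v)))
    domain <- domain & !water_mask
  }
  if (length(unique(v[domain])) < 2L)
    stop("degenerate input at stage 1: < 2 distinct dNBR values in domain",
         call. = FALSE)
  s1 <- otsu_on_raster(dnbr_grid, bins = bins, domain_mask = domain)
  heavy <- domain & v >= s1$threshold_value

  rest <- domain & !heavy
  if (length(unique(v[rest])) < 2L)
    stop("degenerate input at stage 2: stage 1 consumed all remaining variation",
         call. = FALSE)
  s2 <- otsu_on_raster(dnbr_grid, bins = bins, domain_mask = rest)
  mild <- rest & v >= s2$threshold_value

  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[domain] <- 0
  cls[mild] <- 1
  cls[heavy] <- 2
  if (min_patch > 0) cls <- sieve_small_patches(cls, min_patch)

  structure(
    list(classes = grid_like(dnbr_grid, cls),
         threshold1 = s1$threshold_value, threshold2 = s2$threshold_value,
         bins = bins, diagnostics = list(stage1 = s1, stage2 = s2)),
    class = "severity_map"
  )
}

#' @export
print.severity_map <- function(x, ...) {
  n <- tabulate(x$classes$values + 1, nbins = 3)
  cat(sprintf("<severity_map> thresholds: heavy >= %.4f, mild >= %.4f\n",
              x$threshold1, x$threshold2))
  cat(sprintf("  pixels: %d unburned, %d mild, %d heavy\n", n[1], n[2], n[3]))
  invisible(x)
}

# Revert 4-connected burned components smaller than min_patch to unburned.
sieve_small_patches <- function(cls, min_patch) {
  for (code in c(1, 2)) {
    mask <- !is.na(cls) & cls == code
    lab <- label_components(mask)
    if (!length(lab$sizes)) next
    drop <- which(lab$sizes < min_patch)
    if (length(drop)) cls[mask][lab$labels[mask] %in% drop] <- 0
  }
  cls
}

# Iterative flood-fill labelling of TRUE cells (4-connectivity).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  sizes <- integer(0)
  todo <- which(mask)
  k <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    k <- k + 1L
    queue <- start
    labels[start] <- k
    size <- 0L
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      size <- size + length(cur)
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc2 <- cc + d[2L]
        keep <- rr >= 1L & rr <= nr & cc2 >= 1L & cc2 <= nc
        idx <- (cc2[keep] - 1L) * nr + rr[keep]
        idx <- idx[mask[idx] & labels[idx] == 0L]
        if (length(idx)) {
          labels[idx] <- k
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
    sizes[k] <- size
  }
  list(labels = labels, sizes = sizes)
}

#' Burned-area report
#'
#' Per-class pixel counts converted to areas in hm^2 using the map's pixel
#' size; the total is the burned total (heavy + mild).
#'
#' @param sev A `severity_map` from [classify_severity()].
#' @return An object of class `area_report` with fields `heavy_hm2`,
#'   `mild_hm2`, `total_hm2`, `counts` (named per-class pixel counts) and
#'   `pixel_area_hm2`.
#' @export
area_report <- function(sev) {
  stopifnot(inherits(sev, "severity_map"))
  pa <- pixel_area_hm2(sev$classes)
  v <- sev$classes$values
  counts <- c(unburned = sum(v == 0, na.rm = TRUE),
              mild = sum(v == 1, na.rm = TRUE),
              heavy = sum(v == 2, na.rm = TRUE))
  structure(
    list(heavy_hm2 = counts[["heavy"]] * pa, mild_hm2 = counts[["mild"]] * pa,
         total_hm2 = (counts[["heavy"]] + counts[["mild"]]) * pa,
         counts = counts, pixel_area_hm2 = pa),
    class = "area_report"
  )
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("<area_report> heavy %.2f + mild %.2f = %.2f hm^2 (pixel %.4g hm^2)\n",
              x$heavy_hm2, x$mild_hm2, x$total_hm2, x$pixel_area_hm2))
  invisible(x)
}
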