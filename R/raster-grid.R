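#' Single-band raster grid
#'
#' The basic data container of the package: a 2-D matrix of values with a
#' minimal geotransform (square pixels, row-major, pixel-is-area, origin at
#' the top-left corner) and an opaque CRS tag. Nodata cells are encoded as
#' `NA` in `values` and are excluded from every statistic, histogram and
#' classification in the package. All grids entering a joint analysis must
#' already be co-registered; the package performs no reprojection.
#'
#' @param values Numeric matrix (category codes or continuous values). `NA`
#'   marks nodata.
#' @param pixel_m Pixel edge length in metres (square pixels).
#' @param origin Numeric length-2, map coordinates `(x, y)` of the top-left
#'   corner of the top-left pixel.
#' @param crs_tag Opaque coordinate-reference identifier string. Grids are
#'   only comparable when their tags match.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:9, 3, 3), pixel_m = 10)
#' pixel_area_hm2(g)
#' @export
raster_grid <- function(values, pixel_m = 10, origin = c(0, 0), crs_tag = "local") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_m) || length(pixel_m) != 1L || !is.finite(pixel_m) || pixel_m <= 0)
    stop("`pixel_m` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite coordinates", call. = FALSE)
  structure(
    list(values = values, pixel_m = as.numeric(pixel_m),
         origin = as.numeric(origin), crs_tag = as.character(crs_tag)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- valid_values(x)
  cat(sprintf("<raster_grid> %d x %d @ %g m (%s)\n",
              nrow(x$values), ncol(x$values), x$pixel_m, x$crs_tag))
  cat(sprintf("  valid: %d / %d", length(v), length(x$values)))
  if (length(v)) cat(sprintf("  range: [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Pixel area in square hectometres
#'
#' Area of one pixel in hm^2 (hectares): `pixel_m^2 / 10000`. A 10 m pixel
#' covers 0.01 hm^2, a 30 m pixel 0.09 hm^2. All area reports in the package
#' use this unit.
#'
#' @param grid A [raster_grid].
#' @return A single number, hm^2 per pixel.
#' @export
pixel_area_hm2 <- function(grid) {
  stopifnot(is_raster_grid(grid))
  grid$pixel_m^2 / 1e4
}

#' Valid (non-nodata) values of a grid
#' @param grid A [raster_grid].
#' @return Numeric vector of the unmasked cell values.
#' @export
valid_values <- function(grid) {
  stopifnot(is_raster_grid(grid))
  grid$values[!is.na(grid$values)]
}

# Derive a new grid sharing x's georeferencing.
grid_like <- function(x, values) {
  raster_grid(values, pixel_m = x$pixel_m, origin = x$origin, crs_tag = x$crs_tag)
}

#' Check that two grids are co-registered
#'
#' Verifies shape, pixel size, origin and CRS tag agree (numeric fields to a
#' tolerance). Called internally by every pairwise raster operation.
#'
#' @param a,b [raster_grid] objects.
#' @param what Label used in the error message (e.g. an offending band name).
#' @param tol Numeric tolerance on pixel size and origin, in metres.
#' @return Invisibly `TRUE`, or an alignment error.
#' @export
check_aligned <- function(a, b, what = "raster", tol = 1e-6) {
  stopifnot(is_raster_grid(a), is_raster_grid(b))
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("alignment error in %s: shapes %dx%d vs %dx%d differ", what,
                 nrow(a$values), ncol(a$values), nrow(b$values), ncol(b$values)),
         call. = FALSE)
  if (abs(a$pixel_m - b$pixel_m) > tol)
    stop(sprintf("alignment error in %s: pixel sizes %g m vs %g m differ",
                 what, a$pixel_m, b$pixel_m), call. = FALSE)
  if (any(abs(a$origin - b$origin) > tol))
    stop(sprintf("alignment error in %s: origins differ", what), call. = FALSE)
  if (!identical(a$crs_tag, b$crs_tag))
    stop(sprintf("alignment error in %s: CRS tags '%s' vs '%s' differ",
                 what, a$crs_tag, b$crs_tag), call. = FALSE)
  invisible(TRUE)
}

#' Majority-rule resampling of a categorical raster
#'
#' Aggregates a categorical grid to a coarser, integer-multiple pixel size.
#' Each coarse cell takes the majority (modal) category of its source block;
#' ties break toward the higher code so that aggregation never erases burn
#' signal in favour of background. A coarse cell is nodata when more than
#' half of its source block is nodata.
#'
#' @param grid Categorical [raster_grid] (integer-valued codes).
#' @param target_pixel_m Target pixel size; must be an integer multiple of
#'   `grid$pixel_m`.
#' @return A coarser [raster_grid] with the same origin and CRS.
#' @examples
#' g <- raster_grid(matrix(c(2, 1, 0, 2, 1, 0, 2, 0, 0), 3, 3), pixel_m = 10)
#' resample_categorical(g, 30)$values  # majority code 0 (count 4 of 9)
#' @export
resample_categorical <- function(grid, target_pixel_m) {
  stopifnot(is_raster_grid(grid))
  f <- target_pixel_m / grid$pixel_m
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop(sprintf("unsupported resampling: %g m is not an integer multiple of %g m",
                 target_pixel_m, grid$pixel_m), call. = FALSE)
  f <- as.integer(round(f))
  if (f == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  NR <- ceiling(nr / f); NC <- ceiling(nc / f)
  block_row <- (seq_len(nr) - 1L) %/% f
  block_col <- (seq_len(nc) - 1L) %/% f
  block_id <- outer(block_row, block_col, function(r, cc) r + cc * NR) + 1L
  block_n <- tabulate(block_id, nbins = NR * NC)

  codes <- sort(unique(v[!is.na(v)]))
  best_code <- rep(NA_real_, NR * NC)
  best_count <- rep(0L, NR * NC)
  for (code in codes) {  # ascending, so '>=' keeps the higher code on ties
    cnt <- tabulate(block_id[!is.na(v) & v == code], nbins = NR * NC)
    take <- cnt > 0L & cnt >= best_count
    best_code[take] <- code
    best_count[take] <- cnt[take]
  }
  na_cnt <- tabulate(block_id[is.na(v)], nbins = NR * NC)
  best_code[na_cnt > block_n / 2] <- NA_real_

  out <- matrix(best_code, NR, NC)
  raster_grid(out, pixel_m = grid$pixel_m * f, origin = grid$origin,
              crs_tag = grid$crs_tag)
}
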