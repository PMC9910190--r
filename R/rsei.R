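#' Min-max normalization of an indicator raster
#'
#' BI = (I - I_min) / (I_max - I_min) over valid pixels, so each indicator
#' enters the principal-component fusion on an equal \[0, 1\] footing. The
#' output attains 0 and 1 exactly; any positive affine rescaling of the
#' input leaves the output unchanged.
#'
#' @param grid A [raster_grid] with at least two distinct valid values.
#' @return A [raster_grid] in \[0, 1\].
#' @export
normalize_indicator <- function(grid) {
  stopifnot(is_raster_grid(grid))
  v <- valid_values(grid)
  if (length(unique(v)) < 2L)
    stop("degenerate input: cannot min-max normalize a constant raster",
         call. = FALSE)
  lo <- min(v); hi <- max(v)
  grid_like(grid, (grid$values - lo) / (hi - lo))
}

RSEI_INDICATORS <- c("wet", "ndvi", "lst", "si")

#' Indicator stack for the ecological index
#'
#' Bundles the four raw indicator rasters (tasseled-cap wetness, NDVI, land
#' surface temperature, bare-soil dryness) with a shared validity mask: the
#' intersection of the four nodata masks minus any water mask. All
#' statistics, normalization and the PCA operate on that shared domain only.
#'
#' @param wet,ndvi,lst,si Aligned [raster_grid]s (see [wetness()], [ndvi()],
#'   [lst_smw()], [dryness_si()]).
#' @param water Optional logical matrix, `TRUE` over water (see
#'   [water_mask()]).
#' @return An object of class `indicator_stack`.
#' @export
indicator_stack <- function(wet, ndvi, lst, si, water = NULL) {
  grids <- list(wet = wet, ndvi = ndvi, lst = lst, si = si)
  for (nm in RSEI_INDICATORS) {
    stopifnot(is_raster_grid(grids[[nm]]))
    check_aligned(grids$wet, grids[[nm]], what = nm)
  }
  valid <- Reduce(`&`, lapply(grids, function(g) !is.na(g$values)))
  if (!is.null(water)) {
    stopifnot(identical(dim(water), dim(valid)))
    valid <- valid & !water
  }
  structure(list(grids = grids, valid = valid), class = "indicator_stack")
}

#' Remote Sensing Ecological Index (RSEI)
#'
#' Fuses the four normalized indicators by principal component analysis:
#' each indicator is min-max normalized over the shared valid domain, the
#' four-column pixel matrix is centered (no further scaling; the min-max
#' step already equalizes ranges) and eigen-decomposed, and the first
#' principal component — which concentrates the common ecological signal —
#' is taken as the index. PC1 is oriented so that the NDVI loading is
#' positive, which for the expected one-factor structure yields the loading
#' sign pattern wetness +, NDVI +, LST -, SI -: greener and wetter is
#' better, hotter and drier is worse. The oriented PC1 score is min-max
#' normalized again to give RSEI in \[0, 1\], then classed into five levels.
#'
#' @param stack An [indicator_stack] with at least 5 valid shared pixels.
#' @return An object of class `rsei_product`: `normalized` (list of the four
#'   \[0, 1\] indicator grids), `loadings` (4x4 matrix, indicators x PCs),
#'   `variance_share` (percent per PC, descending, summing to 100), `rsei`
#'   ([raster_grid] in \[0, 1\]) and `levels` (categorical grid, codes 1-5;
#'   see [classify_levels()]).
#' @export
compute_rsei <- function(stack) {
  stopifnot(inherits(stack, "indicator_stack"))
  valid <- stack$valid
  if (sum(valid) < 5L)
    stop("degenerate input: need >= 5 valid shared pixels", call. = FALSE)
  normalized <- list()
  X <- matrix(NA_real_, sum(valid), 4L,
              dimnames = list(NULL, RSEI_INDICATORS))
  for (nm in RSEI_INDICATORS) {
    g <- stack$grids[[nm]]
    masked <- g$values
    masked[!valid] <- NA_real_
    ng <- normalize_indicator(grid_like(g, masked))
    normalized[[nm]] <- ng
    X[, nm] <- ng$values[valid]
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  loadings <- pca$rotation
  scores1 <- pca$x[, 1L]
  if (loadings["ndvi", 1L] < 0) {  # orientation: greener must score higher
    loadings[, 1L] <- -loadings[, 1L]
    scores1 <- -scores1
  }
  variance_share <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  pc1 <- matrix(NA_real_, nrow(valid), ncol(valid))
  pc1[valid] <- scores1
  rsei <- normalize_indicator(grid_like(stack$grids$wet, pc1))
  structure(
    list(normalized = normalized, loadings = loadings,
         variance_share = variance_share, rsei = rsei,
         levels = classify_levels(rsei)),
    class = "rsei_product"
  )
}

#' @export
print.rsei_product <- function(x, ...) {
  cat("<rsei_product>\n  PC1 loadings:",
      paste(sprintf("%s %+0.4f", rownames(x$loadings), x$loadings[, 1]),
            collapse = ", "), "\n")
  cat("  variance share (%):",
      paste(sprintf("%.2f", x$variance_share), collapse = ", "), "\n")
  invisible(x)
}

RSEI_LEVEL_LABELS <- c("poor", "fair", "moderate", "good", "excellent")

#' Five-level classing of an RSEI raster
#'
#' Levels on 0.2-wide intervals, half-open on the left and closed at 1:
#' 1 poor \[0, 0.2), 2 fair \[0.2, 0.4), 3 moderate \[0.4, 0.6), 4 good
#' \[0.6, 0.8), 5 excellent \[0.8, 1\].
#'
#' @param rsei A [raster_grid] with values in \[0, 1\].
#' @return A categorical [raster_grid] with codes 1-5 and the level names
#'   attached as attribute `"labels"`.
#' @export
classify_levels <- function(rsei) {
  stopifnot(is_raster_grid(rsei))
  v <- rsei$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("domain error: RSEI values must lie in [0, 1]", call. = FALSE)
  codes <- matrix(findInterval(v, c(0.2, 0.4, 0.6, 0.8)) + 1,
                  nrow(v), ncol(v))
  codes[is.na(v)] <- NA_real_
  out <- grid_like(rsei, codes)
  attr(out, "labels") <- RSEI_LEVEL_LABELS
  out
}

RSEI_CHANGE_LABELS <- c("significant increase", "slight increase",
                        "no significant change", "slight decrease",
                        "significant decrease")

#' Pre/post RSEI change map
#'
#' Bins the per-pixel difference d = pre - post (positive d = ecological
#' decline): d < -0.2 significant increase; \[-0.2, -0.05) slight increase;
#' \[-0.05, 0.05) no significant change; \[0.05, 0.2) slight decrease;
#' d >= 0.2 significant decrease.
#'
#' @param rsei_pre,rsei_post Aligned [raster_grid]s in \[0, 1\].
#' @return A categorical [raster_grid] with codes 1-5 in the order above,
#'   labels attached as attribute `"labels"`.
#' @export
change_map <- function(rsei_pre, rsei_post) {
  check_aligned(rsei_pre, rsei_post, what = "change_map inputs")
  d <- rsei_pre$values - rsei_post$values
  codes <- ifelse(d < -0.2, 1,
           ifelse(d < -0.05, 2,
           ifelse(d < 0.05, 3,
           ifelse(d < 0.2, 4, 5))))
  out <- grid_like(rsei_pre, codes)
  attr(out, "labels") <- RSEI_CHANGE_LABELS
  out
}

#' Zonal mean of a raster
#'
#' @param rsei A [raster_grid].
#' @param zone Logical matrix selecting the zone (e.g. the heavy-burn mask).
#' @return Arithmetic mean over zone pixels that are valid; an error if the
#'   intersection is empty.
#' @export
zonal_mean <- function(rsei, zone) {
  stopifnot(is_raster_grid(rsei), identical(dim(zone), dim(rsei$values)))
  sel <- zone & !is.na(rsei$values)
  if (!any(sel)) stop("empty zone: no valid pixels selected", call. = FALSE)
  mean(rsei$values[sel])
}

#' Level transfer matrix
#'
#' Cross-tabulates pre-fire against post-fire ecological levels over a zone
#' and converts counts to areas. Rows are the post-fire level, columns the
#' pre-fire level. The `change` margin for each pre-fire level is its column
#' total minus the diagonal (the area that left the level).
#'
#' @param levels_pre,levels_post Aligned categorical [raster_grid]s with
#'   codes 1-5 (see [classify_levels()]).
#' @param zone Optional logical matrix restricting the tabulation (default:
#'   everywhere valid).
#' @param pixel_area_hm2 Area of one pixel in hm^2; defaults to the grids'
#'   own pixel size.
#' @return An object of class `transfer_matrix`: `areas` (5x5, hm^2),
#'   `row_totals`, `col_totals`, `change`, `total_hm2`.
#' @export
transfer_matrix <- function(levels_pre, levels_post, zone = NULL,
                            pixel_area_hm2 = NULL) {
  check_aligned(levels_pre, levels_post, what = "transfer inputs")
  if (is.null(pixel_area_hm2)) pixel_area_hm2 <- levels_pre$pixel_m^2 / 1e4
  pre <- levels_pre$values; post <- levels_post$values
  keep <- !is.na(pre) & !is.na(post)
  if (!is.null(zone)) {
    stopifnot(identical(dim(zone), dim(pre)))
    keep <- keep & zone
  }
  if (any(!pre[keep] %in% 1:5) || any(!post[keep] %in% 1:5))
    stop("level codes must be in 1..5", call. = FALSE)
  counts <- table(factor(post[keep], levels = 1:5),
                  factor(pre[keep], levels = 1:5))
  areas <- matrix(as.numeric(counts), 5, 5,
                  dimnames = list(post = RSEI_LEVEL_LABELS,
                                  pre = RSEI_LEVEL_LABELS)) * pixel_area_hm2
  structure(
    list(areas = areas, row_totals = rowSums(areas),
         col_totals = colSums(areas),
         change = colSums(areas) - diag(areas),
         total_hm2 = sum(areas), pixel_area_hm2 = pixel_area_hm2),
    class = "transfer_matrix"
  )
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> total %.2f hm^2 (rows = post, cols = pre)\n",
              x$total_hm2))
  m <- rbind(cbind(x$areas, Total = x$row_totals),
             Total = c(x$col_totals, x$total_hm2),
             Change = c(x$change, NA))
  print(round(m, 2), na.print = "")
  invisible(x)
}

#' Write a transfer matrix as labelled CSV
#'
#' Layout mirrors the printed transfer tables: a 5x5 block with a Total
#' column, then Total and Change rows for the pre-fire margins.
#'
#' @param tm A `transfer_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_transfer_csv <- function(tm, path) {
  stopifnot(inherits(tm, "transfer_matrix"))
  m <- rbind(cbind(tm$areas, Total = tm$row_totals),
             Total = c(tm$col_totals, tm$total_hm2),
             Change = c(tm$change, NA))
  df <- cbind(post = rownames(m), as.data.frame(m))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
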