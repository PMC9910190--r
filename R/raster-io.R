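#' Raster file format
#'
#' Rasters are stored as TIFF images accompanied by a JSON sidecar
#' (`<path>.json`) that carries the georeferencing (pixel size, origin, CRS
#' tag), the raster kind and the value scaling:
#'
#' * `categorical` rasters are written as a single 8-bit band of integer
#'   codes 0-254 (code 255 reserved for nodata); the round trip is
#'   bit-exact.
#' * `continuous` rasters are written as two 32-bit samples per pixel: the
#'   value min-max scaled to \[0, 1\] (scale and offset recorded in the
#'   sidecar) and a validity channel encoding the nodata mask. Read-back
#'   agrees with the written values to well within 1e-7 of the data range.
#'
#' @name raster-io
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' Write a raster grid to disk
#'
#' @param grid A [raster_grid].
#' @param path Output TIFF path; a `<path>.json` sidecar is written next to it.
#' @param kind `"continuous"` or `"categorical"` (integer codes 0-254).
#' @return Invisibly, `path`.
#' @seealso [read_raster()], [raster-io] for the on-disk layout.
#' @export
write_raster <- function(grid, path, kind = c("continuous", "categorical")) {
  stopifnot(is_raster_grid(grid))
  kind <- match.arg(kind)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop(sprintf("I/O error: cannot write to '%s'", path), call. = FALSE)
  v <- grid$values
  meta <- list(format = "burnsev-raster-1", kind = kind,
               pixel_m = grid$pixel_m, origin = grid$origin,
               crs_tag = grid$crs_tag,
               nrow = nrow(v), ncol = ncol(v))
  if (kind == "categorical") {
    codes <- v[!is.na(v)]
    if (length(codes) && (any(codes != round(codes)) || any(codes < 0) || any(codes > 254)))
      stop("categorical rasters must hold integer codes in 0..254", call. = FALSE)
    enc <- v
    enc[is.na(enc)] <- 255
    meta$nodata_code <- 255
    tiff::writeTIFF(enc / 255, path, bits.per.sample = 8L, compression = "none",
                    reduce = FALSE)
  } else {
    val <- v[!is.na(v)]
    lo <- if (length(val)) min(val) else 0
    hi <- if (length(val)) max(val) else 1
    if (hi <= lo) hi <- lo + 1  # constant grid: degenerate but representable
    scaled <- (v - lo) / (hi - lo)
    scaled[is.na(scaled)] <- 0
    a <- array(0, c(nrow(v), ncol(v), 2L))
    a[, , 1L] <- scaled
    a[, , 2L] <- !is.na(v)
    meta$offset <- lo
    meta$scale <- hi - lo
    tiff::writeTIFF(a, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster grid written by [write_raster()]
#'
#' @param path TIFF path (its `<path>.json` sidecar must exist).
#' @return A [raster_grid].
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: no such file '%s'", path), call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("I/O error: missing sidecar '%s'", sp), call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- suppressWarnings(tiff::readTIFF(path))
  if (identical(meta$kind, "categorical")) {
    v <- round(img * 255)
    v[v == meta$nodata_code] <- NA_real_
  } else {
    stopifnot(length(dim(img)) == 3L)
    v <- img[, , 1L] * meta$scale + meta$offset
    v[img[, , 2L] < 0.5] <- NA_real_
  }
  raster_grid(matrix(v, meta$nrow, meta$ncol), pixel_m = meta$pixel_m,
              origin = unlist(meta$origin), crs_tag = meta$crs_tag)
}

#' Read a multispectral scene from per-band raster files
#'
#' Loads one raster per spectral role, checks that all bands are
#' co-registered (shape, pixel size, origin, CRS within `tol`), optionally
#' rescales integer-packed reflectance by `scale_factor`, and maps a stated
#' `nodata_value` to nodata. The thermal role `tir_bt` is never rescaled.
#'
#' @param paths Named list or character vector, role -> file path. Names must
#'   be roles listed in [scene()]; `nir` and any other role the downstream
#'   indices need must be present.
#' @param scale_factor Multiplier applied to reflectance bands (e.g. `1e-4`
#'   for reflectance packed as scaled integers). Default 1 (stored as-is).
#' @param nodata_value Optional value to treat as nodata before scaling.
#' @param tol Alignment tolerance in metres.
#' @return A [scene].
#' @examples
#' d <- tempfile(); dir.create(d)
#' g <- raster_grid(matrix(0.4, 4, 4))
#' write_raster(g, file.path(d, "nir.tif"))
#' write_raster(g, file.path(d, "swir1.tif"))
#' sc <- read_scene(list(nir = file.path(d, "nir.tif"),
#'                       swir1 = file.path(d, "swir1.tif")))
#' @export
read_scene <- function(paths, scale_factor = 1, nodata_value = NULL, tol = 1e-6) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("configuration error: `paths` must be named by band role", call. = FALSE)
  bad <- setdiff(names(paths), scene_roles())
  if (length(bad))
    stop("configuration error: unknown band role(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bands <- list()
  ref <- NULL
  for (role in names(paths)) {
    g <- read_raster(paths[[role]])
    if (!is.null(nodata_value)) g$values[g$values == nodata_value] <- NA_real_
    if (role != "tir_bt" && scale_factor != 1) g$values <- g$values * scale_factor
    if (is.null(ref)) ref <- g else check_aligned(ref, g, what = role, tol = tol)
    bands[[role]] <- g
  }
  scene(bands)
}
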