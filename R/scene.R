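#' Multispectral scene
#'
#' A named stack of co-registered [raster_grid] bands plus a mapping from
#' spectral roles to band names. Recognised roles are `blue`, `green`, `red`,
#' `nir`, `swir1`, `swir2` (surface reflectance, expected in \[0, 1\] with a
#' tolerance of 0.1 on either side for atmospheric-correction overshoot) and
#' `tir_bt` (thermal brightness temperature in kelvin, strictly positive).
#'
#' @param bands Named list of [raster_grid] objects.
#' @param roles Named character vector mapping role -> band name. Defaults to
#'   the identity mapping for band names that are themselves roles.
#' @return An object of class `scene`.
#' @examples
#' g <- raster_grid(matrix(0.3, 2, 2))
#' sc <- scene(list(nir = g, swir1 = g))
#' get_band(sc, "nir")
#' @export
scene <- function(bands, roles = NULL) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("`bands` must be a named list of raster_grid objects", call. = FALSE)
  for (b in bands) stopifnot(is_raster_grid(b))
  ref <- bands[[1L]]
  for (nm in names(bands)) check_aligned(ref, bands[[nm]], what = nm)
  if (is.null(roles)) {
    known <- intersect(names(bands), scene_roles())
    roles <- stats::setNames(known, known)
  }
  bad <- setdiff(names(roles), scene_roles())
  if (length(bad))
    stop("unknown band role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  missing_band <- setdiff(unname(roles), names(bands))
  if (length(missing_band))
    stop("roles point to absent band(s): ", paste(missing_band, collapse = ", "),
         call. = FALSE)
  sc <- structure(list(bands = bands, roles = roles), class = "scene")
  validate_scene_ranges(sc)
  sc
}

scene_roles <- function() c("blue", "green", "red", "nir", "swir1", "swir2", "tir_bt")

validate_scene_ranges <- function(sc) {
  for (role in names(sc$roles)) {
    v <- valid_values(sc$bands[[sc$roles[[role]]]])
    if (!length(v)) next
    if (role == "tir_bt") {
      if (any(v <= 0))
        stop("tir_bt band must be positive kelvin", call. = FALSE)
    } else if (min(v) < -0.1 || max(v) > 1.1) {
      stop(sprintf("band '%s' has reflectance outside [-0.1, 1.1]",
                   sc$roles[[role]]), call. = FALSE)
    }
  }
  invisible(sc)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d band(s): %s\n", length(x$bands),
              paste(names(x$bands), collapse = ", ")))
  cat("  roles:", paste(sprintf("%s=%s", names(x$roles), x$roles), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch a band by spectral role
#'
#' @param sc A [scene].
#' @param role One of the roles listed in [scene()].
#' @return The [raster_grid] mapped to that role; a configuration error if
#'   the role is absent.
#' @export
get_band <- function(sc, role) {
  stopifnot(inherits(sc, "scene"))
  if (!role %in% names(sc$roles))
    stop(sprintf("configuration error: required band role '%s' is not mapped", role),
         call. = FALSE)
  sc$bands[[sc$roles[[role]]]]
}

require_roles <- function(sc, roles) {
  for (r in roles) get_band(sc, r)
  invisible(TRUE)
}
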