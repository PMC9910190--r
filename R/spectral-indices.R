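#' Normalized-difference helper
#'
#' (a - b) / (a + b) per pixel; pixels where a + b == 0 become nodata rather
#' than being forced to +/-1, so sensor noise over dark targets cannot
#' fabricate extreme index values.
#' @noRd
norm_diff <- function(a, b) {
  den <- a$values + b$values
  num <- a$values - b$values
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  grid_like(a, out)
}

#' Normalized Burn Ratio
#'
#' NBR = (rho_nir - rho_swir1) / (rho_nir + rho_swir1). Healthy vegetation is
#' bright in the NIR and dark in the SWIR, so NBR is high before a fire and
#' drops where vegetation burns (NIR falls, SWIR rises over char and ash).
#'
#' @param sc A [scene] carrying roles `nir` and `swir1` (e.g. Sentinel-2
#'   bands 8 and 11).
#' @return A [raster_grid] in \[-1, 1\]; pixels with zero band sum are nodata.
#' @seealso [dnbr()]
#' @export
nbr <- function(sc) {
  require_roles(sc, c("nir", "swir1"))
  norm_diff(get_band(sc, "nir"), get_band(sc, "swir1"))
}

#' Differenced Normalized Burn Ratio
#'
#' dNBR = NBR_pre - NBR_post. Positive values mark vegetation loss; the more
#' severe the burn, the larger the drop in NBR and hence the larger dNBR.
#' Using the pre/post difference suppresses permanently dark surfaces (water,
#' shadow) that confound single-date NBR.
#'
#' @param nbr_pre,nbr_post [raster_grid]s of pre- and post-fire NBR, aligned.
#' @return A [raster_grid]; nodata wherever either input is nodata.
#' @export
dnbr <- function(nbr_pre, nbr_post) {
  check_aligned(nbr_pre, nbr_post, what = "dnbr inputs")
  grid_like(nbr_pre, nbr_pre$values - nbr_post$values)
}

#' Normalized Difference Vegetation Index
#'
#' NDVI = (rho_nir - rho_red) / (rho_nir + rho_red); the greenness indicator
#' of the ecological index.
#'
#' @param sc A [scene] carrying roles `nir` and `red`.
#' @return A [raster_grid] in \[-1, 1\].
#' @export
ndvi <- function(sc) {
  require_roles(sc, c("nir", "red"))
  norm_diff(get_band(sc, "nir"), get_band(sc, "red"))
}

#' Modified Normalized Difference Water Index
#'
#' MNDWI = (rho_green - rho_swir1) / (rho_green + rho_swir1). Open water is
#' positive; the index is used to mask water bodies before wetness and RSEI
#' statistics.
#'
#' @param sc A [scene] carrying roles `green` and `swir1`.
#' @return A [raster_grid] in \[-1, 1\].
#' @export
mndwi <- function(sc) {
  require_roles(sc, c("green", "swir1"))
  norm_diff(get_band(sc, "green"), get_band(sc, "swir1"))
}

#' Water mask from MNDWI
#'
#' @param sc A [scene] with roles `green` and `swir1`.
#' @param threshold Pixels with MNDWI > `threshold` are flagged as water
#'   (default 0).
#' @return A logical matrix, `TRUE` over water; `NA` pixels are `FALSE`.
#' @export
water_mask <- function(sc, threshold = 0) {
  m <- mndwi(sc)$values > threshold
  m[is.na(m)] <- FALSE
  m
}

# Tasseled-cap wetness coefficients for Landsat-8 OLI bands 2-7.
TC_WETNESS <- c(blue = 0.1511, green = 0.1973, red = 0.3283,
                nir = 0.3407, swir1 = -0.7117, swir2 = -0.4559)

#' Tasseled-cap wetness
#'
#' Wet = 0.1511 b2 + 0.1973 b3 + 0.3283 b4 + 0.3407 b5 - 0.7117 b6 -
#' 0.4559 b7, the moisture component of the tasseled-cap transformation for
#' Landsat-8 OLI reflectance (bands 2-7 = blue, green, red, NIR, SWIR1,
#' SWIR2). It indexes surface and soil moisture and serves as the wetness
#' indicator of the ecological index; water bodies should be masked first
#' (see [water_mask()]) so the component reflects land-surface moisture.
#'
#' @param sc A [scene] carrying roles `blue`, `green`, `red`, `nir`, `swir1`,
#'   `swir2`.
#' @return A [raster_grid] of wetness values (dimensionless).
#' @export
wetness <- function(sc) {
  require_roles(sc, names(TC_WETNESS))
  acc <- NULL
  for (role in names(TC_WETNESS)) {
    b <- get_band(sc, role)
    term <- TC_WETNESS[[role]] * b$values
    acc <- if (is.null(acc)) term else acc + term
  }
  grid_like(get_band(sc, "blue"), acc)
}

#' Bare-soil dryness index (SI)
#'
#' SI = ((rho_swir1 + rho_red) - (rho_blue + rho_nir)) /
#' ((rho_swir1 + rho_red) + (rho_blue + rho_nir)). The bare-soil component
#' of the dryness indicator; burned land, which is far from built-up areas,
#' is driven by SI rather than by the building index, so SI alone is used as
#' the dryness indicator here.
#'
#' @param sc A [scene] carrying roles `blue`, `red`, `nir`, `swir1`.
#' @return A [raster_grid] in \[-1, 1\]; zero-denominator pixels are nodata.
#' @export
dryness_si <- function(sc) {
  require_roles(sc, c("blue", "red", "nir", "swir1"))
  plus <- grid_like(get_band(sc, "swir1"),
                    get_band(sc, "swir1")$values + get_band(sc, "red")$values)
  minus <- grid_like(plus, get_band(sc, "blue")$values + get_band(sc, "nir")$values)
  norm_diff(plus, minus)
}

#' Statistical mono-window LST coefficients
#'
#' Coefficient triple of the single-channel statistical mono-window (SMW)
#' land-surface-temperature model, `LST = A * Tb / eps + B / eps + C`. The
#' published coefficient sets are stratified by total-column-water-vapour
#' (TCWV) class and come from radiative-transfer regressions; they are
#' supplied at run time (e.g. from a config file). The identity default
#' (A = 1, B = 0, C = 0) degrades the model to brightness temperature.
#'
#' @param A,B,C Regression coefficients (finite).
#' @param tcwv_class Optional integer 1-10 labelling the water-vapour class.
#' @return An object of class `lst_coefficients`.
#' @export
lst_coefficients <- function(A = 1, B = 0, C = 0, tcwv_class = NULL) {
  vals <- c(A, B, C)
  if (length(vals) != 3L || any(!is.finite(vals)))
    stop("A, B, C must be single finite numbers", call. = FALSE)
  if (!is.null(tcwv_class)) {
    tcwv_class <- as.integer(tcwv_class)
    if (tcwv_class < 1L || tcwv_class > 10L)
      stop("tcwv_class must be in 1..10", call. = FALSE)
  }
  structure(list(A = A, B = B, C = C, tcwv_class = tcwv_class),
            class = "lst_coefficients")
}

#' Land surface temperature (statistical mono-window)
#'
#' LST = A * Tb / eps + B / eps + C, with Tb the brightness temperature of a
#' single thermal channel (kelvin) and eps the surface emissivity in that
#' channel. This is the heat indicator of the ecological index.
#'
#' @param sc A [scene] carrying role `tir_bt` (kelvin).
#' @param emissivity Scalar in (0, 1\] or a [raster_grid] of per-pixel
#'   emissivities. Default 0.98, typical of vegetated land.
#' @param coeffs An [lst_coefficients] object.
#' @return A [raster_grid] of LST in kelvin.
#' @export
lst_smw <- function(sc, emissivity = 0.98, coeffs = lst_coefficients()) {
  require_roles(sc, "tir_bt")
  stopifnot(inherits(coeffs, "lst_coefficients"))
  tb <- get_band(sc, "tir_bt")
  if (is_raster_grid(emissivity)) {
    check_aligned(tb, emissivity, what = "emissivity")
    eps <- emissivity$values
  } else {
    eps <- matrix(emissivity, nrow(tb$values), ncol(tb$values))
  }
  if (any(eps <= 0 | eps > 1, na.rm = TRUE))
    stop("domain error: emissivity must lie in (0, 1]", call. = FALSE)
  grid_like(tb, coeffs$A * tb$values / eps + coeffs$B / eps + coeffs$C)
}
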