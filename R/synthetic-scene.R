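#' Specification of a synthetic fire scene
#'
#' Parameters of the synthetic-scene generator used to exercise the whole
#' pipeline without satellite data. Defaults describe a mostly vegetated
#' landscape in which 30% of the pixels burn (20% mildly, 10% heavily), with
#' per-class reflectance chosen so the noiseless class dNBR values are 0
#' (unburned), 0.2 (mild) and 0.55 (heavy) — straddling the magnitude of
#' dNBR thresholds reported for real fires — and per-band Gaussian noise of
#' sd 0.005, which keeps the dNBR class separation near ten noise standard
#' deviations.
#'
#' @param shape Integer `c(rows, cols)`.
#' @param pixel_m Pixel size in metres (default 10).
#' @param class_fractions Named or ordered numeric `c(unburned, mild, heavy)`
#'   summing to 1.
#' @param spectral_means Per-class band means: a list with elements `pre`
#'   (named reflectance vector used for every class before the fire) and
#'   `post` (list `unburned`, `mild`, `heavy` of named vectors). `NULL` for
#'   the defaults described above.
#' @param noise_sigma Per-band Gaussian noise sd (reflectance units;
#'   thermal noise is scaled 20x to kelvin).
#' @param seed Integer seed; all generation is reproducible from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256, 256), pixel_m = 10,
                       class_fractions = c(unburned = 0.7, mild = 0.2, heavy = 0.1),
                       spectral_means = NULL, noise_sigma = 0.005, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 4L), pixel_m > 0,
            length(class_fractions) == 3L, all(class_fractions >= 0),
            noise_sigma >= 0)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("specification error: class fractions must sum to 1", call. = FALSE)
  names(class_fractions) <- c("unburned", "mild", "heavy")
  if (is.null(spectral_means)) spectral_means <- default_spectral_means()
  rng <- unlist(spectral_means)
  if (any(rng < 0 | rng > 1))
    stop("specification error: spectral means must lie in [0, 1]", call. = FALSE)
  structure(list(shape = shape, pixel_m = pixel_m,
                 class_fractions = class_fractions,
                 spectral_means = spectral_means,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

default_spectral_means <- function() {
  pre <- c(blue = 0.04, green = 0.07, red = 0.05,
           nir = 0.45, swir1 = 0.15, swir2 = 0.10)
  # Burning lowers NIR and raises SWIR, more for heavy than mild:
  # noiseless dNBR comes out at 0 / 0.2 / 0.55.
  mild <- pre; mild[["nir"]] <- 0.39; mild[["swir1"]] <- 0.21
  mild[["red"]] <- 0.06; mild[["swir2"]] <- 0.13
  heavy <- pre; heavy[["nir"]] <- 0.285; heavy[["swir1"]] <- 0.315
  heavy[["red"]] <- 0.07; heavy[["swir2"]] <- 0.17
  list(pre = pre, post = list(unburned = pre, mild = mild, heavy = heavy))
}

#' Generate a co-registered pre/post burn scene pair with ground truth
#'
#' Builds a vegetated pre-fire scene and a post-fire scene in which
#' contiguous blob-shaped burn patches (heavy cores ringed by mild burn,
#' grown from random seed points) show the burned-surface signature: NIR
#' reflectance drops and SWIR1 rises, with a larger shift for heavy than
#' mild severity. Independent Gaussian noise is added per band. The planted
#' severity class of every pixel is returned as ground truth; output is
#' deterministic given the spec's seed.
#'
#' @param spec A [scene_spec].
#' @return A list: `pre` and `post` ([scene]s with roles blue, green, red,
#'   nir, swir1, swir2) and `truth` (categorical [raster_grid], 0 unburned /
#'   1 mild / 2 heavy).
#' @examples
#' sim <- make_burn_pair(scene_spec(shape = c(64, 64), seed = 42))
#' table(sim$truth$values)
#' @export
make_burn_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  n <- nr * nc
  n_heavy <- round(spec$class_fractions[["heavy"]] * n)
  n_mild <- round(spec$class_fractions[["mild"]] * n)
  if (n_heavy + n_mild > n)
    stop("specification error: burn fractions infeasible for shape", call. = FALSE)
  truth <- matrix(0, nr, nc)
  if (n_heavy > 0) {
    heavy <- grow_patches(nr, nc, n_heavy,
                          n_seeds = max(1L, round(n_heavy / 3000)))
    truth[heavy] <- 2
    if (n_mild > 0) {
      mild <- grow_patches(nr, nc, n_mild, from = heavy, exclude = heavy)
      truth[mild] <- 1
    }
  } else if (n_mild > 0) {
    truth[grow_patches(nr, nc, n_mild, n_seeds = max(1L, round(n_mild / 3000)))] <- 1
  }

  band_names <- names(spec$spectral_means$pre)
  make_bands <- function(means_by_class) {
    bands <- list()
    for (bn in band_names) {
      mu <- matrix(0, nr, nc)
      for (k in 0:2) {
        cls <- c("unburned", "mild", "heavy")[k + 1L]
        mu[truth == k] <- means_by_class[[cls]][[bn]]
      }
      if (spec$noise_sigma > 0) mu <- mu + matrix(stats::rnorm(n, 0, spec$noise_sigma), nr, nc)
      bands[[bn]] <- raster_grid(pmin(pmax(mu, 0), 1), pixel_m = spec$pixel_m)
    }
    scene(bands)
  }
  pre_means <- list(unburned = spec$spectral_means$pre,
                    mild = spec$spectral_means$pre,
                    heavy = spec$spectral_means$pre)
  list(pre = make_bands(pre_means),
       post = make_bands(spec$spectral_means$post),
       truth = raster_grid(truth, pixel_m = spec$pixel_m))
}

# Grow contiguous random blobs totalling n_target pixels (4-connectivity).
# `from`: optional logical matrix whose boundary seeds the growth (the blob
# then excludes `exclude`); otherwise n_seeds random interior seed points.
grow_patches <- function(nr, nc, n_target, n_seeds = 1L, from = NULL,
                         exclude = NULL) {
  member <- matrix(FALSE, nr, nc)
  blocked <- if (is.null(exclude)) matrix(FALSE, nr, nc) else exclude
  if (is.null(from)) {
    free <- which(!blocked)
    seeds <- free[sample.int(length(free), min(n_seeds, length(free)))]
    member[seeds] <- TRUE
    n_have <- length(seeds)
    frontier <- setdiff(neighbours_of(seeds, nr, nc), which(member | blocked))
  } else {
    frontier <- setdiff(neighbours_of(which(from), nr, nc),
                        which(from | blocked))
    n_have <- 0L
  }
  while (n_have < n_target && length(frontier)) {
    need <- n_target - n_have
    take_n <- min(need, max(1L, round(length(frontier) * 0.6)))
    take <- frontier[sample.int(length(frontier), take_n)]
    member[take] <- TRUE
    n_have <- n_have + take_n
    grown <- neighbours_of(take, nr, nc)
    frontier <- setdiff(unique(c(setdiff(frontier, take), grown)),
                        which(member | blocked))
  }
  if (n_have < n_target)
    stop("specification error: burn fraction infeasible for shape", call. = FALSE)
  member
}

neighbours_of <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  out <- c(ifelse(r > 1L, idx - 1L, NA_integer_),
           ifelse(r < nr, idx + 1L, NA_integer_),
           ifelse(cc > 1L, idx - nr, NA_integer_),
           ifelse(cc < nc, idx + nr, NA_integer_))
  unique(out[!is.na(out)])
}

#' Generate a Landsat-style scene with a planted one-factor ecological field
#'
#' Draws a smooth latent ecological-condition field e(x) in \[0, 1\]
#' (rank-uniformized smoothed Gaussian noise), then constructs reflectance
#' bands 2-7 and a thermal brightness-temperature band such that, at zero
#' noise, the four RSEI indicators are exactly affine in e — NDVI and
#' tasseled-cap wetness increasing, LST and bare-soil SI decreasing. The
#' indicator stack built from such a scene is rank one, so PC1 carries 100%
#' of the variance with the loading sign pattern (+, +, -, -), and the
#' recovered RSEI equals e up to min-max scaling. Per-band Gaussian noise
#' (sd `spec$noise_sigma`; 20x in kelvin for the thermal band) perturbs this
#' structure realistically.
#'
#' @param spec A [scene_spec] (only `shape`, `pixel_m`, `noise_sigma` and
#'   `seed` are used).
#' @return A list: `scene` (a [scene] with roles blue, green, red, nir,
#'   swir1, swir2, tir_bt) and `latent` ([raster_grid] holding e, for
#'   recovery tests).
#' @export
make_rsei_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed + 1L)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  n <- nr * nc
  z <- smooth_field(matrix(stats::rnorm(n), nr, nc),
                    width = max(3L, round(min(nr, nc) / 16)))
  e <- matrix((rank(z, ties.method = "first") - 1) / (n - 1), nr, nc)

  ndvi_t <- 0.2 + 0.6 * e
  si_t <- 0.25 - 0.45 * e
  wet_t <- -0.115 + 0.18 * e
  lst_t <- 310 - 20 * e

  blue <- matrix(0.05, nr, nc)
  red <- matrix(0.10, nr, nc)
  nir <- red * (1 + ndvi_t) / (1 - ndvi_t)
  u <- blue + nir
  swir1 <- u * (1 + si_t) / (1 - si_t) - red
  swir2 <- matrix(0.10, nr, nc)
  green <- (wet_t - (TC_WETNESS[["blue"]] * blue + TC_WETNESS[["red"]] * red +
                     TC_WETNESS[["nir"]] * nir + TC_WETNESS[["swir1"]] * swir1 +
                     TC_WETNESS[["swir2"]] * swir2)) / TC_WETNESS[["green"]]
  bands <- list(blue = blue, green = green, red = red, nir = nir,
                swir1 = swir1, swir2 = swir2)
  s <- spec$noise_sigma
  bands <- lapply(bands, function(b) {
    if (s > 0) b <- b + matrix(stats::rnorm(n, 0, s), nr, nc)
    raster_grid(pmin(pmax(b, 0), 1.1), pixel_m = spec$pixel_m)
  })
  tb <- lst_t
  if (s > 0) tb <- tb + matrix(stats::rnorm(n, 0, 20 * s), nr, nc)
  bands$tir_bt <- raster_grid(tb, pixel_m = spec$pixel_m)
  list(scene = scene(bands), latent = raster_grid(e, pixel_m = spec$pixel_m))
}

# Separable moving-average smoothing; edge windows shrink rather than pad.
smooth_field <- function(m, width = 9L) {
  half <- max(1L, width %/% 2L)
  ma <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  m <- apply(m, 2L, ma)
  t(apply(t(m), 2L, ma))
}
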