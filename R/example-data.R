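#' Published worked-example tables for the Muli County fires
#'
#' Survey and extraction statistics published for the three Muli County
#' (Sichuan, China) forest fires of 2019-2021, bundled as package data for
#' worked examples and cross-checks of the area-accuracy and transfer-matrix
#' arithmetic:
#'
#' * `areas` — per fire: reference burned areas from the forestry field
#'   survey (heavy / mild / total, hm^2), the areas extracted by the
#'   dNBR + two-stage-Otsu classifier, and the two dNBR thresholds it
#'   selected.
#' * `rsei_means` — zonal mean RSEI before and after each fire over the
#'   heavy- and mild-burn zones.
#' * `transfer_2019_heavy` — the published 2019 heavy-zone RSEI level
#'   transfer matrix (rows = post-fire level, columns = pre-fire level,
#'   hm^2).
#'
#' @param which One of `"areas"`, `"rsei_means"`, `"transfer_2019_heavy"`.
#' @return A data frame.
#' @examples
#' tab <- muli_fire_tables("areas")
#' area_accuracy(tab$extracted_heavy_hm2, tab$reference_heavy_hm2)
#' @export
muli_fire_tables <- function(which = c("areas", "rsei_means",
                                       "transfer_2019_heavy")) {
  which <- match.arg(which)
  file <- switch(which,
                 areas = "muli_fire_areas.csv",
                 rsei_means = "muli_rsei_means.csv",
                 transfer_2019_heavy = "muli_transfer_2019_heavy.csv")
  path <- system.file("extdata", file, package = "burnsev", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
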