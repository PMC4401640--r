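# Generator configuration for synthetic retinal plexuses.

STAGE_LEVELS <- c("1_selection", "2_stenosis", "3_retraction", "4_resolution")

#' Synthetic retina generator configuration
#'
#' Bundles every knob of the synthetic-plexus generator. The defaults describe
#' a postnatal day 6 (P6) mouse retina: roughly 16,000 endothelial cells in a
#' plexus about 1 mm in radius, a mean of 78.1 cleaved-caspase-3-like
#' apoptotic events per retina, and 4.82% of regression profiles colocalized
#' with an apoptotic event.
#'
#' @param retina_radius plexus radius (um).
#' @param optic_center centre of the plexus, 2-vector (um).
#' @param n_arteries,n_veins number of arterial / venous spokes (each >= 1).
#' @param capillary_spacing target capillary mesh spacing (um).
#' @param radius_artery,radius_vein,radius_capillary vessel radii (um).
#' @param n_cells_target total endothelial nucleus count emitted per retina.
#' @param polarity_model list with `mode` (`"uniform"` or
#'   `"vonmises_against_flow"`), `kappa` (von Mises concentration, >= 0),
#'   `magnitude_mean`, `magnitude_sd` (polarity vector length, um).
#' @param regression_rate fraction of capillary segments planted as regression
#'   profiles.
#' @param stage_mix length-4 fractions over the regression stages
#'   (selection, stenosis, retraction, resolution); must sum to 1.
#' @param apoptosis_total_mean Poisson mean of apoptotic events per retina.
#' @param coloc_rate fraction of detectable (stage >= 2) planted regression
#'   segments that receive a colocalized apoptotic event.
#' @param coloc_dist colocalization distance rule (um): an apoptotic nucleus is
#'   associated with a profile if within one cell-body radius of its
#'   centerline.
#' @param pixel_size raster resolution for mask rendering (um/px).
#' @param seed master seed; all stages derive fixed substreams from it.
#'
#' @return A validated list of class `gen_config`.
#' @export
gen_config <- function(retina_radius = 1000,
                       optic_center = c(0, 0),
                       n_arteries = 5,
                       n_veins = 5,
                       capillary_spacing = 30,
                       radius_artery = 12,
                       radius_vein = 15,
                       radius_capillary = 3.5,
                       n_cells_target = 16000,
                       polarity_model = list(mode = "vonmises_against_flow",
                                             kappa = 4,
                                             magnitude_mean = 5,
                                             magnitude_sd = 1.5),
                       regression_rate = 0.02,
                       stage_mix = c(0.10, 0.30, 0.30, 0.30),
                       apoptosis_total_mean = 78.1,
                       coloc_rate = 0.0482,
                       coloc_dist = 10,
                       pixel_size = 2,
                       seed = 1L) {
  cfg <- list(retina_radius = retina_radius, optic_center = optic_center,
              n_arteries = as.integer(n_arteries), n_veins = as.integer(n_veins),
              capillary_spacing = capillary_spacing,
              radius_artery = radius_artery, radius_vein = radius_vein,
              radius_capillary = radius_capillary,
              n_cells_target = as.integer(n_cells_target),
              polarity_model = modifyList(
                list(mode = "vonmises_against_flow", kappa = 4,
                     magnitude_mean = 5, magnitude_sd = 1.5),
                polarity_model),
              regression_rate = regression_rate,
              stage_mix = stage_mix,
              apoptosis_total_mean = apoptosis_total_mean,
              coloc_rate = coloc_rate, coloc_dist = coloc_dist,
              pixel_size = pixel_size, seed = as.integer(seed))
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
  cfg
}

validate_gen_config <- function(cfg) {
  lens <- c(retina_radius = cfg$retina_radius,
            capillary_spacing = cfg$capillary_spacing,
            radius_artery = cfg$radius_artery, radius_vein = cfg$radius_vein,
            radius_capillary = cfg$radius_capillary,
            coloc_dist = cfg$coloc_dist, pixel_size = cfg$pixel_size)
  if (any(lens <= 0)) {
    stop_config("all lengths must be > 0 (offending: ",
                paste(names(lens)[lens <= 0], collapse = ", "), ")")
  }
  fr <- c(regression_rate = cfg$regression_rate, coloc_rate = cfg$coloc_rate)
  if (any(fr < 0 | fr > 1)) stop_config("fractions must lie in [0, 1]")
  if (length(cfg$stage_mix) != 4 || any(cfg$stage_mix < 0) ||
      abs(sum(cfg$stage_mix) - 1) > 1e-9) {
    stop_config("stage_mix must be 4 non-negative fractions summing to 1")
  }
  if (cfg$polarity_model$kappa < 0) stop_config("kappa must be >= 0")
  if (!cfg$polarity_model$mode %in% c("uniform", "vonmises_against_flow")) {
    stop_config("polarity mode must be 'uniform' or 'vonmises_against_flow'")
  }
  if (cfg$polarity_model$magnitude_mean <= 0 || cfg$polarity_model$magnitude_sd < 0) {
    stop_config("polarity magnitude_mean must be > 0 and magnitude_sd >= 0")
  }
  if (cfg$capillary_spacing >= cfg$retina_radius) {
    stop_config("infeasible geometry: capillary_spacing >= retina_radius")
  }
  if (cfg$apoptosis_total_mean < 0) stop_config("apoptosis_total_mean must be >= 0")
  if (cfg$n_cells_target < 0) stop_config("n_cells_target must be >= 0")
  invisible(cfg)
}
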