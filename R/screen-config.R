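#' Configuration for a synthetic qHTS antagonist screen
#'
#' Bundles every tunable of the synthetic screen generator: assay geometry
#' (plate format, titration series), control-well statistics (vehicle CV,
#' signal-to-background ratio, positive-control CV), and the composition of
#' the planted compound library (fractions of true antagonists and cytotoxic
#' compounds, structural-cluster mixture).
#'
#' Defaults emulate a 1536-well luciferase reporter antagonist screen:
#' a 7-point titration from 46 uM down to 1.5 nM with exact geometric
#' spacing, vehicle-well coefficient of variation 7.04%, signal-to-background
#' ratio 3.54, and a positive-control SD derived so that the Z' factor of a
#' generated plate is 0.572 in expectation (see Details).
#'
#' @details
#' The Z' factor of a plate is \eqn{1 - 3(\sigma_p + \sigma_v)/|\mu_v -
#' \mu_p|} where subscripts denote positive-control and vehicle wells.  The
#' vehicle statistics fix \eqn{\mu_v} and \eqn{\sigma_v = \mu_v\,
#' \mathrm{cv}_v}; given a target Z' the positive-control SD is therefore
#' determined, and `pos_control_cv`, when left `NULL`, is solved from that
#' identity:
#' \deqn{\mathrm{cv}_p = (1 - Z')(S/B - 1)/3 - \mathrm{cv}_v \cdot S/B}
#' (all relative to \eqn{\mu_p = 1}).  With the defaults this gives
#' cv_p = 0.1132, i.e. sigma_p = 0.113 when mu_p = 1 and mu_v = 3.54.
#'
#' Noise on every well is multiplicative Gaussian (signal times
#' \eqn{1 + N(0, \mathrm{cv})}), since well-to-well variability in these
#' assays is quoted as a percentage of signal.
#'
#' @param n_compounds number of library compounds to plant.
#' @param n_concentrations points per titration (>= 2).
#' @param conc_top,conc_bottom top and bottom concentration of the series,
#'   in uM; spacing between them is exactly geometric.
#' @param plate_format wells per plate; one of 96, 384, 1536.
#' @param dmso_cv coefficient of variation of vehicle (DMSO) wells, as a
#'   fraction.
#' @param signal_to_background ratio of mean vehicle signal to mean
#'   positive-control signal.
#' @param pos_control_cv coefficient of variation of positive-control wells;
#'   `NULL` (default) derives it from `z_prime_target` as described above.
#' @param z_prime_target expected plate Z' used to derive `pos_control_cv`.
#' @param fraction_true_antagonists fraction of compounds planted as true
#'   antagonists.
#' @param fraction_cytotoxic fraction planted as cytotoxic (disjoint from
#'   the antagonists).
#' @param spatial_artifact_amplitude amplitude, in raw signal units, of a
#'   smooth deterministic plate-surface artifact added to the luminescence
#'   channel of every plate (0 = clean plates).
#' @param vehicle_mean mean raw luminescence of a vehicle well, in
#'   instrument units (arbitrary scale; normalization removes it).
#' @param vehicle_fluor_mean mean raw fluorescence of a vehicle well.
#' @param n_clusters number of structural clusters compounds are assigned to.
#' @param active_cluster_bias probability that a planted antagonist is
#'   assigned to one of the designated "enriched" clusters (the first
#'   `max(2, n_clusters %/% 8)` cluster labels) rather than uniformly.
#' @param rng_seed integer seed making the generated screen reproducible.
#'
#' @return An object of class `screen_config` (a validated named list).
#' @examples
#' cfg <- screen_config(n_compounds = 100)
#' cfg$pos_control_cv # derived from the Z' identity
#' @export
screen_config <- function(n_compounds = 5099L,
                          n_concentrations = 7L,
                          conc_top = 46,
                          conc_bottom = 0.0015,
                          plate_format = 1536L,
                          dmso_cv = 0.0704,
                          signal_to_background = 3.54,
                          pos_control_cv = NULL,
                          z_prime_target = 0.572,
                          fraction_true_antagonists = 0.018,
                          fraction_cytotoxic = 0.02,
                          spatial_artifact_amplitude = 0,
                          vehicle_mean = 3540,
                          vehicle_fluor_mean = 2000,
                          n_clusters = 25L,
                          active_cluster_bias = 0.7,
                          rng_seed = 1L) {
  stopifnot("dmso_cv must be a fraction in [0, 1]" =
              dmso_cv >= 0 && dmso_cv <= 1,
            "signal_to_background must exceed 1" = signal_to_background > 1)
  if (is.null(pos_control_cv)) {
    pos_control_cv <- (1 - z_prime_target) * (signal_to_background - 1) / 3 -
      dmso_cv * signal_to_background
  }
  cfg <- list(
    n_compounds = as.integer(n_compounds),
    n_concentrations = as.integer(n_concentrations),
    conc_top = conc_top,
    conc_bottom = conc_bottom,
    plate_format = as.integer(plate_format),
    dmso_cv = dmso_cv,
    signal_to_background = signal_to_background,
    pos_control_cv = pos_control_cv,
    z_prime_target = z_prime_target,
    fraction_true_antagonists = fraction_true_antagonists,
    fraction_cytotoxic = fraction_cytotoxic,
    spatial_artifact_amplitude = spatial_artifact_amplitude,
    vehicle_mean = vehicle_mean,
    vehicle_fluor_mean = vehicle_fluor_mean,
    n_clusters = as.integer(n_clusters),
    active_cluster_bias = active_cluster_bias,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  stopifnot(
    "n_compounds must be positive" = cfg$n_compounds >= 1L,
    "n_concentrations must be >= 2" = cfg$n_concentrations >= 2L,
    "concentrations must satisfy conc_top > conc_bottom > 0" =
      cfg$conc_top > cfg$conc_bottom && cfg$conc_bottom > 0,
    "signal_to_background must exceed 1" = cfg$signal_to_background > 1,
    "pos_control_cv must be non-negative" = cfg$pos_control_cv >= 0,
    "dmso_cv must be a fraction in [0, 1]" =
      cfg$dmso_cv >= 0 && cfg$dmso_cv <= 1,
    "compound fractions must lie in [0, 1]" =
      cfg$fraction_true_antagonists >= 0 &&
        cfg$fraction_true_antagonists <= 1 &&
        cfg$fraction_cytotoxic >= 0 && cfg$fraction_cytotoxic <= 1 &&
        cfg$fraction_true_antagonists + cfg$fraction_cytotoxic <= 1,
    "active_cluster_bias must lie in [0, 1]" =
      cfg$active_cluster_bias >= 0 && cfg$active_cluster_bias <= 1
  )
  plate_dims(cfg$plate_format) # errors on unsupported formats
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("qHTS synthetic screen configuration\n")
  cat(sprintf("  compounds: %d (%.1f%% antagonist, %.1f%% cytotoxic)\n",
              x$n_compounds, 100 * x$fraction_true_antagonists,
              100 * x$fraction_cytotoxic))
  cat(sprintf("  titration: %d points, %.4g to %.4g uM (geometric)\n",
              x$n_concentrations, x$conc_top, x$conc_bottom))
  cat(sprintf("  plate format: %d wells\n", x$plate_format))
  cat(sprintf("  vehicle CV %.4f | S/B %.3f | pos-control CV %.4f (Z' target %.3f)\n",
              x$dmso_cv, x$signal_to_background, x$pos_control_cv,
              x$z_prime_target))
  invisible(x)
}

#' Titration series of a screen configuration
#'
#' Concentrations are spaced exactly geometrically between the configured
#' endpoints (the printed endpoints of a real dilution series are rarely an
#' exact power of a round ratio, so the endpoints, not the step, are taken
#' as authoritative).
#'
#' @param config a [screen_config()].
#' @return Increasing numeric vector of concentrations in uM.
#' @examples
#' concentration_series(screen_config())
#' @export
concentration_series <- function(config) {
  exp(seq(log(config$conc_bottom), log(config$conc_top),
          length.out = config$n_concentrations))
}

# rows x cols of the supported plate formats (rows are lettered in hardware,
# indexed here)
plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
    "96" = c(8L, 12L),
    "384" = c(16L, 24L),
    "1536" = c(32L, 48L),
    stop("unsupported plate format: ", plate_format,
         " (supported: 96, 384, 1536)")
  )
}
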