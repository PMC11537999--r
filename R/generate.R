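#' Generate a synthetic qHTS antagonist screen
#'
#' Simulates the raw output of a full-library quantitative high-throughput
#' antagonist screen with a dual luminescence (reporter) / fluorescence
#' (viability) readout, together with the ground-truth table of planted
#' compound activities.  Every compound is titrated across the configured
#' geometric concentration series, one concentration per plate stack, as in
#' a real qHTS campaign; each plate carries vehicle (DMSO), positive-control
#' (reference antagonist, full inhibition) and cytotoxicity-control wells in
#' dedicated columns.  Two DMSO-only plates flank the compound stack for
#' background pattern correction.
#'
#' Signal model: a compound whose true antagonist activity at concentration
#' c is `a(c)` (in percent, 0 = vehicle, -100 = full inhibition) and whose
#' surviving cell fraction is `s(c)` produces mean luminescence
#' `mu_p + (mu_v - mu_p) * (1 + a(c)/100) * s(c)`: cytotoxicity depresses
#' the reporter channel too, so a cytotoxic compound mimics an antagonist
#' unless the viability counter-screen unmasks it.  Mean fluorescence is
#' `mu_fp + (mu_fv - mu_fp) * s(c)`.  All wells receive multiplicative
#' Gaussian noise at the channel's configured CV.
#'
#' @param config a [screen_config()].
#' @param truth optional ground-truth table overriding the randomly planted
#'   one; a data frame with the columns returned in `$truth` (used e.g. to
#'   plant replicate titrations of a known control compound).
#' @return A list with elements
#'   \describe{
#'     \item{plates}{data frame of every well: `plate_id`, `row`, `col`,
#'       `role` (`compound`, `vehicle_control`, `positive_control`,
#'       `cytotox_control`, `empty`), `compound_id`, `concentration_um`,
#'       `lum`, `fluor`.}
#'     \item{truth}{data frame: `compound_id`, `true_ic50`,
#'       `true_efficacy`, `true_hill_n`, `cytotoxic_ic50`, `cluster_id`.}
#'   }
#' @examples
#' scr <- generate_screen(screen_config(n_compounds = 50, rng_seed = 7))
#' head(scr$plates)
#' table(scr$plates$role)
#' @export
generate_screen <- function(config, truth = NULL) {
  validate_screen_config(config)
  dims <- plate_dims(config$plate_format)
  n_rows <- dims[1]; n_cols <- dims[2]
  n_compound_cols <- n_cols - 4L
  wells_per_plate <- n_rows * n_compound_cols
  if (wells_per_plate < 1L)
    stop("plate too small for the control-column layout")

  withr_seed(config$rng_seed, {
    if (is.null(truth)) truth <- plant_truth(config)
    stopifnot(nrow(truth) == config$n_compounds)

    conc <- concentration_series(config)
    n_blocks <- ceiling(config$n_compounds / wells_per_plate)

    plates <- vector("list", n_blocks * config$n_concentrations + 2L)
    idx <- 1L
    for (b in seq_len(n_blocks)) {
      cmp_idx <- seq((b - 1L) * wells_per_plate + 1L,
                     min(b * wells_per_plate, config$n_compounds))
      block_truth <- truth[cmp_idx, , drop = FALSE]
      for (ci in seq_along(conc)) {
        plates[[idx]] <- simulate_plate(
          config, sprintf("P%02d_C%d", b, ci), block_truth, conc[ci])
        idx <- idx + 1L
      }
    }
    # flanking DMSO-only plates, used downstream for pattern correction
    plates[[idx]] <- simulate_plate(config, "DMSO_START", NULL, NA_real_)
    plates[[idx + 1L]] <- simulate_plate(config, "DMSO_END", NULL, NA_real_)
    plates <- do.call(rbind, plates)
    rownames(plates) <- NULL

    if (config$spatial_artifact_amplitude > 0) {
      pattern <- spatial_pattern(config$plate_format,
                                 config$spatial_artifact_amplitude)
      plates <- inject_spatial_artifact(plates, pattern)
    }
    list(plates = plates, truth = truth)
  })
}

# Draw the planted compound library: which compounds are antagonists, which
# are cytotoxic, their curve parameters, and a cluster assignment mixture in
# which a few designated clusters are genuinely enriched for actives.
plant_truth <- function(config) {
  n <- config$n_compounds
  id <- sprintf("CMP%05d", seq_len(n))
  n_ant <- round(config$fraction_true_antagonists * n)
  n_tox <- round(config$fraction_cytotoxic * n)
  type <- rep("inactive", n)
  type[seq_len(n_ant)] <- "antagonist"
  if (n_tox > 0) type[n_ant + seq_len(n_tox)] <- "cytotoxic"
  type <- sample(type) # shuffle positions across the plates

  is_ant <- type == "antagonist"
  is_tox <- type == "cytotoxic"
  true_ic50 <- rep(NA_real_, n)
  true_efficacy <- rep(0, n)
  true_hill_n <- rep(1, n)
  cytotoxic_ic50 <- rep(NA_real_, n)

  # antagonist potencies log-uniform well inside the titration window, with
  # strong efficacy so planted truths are recoverable above plate noise
  true_ic50[is_ant] <- 10^stats::runif(sum(is_ant), log10(0.05), log10(5))
  true_efficacy[is_ant] <- stats::runif(sum(is_ant), -100, -70)
  true_hill_n[is_ant] <- stats::runif(sum(is_ant), 0.9, 2.1)
  cytotoxic_ic50[is_tox] <- 10^stats::runif(sum(is_tox), log10(0.5), log10(20))

  # cluster mixture: antagonists concentrate in a few designated clusters so
  # enrichment is detectable; everything else is uniform
  n_enriched <- max(2L, config$n_clusters %/% 8L)
  cluster_id <- sprintf("k%02d", sample.int(config$n_clusters, n, replace = TRUE))
  biased <- is_ant & stats::runif(n) < config$active_cluster_bias
  cluster_id[biased] <- sprintf("k%02d",
                                sample.int(n_enriched, sum(biased), replace = TRUE))

  data.frame(compound_id = id, true_ic50 = true_ic50,
             true_efficacy = true_efficacy, true_hill_n = true_hill_n,
             cytotoxic_ic50 = cytotoxic_ic50, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}

# One plate: columns 1-4 are controls (positive, vehicle, cytotox, vehicle),
# remaining columns hold compounds in row-major order at a single shared
# concentration.  block_truth = NULL gives a DMSO-only plate (all
# compound positions become vehicle wells), as stacked around the compound
# plates in a production run.
simulate_plate <- function(config, plate_id, block_truth, conc_um) {
  dims <- plate_dims(config$plate_format)
  n_rows <- dims[1]; n_cols <- dims[2]
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$col, grid$row), , drop = FALSE]

  role <- rep("compound", nrow(grid))
  role[grid$col == 1L] <- "positive_control"
  role[grid$col %in% c(2L, 4L)] <- "vehicle_control"
  role[grid$col == 3L] <- "cytotox_control"
  if (is.null(block_truth)) role[role == "compound"] <- "vehicle_control"

  compound_id <- rep(NA_character_, nrow(grid))
  concentration <- rep(NA_real_, nrow(grid))
  cmp_wells <- which(role == "compound")
  if (!is.null(block_truth)) {
    k <- seq_len(min(length(cmp_wells), nrow(block_truth)))
    compound_id[cmp_wells[k]] <- block_truth$compound_id[k]
    concentration[cmp_wells[k]] <- conc_um
    role[cmp_wells[-k]] <- "empty"
    if (length(k) < length(cmp_wells)) {
      # leftover wells stay empty
    }
  }

  mu_v <- config$vehicle_mean
  mu_p <- mu_v / config$signal_to_background
  mu_fv <- config$vehicle_fluor_mean
  mu_fp <- mu_fv / config$signal_to_background

  # reporter fraction (1 = vehicle level, 0 = full inhibition) and survival
  rel <- rep(1, nrow(grid))
  surv <- rep(1, nrow(grid))
  if (!is.null(block_truth)) {
    m <- match(compound_id, block_truth$compound_id)
    has <- !is.na(m)
    # percent activity of the antagonist component (0 vehicle, -100 full)
    a <- ifelse(is.na(block_truth$true_ic50[m[has]]), 0,
                block_truth$true_efficacy[m[has]] *
                  hill_fraction(concentration[has],
                                block_truth$true_ic50[m[has]],
                                block_truth$true_hill_n[m[has]]))
    rel[has] <- 1 + a / 100
    s <- ifelse(is.na(block_truth$cytotoxic_ic50[m[has]]), 1,
                1 - hill_fraction(concentration[has],
                                  block_truth$cytotoxic_ic50[m[has]], 1.5))
    surv[has] <- s
  }
  rel[role == "positive_control"] <- 0
  surv[role == "cytotox_control"] <- 0

  lum_mean <- mu_p + (mu_v - mu_p) * rel * surv
  fluor_mean <- mu_fp + (mu_fv - mu_fp) * surv

  cv <- rep(config$dmso_cv, nrow(grid))
  cv[role == "positive_control"] <- config$pos_control_cv
  cv[role == "cytotox_control"] <- config$pos_control_cv

  lum <- lum_mean * (1 + stats::rnorm(nrow(grid), 0, cv))
  fluor <- fluor_mean * (1 + stats::rnorm(nrow(grid), 0, cv))
  lum[role == "empty"] <- NA_real_
  fluor[role == "empty"] <- NA_real_

  data.frame(plate_id = plate_id, row = grid$row, col = grid$col,
             role = role, compound_id = compound_id,
             concentration_um = concentration, lum = lum, fluor = fluor,
             stringsAsFactors = FALSE)
}

# fractional occupancy c^n / (k^n + c^n), the building block of every
# planted curve
hill_fraction <- function(c, k, n) {
  ifelse(c <= 0, 0, 1 / (1 + (k / c)^n))
}

#' Deterministic smooth plate-surface artifact
#'
#' A sinusoidal row-by-column surface of the kind edge effects and dispense
#' gradients leave on real plates; used as input for
#' [inject_spatial_artifact()] and to exercise [pattern_correct()].
#'
#' @param plate_format wells per plate (96, 384 or 1536).
#' @param amplitude peak offset in raw signal units.
#' @param type `"sinusoidal"` (default), `"column"` (constant offset on one
#'   column) or `"constant"`.
#' @param column column index for `type = "column"`.
#' @return Data frame `row`, `col`, `offset` covering every well.
#' @export
spatial_pattern <- function(plate_format, amplitude,
                            type = c("sinusoidal", "column", "constant"),
                            column = 1L) {
  type <- match.arg(type)
  dims <- plate_dims(plate_format)
  grid <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]),
                      KEEP.OUT.ATTRS = FALSE)
  grid$offset <- switch(type,
    sinusoidal = amplitude * sin(2 * pi * grid$row / dims[1]) *
      cos(pi * grid$col / dims[2]),
    column = ifelse(grid$col == column, amplitude, 0),
    constant = rep(amplitude, nrow(grid))
  )
  grid
}

#' Add a spatial artifact to the luminescence channel of every plate
#'
#' Offsets are added to the luminescence channel only (the reporter read is
#' the one susceptible to stack-position and dispense patterns in this
#' design); the input is not modified.
#'
#' @param plates plate table as produced by [generate_screen()].
#' @param pattern data frame `row`, `col`, `offset` (one entry per well
#'   position), e.g. from [spatial_pattern()].
#' @return A plate table with offset luminescence values.
#' @export
inject_spatial_artifact <- function(plates, pattern) {
  stopifnot(all(c("row", "col", "offset") %in% names(pattern)))
  key_p <- paste(plates$row, plates$col)
  key_a <- paste(pattern$row, pattern$col)
  m <- match(key_p, key_a)
  if (anyNA(m))
    stop("pattern dimensions do not match the plate layout")
  plates$lum <- plates$lum + pattern$offset[m]
  plates
}

#' Simulate replicate control titrations
#'
#' Generates normalized concentration-response series for a compound of
#' known potency by planting it repeatedly in a synthetic screen and running
#' plate normalization, exactly as the positive-control titration is
#' re-measured on every plate of a production screen.
#'
#' @param config a [screen_config()]; its noise parameters and titration
#'   series are used.
#' @param n_replicates number of independent replicate series.
#' @param ic50 true IC50 in uM.
#' @param efficacy true efficacy in percent (negative for inhibition).
#' @param hill_n true Hill coefficient.
#' @return Long data frame `compound_id`, `readout`, `concentration_um`,
#'   `percent_activity` with one `compound_id` per replicate.
#' @examples
#' cfg <- screen_config(rng_seed = 3)
#' tit <- simulate_control_titrations(cfg, n_replicates = 5, ic50 = 0.169,
#'                                    efficacy = -100, hill_n = 1)
#' @export
simulate_control_titrations <- function(config, n_replicates, ic50, efficacy,
                                        hill_n = 1) {
  truth <- data.frame(
    compound_id = sprintf("REP%03d", seq_len(n_replicates)),
    true_ic50 = ic50, true_efficacy = efficacy, true_hill_n = hill_n,
    cytotoxic_ic50 = NA_real_, cluster_id = "k01",
    stringsAsFactors = FALSE)
  cfg <- config
  cfg$n_compounds <- n_replicates
  scr <- generate_screen(cfg, truth = truth)
  norm <- normalize_plates(scr$plates)
  resp <- screen_responses(norm)
  resp[resp$readout == "activity", , drop = FALSE]
}

# Evaluate a seeded code block without clobbering the caller's RNG stream.
withr_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
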