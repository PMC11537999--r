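test_that("percent activity maps controls to 0 and -100 and is linear", {
  expect_equal(percent_activity(1000, 1000, 300), 0)
  expect_equal(percent_activity(300, 1000, 300), -100)
  expect_equal(percent_activity(860, 1000, 300), -20)
  expect_error(percent_activity(500, 700, 700), "degenerate")
})

test_that("normalization is invariant to a common rescaling of raw signal", {
  cfg <- screen_config(n_compounds = 10, rng_seed = 3)
  scr <- generate_screen(cfg)
  n1 <- normalize_plates(scr$plates)
  scaled <- scr$plates
  scaled$lum <- scaled$lum * 2.7
  scaled$fluor <- scaled$fluor * 2.7
  n2 <- normalize_plates(scaled)
  expect_equal(n2$pct_activity, n1$pct_activity, tolerance = 1e-12)
  expect_equal(n2$pct_viability, n1$pct_viability, tolerance = 1e-12)
})

test_that("normalized control medians sit at 0% and -100%", {
  cfg <- screen_config(n_compounds = 10, rng_seed = 9)
  norm <- normalize_plates(generate_screen(cfg)$plates)
  one <- norm[norm$plate_id == norm$plate_id[1], ]
  expect_equal(median(one$pct_activity[one$role == "vehicle_control"]), 0,
               tolerance = 1e-9)
  expect_equal(median(one$pct_activity[one$role == "positive_control"]),
               -100, tolerance = 1e-9)
  # plates without enough controls are rejected
  broken <- one[one$role != "positive_control", ]
  expect_error(normalize_plates(broken), "positive-control")
})

test_that("pattern correction removes exactly what the DMSO plates see", {
  scr <- generate_screen(quiet_config(n_compounds = 40))
  norm <- normalize_plates(scr$plates)
  is_dmso <- grepl("^DMSO", norm$plate_id)
  comp <- norm[!is_dmso, ]
  dmso <- norm[is_dmso, ]

  # clean DMSO plates: correction is a no-op
  corr0 <- pattern_correct(comp, dmso)
  expect_equal(corr0$pct_activity, comp$pct_activity, tolerance = 1e-9)

  # a +10%-of-dynamic-range artifact on one compound column, present in
  # compound and DMSO plates alike, is removed exactly (control columns
  # stay clean so the normalization anchors do not move)
  mu_v <- 3540; mu_p <- mu_v / 3.54
  pat1 <- spatial_pattern(1536, 0.10 * (mu_v - mu_p), type = "column",
                          column = 5)
  art <- inject_spatial_artifact(scr$plates, pat1)
  norm_a <- normalize_plates(art)
  comp_a <- norm_a[!is_dmso, ]
  dmso_a <- norm_a[is_dmso, ]
  hit <- comp_a$col == 5 & !is.na(comp_a$pct_activity)
  expect_true(any(hit))
  expect_true(all(abs(comp_a$pct_activity[hit] - 10) < 1e-9))
  corr <- pattern_correct(comp_a, dmso_a)
  expect_true(all(abs(corr$pct_activity[hit]) < 1e-9))

  # idempotence: once removed, a second pass changes nothing
  corr2 <- pattern_correct(corr, pattern_correct(dmso_a, dmso_a))
  expect_equal(corr2$pct_activity, corr$pct_activity, tolerance = 1e-9)
})

test_that("a sinusoidal artifact is flattened to within noise", {
  cfg <- screen_config(n_compounds = 10, rng_seed = 21)
  scr <- generate_screen(cfg)
  mu_v <- 3540; mu_p <- mu_v / 3.54
  pat <- spatial_pattern(1536, 0.3 * (mu_v - mu_p)) # 30%-amplitude surface
  art <- inject_spatial_artifact(scr$plates, pat)
  norm <- normalize_plates(art)
  is_dmso <- grepl("^DMSO", norm$plate_id)
  comp <- norm[!is_dmso, ]
  corr <- pattern_correct(comp, norm[is_dmso, ])
  surf_rms <- function(d) {
    veh <- d[d$role == "vehicle_control", ]
    resid <- tapply(veh$pct_activity, paste(veh$row, veh$col), median)
    sqrt(mean(resid^2))
  }
  # the injected surface dominates before correction and is flattened to
  # near the vehicle-noise floor afterwards
  expect_gt(surf_rms(comp), 8)
  expect_lt(surf_rms(corr), 0.5 * surf_rms(comp))
  veh <- corr[corr$role == "vehicle_control", ]
  resid <- tapply(veh$pct_activity, paste(veh$row, veh$col), median)
  expect_lt(abs(median(resid)), 2)
})

test_that("plate QC reproduces its defining formulas", {
  # zero-noise plate: Z' = 1 exactly
  qc0 <- plate_qc(generate_screen(quiet_config(n_compounds = 4))$plates)
  expect_equal(qc0$z_prime, rep(1, nrow(qc0)))
  expect_equal(qc0$cv, rep(0, nrow(qc0)))
  expect_equal(qc0$s_b, rep(3.54, nrow(qc0)), tolerance = 1e-12)

  # hand-built plate hitting the printed screen statistics: vehicle wells
  # with mean 3.54 / SD 0.2492, positive wells with mean 1 / SD 0.1132
  mk <- function(role, mu, sdv, col) data.frame(
    plate_id = "X", row = seq_len(2), col = col, role = role,
    compound_id = NA_character_, concentration_um = NA_real_,
    lum = c(mu - sdv / sqrt(2), mu + sdv / sqrt(2)), fluor = 1)
  plate <- rbind(mk("vehicle_control", 3.54, 0.0704 * 3.54, 2),
                 mk("positive_control", 1, 0.1131573, 1))
  qc <- plate_qc(plate)
  expect_equal(qc$cv, 7.04, tolerance = 1e-9)
  expect_equal(qc$s_b, 3.54, tolerance = 1e-9)
  expect_equal(qc$z_prime,
               1 - 3 * (0.1131573 + 0.0704 * 3.54) / (3.54 - 1),
               tolerance = 1e-9)
  expect_equal(qc$z_prime, 0.572, tolerance = 1e-3)

  # CV of {90, 100, 110} is 10%
  v <- data.frame(plate_id = "Y", row = 1:3, col = 2,
                  role = "vehicle_control", compound_id = NA_character_,
                  concentration_um = NA_real_, lum = c(90, 100, 110),
                  fluor = 1)
  p <- data.frame(plate_id = "Y", row = 1:2, col = 1,
                  role = "positive_control", compound_id = NA_character_,
                  concentration_um = NA_real_, lum = c(10, 10), fluor = 1)
  expect_equal(plate_qc(rbind(v, p))$cv, 10)
})

test_that("noise band estimates three vehicle-well SDs", {
  cfg <- screen_config(n_compounds = 10, rng_seed = 13)
  norm <- normalize_plates(generate_screen(cfg)$plates)
  b <- noise_band(norm)
  # vehicle %-activity SD is 100 * cv * S/B / (S/B - 1) in expectation
  expected <- 3 * 100 * 0.0704 * 3.54 / 2.54
  expect_equal(b, expected, tolerance = 0.15)
})
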