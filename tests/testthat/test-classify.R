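# classes the rank mapping is defined over
all_classes <- c(-1.1, -1.2, -2.1, -2.2, -3, 1.1, 1.2, 2.1, 2.2, 3, 4)

test_that("curve classes follow the asymptote and point-count rules", {
  conc <- conc7()
  band <- 15

  # everything inside the band: inactive
  flatfit <- fit_hill(conc, rep(2, 7))
  expect_equal(assign_class(flatfit, conc, rep(2, 7), band), 4)

  # complete high-quality sigmoid: Class -1.1
  truth <- list(a0 = 0, a_inf = -100, k = 0.2, n = 1.5)
  y <- hill_eval(truth, conc)
  f <- fit_hill(conc, y)
  expect_equal(assign_class(f, conc, y, band), -1.1)

  # incomplete curve (IC50 near the top of the range): Class -2.x
  truth2 <- list(a0 = 0, a_inf = -100, k = 30, n = 1.2)
  y2 <- hill_eval(truth2, conc)
  f2 <- fit_hill(conc, y2)
  cls2 <- assign_class(f2, conc, y2, band)
  expect_equal(trunc(cls2), -2)

  # one isolated point of activity: Class -3 (and +3 mirrored)
  y3 <- c(rep(0, 6), -60)
  f3 <- fit_hill(conc, y3)
  expect_equal(assign_class(f3, conc, y3, band), -3)
  expect_equal(assign_class(f3, conc, -y3, band), 3)

  # low-efficacy complete curve lands in subclass .2
  truth4 <- list(a0 = 0, a_inf = -60, k = 0.2, n = 1.5)
  y4 <- hill_eval(truth4, conc)
  f4 <- fit_hill(conc, y4)
  expect_equal(assign_class(f4, conc, y4, band = 10), -1.2)
})

test_that("curve rank spans [-9, 9], is zero iff inactive, and is monotone", {
  effs <- seq(-100, 100, by = 1)
  grid <- expand.grid(cls = all_classes, eff = effs)
  ranks <- curve_rank(grid$cls, grid$eff)
  expect_true(all(abs(ranks) <= 9))
  expect_true(all((ranks == 0) == (grid$cls == 4)))
  expect_true(all(abs(ranks[abs(grid$cls) == 1.1]) >= 8))
  expect_true(all(abs(ranks)[abs(ranks) == 9] == 9 &
                    abs(grid$cls[abs(ranks) == 9]) == 1.1))
  expect_true(all(sign(ranks) == sign(grid$cls) | ranks == 0 |
                    grid$cls == 4))
  # monotone within class: larger |efficacy| never lowers |rank|
  for (cls in setdiff(all_classes, 4)) {
    r <- abs(curve_rank(rep(cls, length(effs)), effs))
    up <- effs >= 0
    expect_true(all(diff(r[up]) >= 0))
    expect_true(all(diff(rev(r[!up])) >= 0))
  }
  expect_equal(curve_rank(-1.1, -100), -9)
  expect_equal(curve_rank(-3, -55), -2)
  expect_equal(curve_rank(4, -100), 0)
  expect_error(curve_rank(5.1, -50), "invalid")
})

test_that("activity outcomes match a brute-force truth-table oracle", {
  # independent re-statement of the calling rule as literal branches
  oracle <- function(rank, eff, viab_inactive, sep) {
    rescued <- viab_inactive || (!is.na(sep) && sep >= 6)
    if (rank < -1 && eff < -50 && rescued) return("active")
    if (abs(rank) < 1) return("inactive")
    "inconclusive"
  }
  cases <- expand.grid(rank = -9:9,
                       eff = c(-120, -90, -50.5, -50, -20, 0, 60),
                       viab = c(TRUE, FALSE),
                       sep = c(NA, 0.5, 2, 5.99, 6, 40))
  got <- activity_outcome(cases$rank, cases$eff, cases$viab, cases$sep)
  want <- mapply(oracle, cases$rank, cases$eff, cases$viab, cases$sep)
  expect_identical(got, unname(want))
  # spot checks straight from the rule
  expect_equal(activity_outcome(-5, -90, TRUE, NA), "active")
  expect_equal(activity_outcome(0, 0, TRUE, NA), "inactive")
  expect_equal(activity_outcome(-4, -80, FALSE, 2), "inconclusive")
})

test_that("selection filters equal a row-by-row oracle on a planted table", {
  calls <- data.frame(
    compound_id = sprintf("C%02d", 1:10),
    efficacy = c(-90, -80, -40, -60, -95, -77, -100, -55, -76, -85),
    ic50_um = c(1, 12, 0.5, 3, 8, 0.2, 25, 6, 4, 0.9),
    viability_inactive = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                           TRUE, TRUE, FALSE),
    potency_separation = c(NA, NA, NA, 2, NA, 10, NA, NA, NA, 3),
    stringsAsFactors = FALSE)
  conf <- select_confirmation(calls)
  oracle_conf <- calls$compound_id[
    calls$efficacy < -50 & calls$ic50_um < 10 &
      (calls$viability_inactive |
         (!is.na(calls$potency_separation) & calls$potency_separation >= 6))]
  expect_setequal(conf, oracle_conf)
  expect_false("C03" %in% conf)  # efficacy -40 misses the cut
  expect_true("C01" %in% conf)
  expect_false("C04" %in% conf)  # cytotoxic without 6-fold separation

  fu <- select_followup(calls)
  oracle_fu <- calls$compound_id[
    calls$efficacy < -75 & calls$ic50_um < 10 & calls$viability_inactive]
  expect_setequal(fu, oracle_fu)
  expect_true(all(fu %in% union(conf, fu)))

  # explicit negative controls ride along
  expect_true("NEG1" %in%
                select_confirmation(calls, negative_controls = "NEG1"))
})

test_that("confirmation rate is plain percentage arithmetic", {
  expect_equal(confirmation_rate(94, 66), 70.2)
  expect_equal(confirmation_rate(10, 10), 100)
  expect_equal(confirmation_rate(10, 3), 30.0)
  expect_error(confirmation_rate(0, 0))
  expect_error(confirmation_rate(5, 6))
})

test_that("call_compounds separates antagonists from cytotoxic mimics", {
  conc <- conc7()
  mk <- function(id, readout, y)
    data.frame(compound_id = id, readout = readout, concentration_um = conc,
               percent_activity = y, stringsAsFactors = FALSE)
  ant <- list(a0 = 0, a_inf = -95, k = 0.3, n = 1.3)
  tox <- list(a0 = 0, a_inf = -95, k = 2, n = 1.3)
  resp <- rbind(
    mk("ANT", "activity", hill_eval(ant, conc)),
    mk("ANT", "viability", rep(0, 7)),
    mk("TOX", "activity", hill_eval(tox, conc)),
    mk("TOX", "viability", hill_eval(tox, conc)),   # same potency: mimic
    mk("SEP", "activity", hill_eval(ant, conc)),
    mk("SEP", "viability", hill_eval(list(a0 = 0, a_inf = -95, k = 0.3 * 8,
                                          n = 1.3), conc)),
    mk("NUL", "activity", rep(0, 7)),
    mk("NUL", "viability", rep(0, 7)))
  fits <- fit_screen(resp, noise_band = 15)
  calls <- call_compounds(resp, fits, band = 15)
  out <- setNames(calls$outcome, calls$compound_id)
  expect_equal(out[["ANT"]], "active")        # clean antagonist
  expect_equal(out[["TOX"]], "inconclusive")  # cytotoxicity masquerading
  expect_equal(out[["SEP"]], "active")        # rescued by 8-fold separation
  expect_equal(out[["NUL"]], "inactive")
  expect_gte(calls$potency_separation[calls$compound_id == "SEP"], 6)
})
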