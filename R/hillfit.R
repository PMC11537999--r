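#' Evaluate a four-parameter Hill curve
#'
#' \deqn{a(c) = a_0 + (a_\infty - a_0)\frac{c^n}{k^n + c^n}}
#' where `a0` is the activity at zero concentration, `a_inf` the activity at
#' infinite concentration, `k` the half-maximal concentration (IC50 for an
#' inhibitor) and `n` the Hill coefficient.  `c = 0` returns `a0` exactly.
#'
#' @param fit a `hill_fit` object (from [fit_hill()]) or any list carrying
#'   `a0`, `a_inf`, `k`, `n`.
#' @param conc concentration(s), same units as `k`; non-negative.
#' @return Percent activity at each concentration.
#' @examples
#' f <- list(a0 = 0, a_inf = -100, k = 1, n = 1)
#' hill_eval(f, c(0, 1, 3)) # 0, -50, -75
#' @export
hill_eval <- function(fit, conc) {
  stopifnot(all(conc >= 0))
  hill_response(conc, fit$a0, fit$a_inf, fit$k, fit$n)
}

hill_response <- function(c, a0, a_inf, k, n) {
  ifelse(c <= 0, a0, a0 + (a_inf - a0) / (1 + (k / c)^n))
}

#' Fit a four-parameter Hill curve to one concentration-response series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, IC50 fitted on the
#' log scale) from three deterministic starting points; the best-loss
#' solution wins, ties broken toward the lower IC50.  Starting values follow
#' the standard 4PL heuristic: `a0` from the lowest-concentration response,
#' `a_inf` from the highest, `k` from the concentration whose response is
#' nearest the half-range, `n = 1`.  With fewer than four usable points the
#' Hill coefficient is fixed at 1 and three parameters are fitted; with
#' fewer than two, no fit is attempted and `converged` is `FALSE`.
#'
#' After the first fit a single point whose residual exceeds three robust
#' SDs (1.4826 x MAD) of the residuals may be masked and the fit repeated
#' once, mimicking the single-outlier tolerance of production qHTS fitting.
#'
#' The IC50 is constrained to `[min(conc)/10, max(conc) * 10]` and the Hill
#' coefficient to `[0.3, 8]`; a fit never reports parameters outside these
#' boxes.  Failures are reported via `converged = FALSE`, never as errors.
#'
#' @param conc concentrations in uM, strictly positive.
#' @param response percent activity at each concentration.
#' @param mask logical vector, `TRUE` for points to include (default all).
#' @param n_bounds bounds for the Hill coefficient.
#' @param k_bounds bounds for the IC50 in uM; default derived from the
#'   concentration range.
#' @param asym_bounds bounds shared by `a0` and `a_inf`, in percent.
#' @param mask_outliers whether the one-point outlier rule is applied.
#' @param compound_id,readout optional labels carried into the result.
#' @return An object of class `hill_fit`: list with `a0`, `a_inf`, `k`,
#'   `n`, `efficacy` (`a_inf - a0`), `r_squared`, `converged`, `mask`,
#'   `conc`, `response`, `compound_id`, `readout`.
#' @examples
#' conc <- exp(seq(log(0.0015), log(46), length.out = 7))
#' resp <- hill_response(conc, 0, -100, 0.2, 1.2)
#' fit_hill(conc, resp)
#' @export
fit_hill <- function(conc, response, mask = NULL,
                     n_bounds = c(0.3, 8), k_bounds = NULL,
                     asym_bounds = c(-200, 200),
                     mask_outliers = TRUE,
                     compound_id = NA_character_,
                     readout = NA_character_) {
  stopifnot(length(conc) == length(response), all(conc > 0))
  ord <- order(conc)
  conc <- conc[ord]; response <- response[ord]
  if (is.null(mask)) mask <- rep(TRUE, length(conc)) else mask <- mask[ord]
  mask <- mask & !is.na(response)
  if (is.null(k_bounds)) k_bounds <- c(min(conc) / 10, max(conc) * 10)

  res <- fit_hill_masked(conc, response, mask, n_bounds, k_bounds,
                         asym_bounds)
  # one-shot single-outlier masking on the residuals of the first fit
  if (mask_outliers && res$converged && sum(mask) >= 5L) {
    r <- response[mask] - hill_response(conc[mask], res$a0, res$a_inf,
                                        res$k, res$n)
    rsd <- stats::mad(r)
    if (rsd > 0 && max(abs(r)) > 3 * rsd) {
      drop <- which(mask)[which.max(abs(r))]
      mask2 <- mask; mask2[drop] <- FALSE
      res2 <- fit_hill_masked(conc, response, mask2, n_bounds, k_bounds,
                              asym_bounds)
      if (res2$converged) { res <- res2; mask <- mask2 }
    }
  }

  structure(c(res, list(mask = mask, conc = conc, response = response,
                        compound_id = compound_id, readout = readout)),
            class = "hill_fit")
}

fit_hill_masked <- function(conc, response, mask, n_bounds, k_bounds,
                            asym_bounds) {
  x <- conc[mask]; y <- response[mask]
  no_fit <- list(a0 = NA_real_, a_inf = NA_real_, k = NA_real_,
                 n = NA_real_, efficacy = 0, r_squared = NA_real_,
                 converged = FALSE)
  if (length(x) < 2L) return(no_fit)
  if (stats::sd(y) == 0) {
    # perfectly flat series: nothing to optimize
    return(list(a0 = y[1], a_inf = y[1], k = exp(mean(log(range(conc)))),
                n = 1, efficacy = 0, r_squared = NA_real_, converged = TRUE))
  }

  fit_n <- length(x) >= 4L # else Hill coefficient fixed at 1
  a0_init <- y[1]; ainf_init <- y[length(y)]
  half <- (a0_init + ainf_init) / 2
  k_init <- x[which.min(abs(y - half))]
  k_init <- min(max(k_init, k_bounds[1]), k_bounds[2])
  k_mid <- exp(mean(log(k_bounds)))
  starts <- list(c(k = k_init, n = 1), c(k = k_mid, n = 1),
                 c(k = k_init, n = 2))

  resid_fun <- function(par) {
    n_par <- if (fit_n) min(max(par[4], n_bounds[1]), n_bounds[2]) else 1
    y - hill_response(x, par[1], par[2], 10^par[3], n_par)
  }
  lower <- c(asym_bounds[1], asym_bounds[1], log10(k_bounds[1]), n_bounds[1])
  upper <- c(asym_bounds[2], asym_bounds[2], log10(k_bounds[2]), n_bounds[2])
  if (!fit_n) { lower <- lower[1:3]; upper <- upper[1:3] }

  best <- NULL
  for (s in starts) {
    par0 <- c(a0_init, ainf_init, log10(s[["k"]]),
              if (fit_n) s[["n"]] else NULL)
    par0 <- pmin(pmax(par0, lower), upper)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ans) || !ans$info %in% 1:4) next
    sse <- sum(ans$fvec^2)
    k_hat <- 10^ans$par[3]
    if (is.null(best) || sse < best$sse * (1 - 1e-9) ||
        (abs(sse - best$sse) <= best$sse * 1e-9 && k_hat < best$k)) {
      best <- list(par = ans$par, sse = sse, k = k_hat)
    }
  }
  if (is.null(best)) return(no_fit)

  a0 <- best$par[1]; a_inf <- best$par[2]
  # 10^log10(k) can undershoot the boundary by one ulp; pin it back
  k <- min(max(best$k, k_bounds[1]), k_bounds[2])
  n <- if (fit_n) best$par[4] else 1
  ss_tot <- sum((y - mean(y))^2)
  list(a0 = a0, a_inf = a_inf, k = k, n = n,
       efficacy = a_inf - a0,
       r_squared = if (ss_tot > 0) 1 - best$sse / ss_tot else NA_real_,
       converged = TRUE)
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: not converged (",
        sum(x$mask), "of", length(x$mask), "points usable )\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Hill fit: a0 = %.2f%%, a_inf = %.2f%%, IC50 = %.4g uM, n = %.2f\n",
    x$a0, x$a_inf, x$k, x$n))
  cat(sprintf("  efficacy = %.2f%%, r^2 = %.4f, %d/%d points\n",
              x$efficacy, x$r_squared, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Concentration producing x% of the fitted maximal effect
#'
#' Inverts the fitted Hill curve:
#' \eqn{IC_x = k\,(x/(100-x))^{1/n}}.  `x = 50` returns the IC50 `k`
#' itself; IC70 and IC90 are the usual choices when a follow-up assay needs
#' a near-saturating but on-scale concentration.
#'
#' @param fit converged `hill_fit` with nonzero efficacy.
#' @param x percent of maximal effect, strictly between 0 and 100.
#' @return Concentration in the units of `fit$k`.
#' @examples
#' f <- list(a0 = 0, a_inf = -100, k = 1, n = 1, efficacy = -100,
#'           converged = TRUE)
#' derive_icx(f, 70) # 7/3
#' @export
derive_icx <- function(fit, x) {
  stopifnot(x > 0, x < 100)
  if (!isTRUE(fit$converged) || is.na(fit$k) || fit$efficacy == 0)
    stop("ICx is undefined for a flat or unconverged fit")
  fit$k * (x / (100 - x))^(1 / fit$n)
}

#' Fit Hill curves to every series of a screen
#'
#' Applies [fit_hill()] per compound and readout.  When a `noise_band` is
#' supplied, series with no point outside the band are recorded directly as
#' flat no-fit rows — their curve class is fully determined (inactive)
#' without optimization, which keeps full-library screens fast.
#'
#' @param responses long table `compound_id`, `readout`,
#'   `concentration_um`, `percent_activity` (e.g. from
#'   [screen_responses()]).
#' @param noise_band optional percent-activity band for the flat-series
#'   fast path.
#' @param ... passed on to [fit_hill()].
#' @return Data frame `compound_id`, `readout`, `a0`, `ainf`, `ic50_um`,
#'   `hill_n`, `efficacy`, `r2`, `converged`.
#' @export
fit_screen <- function(responses, noise_band = NULL, ...) {
  req <- c("compound_id", "readout", "concentration_um", "percent_activity")
  stopifnot(all(req %in% names(responses)))
  pieces <- split(responses,
                  list(responses$compound_id, responses$readout),
                  drop = TRUE)
  rows <- lapply(pieces, function(p) {
    flat <- !is.null(noise_band) &&
      all(abs(p$percent_activity) <= noise_band, na.rm = TRUE)
    if (flat) {
      return(data.frame(compound_id = p$compound_id[1],
                        readout = p$readout[1], a0 = NA_real_,
                        ainf = NA_real_, ic50_um = NA_real_,
                        hill_n = NA_real_, efficacy = 0, r2 = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    f <- fit_hill(p$concentration_um, p$percent_activity,
                  compound_id = p$compound_id[1], readout = p$readout[1],
                  ...)
    data.frame(compound_id = p$compound_id[1], readout = p$readout[1],
               a0 = f$a0, ainf = f$a_inf, ic50_um = f$k, hill_n = f$n,
               efficacy = f$efficacy, r2 = f$r_squared,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound_id, out$readout), , drop = FALSE]
}
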