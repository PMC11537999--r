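#' Assign a signed qHTS curve class
#'
#' Concentration-response series are binned into the standard qHTS curve
#' classes: Class 1, a complete curve showing both asymptotes; Class 2, an
#' incomplete curve showing only the lower (zero-concentration) asymptote;
#' Class 3, a single point of activity with no curve support; Class 4,
#' inactive.  Classes 1 and 2 carry a quality subclass: `.1` when the fit
#' is both efficacious (|efficacy| >= `high_eff`) and well determined
#' (r^2 >= `r2_threshold`), `.2` otherwise.  The sign of the class follows
#' the sign of the response (negative = inhibition).
#'
#' A response point is "active" when it lies outside `band`, the
#' vehicle-well noise band (see [noise_band()]).  Asymptote observation is
#' judged against the fitted plateaus: the lower asymptote is observed when
#' the lowest-concentration response is within `band` of `a0`, the upper
#' when the highest-concentration response is within `band` of `a_inf`.
#' Series with several active points but no usable fit, or with curve
#' support that shows neither plateau, fall back to Class 3.
#'
#' @param fit `hill_fit` for the series (may be unconverged).
#' @param conc,response the (unmasked) series the class is judged on.
#' @param band noise band in percent-activity units.
#' @param high_eff efficacy magnitude (percent) for subclass `.1`.
#' @param r2_threshold fit quality for subclass `.1`.
#' @return Signed numeric class: one of -1.1, -1.2, -2.1, -2.2, -3,
#'   1.1, ..., 3, or 4 (inactive, unsigned).
#' @export
assign_class <- function(fit, conc, response, band,
                         high_eff = 80, r2_threshold = 0.9) {
  keep <- !is.na(response)
  conc <- conc[keep]; response <- response[keep]
  if (!is.null(fit$mask)) {
    m <- fit$mask[keep]
    conc <- conc[m]; response <- response[m]
  }
  if (length(response) == 0L) return(4)
  ord <- order(conc)
  conc <- conc[ord]; response <- response[ord]

  outside <- abs(response) > band
  n_out <- sum(outside)
  if (n_out == 0L) return(4)
  if (n_out == 1L) return(3 * sign(response[outside]))

  sgn <- sign(sum(sign(response[outside])))
  if (sgn == 0) sgn <- sign(response[outside][n_out])
  if (!isTRUE(fit$converged) || is.na(fit$k) || fit$efficacy == 0)
    return(3 * sgn)

  sgn <- sign(fit$efficacy)
  lower_seen <- abs(response[1] - fit$a0) <= band
  upper_seen <- abs(response[length(response)] - fit$a_inf) <= band
  good <- abs(fit$efficacy) >= high_eff &&
    !is.na(fit$r_squared) && fit$r_squared >= r2_threshold
  sub <- if (good) 0.1 else 0.2
  if (lower_seen && upper_seen) return(sgn * (1 + sub))
  if (lower_seen) return(sgn * (2 + sub))
  3 * sgn
}

# table of |rank| by |class| and |efficacy|; each class spans two adjacent
# ranks, the upper one taken at or above the class's efficacy split
rank_table <- list(
  "1.1" = c(lo = 8, hi = 9, split = 80),
  "1.2" = c(lo = 6, hi = 7, split = 50),
  "2.1" = c(lo = 4, hi = 5, split = 80),
  "2.2" = c(lo = 2, hi = 3, split = 50),
  "3"   = c(lo = 1, hi = 2, split = 50)
)

#' Convert a signed curve class and efficacy to a curve rank
#'
#' Curve rank compresses class and efficacy into a single signed score in
#' \[-9, 9\]: 0 is inactive, large negative values are strong inhibitors,
#' large positive values strong activators.  The mapping (overridable via
#' the internal table) gives each class a two-rank span, ordered so
#' higher-quality classes always outrank lower ones, with the upper rank of
#' the span taken at high |efficacy|:
#' class 1.1 -> 8-9, 1.2 -> 6-7, 2.1 -> 4-5, 2.2 -> 2-3, 3 -> 1-2,
#' 4 -> 0.  Within a class, larger |efficacy| never lowers |rank|.
#'
#' @param curve_class signed class from [assign_class()]; vectorized.
#' @param efficacy fitted efficacy in percent; vectorized.
#' @return Integer-valued rank in \[-9, 9\], sign following the class sign.
#' @examples
#' curve_rank(-1.1, -100) # -9
#' curve_rank(4, 0)       # 0
#' @export
curve_rank <- function(curve_class, efficacy) {
  mapply(function(cls, eff) {
    if (cls == 4) return(0)
    key <- format(abs(cls), nsmall = if (abs(cls) == 3) 0 else 1)
    row <- rank_table[[key]]
    if (is.null(row)) stop("invalid curve class: ", cls)
    r <- if (abs(eff) >= row[["split"]]) row[["hi"]] else row[["lo"]]
    r * sign(cls)
  }, curve_class, efficacy, USE.NAMES = FALSE)
}

#' Activity outcome from the antagonist readout and viability counter-screen
#'
#' A compound is called `active` when its antagonist curve rank is below
#' -1, its efficacy below -50%, and the cytotoxicity counter-screen clears
#' it — either inactive in the viability readout or at least `fold_cutoff`
#' times more potent in the antagonist readout than in viability.  A
#' compound with |rank| < 1 is `inactive`; everything else is
#' `inconclusive` (real signal that cannot be separated from cytotoxicity
#' or is too weak to call).
#'
#' @param rank antagonist curve rank; vectorized.
#' @param efficacy antagonist efficacy in percent; vectorized.
#' @param viability_inactive logical: compound shows no viability response
#'   (no fit, or viability |rank| < 1); vectorized.
#' @param potency_separation viability IC50 / antagonist IC50; `NA` when
#'   either is undefined.
#' @param fold_cutoff potency-separation fold required to rescue a
#'   viability-active compound.
#' @return Character vector: `"active"`, `"inactive"` or `"inconclusive"`.
#' @examples
#' activity_outcome(-5, -90, TRUE, NA)    # active
#' activity_outcome(0, 0, TRUE, NA)       # inactive
#' activity_outcome(-4, -80, FALSE, 2)    # inconclusive
#' @export
activity_outcome <- function(rank, efficacy, viability_inactive,
                             potency_separation = NA_real_,
                             fold_cutoff = 6) {
  sep_ok <- !is.na(potency_separation) & potency_separation >= fold_cutoff
  active <- rank < -1 & efficacy < -50 & (viability_inactive | sep_ok)
  ifelse(active, "active",
         ifelse(abs(rank) < 1, "inactive", "inconclusive"))
}

#' Call every compound of a screen
#'
#' Combines the antagonist and viability fits into per-compound curve
#' classes, curve ranks and activity outcomes.  The viability readout is
#' classified with the same machinery; a compound counts as
#' viability-inactive when its viability |rank| < 1 (or no viability series
#' exists).  Potency separation is the ratio of fitted viability IC50 to
#' antagonist IC50 where both converge.
#'
#' The `efficacy` column is the call-level efficacy: the fitted
#' `a_inf - a0` for curves with real support (Classes 1 and 2), but the
#' extreme observed response for Class 3 — a single point of activity
#' cannot support an extrapolated asymptote, and using one would let noise
#' spikes masquerade as efficacious actives.
#'
#' @param responses long response table (see [screen_responses()]).
#' @param fits fits table from [fit_screen()] covering both readouts.
#' @param band noise band in percent-activity units.
#' @param high_eff,r2_threshold subclass thresholds, see [assign_class()].
#' @param fold_cutoff see [activity_outcome()].
#' @return Data frame `compound_id`, `curve_class`, `curve_rank`,
#'   `efficacy`, `ic50_um`, `viability_class`, `viability_rank`,
#'   `viability_inactive`, `potency_separation`, `outcome`.
#' @export
call_compounds <- function(responses, fits, band, high_eff = 80,
                           r2_threshold = 0.9, fold_cutoff = 6) {
  act_fits <- fits[fits$readout == "activity", , drop = FALSE]
  via_fits <- fits[fits$readout == "viability", , drop = FALSE]
  ra <- responses[responses$readout == "activity", , drop = FALSE]
  rv <- responses[responses$readout == "viability", , drop = FALSE]
  resp_act <- split(ra, ra$compound_id)
  resp_via <- split(rv, rv$compound_id)
  via_index <- match(act_fits$compound_id, via_fits$compound_id)

  classify_one <- function(frow, p) {
    fit <- list(a0 = frow$a0, a_inf = frow$ainf, k = frow$ic50_um,
                n = frow$hill_n, efficacy = frow$efficacy,
                r_squared = frow$r2, converged = frow$converged,
                mask = NULL)
    assign_class(fit, p$concentration_um, p$percent_activity, band,
                 high_eff, r2_threshold)
  }
  # call-level efficacy: a Class 3 curve has no support beyond its single
  # active point, so its efficacy is that observed response, never the
  # extrapolated fitted asymptote
  call_efficacy <- function(cls, fitted_eff, p) {
    if (!is.na(cls) && abs(cls) == 3) {
      resp <- p$percent_activity[!is.na(p$percent_activity)]
      resp[which.max(abs(resp))]
    } else fitted_eff
  }

  rows <- lapply(seq_len(nrow(act_fits)), function(i) {
    id <- act_fits$compound_id[i]
    pa <- resp_act[[id]]
    cls <- classify_one(act_fits[i, ], pa)
    eff <- call_efficacy(cls, act_fits$efficacy[i], pa)
    rnk <- curve_rank(cls, eff)

    vi <- via_index[i]
    if (!is.na(vi)) {
      pv <- resp_via[[id]]
      vcls <- classify_one(via_fits[vi, ], pv)
      vrnk <- curve_rank(vcls, call_efficacy(vcls, via_fits$efficacy[vi], pv))
      v_inactive <- abs(vrnk) < 1
      sep <- if (!v_inactive && isTRUE(via_fits$converged[vi]) &&
                 isTRUE(act_fits$converged[i]))
        via_fits$ic50_um[vi] / act_fits$ic50_um[i] else NA_real_
    } else {
      vcls <- NA_real_; vrnk <- NA_real_
      v_inactive <- TRUE; sep <- NA_real_
    }

    data.frame(compound_id = id, curve_class = cls, curve_rank = rnk,
               efficacy = eff, ic50_um = act_fits$ic50_um[i],
               viability_class = vcls, viability_rank = vrnk,
               viability_inactive = v_inactive, potency_separation = sep,
               outcome = activity_outcome(rnk, eff, v_inactive, sep,
                                          fold_cutoff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select compounds for a confirmation screen
#'
#' Conjunctive filter on the primary-screen calls: efficacy below
#' `eff_cutoff`, fitted IC50 below `ic50_cutoff` uM, and no sign of
#' cytotoxicity (viability-inactive, or antagonist potency at least
#' `fold_cutoff`-fold separated from the viability potency).  Explicit
#' negative controls can be appended by id.
#'
#' @param calls calls table from [call_compounds()].
#' @param eff_cutoff efficacy threshold in percent (select strictly below).
#' @param ic50_cutoff potency threshold in uM (select strictly below).
#' @param fold_cutoff potency-separation fold clearing cytotoxic actives.
#' @param negative_controls character vector of compound ids appended
#'   regardless of the filter.
#' @return Character vector of selected compound ids.
#' @export
select_confirmation <- function(calls, eff_cutoff = -50, ic50_cutoff = 10,
                                fold_cutoff = 6,
                                negative_controls = character()) {
  sep_ok <- !is.na(calls$potency_separation) &
    calls$potency_separation >= fold_cutoff
  keep <- !is.na(calls$efficacy) & calls$efficacy < eff_cutoff &
    !is.na(calls$ic50_um) & calls$ic50_um < ic50_cutoff &
    (calls$viability_inactive | sep_ok)
  union(calls$compound_id[keep], negative_controls)
}

#' Select compounds for in-depth follow-up
#'
#' The tighter post-confirmation filter: efficacy below -75%, IC50 below
#' 10 uM, and no cytotoxicity at all (viability-inactive; the fold-
#' separation rescue does not apply here).
#'
#' @inheritParams select_confirmation
#' @return Character vector of selected compound ids.
#' @export
select_followup <- function(calls, eff_cutoff = -75, ic50_cutoff = 10) {
  keep <- !is.na(calls$efficacy) & calls$efficacy < eff_cutoff &
    !is.na(calls$ic50_um) & calls$ic50_um < ic50_cutoff &
    calls$viability_inactive
  calls$compound_id[keep]
}

#' Confirmation rate of a screen
#'
#' Percentage of primary-screen actives reproduced in the confirmation
#' screen, reported to one decimal.
#'
#' @param primary_actives number of actives entering confirmation.
#' @param confirmed number confirmed.
#' @return Percentage, rounded to one decimal.
#' @examples
#' confirmation_rate(94, 66) # 70.2
#' @export
confirmation_rate <- function(primary_actives, confirmed) {
  stopifnot(primary_actives > 0, confirmed >= 0,
            confirmed <= primary_actives)
  round(100 * confirmed / primary_actives, 1)
}
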