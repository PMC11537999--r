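#' Percent activity of a well relative to plate controls
#'
#' Scales a raw signal so the vehicle-control level maps to 0% and the
#' positive-control (full inhibition) level to -100%:
#' \deqn{\%\,activity = \frac{V_{compound} - V_{DMSO}}{V_{DMSO} - V_{pos}}
#'   \times 100}
#'
#' @param v_compound raw signal of the well(s); vectorized.
#' @param v_dmso summary (median) signal of the vehicle-control wells.
#' @param v_pos summary (median) signal of the positive-control wells.
#' @return Percent activity; 0 at the vehicle level, -100 at the
#'   positive-control level.
#' @examples
#' percent_activity(860, v_dmso = 1000, v_pos = 300) # -20
#' @export
percent_activity <- function(v_compound, v_dmso, v_pos) {
  if (isTRUE(all.equal(v_dmso, v_pos)))
    stop("degenerate controls: vehicle and positive-control levels coincide")
  (v_compound - v_dmso) / (v_dmso - v_pos) * 100
}

#' Normalize raw plates to percent activity and percent viability
#'
#' Each plate is normalized independently against the median of its own
#' control wells: the luminescence channel against vehicle vs
#' positive-control wells (antagonist readout) and the fluorescence channel
#' against vehicle vs cytotoxicity-control wells (viability readout).
#' Medians, not means, summarize the controls so single stuck or splashed
#' control wells cannot skew a whole plate.
#'
#' @param plates plate table in the [generate_screen()] well schema.
#' @return The same table with `pct_activity` and `pct_viability` columns
#'   appended (NA on empty wells).
#' @export
normalize_plates <- function(plates) {
  req <- c("plate_id", "role", "lum", "fluor")
  stopifnot(all(req %in% names(plates)))
  out <- split(plates, plates$plate_id)
  out <- lapply(out, normalize_one_plate)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$plate_id, unique(plates$plate_id))), , drop = FALSE]
}

normalize_one_plate <- function(plate) {
  veh <- plate$role == "vehicle_control"
  pos <- plate$role == "positive_control"
  tox <- plate$role == "cytotox_control"
  if (sum(veh) < 2L || sum(pos) < 2L)
    stop("plate ", plate$plate_id[1],
         ": need at least 2 vehicle and 2 positive-control wells")
  v_dmso <- stats::median(plate$lum[veh], na.rm = TRUE)
  v_pos <- stats::median(plate$lum[pos], na.rm = TRUE)
  plate$pct_activity <- percent_activity(plate$lum, v_dmso, v_pos)
  if (sum(tox) >= 2L) {
    f_dmso <- stats::median(plate$fluor[veh], na.rm = TRUE)
    f_tox <- stats::median(plate$fluor[tox], na.rm = TRUE)
    plate$pct_viability <- percent_activity(plate$fluor, f_dmso, f_tox)
  } else {
    plate$pct_viability <- NA_real_
  }
  plate
}

#' Background pattern correction from flanking DMSO-only plates
#'
#' Production plate stacks carry systematic well-position patterns (edge
#' effects, dispense gradients).  DMSO-only plates run at the start and end
#' of the stack measure that surface directly; the per-well-position median
#' of their normalized vehicle-well activity is subtracted from every
#' compound plate at the same position.  Positions the DMSO plates cannot
#' speak for (their own control columns) receive no correction; a layout
#' whose compound-well positions are not covered is rejected.  Applied
#' twice the second pass subtracts a surface that is already flat, so the
#' correction is idempotent up to the DMSO plates' own noise.
#'
#' @param plates normalized compound-plate table (from
#'   [normalize_plates()]).
#' @param dmso_plates normalized DMSO-only plate table; at least one plate.
#' @return `plates` with `pct_activity` corrected.
#' @export
pattern_correct <- function(plates, dmso_plates) {
  stopifnot("pct_activity" %in% names(plates),
            "pct_activity" %in% names(dmso_plates))
  if (nrow(dmso_plates) == 0L) stop("at least one DMSO-only plate required")
  ref <- dmso_plates[dmso_plates$role == "vehicle_control", , drop = FALSE]
  if (nrow(ref) == 0L) stop("DMSO-only plates carry no vehicle wells")
  key_d <- paste(ref$row, ref$col)
  surface <- tapply(ref$pct_activity, key_d, stats::median, na.rm = TRUE)
  key_p <- paste(plates$row, plates$col)
  m <- match(key_p, names(surface))
  if (anyNA(m[plates$role == "compound"]))
    stop("plate layout does not match the DMSO-only plates")
  offset <- ifelse(is.na(m), 0, as.numeric(surface[m]))
  plates$pct_activity <- plates$pct_activity - offset
  plates
}

#' Plate quality-control metrics
#'
#' Computes, per plate and on the raw luminescence channel, the three
#' standard screen-performance statistics:
#' \itemize{
#'   \item CV: 100 x SD/mean of the vehicle-control wells;
#'   \item S/B: mean vehicle signal over mean positive-control signal;
#'   \item Z': \eqn{1 - 3(\sigma_{pos} + \sigma_{veh}) /
#'     |\mu_{veh} - \mu_{pos}|}.
#' }
#'
#' @param plates plate table (raw well schema); may contain several plates.
#' @return Data frame `plate_id`, `cv`, `s_b`, `z_prime`.
#' @examples
#' scr <- generate_screen(screen_config(n_compounds = 10, rng_seed = 1))
#' plate_qc(scr$plates)
#' @export
plate_qc <- function(plates) {
  out <- lapply(split(plates, plates$plate_id), function(p) {
    v <- p$lum[p$role == "vehicle_control"]
    b <- p$lum[p$role == "positive_control"]
    if (length(v) < 2L || length(b) < 2L)
      stop("plate ", p$plate_id[1], ": control wells missing")
    mu_v <- mean(v); mu_p <- mean(b)
    if (isTRUE(all.equal(mu_v, mu_p)))
      stop("plate ", p$plate_id[1], ": degenerate controls")
    data.frame(plate_id = p$plate_id[1],
               cv = 100 * stats::sd(v) / mu_v,
               s_b = mu_v / mu_p,
               z_prime = 1 - 3 * (stats::sd(b) + stats::sd(v)) /
                 abs(mu_v - mu_p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$plate_id, unique(plates$plate_id))), , drop = FALSE]
}

#' Collect per-compound concentration-response series from normalized plates
#'
#' Reshapes normalized plate tables into the long fitting schema, one row
#' per compound well and readout (`activity` from the reporter channel,
#' `viability` from the counter-screen channel).
#'
#' @param plates normalized (and typically pattern-corrected) plate table.
#' @return Data frame `compound_id`, `readout`, `concentration_um`,
#'   `percent_activity`, sorted by compound and increasing concentration.
#' @export
screen_responses <- function(plates) {
  cw <- plates[plates$role == "compound" & !is.na(plates$compound_id), ,
               drop = FALSE]
  act <- data.frame(compound_id = cw$compound_id, readout = "activity",
                    concentration_um = cw$concentration_um,
                    percent_activity = cw$pct_activity,
                    stringsAsFactors = FALSE)
  via <- data.frame(compound_id = cw$compound_id, readout = "viability",
                    concentration_um = cw$concentration_um,
                    percent_activity = cw$pct_viability,
                    stringsAsFactors = FALSE)
  out <- rbind(act, via)
  out <- out[!is.na(out$percent_activity), , drop = FALSE]
  out <- out[order(out$compound_id, out$readout, out$concentration_um), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen-wide noise band from vehicle wells
#'
#' Three robust SDs of the normalized vehicle-well activity, the band
#' outside which a response point counts as real signal during curve
#' classification.
#'
#' @param plates normalized plate table.
#' @return Noise band in percent-activity units.
#' @export
noise_band <- function(plates) {
  v <- plates$pct_activity[plates$role == "vehicle_control"]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("no vehicle wells to estimate the noise band")
  3 * stats::sd(v)
}
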