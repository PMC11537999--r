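#' Run the full primary-screen analysis
#'
#' Chains every stage applied to a raw plate stack: per-plate
#' normalization, background pattern correction against the DMSO-only
#' plates (any plate containing no compound wells is treated as DMSO-only),
#' noise-band estimation from vehicle wells, Hill fitting of both readouts,
#' and curve classification / activity calling with the cytotoxicity
#' counter-screen.
#'
#' @param plates raw plate table in the [generate_screen()] schema.
#' @param band optional noise band override (percent activity); default is
#'   estimated from the corrected vehicle wells via [noise_band()].
#' @param ... passed to [call_compounds()].
#' @return List: `qc` (per-plate [plate_qc()] table for the compound
#'   plates), `noise_band`, `responses`, `fits`, `calls`.
#' @examples
#' scr <- generate_screen(screen_config(n_compounds = 40, rng_seed = 2))
#' res <- screen_pipeline(scr$plates)
#' table(res$calls$outcome)
#' @export
screen_pipeline <- function(plates, band = NULL, ...) {
  has_compounds <- tapply(plates$role == "compound", plates$plate_id, any)
  dmso_ids <- names(has_compounds)[!has_compounds]
  comp_ids <- names(has_compounds)[has_compounds]
  if (length(comp_ids) == 0L) stop("no compound plates in the stack")

  norm <- normalize_plates(plates)
  comp <- norm[norm$plate_id %in% comp_ids, , drop = FALSE]
  if (length(dmso_ids) > 0L) {
    dmso <- norm[norm$plate_id %in% dmso_ids, , drop = FALSE]
    comp <- pattern_correct(comp, dmso)
  }
  if (is.null(band)) band <- noise_band(comp)

  responses <- screen_responses(comp)
  fits <- fit_screen(responses, noise_band = band)
  calls <- call_compounds(responses, fits, band, ...)
  qc <- plate_qc(plates[plates$plate_id %in% comp_ids, , drop = FALSE])
  list(qc = qc, noise_band = band, responses = responses, fits = fits,
       calls = calls)
}
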