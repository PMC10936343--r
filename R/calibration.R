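#' Compute the instrument calibration from a reference stack
#'
#' A reference standard of known single-exponential lifetime (fluorescein,
#' 4.04 ns at pH 9, or an SHG signal, 0 ns) is measured with the same
#' acquisition settings as the data. Its aggregate phasor (the transform of
#' the summed decay of all admitted pixels) is compared with the theoretical
#' phasor of the known lifetime:
#' \deqn{\Delta\phi = \phi_{meas} - \phi_{theory}, \qquad
#'       M = m_{theory} / m_{meas}.}
#' Applying the resulting transform to the reference's own aggregate phasor
#' reproduces the theoretical point exactly; applied to data it removes the
#' instrument phase delay and modulation loss.
#'
#' @param ref_stack A [flim_stack()] of the reference standard.
#' @param reference_lifetime_ns Known lifetime of the standard in ns (>= 0).
#' @param params [acquisition_params()] shared by reference and data.
#' @param min_intensity Pixels with fewer total counts are excluded from the
#'   aggregate (default 0: all pixels with any photons are admitted).
#' @return Object of class `phasor_calibration` with fields
#'   `phase_offset_rad`, `modulation_factor`, `harmonic`,
#'   `reference_lifetime_ns` and `params`.
#' @export
compute_calibration <- function(ref_stack, reference_lifetime_ns, params,
                                min_intensity = 0) {
  stopifnot(inherits(ref_stack, "flim_stack"),
            inherits(params, "acquisition_params"),
            is.numeric(reference_lifetime_ns),
            length(reference_lifetime_ns) == 1L)
  if (reference_lifetime_ns < 0)
    stop("reference lifetime must be non-negative")
  field <- phasor_transform(ref_stack, params)
  keep <- field$intensity >= min_intensity & field$intensity > 0
  if (!any(keep))
    stop("no reference pixels above the intensity threshold")
  mask <- flim_mask(keep, list(list(criterion = "calibration intensity",
                                    lo = min_intensity, hi = Inf)))
  agg <- aggregate_phasor(field, mask)
  if (agg$m == 0)
    stop("reference aggregate phasor has zero modulation")
  th <- theoretical_phasor(reference_lifetime_ns, params)
  phi_th <- atan2(th$s, th$g)
  m_th <- sqrt(th$g^2 + th$s^2)
  structure(list(phase_offset_rad = agg$phi - phi_th,
                 modulation_factor = m_th / agg$m,
                 harmonic = params$harmonic,
                 reference_lifetime_ns = reference_lifetime_ns,
                 params = params),
            class = "phasor_calibration")
}

#' Construct a calibration transform from explicit corrections
#'
#' @param phase_offset_rad Instrument phase offset in radians (subtracted
#'   from measured phases).
#' @param modulation_factor Instrument modulation correction (> 0; measured
#'   modulations are multiplied by it).
#' @param harmonic Harmonic the correction was determined at.
#' @param reference_lifetime_ns Lifetime of the standard it derives from
#'   (NA if entered manually).
#' @return A `phasor_calibration`.
#' @export
phasor_calibration <- function(phase_offset_rad, modulation_factor,
                               harmonic = 1L,
                               reference_lifetime_ns = NA_real_) {
  stopifnot(is.numeric(phase_offset_rad), is.numeric(modulation_factor))
  if (modulation_factor <= 0)
    stop("modulation_factor must be positive")
  structure(list(phase_offset_rad = phase_offset_rad,
                 modulation_factor = modulation_factor,
                 harmonic = as.integer(harmonic),
                 reference_lifetime_ns = reference_lifetime_ns,
                 params = NULL),
            class = "phasor_calibration")
}

#' Apply an instrument calibration to a phasor field
#'
#' Per pixel, the phase is shifted and the modulation rescaled:
#' `phi' = phi - phase_offset`, `m' = m * modulation_factor`, then `(g, s)`
#' are recomposed. This is a single complex multiplication, so it is linear
#' in `(g, s)` and preserves mixture linearity. Intensity is untouched.
#' A field can only be calibrated once, and only with a calibration computed
#' at the same harmonic.
#'
#' @param field An uncalibrated `phasor_field`.
#' @param calib A `phasor_calibration`.
#' @return The calibrated `phasor_field`.
#' @export
apply_calibration <- function(field, calib) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(calib, "phasor_calibration"))
  if (field$calibrated)
    stop("field is already calibrated")
  if (calib$harmonic != field$params$harmonic)
    stop(sprintf("calibration harmonic (%d) does not match field harmonic (%d)",
                 calib$harmonic, field$params$harmonic))
  pm <- phase_modulation(field)
  phi <- pm$phi - calib$phase_offset_rad
  m <- pm$m * calib$modulation_factor
  g <- m * cos(phi)
  s <- m * sin(phi)
  new_phasor_field(g = g, s = s, intensity = field$intensity,
                   params = field$params, calibrated = TRUE,
                   median_passes = field$median_passes,
                   unfiltered_g = g, unfiltered_s = s,
                   provenance = c(field$provenance, sprintf(
                     "calibration applied: phase offset %.6g rad, modulation factor %.6g (reference %.4g ns, harmonic %d)",
                     calib$phase_offset_rad, calib$modulation_factor,
                     calib$reference_lifetime_ns, calib$harmonic)))
}

#' Save a calibration record as JSON
#'
#' @param calib A `phasor_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "phasor_calibration"))
  rec <- list(phase_offset_rad = calib$phase_offset_rad,
              modulation_factor = calib$modulation_factor,
              harmonic = calib$harmonic,
              reference_lifetime_ns = calib$reference_lifetime_ns)
  if (!is.null(calib$params))
    rec$acquisition <- list(rep_rate_mhz = calib$params$rep_rate_mhz,
                            n_bins = calib$params$n_bins,
                            bin_width_ns = calib$params$bin_width_ns,
                            harmonic = calib$params$harmonic)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calibration record from JSON
#'
#' @param path Path written by [write_calibration()].
#' @return A `phasor_calibration`.
#' @export
read_calibration <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  calib <- phasor_calibration(
    phase_offset_rad = rec$phase_offset_rad,
    modulation_factor = rec$modulation_factor,
    harmonic = rec$harmonic,
    reference_lifetime_ns = if (is.null(rec$reference_lifetime_ns))
      NA_real_ else rec$reference_lifetime_ns)
  if (!is.null(rec$acquisition))
    calib$params <- acquisition_params(rec$acquisition$rep_rate_mhz,
                                       rec$acquisition$n_bins,
                                       rec$acquisition$bin_width_ns,
                                       rec$acquisition$harmonic)
  calib
}

#' @export
print.phasor_calibration <- function(x, ...) {
  cat(sprintf(
    "Phasor calibration (harmonic %d): phase offset %.6g rad, modulation factor %.6g\n",
    x$harmonic, x$phase_offset_rad, x$modulation_factor))
  if (is.finite(x$reference_lifetime_ns))
    cat(sprintf("  reference standard lifetime: %.4g ns\n",
                x$reference_lifetime_ns))
  invisible(x)
}
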