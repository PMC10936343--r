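#' Per-pixel phasor transform of a FLIM stack
#'
#' For each pixel the decay histogram `I(t_k)` is projected on the first
#' Fourier harmonic at `omega = 2 * pi * n * f`:
#' \deqn{g = \frac{\sum_k I_k \cos(\omega t_k)}{\sum_k I_k}, \qquad
#'       s = \frac{\sum_k I_k \sin(\omega t_k)}{\sum_k I_k}}
#' with left-edge bin times `t_k = k * bin_width_ns`. Pixels with zero total
#' intensity have undefined coordinates (NaN). The result is uncalibrated:
#' the instrument phase offset and modulation loss are removed later by
#' [apply_calibration()].
#'
#' @param stack A [flim_stack()].
#' @param params An [acquisition_params()] object; its `n_bins` must match
#'   the stack's third dimension.
#' @return An object of class `phasor_field` with components `g`, `s`,
#'   `intensity` (matrices), `params`, `calibrated`, `median_passes`,
#'   pristine copies `unfiltered_g`/`unfiltered_s`, and a `provenance`
#'   character vector.
#' @seealso [theoretical_phasor()], [phase_modulation()], [lifetime_maps()]
#' @export
phasor_transform <- function(stack, params) {
  stopifnot(inherits(stack, "flim_stack"), inherits(params, "acquisition_params"))
  d <- dim(stack$counts)
  if (d[3] != params$n_bins)
    stop(sprintf("stack has %d temporal bins but params declare %d",
                 d[3], params$n_bins))
  w <- omega(params)
  tk <- bin_times(params)
  M <- matrix(stack$counts, nrow = d[1] * d[2], ncol = d[3])
  intensity <- rowSums(M)
  if (all(intensity == 0))
    warning("stack contains no photons; every phasor is undefined")
  g <- as.vector(M %*% cos(w * tk)) / intensity
  s <- as.vector(M %*% sin(w * tk)) / intensity
  g[intensity == 0] <- NaN
  s[intensity == 0] <- NaN

  new_phasor_field(g = matrix(g, d[1], d[2]),
                   s = matrix(s, d[1], d[2]),
                   intensity = matrix(intensity, d[1], d[2]),
                   params = params,
                   provenance = sprintf(
                     "phasor transform of %s at harmonic %d (omega = %.6g rad/ns)",
                     stack$source_path, params$harmonic, w))
}

#' Construct a phasor field from explicit coordinate grids
#'
#' Low-level constructor used by the transform, by tests, and wherever a
#' phasor location is given directly (e.g. published coordinates) rather
#' than computed from a decay.
#'
#' @param g,s Numeric matrices of phasor coordinates (NaN where undefined).
#' @param intensity Numeric matrix of total counts per pixel; defaults to 1
#'   everywhere.
#' @param params An [acquisition_params()] object.
#' @param calibrated Logical; whether the coordinates are already referenced
#'   to the instrument calibration.
#' @param provenance Character vector of log lines.
#' @return A `phasor_field`.
#' @export
phasor_field <- function(g, s, intensity = NULL, params,
                         calibrated = FALSE, provenance = character()) {
  g <- as.matrix(g); s <- as.matrix(s)
  if (is.null(intensity)) intensity <- matrix(1, nrow(g), ncol(g))
  intensity <- as.matrix(intensity)
  new_phasor_field(g, s, intensity, params,
                   calibrated = calibrated, provenance = provenance)
}

new_phasor_field <- function(g, s, intensity, params, calibrated = FALSE,
                             median_passes = 0L, unfiltered_g = g,
                             unfiltered_s = s, provenance = character()) {
  stopifnot(identical(dim(g), dim(s)), identical(dim(g), dim(intensity)),
            inherits(params, "acquisition_params"))
  structure(list(g = g, s = s, intensity = intensity, params = params,
                 calibrated = isTRUE(calibrated),
                 median_passes = as.integer(median_passes),
                 unfiltered_g = unfiltered_g, unfiltered_s = unfiltered_s,
                 provenance = provenance),
            class = "phasor_field")
}

#' Phase and modulation representation of a phasor field
#'
#' The polar form of the phasor: `phi = atan2(s, g)` is the phase lag of the
#' emission with respect to the excitation and `m = sqrt(g^2 + s^2)` its
#' demodulation. Undefined pixels stay NaN.
#'
#' @param field A `phasor_field`.
#' @return List with matrices `phi` (radians) and `m` (dimensionless).
#' @export
phase_modulation <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  list(phi = atan2(field$s, field$g),
       m = sqrt(field$g^2 + field$s^2))
}

#' Theoretical phasor of a single-exponential decay
#'
#' For `I(t) = exp(-t / tau)` the phasor at angular frequency `omega` is
#' \deqn{g = \frac{1}{1 + (\omega\tau)^2}, \qquad
#'       s = \frac{\omega\tau}{1 + (\omega\tau)^2},}
#' which lies on the universal semicircle of radius 1/2 centred at (1/2, 0):
#' `tau = 0` maps to (1, 0) and `tau -> Inf` approaches (0, 0).
#'
#' @param tau_ns Lifetime(s) in ns, finite and non-negative (vectorised).
#' @param params An [acquisition_params()] object.
#' @return List with numeric vectors `g` and `s`.
#' @export
theoretical_phasor <- function(tau_ns, params) {
  stopifnot(is.numeric(tau_ns), all(is.finite(tau_ns)))
  if (any(tau_ns < 0)) stop("lifetime must be non-negative")
  wt <- omega(params) * tau_ns
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Intensity-weighted aggregate phasor of a field
#'
#' Equivalent to transforming the summed decay of the selected pixels: the
#' per-pixel phasors averaged with their total counts as weights. This is
#' the aggregation used for calibration, where it is the noise-optimal
#' combination for Poisson counting statistics.
#'
#' @param field A `phasor_field`.
#' @param mask Optional [flim_mask()] restricting the pixels.
#' @return List with scalars `g`, `s`, `phi`, `m`, `intensity` (total counts)
#'   and `n_pixels`.
#' @export
aggregate_phasor <- function(field, mask = NULL) {
  stopifnot(inherits(field, "phasor_field"))
  keep <- !is.na(field$g) & !is.na(field$s)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "flim_mask"),
              identical(dim(mask$include), dim(field$g)))
    keep <- keep & mask$include
  }
  wsum <- sum(field$intensity[keep])
  if (sum(keep) == 0L || wsum == 0)
    stop("no defined pixels with nonzero intensity to aggregate")
  g <- sum(field$g[keep] * field$intensity[keep]) / wsum
  s <- sum(field$s[keep] * field$intensity[keep]) / wsum
  list(g = g, s = s, phi = atan2(s, g), m = sqrt(g^2 + s^2),
       intensity = wsum, n_pixels = sum(keep))
}

#' Phase and modulation lifetime maps
#'
#' Per-pixel lifetime estimates from a calibrated phasor field:
#' \deqn{\tau_\phi = \tan(\phi)/\omega, \qquad
#'       \tau_M = \frac{1}{\omega}\sqrt{1/m^2 - 1}.}
#' Both invert the single-exponential model, so on the universal semicircle
#' they agree; for multi-exponential pixels (inside the circle) `tau_M >
#' tau_phi`. Out-of-range pixels produced by noise are flagged undefined:
#' `phi < 0` or `phi >= pi/2` gives NaN `tau_phi` (except `phi == 0`, which
#' is exactly 0 ns); `m > 1` gives NaN `tau_M`; `m == 0` gives NaN for both.
#'
#' @param field A calibrated `phasor_field`.
#' @return Object of class `lifetime_maps`: list of matrices `taup_ns`,
#'   `taum_ns`.
#' @export
lifetime_maps <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  if (!field$calibrated)
    stop("lifetime maps require a calibrated phasor field")
  w <- omega(field$params)
  pm <- phase_modulation(field)

  taup <- tan(pm$phi) / w
  taup[pm$phi < 0 | pm$phi >= pi / 2] <- NaN
  taup[pm$phi == 0] <- 0
  taup[pm$m == 0] <- NaN

  taum <- sqrt(pmax(1 / pm$m^2 - 1, 0)) / w
  taum[pm$m > 1 | pm$m == 0] <- NaN

  structure(list(taup_ns = taup, taum_ns = taum), class = "lifetime_maps")
}

defined_pixels <- function(field) !is.na(field$g) & !is.na(field$s)

#' @export
print.phasor_field <- function(x, ...) {
  d <- dim(x$g)
  nd <- sum(defined_pixels(x))
  cat(sprintf("Phasor field %d x %d (%d defined pixels), harmonic %d, %s\n",
              d[1], d[2], nd, x$params$harmonic,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  if (x$median_passes > 0)
    cat(sprintf("  median filter: %d pass(es) applied (reversible)\n",
                x$median_passes))
  if (nd > 0) {
    a <- aggregate_phasor(x)
    cat(sprintf("  aggregate phasor: g = %.4f, s = %.4f (phi = %.4f rad, m = %.4f)\n",
                a$g, a$s, a$phi, a$m))
  }
  invisible(x)
}

#' @export
summary.phasor_field <- function(object, ...) {
  a <- aggregate_phasor(object)
  out <- list(dim = dim(object$g), n_defined = sum(defined_pixels(object)),
              aggregate = a, calibrated = object$calibrated,
              median_passes = object$median_passes,
              provenance = object$provenance)
  class(out) <- "summary.phasor_field"
  out
}

#' @export
print.summary.phasor_field <- function(x, ...) {
  cat(sprintf("Phasor field %d x %d, %d defined pixels, %s, %d median pass(es)\n",
              x$dim[1], x$dim[2], x$n_defined,
              if (x$calibrated) "calibrated" else "uncalibrated",
              x$median_passes))
  cat(sprintf("  aggregate: g = %.4f, s = %.4f, phi = %.4f rad, m = %.4f\n",
              x$aggregate$g, x$aggregate$s, x$aggregate$phi, x$aggregate$m))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (line in x$provenance) cat("   -", line, "\n")
  }
  invisible(x)
}

#' Plot a phasor field as a density histogram on the universal circle
#'
#' Convenience method: bins the field with [phasor_histogram()] and draws it
#' on the current device with the universal semicircle overlaid.
#'
#' @param x A `phasor_field`.
#' @param bins Number of histogram bins per axis.
#' @param ... Passed to [draw_phasor_plot()].
#' @export
plot.phasor_field <- function(x, bins = 200L, ...) {
  draw_phasor_plot(phasor_histogram(x, bins = bins), ...)
  invisible(x)
}
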