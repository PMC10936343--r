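#' Acquisition parameters for a time-domain FLIM measurement
#'
#' Bundles the quantities that define the angular frequency of the phasor
#' transform: the laser repetition rate, the number of temporal bins, the
#' bin width and the harmonic. The laser period is `T = 1/f`; for a complete,
#' untruncated acquisition it should equal `n_bins * bin_width_ns`. A relative
#' disagreement larger than 0.1% triggers a warning (the supplied bin width
#' is still used, so stacks recorded over a partial period can be processed
#' deliberately).
#'
#' @param rep_rate_mhz Laser repetition rate in MHz (e.g. 80).
#' @param n_bins Number of temporal bins per pixel (at least 2).
#' @param bin_width_ns Temporal bin width in ns. Defaults to
#'   `1000 / (rep_rate_mhz * n_bins)`, i.e. the laser period divided evenly
#'   over the bins.
#' @param harmonic Positive integer harmonic of the repetition rate at which
#'   the transform is evaluated. Default 1.
#' @return An object of class `acquisition_params`.
#' @examples
#' p <- acquisition_params(80, 56)
#' omega(p)  # rad/ns
#' @export
acquisition_params <- function(rep_rate_mhz, n_bins,
                               bin_width_ns = 1000 / (rep_rate_mhz * n_bins),
                               harmonic = 1L) {
  stopifnot(is.numeric(rep_rate_mhz), length(rep_rate_mhz) == 1L,
            is.finite(rep_rate_mhz), rep_rate_mhz > 0)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("n_bins must be an integer >= 2")
  stopifnot(is.numeric(bin_width_ns), length(bin_width_ns) == 1L,
            is.finite(bin_width_ns), bin_width_ns > 0)
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L)
    stop("harmonic must be a positive integer")

  period_ns <- 1000 / rep_rate_mhz
  if (abs(period_ns - n_bins * bin_width_ns) / period_ns > 1e-3)
    warning(sprintf(paste0(
      "laser period (%.6g ns) differs from n_bins * bin_width_ns (%.6g ns) ",
      "by more than 0.1%%; proceeding with the supplied bin width"),
      period_ns, n_bins * bin_width_ns))

  structure(list(rep_rate_mhz = rep_rate_mhz,
                 n_bins = n_bins,
                 bin_width_ns = bin_width_ns,
                 harmonic = harmonic),
            class = "acquisition_params")
}

#' Angular frequency of the phasor transform
#'
#' `omega = 2 * pi * harmonic * f` with `f` in GHz, so the result is in
#' rad/ns and lifetimes computed from it come out in ns.
#'
#' @param params An [acquisition_params()] object.
#' @return Angular frequency in rad/ns.
#' @export
omega <- function(params) {
  stopifnot(inherits(params, "acquisition_params"))
  2 * pi * params$harmonic * params$rep_rate_mhz / 1000
}

#' Temporal bin coordinates
#'
#' Left-edge times `t_k = k * bin_width_ns`, `k = 0 .. n_bins - 1`. Any
#' constant time offset is absorbed by the calibration phase offset; the
#' left-edge choice places an instantaneous (delta) decay exactly at
#' phasor (1, 0) before calibration.
#'
#' @param params An [acquisition_params()] object.
#' @return Numeric vector of bin start times in ns.
#' @keywords internal
bin_times <- function(params) {
  (seq_len(params$n_bins) - 1) * params$bin_width_ns
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "FLIM acquisition: %g MHz, %d bins x %.5g ns, harmonic %d (omega = %.5g rad/ns)\n",
    x$rep_rate_mhz, x$n_bins, x$bin_width_ns, x$harmonic, omega(x)))
  invisible(x)
}
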