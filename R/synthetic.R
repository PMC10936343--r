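#' Ground truth for a synthetic FLIM acquisition
#'
#' Describes the decay composition, photon budget and instrument distortion
#' from which [simulate_stack()] generates a stack. Emulates the acquisition
#' regime of a two-photon TCSPC microscope: 80 MHz repetition rate, ~56
#' temporal bins and a few hundred photons per pixel are typical defaults
#' elsewhere in the package.
#'
#' @param components Decay composition: a data frame (or 2-column matrix)
#'   with columns `tau_ns` and `fraction` (intensity fractions summing to 1),
#'   or a list of such tables with `region` assigning one table per pixel.
#' @param photons_per_pixel Expected total counts per pixel (> 0).
#' @param instrument_phase_rad Phase distortion applied by the virtual
#'   instrument at the analysis harmonic (radians).
#' @param instrument_modulation Modulation gain of the virtual instrument
#'   (0 < gain, typically <= 1).
#' @param poisson Draw per-pixel Poisson counts (`TRUE`) or return noiseless
#'   expected histograms (`FALSE`).
#' @param seed Integer seed controlling all randomness of the simulation.
#' @param region Optional integer matrix (same shape as the simulated image)
#'   indexing into `components` when it is a list; defaults to one region.
#' @return Object of class `flim_ground_truth`.
#' @export
ground_truth <- function(components, photons_per_pixel = 500,
                         instrument_phase_rad = 0,
                         instrument_modulation = 1,
                         poisson = TRUE, seed = 1L, region = NULL) {
  if (!is.list(components) || is.data.frame(components))
    components <- list(components)
  components <- lapply(components, as_components)
  stopifnot(photons_per_pixel > 0, instrument_modulation > 0)
  structure(list(components = components,
                 photons_per_pixel = photons_per_pixel,
                 instrument_phase_rad = instrument_phase_rad,
                 instrument_modulation = instrument_modulation,
                 poisson = isTRUE(poisson), seed = as.integer(seed),
                 region = region),
            class = "flim_ground_truth")
}

as_components <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("tau_ns", "fraction") %in% names(x)))
    stop("components need columns tau_ns and fraction")
  if (any(x$tau_ns < 0)) stop("lifetimes must be non-negative")
  if (any(x$fraction < 0)) stop("fractions must be non-negative")
  if (abs(sum(x$fraction) - 1) > 1e-9)
    stop("intensity fractions must sum to 1")
  x
}

#' Expected decay histogram of a (multi-)exponential mixture
#'
#' Bin `k` collects the exact integral of each exponential component over
#' `[t_k, t_{k+1})`, weighted by its intensity fraction and normalised so
#' the bins sum to `photons`; this is how TCSPC bins accumulate counts and,
#' for the phasor transform, is exactly equivalent to geometric point
#' sampling. A zero lifetime puts all counts in bin 0; a lifetime much
#' longer than the period tends to a uniform histogram. Periodic
#' re-excitation only rescales the single-period exponential, so no
#' wrap-around term is needed.
#'
#' @param components Data frame with columns `tau_ns` and `fraction`
#'   (fractions sum to 1).
#' @param params An [acquisition_params()] object.
#' @param photons Expected total counts.
#' @return Numeric vector of `n_bins` expected counts.
#' @export
simulate_decay <- function(components, params, photons) {
  components <- as_components(components)
  stopifnot(inherits(params, "acquisition_params"), photons > 0)
  N <- params$n_bins
  dt <- params$bin_width_ns
  tk <- bin_times(params)
  h <- numeric(N)
  for (i in seq_len(nrow(components))) {
    tau <- components$tau_ns[i]
    if (tau == 0) {
      comp <- c(1, numeric(N - 1L))
    } else {
      # exact bin integrals of exp(-t/tau): proportional to r^k with
      # r = exp(-dt/tau); expm1 keeps the long-lifetime limit accurate
      comp <- exp(-tk / tau) * (-expm1(-dt / tau))
      comp <- comp / sum(comp)
    }
    h <- h + components$fraction[i] * comp
  }
  h * photons
}

# Distort a histogram so that its phasor at the analysis harmonic is
# multiplied by exactly gain * exp(1i * phase_rad). The phase is realised as
# a convex mix of two integer circular shifts (a linear-interpolation shift
# whose mixing weight is solved so the added phase is exact); the residual
# modulation of that mix and the requested gain are then set by mixing with
# (or subtracting) a uniform histogram, which has zero phasor at any nonzero
# harmonic. Gains above the attainable headroom of the decay shape raise an
# error.
distort_histogram <- function(h, phase_rad, gain, harmonic) {
  N <- length(h)
  if (phase_rad == 0 && gain == 1) return(h)
  theta <- 2 * pi * harmonic / N
  ph <- phase_rad %% (2 * pi)
  j <- floor(ph / theta)
  rem <- ph - j * theta
  rot <- function(x, by) {
    by <- by %% N
    if (by == 0) x else c(x[(N - by + 1L):N], x[1:(N - by)])
  }
  if (rem == 0) {
    shifted <- rot(h, j)
    rho <- 1
  } else {
    tr <- tan(rem)
    alpha <- (sin(theta) - tr * cos(theta)) /
      (tr + sin(theta) - tr * cos(theta))
    shifted <- alpha * rot(h, j) + (1 - alpha) * rot(h, j + 1L)
    rho <- Mod(alpha + (1 - alpha) * exp(1i * theta))
  }
  lambda <- gain / rho
  out <- lambda * shifted + (1 - lambda) * (sum(h) / N)
  if (any(out < 0))
    stop(sprintf(
      "modulation gain %.4g is not realizable for this decay shape", gain))
  out
}

#' Simulate a FLIM stack with known ground truth
#'
#' Builds the expected histogram of every pixel from the ground truth,
#' applies the instrument distortion (a phase offset and modulation gain at
#' the analysis harmonic, exactly the model a reference calibration can
#' invert), and draws per-pixel Poisson counts around it (or returns the
#' noiseless expectations). Fully deterministic given the truth's seed.
#'
#' @param truth A [ground_truth()] record.
#' @param shape `c(rows, cols)` of the simulated image.
#' @param params An [acquisition_params()] object.
#' @return A [flim_stack()]; the generating `truth` is attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_stack <- function(truth, shape, params) {
  stopifnot(inherits(truth, "flim_ground_truth"),
            inherits(params, "acquisition_params"),
            length(shape) == 2L, all(shape >= 1))
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  region <- truth$region
  if (is.null(region)) region <- matrix(1L, rows, cols)
  stopifnot(identical(dim(region), c(rows, cols)),
            all(region %in% seq_along(truth$components)))

  expected <- lapply(truth$components, function(comp) {
    distort_histogram(
      simulate_decay(comp, params, truth$photons_per_pixel),
      truth$instrument_phase_rad, truth$instrument_modulation,
      params$harmonic)
  })

  counts <- array(0, dim = c(rows, cols, params$n_bins))
  if (truth$poisson) {
    set.seed(truth$seed)
    for (reg in seq_along(expected)) {
      npix <- sum(region == reg)
      if (npix == 0L) next
      draws <- matrix(stats::rpois(npix * params$n_bins,
                                   rep(expected[[reg]], each = npix)),
                      nrow = npix)
      for (k in seq_len(params$n_bins)) {
        slab <- counts[, , k]
        slab[region == reg] <- draws[, k]
        counts[, , k] <- slab
      }
    }
  } else {
    for (reg in seq_along(expected)) {
      for (k in seq_len(params$n_bins)) {
        slab <- counts[, , k]
        slab[region == reg] <- expected[[reg]][k]
        counts[, , k] <- slab
      }
    }
  }
  out <- flim_stack(counts, source_path = sprintf(
    "<synthetic seed %d%s>", truth$seed,
    if (truth$poisson) "" else ", noiseless"))
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate a spatially uniform reference (calibration standard) stack
#'
#' A single-lifetime stack, by default noiseless (a calibration standard is
#' measured at high signal-to-noise), carrying the same instrument
#' distortion model as the data it will calibrate.
#'
#' @param tau_ref_ns Reference lifetime in ns (0 for an SHG-style
#'   instantaneous standard).
#' @param params An [acquisition_params()] object.
#' @param shape Image shape, default 16 x 16.
#' @param photons_per_pixel Expected counts per pixel.
#' @param instrument_phase_rad,instrument_modulation Instrument distortion,
#'   as in [ground_truth()].
#' @param poisson Add Poisson noise? Default `FALSE`.
#' @param seed Seed when `poisson = TRUE`.
#' @return A [flim_stack()].
#' @export
make_reference_stack <- function(tau_ref_ns, params, shape = c(16L, 16L),
                                 photons_per_pixel = 10000,
                                 instrument_phase_rad = 0,
                                 instrument_modulation = 1,
                                 poisson = FALSE, seed = 1L) {
  stopifnot(tau_ref_ns >= 0)
  truth <- ground_truth(data.frame(tau_ns = tau_ref_ns, fraction = 1),
                        photons_per_pixel = photons_per_pixel,
                        instrument_phase_rad = instrument_phase_rad,
                        instrument_modulation = instrument_modulation,
                        poisson = poisson, seed = seed)
  simulate_stack(truth, shape, params)
}
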