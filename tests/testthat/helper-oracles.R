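# Shared fixtures and independent oracles.
#
# The phasor oracle is the closed geometric-series form for the DFT of a
# sampled exponential: with r = exp(-dt/tau) and theta = 2*pi*n/N (one full
# period split into N bins), the normalised phasor is (1-r)/(1-r*e^{i theta}).
# It is evaluated directly from complex arithmetic, independently of the
# package's sum-based transform.

std_params <- function(n_bins = 56L, harmonic = 1L, rep_rate_mhz = 80)
  acquisition_params(rep_rate_mhz, n_bins, harmonic = harmonic)

oracle_sampled_phasor <- function(tau_ns, n_bins, harmonic = 1L,
                                  rep_rate_mhz = 80) {
  if (tau_ns == 0) return(complex(real = 1, imaginary = 0))
  dt <- 1000 / (rep_rate_mhz * n_bins)
  r <- exp(-dt / tau_ns)
  (1 - r) / (1 - r * exp(1i * 2 * pi * harmonic / n_bins))
}

oracle_theoretical <- function(tau_ns, harmonic = 1L, rep_rate_mhz = 80) {
  w <- 2 * pi * harmonic * rep_rate_mhz / 1000
  complex(real = 1 / (1 + (w * tau_ns)^2),
          imaginary = w * tau_ns / (1 + (w * tau_ns)^2))
}

# calibration constants a noiseless reference should produce
oracle_calibration <- function(tau_ref, n_bins = 56L, harmonic = 1L) {
  zm <- oracle_sampled_phasor(tau_ref, n_bins, harmonic)
  zt <- oracle_theoretical(tau_ref, harmonic)
  list(offset = Arg(zm) - Arg(zt), factor = Mod(zt) / Mod(zm))
}

# brute-force NaN-aware 3x3 median with symmetric edge padding, written as
# plain per-pixel loops so it shares no code with the vectorised filter
brute_median3x3 <- function(x) {
  r <- nrow(x); cc <- ncol(x)
  out <- matrix(NaN, r, cc)
  clamp <- function(i, n) min(max(i, 1L), n)
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    if (is.na(x[i, j])) next
    win <- numeric(0)
    for (di in -1:1) for (dj in -1:1)
      win <- c(win, x[clamp(i + di, r), clamp(j + dj, cc)])
    win <- win[!is.na(win)]
    out[i, j] <- stats::median(win)
  }
  out
}

# stack with a single shared decay histogram in every pixel
uniform_stack <- function(hist, rows = 4L, cols = 4L) {
  flim_stack(array(rep(hist, each = rows * cols),
                   dim = c(rows, cols, length(hist))))
}

noiseless_stack <- function(tau_ns, params, shape = c(8L, 8L),
                            photons = 500) {
  simulate_stack(
    ground_truth(data.frame(tau_ns = tau_ns, fraction = 1),
                 photons_per_pixel = photons, poisson = FALSE),
    shape, params)
}
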