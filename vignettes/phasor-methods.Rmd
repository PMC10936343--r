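---
title: "Phasor analysis of time-domain FLIM: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor analysis of time-domain FLIM: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimphasor)
```

## The model

Time-domain FLIM records, for every pixel of an image, a histogram of photon
arrival times over one period `T = 1/f` of a pulsed laser with repetition
rate `f`. Rather than fitting exponentials pixel by pixel, the phasor
approach projects each histogram onto a single Fourier harmonic at
`omega = 2 pi n f` (harmonic `n`, `f` in GHz so `omega` is in rad/ns):

    g = sum_k I_k cos(omega t_k) / sum_k I_k
    s = sum_k I_k sin(omega t_k) / sum_k I_k

The pair `(g, s)` is the pixel's *phasor*; its polar form is the phase
`phi = atan2(s, g)` and modulation `m = sqrt(g^2 + s^2)`. For a
single-exponential decay with lifetime `tau`,

    g = 1 / (1 + (omega tau)^2),   s = omega tau / (1 + (omega tau)^2),

which traces the *universal semicircle* of radius 1/2 centred at (1/2, 0):
`tau = 0` sits at (1, 0), `tau -> Inf` approaches (0, 0), and every
multi-exponential decay falls strictly inside, at the intensity-weighted
average of its components' phasors. That linearity is the workhorse of the
whole method: mixtures of two species lie on the chord between the species'
phasors, and the fractional distance along the chord is the intensity
fraction of each species.

Two per-pixel lifetime estimates invert the single-exponential model:

    tau_phi = tan(phi) / omega
    tau_M   = sqrt(1/m^2 - 1) / omega

They agree on the semicircle; `tau_M > tau_phi` flags multi-exponential
pixels.

## Calibration

The instrument response delays and demodulates every decay, so raw phasors
are rotated and shrunk by an unknown factor. A reference standard with known
single-exponential lifetime (fluorescein, 4.04 ns at pH 9, or a
second-harmonic-generation signal, which is instantaneous and treated as
0 ns) is measured with the same settings; comparing its measured aggregate
phasor with the theoretical point on the semicircle gives a phase offset
`dphi = phi_meas - phi_theory` and a modulation factor
`M = m_theory / m_meas`. Applying `phi -> phi - dphi`, `m -> m * M` to the
data is one complex multiplication per pixel, hence linear in `(g, s)`:
calibration commutes with mixing and never bends chords.

The reference aggregate is the transform of the *summed* decay of all
admitted pixels — identical to the intensity-weighted mean of their phasors
and the noise-optimal combination for Poisson counts. Calibration is tied to
the harmonic it was computed at; applying it to a field transformed at
another harmonic is refused.

## Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `rep_rate_mhz` | MHz | — | laser repetition rate; sets `T` and `omega` |
| `n_bins` | — | — | temporal bins per pixel (56 is typical of TCSPC cards at 80 MHz) |
| `bin_width_ns` | ns | `1000/(rep_rate_mhz * n_bins)` | bin width; a mismatch with `T/n_bins` beyond 0.1% warns |
| `harmonic` | — | 1 | Fourier harmonic; higher harmonics spread long-lifetime species |
| `min_intensity` | counts | 0 | intensity threshold; dim pixels dominate phasor noise |
| `median_passes` | — | 0 | reversible 3x3 median passes on g/s |

## Numerical choices

* **Bin time origin.** `t_k = k * bin_width_ns` (left edge). The transform
  is invariant to this choice *after* calibration — a constant time shift is
  a constant rotation absorbed into the phase offset — and the left edge
  makes an instantaneous decay land exactly at (1, 0) before calibration,
  which keeps the zero-lifetime anchor test exact.
* **Undefined pixels.** Zero-intensity pixels have NaN phasors and stay NaN
  through every downstream map. Noise can push phasors out of the physical
  range; the lifetime maps flag `phi` outside `[0, pi/2)` and `m > 1` as NaN
  (with `phi == 0` giving exactly 0 ns and `m == 0` undefined for both
  estimates) instead of reporting negative or complex lifetimes.
* **Median filter.** 3x3 window, symmetric edge padding; NaN neighbours are
  excluded from each window and an undefined centre stays undefined.
  Medians are not invertible, so "reversible" is implemented by retaining
  the pristine `g`/`s` grids and restoring them on request; the intensity
  image is never filtered. Filtering is applied to the *calibrated* field;
  the order is recorded in the provenance log.
* **Thresholds** are inclusive at both bounds, so widening a range is
  monotone: it can only add pixels.
* **Fraction maps** report the raw ratio `d_B / |AB|` by default; values
  outside [0, 1] are informative (off-chord pixels) and clipping is an
  explicit switch. Fractions are intensity fractions, not corrected for the
  species' quantum yields.
* **Cursors** are disks in phasor units — a shape-neutral default for
  reciprocity selection.

## The synthetic generator

`simulate_decay()` builds expected histograms from exact bin integrals of
the (periodically re-excited) exponential — the way TCSPC bins accumulate
counts; for the phasor this is exactly equivalent to geometric point
sampling, and the closed form `(1 - r) / (1 - r e^{i 2 pi n / N})` with
`r = exp(-dt/tau)` serves as an independent oracle throughout the tests.
Periodic wrap-around only rescales the single-period histogram, so it drops
out of the normalised phasor and is omitted.

`simulate_stack()` adds two effects:

* **Instrument distortion** — a phase offset and modulation gain at the
  analysis harmonic, i.e. exactly the model the reference calibration can
  invert. It is realised on the histogram itself: the phase by a convex mix
  of two integer circular shifts whose mixing weight is solved so the added
  phase is exact, the gain by mixing with (or subtracting) a uniform
  histogram, which has zero phasor at any nonzero harmonic. Composition is
  therefore exact to machine precision, which is what makes the
  calibration-recovery tests sharp. A full measured-IRF convolution is
  deliberately out of scope: it would introduce distortions outside the
  calibration model and is not needed to validate the pipeline.
* **Poisson noise** — independent per-pixel, per-bin draws around the
  expected histogram, controlled by a single root seed with a fixed draw
  order, so stacks are bit-reproducible.

Defaults mirror a typical two-photon TCSPC acquisition: 80 MHz repetition
rate, 56 bins over one 12.5 ns period, and 400–800 photons per pixel (the
generator default is 500).

What the generator does **not** emulate: detector afterpulsing, dark
counts, pile-up, spatially varying instrument response, and realistic
multi-species spatial textures. Passing tests therefore demonstrate the
correctness of the transform, calibration algebra, filtering and unmixing
arithmetic — not robustness to every artefact of real instruments.

## Validation design and problem sizes

The test suite validates each layer against an independent route: the
geometric-series closed form for the transform (to 1e-12 over lifetimes
0.4–4.04 ns, 16–256 bins, harmonics 1–3), a per-pixel loop implementation
of the 3x3 median, analytic endpoints for masks, distances and fractions,
and generator ground truth for end-to-end recovery. Simulated images are
kept small (1x1 to 64x64 pixels, 20 Poisson seeds where sampling
distributions matter) — large enough for the statistics being checked,
small enough that the full suite runs in seconds.

Two-component fraction recovery is validated with the species endpoints
*measured* from calibrated pure stacks, the same workflow a practitioner
uses when the pure species are available. With endpoints placed from
theoretical lifetimes instead, noiseless recovery is exact only up to the
sampling residual discussed below (~1e-3 in phasor units at 56 bins).

## Known limitations

* **Discretisation bias at short lifetimes.** The DFT phasor of a sampled
  exponential differs from the continuous-model phasor by a factor that
  depends on the lifetime; single-reference calibration removes it exactly
  only at the reference lifetime. With 56 bins and a 4.04 ns reference the
  residual is negligible for `tau_M` (< 0.1% everywhere in 0.4–4.04 ns) but
  biases `tau_phi` by about +2.4% at 0.4 ns, falling below 0.5% from 1 ns
  up — the values the recovery tests measure. Real acquisitions with more
  bins, or a reference lifetime closer to the sample's, shrink it further.
* **Truncated or time-gated acquisitions** (decay not recorded over a full
  period) are not corrected for; the period-consistency warning flags them.
* **Vendor raw formats** (.sdt, .ptu, .fbd) are not parsed; stacks must be
  exported to multi-page TIFF first.
* Exported float maps use a fixed 32-bit little-endian TIFF dialect chosen
  for ImageJ interoperability; no claim is made that other phasor tools
  write byte-identical files.

## Interfaces

All heavy objects are S3-classed (`flim_stack`, `phasor_field`,
`phasor_calibration`, `flim_result`, ...) with `print`/`summary`/`plot`
methods; `flim_analyze()` drives the full pipeline, `flim_batch()` maps it
over file sets, and the `flimphasor` script (under `inst/exec`) exposes
`calibrate` / `analyze` / `batch` subcommands for shell use. In run
configurations and at the command line, the first species listed is the
distance reference (point B); a second species enables fraction maps.
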