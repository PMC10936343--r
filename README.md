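# flimphasor

Fit-free phasor analysis of time-domain fluorescence lifetime imaging
microscopy (FLIM) data, for microscopists and image analysts who have
per-pixel photon-arrival histograms (TCSPC or time-gated, exported as
multi-page TIFF stacks) and want lifetime contrast, metabolic
bound/free-NADH style unmixing and reproducible batch processing without a
GUI and without per-pixel curve fitting.

## The method

Each pixel's decay histogram `I(t_k)` is projected onto one Fourier
harmonic of the laser repetition rate (`omega = 2 pi n f`):

    g = sum_k I_k cos(omega t_k) / sum_k I_k
    s = sum_k I_k sin(omega t_k) / sum_k I_k

Single-exponential decays with lifetime `tau` fall on the universal
semicircle `(g - 1/2)^2 + s^2 = 1/4`:

    g = 1 / (1 + (omega tau)^2),   s = omega tau / (1 + (omega tau)^2)

and mixtures fall inside it, at the intensity-weighted average of their
components. After calibrating phase and modulation against a standard of
known lifetime (fluorescein 4.04 ns, or an SHG signal at 0 ns), per-pixel
lifetimes are estimated from the phase, `tau_phi = tan(phi)/omega`, and the
modulation, `tau_M = sqrt(1/m^2 - 1)/omega`; the Euclidean phasor distance
`d_B` to a molecular species located at `(g_B, s_B)` maps similarity to
that species, and `f_A = d_B / |AB|` unmixes a two-species system. A
reversible 3x3 median filter on g/s, intensity/lifetime/distance
thresholds, cursor (reciprocity) selection, ROI statistics, figure export
and batch processing complete the workflow. A synthetic decay generator
with exact ground truth makes the entire pipeline testable without any
instrument data.

## Worked example

Simulate a calibration standard and a two-component sample (30% of the
intensity from a 0.4 ns species, 70% from 3.2 ns, 500 photons/pixel), then
run the full pipeline:

```r
library(flimphasor)

params <- acquisition_params(rep_rate_mhz = 80, n_bins = 56)

ref   <- make_reference_stack(4.04, params, photons_per_pixel = 800)
calib <- compute_calibration(ref, reference_lifetime_ns = 4.04, params = params)
print(calib)
#> Phasor calibration (harmonic 1): phase offset -0.0555832 rad, modulation factor 0.999476
#>   reference standard lifetime: 4.04 ns

truth <- ground_truth(
  data.frame(tau_ns = c(0.4, 3.2), fraction = c(0.3, 0.7)),
  photons_per_pixel = 500, seed = 42)
stack <- simulate_stack(truth, shape = c(64, 64), params = params)

result <- flim_analyze(stack, params, calib,
                       min_intensity = 200, median_passes = 3,
                       species_b = species_from_lifetime("free NADH", 0.4, params))
print(result)
#> FLIM analysis of <synthetic seed 42> (64 x 64 pixels)
#> ROI statistics over 4096 pixels:
#>   mean g = 0.4834, mean s = 0.3736
#>   mean TauP = 1.5380 ns, mean TauM = 2.5780 ns
#>   mean distance from species = 0.5107
```

The small calibration constants are the sampling residual of the virtual
(undistorted) instrument. `tau_M > tau_phi` is the signature of a
multi-exponential pixel: both estimates invert a single-exponential model,
and they only agree on the universal semicircle. The mean distance from
free NADH (0.51 phasor units) is the kind of metabolic contrast used to
compare conditions; `write_result()` exports the maps as 32-bit float
TIFFs plus a summary CSV and provenance log, and `plot(result$field)`
draws the phasor cloud on the universal circle.

The same pipeline is scriptable from a shell via the installed
`exec/flimphasor` entry point:

```sh
flimphasor calibrate --reference fluorescein.tif --tau-ref 4.04 \
    --freq-mhz 80 --bins 56 --out cal.json
flimphasor analyze --input cells.tif --calibration cal.json \
    --min-intensity 200 --median-passes 3 --species-tau 0.4 --outdir out/
flimphasor batch --config run.yaml
```

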