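test_that("species placed from lifetimes sit on the universal semicircle", {
  p <- std_params()
  shg <- species_from_lifetime("collagen/SHG", 0, p)
  expect_identical(c(shg$g, shg$s), c(1, 0))
  nadh <- species_from_lifetime("free NADH", 0.4, p)
  expect_equal(c(nadh$g, nadh$s), c(0.9611449, 0.1932496), tolerance = 1e-6)
  fluo <- species_from_lifetime("fluorescein", 4.04, p)
  expect_equal(c(fluo$g, fluo$s), c(0.1951659, 0.3963284), tolerance = 1e-6)
  expect_equal((fluo$g - 0.5)^2 + fluo$s^2, 0.25, tolerance = 1e-12)
  expect_error(species_from_lifetime("x", -1, p), "non-negative")
})

test_that("the mCherry-to-collagen phasor distance reproduces the published 0.58", {
  p <- std_params()
  # mCherry location as printed from the averaged phasor plot
  f <- phasor_field(g = matrix(0.634), s = matrix(0.45), params = p,
                    calibrated = TRUE)
  collagen <- species_from_lifetime("collagen", 0, p)
  d <- distance_map(f, collagen)
  expect_equal(round(d$d[1, 1], 2), 0.58)
})

test_that("distance maps behave like a pointwise metric to the species", {
  p <- std_params()
  sp <- species_location("B", 1, 0)
  f <- phasor_field(g = matrix(c(1, 0, 0.5, NaN), 2, 2),
                    s = matrix(c(0, 0, 0.5, NaN), 2, 2),
                    params = p, calibrated = TRUE)
  d <- distance_map(f, sp)
  expect_identical(d$d[1, 1], 0)           # coincident pixel
  expect_identical(d$d[2, 1], 1)           # unit separation
  expect_equal(d$d[1, 2], sqrt(0.5))
  expect_true(is.nan(d$d[2, 2]))
  expect_true(all(d$d >= 0, na.rm = TRUE))

  # 1-Lipschitz in (g, s)
  set.seed(14)
  for (rep in 1:20) {
    a <- c(runif(1), runif(1, 0, 0.6)); b <- c(runif(1), runif(1, 0, 0.6))
    fa <- phasor_field(g = matrix(a[1]), s = matrix(a[2]), params = p,
                       calibrated = TRUE)
    fb <- phasor_field(g = matrix(b[1]), s = matrix(b[2]), params = p,
                       calibrated = TRUE)
    dd <- abs(distance_map(fa, sp)$d - distance_map(fb, sp)$d)
    expect_lte(dd[1, 1], sqrt(sum((a - b)^2)) + 1e-12)
  }

  fu <- phasor_field(g = matrix(1), s = matrix(0), params = p)
  expect_error(distance_map(fu, sp), "calibrated")
})

test_that("fractions hit the endpoints, the midpoint and swap symmetry", {
  p <- std_params()
  A <- species_location("A", 0.2, 0.4)
  B <- species_location("B", 0.9, 0.1)
  f <- phasor_field(g = matrix(c(A$g, B$g, (A$g + B$g) / 2), 1, 3),
                    s = matrix(c(A$s, B$s, (A$s + B$s) / 2), 1, 3),
                    params = p, calibrated = TRUE)
  fm <- fraction_map(f, A, B)
  expect_equal(fm$f_a[1, 1], 1)
  expect_equal(fm$f_a[1, 2], 0)
  expect_equal(fm$f_a[1, 3], 0.5)
  # swapping A and B flips the fraction for on-segment pixels
  fm_swap <- fraction_map(f, B, A)
  expect_equal(fm_swap$f_a, 1 - fm$f_a, tolerance = 1e-12)
  expect_error(fraction_map(f, A, species_location("B", A$g, A$s)),
               "coincide")

  # off-segment values may exceed [0, 1]; clip clamps them
  fo <- phasor_field(g = matrix(-1), s = matrix(0), params = p,
                     calibrated = TRUE)
  AB <- fraction_map(fo, species_location("A", 0, 0),
                     species_location("B", 1, 0))
  expect_gt(AB$f_a[1, 1], 1)
  expect_equal(fraction_map(fo, species_location("A", 0, 0),
                            species_location("B", 1, 0), clip = TRUE)$f_a[1, 1],
               1)
})

test_that("programmed two-component mixtures recover their intensity fraction", {
  p <- std_params()
  cal <- compute_calibration(make_reference_stack(4.04, p), 4.04, p)
  mix_stack <- function(fa, poisson = FALSE, seed = 1L) {
    comp <- data.frame(tau_ns = c(0.4, 3), fraction = c(fa, 1 - fa))
    if (fa == 0) comp <- comp[2, ]
    if (fa == 1) comp <- comp[1, ]
    simulate_stack(ground_truth(comp, photons_per_pixel = 500,
                                poisson = poisson, seed = seed),
                   c(8L, 8L), p)
  }
  calibrated_field <- function(st) apply_calibration(phasor_transform(st, p), cal)
  # endpoints measured from the calibrated pure stacks, as in practice
  aggA <- aggregate_phasor(calibrated_field(mix_stack(1)))
  aggB <- aggregate_phasor(calibrated_field(mix_stack(0)))
  A <- species_location("free-like", aggA$g, aggA$s)
  B <- species_location("bound-like", aggB$g, aggB$s)

  for (fa in c(0, 0.3, 0.5, 1)) {
    fm <- fraction_map(calibrated_field(mix_stack(fa)), A, B)
    expect_equal(mean(fm$f_a), fa, tolerance = 1e-9)
  }

  # Poisson case: the mean over pixels is unbiased within 2 SE across seeds
  seed_means <- vapply(1:20, function(sd) {
    fm <- fraction_map(calibrated_field(mix_stack(0.3, poisson = TRUE,
                                                  seed = sd)), A, B)
    mean(fm$f_a)
  }, numeric(1))
  se <- sd(seed_means) / sqrt(length(seed_means))
  expect_lt(abs(mean(seed_means) - 0.3), 2 * se + 1e-3)
})

test_that("phasor cursors select exactly the pixels generated at each lifetime", {
  p <- std_params()
  region <- matrix(1L, 8, 8); region[, 5:8] <- 2L
  st <- simulate_stack(
    ground_truth(list(data.frame(tau_ns = 0.5, fraction = 1),
                      data.frame(tau_ns = 3, fraction = 1)),
                 photons_per_pixel = 500, poisson = FALSE, region = region),
    c(8L, 8L), p)
  cal <- compute_calibration(make_reference_stack(4.04, p), 4.04, p)
  f <- apply_calibration(phasor_transform(st, p), cal)
  th1 <- theoretical_phasor(0.5, p); th2 <- theoretical_phasor(3, p)
  m1 <- cursor_mask(f, th1$g, th1$s, 0.05)
  m2 <- cursor_mask(f, th2$g, th2$s, 0.05)
  expect_identical(m1$include, region == 1L)
  expect_identical(m2$include, region == 2L)
  # a tiny cursor on a pixel's own location contains at least that pixel
  m3 <- cursor_mask(f, f$g[1, 1], f$s[1, 1], 1e-6)
  expect_true(m3$include[1, 1])
  # a huge cursor covers every defined pixel
  expect_true(all(cursor_mask(f, 0.5, 0.25, 2)$include))
  expect_error(cursor_mask(f, 0.5, 0.25, 0), "positive")
})

test_that("ROI statistics average the included defined pixels", {
  p <- std_params()
  cal <- compute_calibration(make_reference_stack(4.04, p), 4.04, p)
  region <- matrix(1L, 6, 6); region[4:6, ] <- 2L
  st <- simulate_stack(
    ground_truth(list(data.frame(tau_ns = 1, fraction = 1),
                      data.frame(tau_ns = 3, fraction = 1)),
                 photons_per_pixel = 500, poisson = FALSE, region = region),
    c(6L, 6L), p)
  res <- flim_analyze(st, p, cal,
                      species_b = species_from_lifetime("free NADH", 0.4, p))

  one <- flim_mask(matrix(seq_len(36) == 1, 6, 6))
  st1 <- roi_statistics(res, one)
  expect_identical(st1$n_pixels, 1L)
  expect_equal(st1$mean_g, res$g_map[1, 1])
  expect_equal(st1$mean_taup_ns, res$taup_map[1, 1])

  pop1 <- roi_statistics(res, flim_mask(region == 1L))
  expect_identical(pop1$n_pixels, 18L)
  expect_equal(pop1$mean_taup_ns, res$taup_map[1, 1], tolerance = 1e-12)
  expect_equal(pop1$mean_taum_ns, 1, tolerance = 1e-2)

  expect_error(roi_statistics(res, flim_mask(matrix(FALSE, 6, 6))),
               "no pixels")
})
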