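test_that("delta and uniform decays land at the analytic anchor points", {
  p <- std_params(n_bins = 8L)
  delta <- uniform_stack(c(100, rep(0, 7)), 2, 2)
  f <- phasor_transform(delta, p)
  expect_identical(f$g[1, 1], 1)  # t_0 = 0: exact
  expect_identical(f$s[1, 1], 0)
  expect_equal(f$intensity[1, 1], 100)

  flat <- uniform_stack(rep(25, 8), 2, 2)
  ff <- phasor_transform(flat, p)
  expect_equal(ff$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(ff$s[1, 1], 0, tolerance = 1e-12)
})

test_that("noiseless exponentials match the geometric-series oracle to 1e-12", {
  for (N in c(16L, 56L)) for (h in 1:3) for (tau in c(0.4, 2, 4.04)) {
    p <- std_params(n_bins = N, harmonic = h)
    st <- noiseless_stack(tau, p, shape = c(2L, 2L))
    f <- phasor_transform(st, p)
    z <- oracle_sampled_phasor(tau, N, h)
    expect_equal(f$g[1, 1], Re(z), tolerance = 1e-12)
    expect_equal(f$s[1, 1], Im(z), tolerance = 1e-12)
  }
})

test_that("transform at harmonic n equals the same sums evaluated at n*omega", {
  set.seed(11)
  p1 <- std_params(n_bins = 32L)
  counts <- array(rpois(3 * 3 * 32, 20), dim = c(3, 3, 32))
  st <- flim_stack(counts)
  for (h in 2:3) {
    ph <- std_params(n_bins = 32L, harmonic = h)
    f <- phasor_transform(st, ph)
    w <- h * omega(p1)
    tk <- (0:31) * p1$bin_width_ns
    for (i in 1:3) for (j in 1:3) {
      ck <- counts[i, j, ]
      expect_equal(f$g[i, j], sum(ck * cos(w * tk)) / sum(ck))
      expect_equal(f$s[i, j], sum(ck * sin(w * tk)) / sum(ck))
    }
  }
})

test_that("the phasor of a summed decay is the intensity-weighted phasor average", {
  set.seed(5)
  p <- std_params(n_bins = 24L)
  for (rep in 1:10) {
    a <- runif(24, 0, 50)
    b <- runif(24, 0, 200)
    fa <- phasor_transform(uniform_stack(a, 1, 1), p)
    fb <- phasor_transform(uniform_stack(b, 1, 1), p)
    fab <- phasor_transform(uniform_stack(a + b, 1, 1), p)
    wa <- sum(a) / sum(a + b)
    expect_equal(fab$g[1, 1], wa * fa$g[1, 1] + (1 - wa) * fb$g[1, 1])
    expect_equal(fab$s[1, 1], wa * fa$s[1, 1] + (1 - wa) * fb$s[1, 1])
  }
})

test_that("zero-intensity pixels are undefined and an empty stack warns", {
  p <- std_params(n_bins = 4L)
  counts <- array(0, c(2, 2, 4))
  counts[1, 1, ] <- c(5, 3, 1, 1)
  f <- phasor_transform(flim_stack(counts), p)
  expect_true(is.nan(f$g[2, 2]))
  expect_true(is.nan(f$s[2, 2]))
  expect_false(is.na(f$g[1, 1]))
  expect_warning(phasor_transform(flim_stack(array(0, c(2, 2, 4))), p),
                 "no photons")
  expect_error(phasor_transform(flim_stack(array(1, c(2, 2, 5))), p),
               "temporal bins")
})

test_that("phase and modulation are the polar form of the phasor", {
  p <- std_params()
  f <- phasor_field(g = matrix(c(1, 0.5, 0.1951659, NaN), 2, 2),
                    s = matrix(c(0, 0.5, 0.3963284, NaN), 2, 2),
                    params = p)
  pm <- phase_modulation(f)
  expect_equal(pm$phi[1, 1], 0)
  expect_equal(pm$m[1, 1], 1)
  expect_equal(pm$phi[2, 1], pi / 4)
  expect_equal(pm$m[2, 1], sqrt(2) / 2)
  # fluorescein location: compare against direct atan2/hypot
  expect_equal(pm$phi[1, 2], atan2(0.3963284, 0.1951659), tolerance = 1e-12)
  expect_equal(pm$m[1, 2], sqrt(0.1951659^2 + 0.3963284^2), tolerance = 1e-12)
  expect_equal(pm$phi[1, 2], 1.113219, tolerance = 1e-6)
  expect_equal(pm$m[1, 2], 0.4417758, tolerance = 1e-6)
  expect_true(is.nan(pm$phi[2, 2]) && is.nan(pm$m[2, 2]))
})

test_that("single-exponential phasors lie exactly on the universal semicircle", {
  p <- std_params()
  taus <- c(0, 0.05, 0.4, 1, 2, 4.04, 10, 100, 1e6)
  th <- theoretical_phasor(taus, p)
  expect_equal((th$g - 0.5)^2 + th$s^2, rep(0.25, length(taus)),
               tolerance = 1e-15)
  expect_identical(th$g[1], 1)   # tau = 0 anchor
  expect_identical(th$s[1], 0)
  expect_lt(abs(th$g[length(taus)]), 1e-10)  # tau -> Inf tends to (0, 0)
  th404 <- theoretical_phasor(4.04, p)
  expect_equal(c(th404$g, th404$s), c(0.1951659, 0.3963284),
               tolerance = 1e-6)
  th04 <- theoretical_phasor(0.4, p)
  expect_equal(c(th04$g, th04$s), c(0.9611449, 0.1932496), tolerance = 1e-6)
  expect_error(theoretical_phasor(-1, p), "non-negative")
})

test_that("lifetime maps invert the single-exponential model on the semicircle", {
  p <- std_params()
  th <- theoretical_phasor(c(0.4, 1, 2, 4.04), p)
  f <- phasor_field(g = matrix(th$g, 2, 2), s = matrix(th$s, 2, 2),
                    params = p, calibrated = TRUE)
  lt <- lifetime_maps(f)
  expect_equal(as.vector(lt$taup_ns), c(0.4, 1, 2, 4.04), tolerance = 1e-9)
  expect_equal(as.vector(lt$taum_ns), c(0.4, 1, 2, 4.04), tolerance = 1e-9)
  expect_equal(lt$taup_ns, lt$taum_ns, tolerance = 1e-9)

  # (0.5, 0.5): phi = pi/4 and m = sqrt(1/2) give the same lifetime
  f2 <- phasor_field(g = matrix(0.5), s = matrix(0.5), params = p,
                     calibrated = TRUE)
  lt2 <- lifetime_maps(f2)
  expect_equal(lt2$taup_ns[1, 1], tan(pi / 4) / omega(p))
  expect_equal(lt2$taup_ns[1, 1], 1.989437, tolerance = 1e-6)
  expect_equal(lt2$taum_ns[1, 1], lt2$taup_ns[1, 1], tolerance = 1e-12)
})

test_that("out-of-range phasors follow the undefined-lifetime policy", {
  p <- std_params()
  f <- phasor_field(g = matrix(c(1.1, 0, -0.2, 0), 2, 2),
                    s = matrix(c(0, 1.2, 0.1, 0), 2, 2),
                    params = p, calibrated = TRUE)
  lt <- lifetime_maps(f)
  expect_identical(lt$taup_ns[1, 1], 0)        # phi exactly 0
  expect_true(is.nan(lt$taum_ns[1, 1]))        # m > 1
  expect_true(is.nan(lt$taup_ns[2, 1]))        # phi >= pi/2
  expect_true(is.nan(lt$taup_ns[1, 2]))        # phi < 0 (second quadrant g<0 gives phi>pi/2)
  expect_true(is.nan(lt$taup_ns[2, 2]) && is.nan(lt$taum_ns[2, 2]))  # m == 0

  fu <- phasor_field(g = matrix(0.5), s = matrix(0.3), params = p)
  expect_error(lifetime_maps(fu), "calibrated")
})
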