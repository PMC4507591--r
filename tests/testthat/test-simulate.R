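test_that("reference pulse is deterministic given a seed and analytic when noiseless", {
  inst <- thz_instrument()
  r1 <- make_reference_pulse(inst, seed = 7)
  r2 <- make_reference_pulse(inst, seed = 7)
  expect_identical(r1, r2)
  r3 <- make_reference_pulse(inst, seed = 8)
  expect_false(identical(r1$amplitudes, r3$amplitudes))

  quiet <- quiet_instrument()
  ra <- make_reference_pulse(quiet, seed = 1)
  rb <- make_reference_pulse(quiet, seed = 99)
  expect_identical(ra, rb)  # no noise channels, seed is irrelevant
  # closed form of the Gaussian-derivative pulse
  u <- (ra$delays - quiet$pulse_center) / quiet$pulse_width
  e <- -u * exp(-u^2 / 2)
  expect_equal(ra$amplitudes, e / max(abs(e)), tolerance = 1e-12)
})

test_that("pulse power spectrum peaks inside the usable THz band", {
  spec <- to_frequency(make_reference_pulse(quiet_instrument()))
  f_peak <- spec$frequencies[which.max(Mod(spec$complex_amplitudes))]
  expect_gt(f_peak, 0.2)
  expect_lt(f_peak, 2.0)
  # analytic peak of |omega * exp(-omega^2 tau^2 / 2)| is at 1/(2 pi tau)
  expect_equal(f_peak, 1 / (2 * pi * 0.3), tolerance = 0.05)
})

test_that("material properties reduce to an affine curve without bump or deviation", {
  grid <- seq(0.2, 1.5, length.out = 40)
  prof <- class_profile(1, alpha_offset = 40, alpha_slope = 20,
                        signal_amplitude = 0)
  props <- material_properties(prof, grid, seed = 1, deviation_sd = 0,
                               n_deviation_sd = 0)
  expected <- 40 + 20 * (grid - 0.85)
  expect_equal(props$alpha, expected, tolerance = 1e-12)
  expect_equal(props$n, rep(1.5, 40), tolerance = 1e-12)
  # second differences vanish for an affine function
  expect_lt(max(abs(diff(props$alpha, differences = 2))), 1e-10)
})

test_that("negative absorption is clipped to zero with a warning", {
  grid <- seq(0.2, 1.5, length.out = 20)
  prof <- class_profile(1, alpha_offset = 2, alpha_slope = 20)
  expect_warning(
    props <- material_properties(prof, grid, seed = 1, deviation_sd = 0,
                                 n_deviation_sd = 0),
    "clipped")
  expect_true(all(props$alpha >= 0))
})

test_that("two seeds give different deviations but the same class mean", {
  grid <- seq(0.2, 1.5, length.out = 64)
  prof <- class_profile(3, alpha_offset = 39)
  p1 <- material_properties(prof, grid, seed = 1)
  p2 <- material_properties(prof, grid, seed = 2)
  expect_false(isTRUE(all.equal(p1$alpha, p2$alpha)))
  # Monte-Carlo mean over many draws approaches the configured offset
  set.seed(42)
  means <- replicate(150, mean(material_properties(prof, grid)$alpha))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 39), 4 * se + 0.2)
})

test_that("propagation through vacuum and a lossless pellet match hand values", {
  inst <- quiet_instrument()
  ref <- to_frequency(make_reference_pulse(inst))
  geom <- sample_geometry(thickness = 1)
  grid <- ref$frequencies

  vac <- structure(list(frequencies = grid, n = rep(1, length(grid)),
                        k = rep(0, length(grid)),
                        alpha = rep(0, length(grid))),
                   class = "optical_properties")
  out <- propagate(ref, vac, geom)
  expect_equal(out$complex_amplitudes, ref$complex_amplitudes,
               tolerance = 1e-12)

  lossless <- vac
  lossless$n <- rep(1.5, length(grid))
  out <- propagate(ref, lossless, geom)
  h <- out$complex_amplitudes / ref$complex_amplitudes
  nz <- Mod(ref$complex_amplitudes) > 1e-6 * max(Mod(ref$complex_amplitudes))
  # Fresnel amplitude 4n/(n+1)^2 = 0.96 at every usable bin
  expect_equal(Mod(h[nz]), rep(4 * 1.5 / 2.5^2, sum(nz)), tolerance = 1e-9)
  # propagation phase at the 1 THz bin: omega (n-1) d / c
  i1 <- which.min(abs(grid - 1))
  expected_phase <- 2 * pi * grid[i1] * 1e12 * 0.5 * 1e-3 / 299792458
  measured <- -Arg(h[i1])
  expect_equal((measured - expected_phase) %% (2 * pi), 0, tolerance = 1e-9)
})

test_that("zero-amplitude reference bins pass through propagation as zero", {
  inst <- quiet_instrument()
  ref <- to_frequency(make_reference_pulse(inst))
  ref$complex_amplitudes[5] <- 0 + 0i
  props <- material_properties(class_profile(1, 40), ref$frequencies,
                               seed = 1, deviation_sd = 0, n_deviation_sd = 0)
  out <- propagate(ref, props, sample_geometry())
  expect_identical(out$complex_amplitudes[5], 0 + 0i)
})

test_that("datasets are reproducible from the seed and structurally complete", {
  profs <- wheat_class_profiles()[1:2]
  d1 <- generate_dataset(profs, n_per_class = 2, seed = 11)
  d2 <- generate_dataset(profs, n_per_class = 2, seed = 11)
  expect_identical(d1, d2)
  d3 <- generate_dataset(profs, n_per_class = 2, seed = 12)
  expect_false(identical(d1$traces, d3$traces))

  expect_length(d1$traces, 4L)
  expect_true(all(vapply(d1$traces, length, 0L) == 3L))
  expect_length(d1$reference_traces, ceiling(4 / 3))
  expect_setequal(unique(d1$labels), 1:2)
})

test_that("noiseless generation and extraction round-trip the planted absorption", {
  profs <- wheat_class_profiles(signal_step = 0)[1:2]
  ds <- generate_dataset(profs, n_per_class = 2,
                         instrument = quiet_instrument(),
                         seed = 5, deviation_sd = 0, n_deviation_sd = 0)
  props <- extract_dataset(ds, band = c(0.3, 1.4))
  for (i in seq_along(props)) {
    planted <- approx(ds$truth[[i]]$frequencies, ds$truth[[i]]$alpha,
                      xout = props[[i]]$frequencies)$y
    expect_lt(max(abs(props[[i]]$alpha - planted)), 1e-3)
  }
})

test_that("the direct spectra-matrix generator is seeded and class-labelled", {
  profs <- wheat_class_profiles()
  sm1 <- simulate_spectra_matrix(profs, n_per_class = 3, seed = 2)
  sm2 <- simulate_spectra_matrix(profs, n_per_class = 3, seed = 2)
  expect_identical(sm1, sm2)
  expect_equal(dim(sm1), c(24L, 128L))
  expect_equal(tabulate(sm1$y), rep(3L, 8))
})

test_that("invalid constructor arguments are rejected", {
  expect_error(thz_instrument(time_step = 0), "time_step")
  expect_error(thz_instrument(n_points = 32), "n_points")
  expect_error(class_profile(1, alpha_offset = -1), "alpha_offset")
  expect_error(class_profile(1, 40, n_baseline = 0.9), "n_baseline")
  expect_error(sample_geometry(thickness = -1), "thickness")
  expect_error(generate_dataset(wheat_class_profiles()[1], 5), "2 class")
  expect_error(generate_dataset(wheat_class_profiles()[1:2], 1), "n_per_class")
})
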