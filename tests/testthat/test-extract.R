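test_that("scan averaging is the pointwise mean and shrinks noise like 1/sqrt(3)", {
  t <- seq(0, 6.3, by = 0.1)
  base <- thz_trace(t, sin(t))
  expect_equal(average_scans(list(base, base, base)), base)

  tr1 <- thz_trace(t, rep(1, length(t)))
  tr2 <- thz_trace(t, rep(2, length(t)))
  tr3 <- thz_trace(t, rep(3, length(t)))
  expect_equal(average_scans(list(tr1, tr2, tr3))$amplitudes,
               rep(2, length(t)))

  bad <- thz_trace(t + 0.05, sin(t))
  expect_error(average_scans(list(base, bad)), "scan 2")

  # Monte-Carlo: averaging 3 scans of white noise reduces the SD by sqrt(3)
  set.seed(1)
  sds <- replicate(1000, {
    scans <- lapply(1:3, function(i) thz_trace(t, rnorm(length(t))))
    sd(average_scans(scans)$amplitudes)
  })
  expect_equal(mean(sds), 1 / sqrt(3), tolerance = 0.02)
})

test_that("the Fourier transform places a cosine at its bin, conserves energy and obeys the shift theorem", {
  n <- 256L
  dt <- 0.05
  t <- (0:(n - 1)) * dt
  f0 <- 1  # THz; exactly bin 1 * n * dt / ... -> 1/(n*dt) * k with k = 12.8?
  # use an exact bin frequency so leakage is zero
  k <- 16L
  f0 <- k / (n * dt)
  tr <- thz_trace(t, cos(2 * pi * f0 * t))
  spec <- to_frequency(tr)
  expect_equal(which.max(Mod(spec$complex_amplitudes)) - 1L, k)

  # Parseval for the unnormalised DFT: sum|x|^2 = sum|X|^2 / n
  set.seed(2)
  tr2 <- thz_trace(t, rnorm(n))
  sp2 <- to_frequency(tr2)
  half <- n %/% 2L
  w <- c(1, rep(2, half - 1L), 1)  # one-sided bin multiplicities
  e_time <- sum(tr2$amplitudes^2)
  e_freq <- sum(w * Mod(sp2$complex_amplitudes)^2) / n
  expect_equal(e_freq, e_time, tolerance = 1e-9)

  # delaying by m samples multiplies each bin's phase by -omega * dt * m
  x <- exp(-((t - 3) / 0.2)^2)
  m <- 10L
  xd <- c(numeric(m), x[1:(n - m)])
  sa <- to_frequency(thz_trace(t, x))
  sb <- to_frequency(thz_trace(t, xd))
  sel <- Mod(sa$complex_amplitudes) > 1e-6 * max(Mod(sa$complex_amplitudes))
  ratio <- sb$complex_amplitudes[sel] / sa$complex_amplitudes[sel]
  expected <- exp(-2i * pi * sa$frequencies[sel] * dt * m)
  expect_equal(ratio, expected, tolerance = 1e-8)

  expect_error(to_frequency(tr, zero_pad_to = 100), "zero_pad_to")
})

test_that("transfer function identity, scaling and dead-bin detection behave", {
  spec <- to_frequency(make_reference_pulse(quiet_instrument()))
  tf <- transfer_function(spec, spec, band = c(0.3, 1.4))
  expect_equal(tf$rho, rep(1, length(tf$rho)), tolerance = 1e-12)
  expect_equal(tf$phi, rep(0, length(tf$phi)), tolerance = 1e-12)

  half_spec <- spec
  half_spec$complex_amplitudes <- 0.5 * spec$complex_amplitudes
  tf2 <- transfer_function(half_spec, spec, band = c(0.3, 1.4))
  expect_equal(tf2$rho, rep(0.5, length(tf2$rho)), tolerance = 1e-12)
  expect_equal(tf2$phi, rep(0, length(tf2$phi)), tolerance = 1e-12)

  # far above the pulse bandwidth the reference is below the floor
  expect_error(transfer_function(spec, spec, band = c(4, 9)),
               "noise floor")
})

test_that("transfer-function phase matches the forward-model phase to 1e-6 rad", {
  inst <- quiet_instrument()
  ref <- to_frequency(make_reference_pulse(inst))
  geom <- sample_geometry()
  props <- material_properties(class_profile(1, 40, alpha_slope = 15),
                               ref$frequencies, seed = 3,
                               deviation_sd = 0, n_deviation_sd = 0)
  props$n[] <- 1.7
  sam <- propagate(ref, props, geom)
  tf <- transfer_function(sam, ref, band = c(0.25, 1.45))
  expected <- 2 * pi * tf$frequencies * 1e12 * 0.7 * 1e-3 / 299792458
  expect_lt(max(abs(tf$phi - expected)), 1e-6)
})

test_that("phase unwrapping survives optically thick pellets (n*d up to 3 mm-equivalents)", {
  inst <- quiet_instrument()
  ref <- to_frequency(make_reference_pulse(inst))
  for (nd in list(c(2.0, 2), c(2.5, 2))) {  # (n, d_mm): (n-1)*d = 2 and 3 mm
    geom <- sample_geometry(thickness = nd[2])
    props <- structure(list(frequencies = ref$frequencies,
                            n = rep(nd[1], length(ref$frequencies)),
                            k = rep(0, length(ref$frequencies)),
                            alpha = rep(0, length(ref$frequencies))),
                       class = "optical_properties")
    sam <- propagate(ref, props, geom)
    tf <- transfer_function(sam, ref, band = c(0.25, 1.45))
    analytic <- 2 * pi * tf$frequencies * 1e12 * (nd[1] - 1) *
      nd[2] * 1e-3 / 299792458
    expect_lt(max(abs(tf$phi - analytic)), 1e-6)
  }
})

test_that("refractive index inversion recovers vacuum and a 1.5-index pellet", {
  f <- seq(0.3, 1.4, by = 0.02)
  geom <- sample_geometry(thickness = 1)
  tf0 <- structure(list(frequencies = f, rho = rep(1, length(f)),
                        phi = rep(0, length(f))), class = "transfer_function")
  expect_equal(refractive_index(tf0, geom), rep(1, length(f)))

  phi <- 2 * pi * f * 1e12 * 0.5 * 1e-3 / 299792458
  tf1 <- structure(list(frequencies = f, rho = rep(1, length(f)), phi = phi),
                   class = "transfer_function")
  expect_equal(refractive_index(tf1, geom), rep(1.5, length(f)),
               tolerance = 1e-12)
})

test_that("absorption inversion matches hand-evaluated cases", {
  f <- seq(0.3, 1.4, by = 0.02)
  geom <- sample_geometry(thickness = 1)
  n <- rep(1.5, length(f))
  fresnel <- 4 * 1.5 / 2.5^2  # 0.96

  tf <- structure(list(frequencies = f, rho = rep(fresnel, length(f)),
                       phi = rep(0, length(f))), class = "transfer_function")
  expect_equal(absorption_coefficient(tf, n, geom), rep(0, length(f)),
               tolerance = 1e-12)

  # rho = 0.96 * exp(-1) through 1 mm: alpha = (2 / 0.1 cm) * 1 = 20 cm^-1
  tf$rho <- rep(fresnel * exp(-1), length(f))
  expect_equal(absorption_coefficient(tf, n, geom), rep(20, length(f)),
               tolerance = 1e-12)

  tf$rho[3] <- 0
  expect_error(absorption_coefficient(tf, n, geom), "rho")

  tf$rho <- rep(fresnel * 1.01, length(f))  # above lossless -> negative alpha
  expect_warning(a <- absorption_coefficient(tf, n, geom), "negative")
  expect_true(all(a < 0))
})

test_that("noiseless round trip recovers planted n and alpha to tight tolerances", {
  inst <- quiet_instrument()
  geom <- sample_geometry()
  prof <- class_profile(2, alpha_offset = 39.4, signal_amplitude = 2)
  ds <- generate_dataset(list(prof, class_profile(1, 37.1)), n_per_class = 2,
                         instrument = inst, geometry = geom, seed = 9,
                         deviation_sd = 0, n_deviation_sd = 0)
  props <- extract_dataset(ds, band = c(0.3, 1.4))
  i <- 1L
  truth_n <- approx(ds$truth[[i]]$frequencies, ds$truth[[i]]$n,
                    xout = props[[i]]$frequencies)$y
  truth_a <- approx(ds$truth[[i]]$frequencies, ds$truth[[i]]$alpha,
                    xout = props[[i]]$frequencies)$y
  expect_lt(max(abs(props[[i]]$n - truth_n)), 1e-4)
  expect_lt(max(abs(props[[i]]$alpha - truth_a)), 1e-2)
})

test_that("absorption in cm^-1 is invariant to the declared thickness unit", {
  f <- seq(0.3, 1.4, by = 0.05)
  n <- rep(1.5, length(f))
  tf <- structure(list(frequencies = f,
                       rho = rep(0.96 * exp(-1), length(f)),
                       phi = rep(0, length(f))), class = "transfer_function")
  a_mm <- absorption_coefficient(tf, n, sample_geometry(1, units = "mm"))
  a_um <- absorption_coefficient(tf, n, sample_geometry(1000, units = "um"))
  a_m <- absorption_coefficient(tf, n, sample_geometry(0.001, units = "m"))
  expect_equal(a_mm, a_um, tolerance = 1e-12)
  expect_equal(a_mm, a_m, tolerance = 1e-12)
})

test_that("the feature matrix resamples each sample onto the target grid", {
  grid <- seq(0.2, 1.5, length.out = 128)
  mk <- function(alpha) structure(
    list(frequencies = grid, n = rep(1.5, 128),
         k = rep(0, 128), alpha = alpha),
    class = "optical_properties")

  samples <- list(mk(40 + grid), mk(rep(40, 128)))
  sm <- build_matrix(samples, labels = c(1, 2), band = c(0.2, 1.5),
                     n_variables = 128)
  expect_equal(ncol(sm$X), 128L)
  # grid already equals target grid: rows are exact copies
  expect_equal(unname(sm$X[1, ]), 40 + grid, tolerance = 1e-12)
  expect_equal(unname(sm$X[2, ]), rep(40, 128), tolerance = 1e-12)

  narrow <- list(structure(list(frequencies = seq(0.4, 1.2, by = 0.01),
                                n = rep(1.5, 81), k = rep(0, 81),
                                alpha = rep(40, 81)),
                           class = "optical_properties"))
  expect_error(build_matrix(narrow, labels = 1, band = c(0.2, 1.5)),
               "cover")
})
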