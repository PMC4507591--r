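#' Time-domain trace
#'
#' Container for one sampled THz field trace: delay in picoseconds on a
#' uniform grid and field amplitude in arbitrary units.
#'
#' @param delays numeric vector of delays, ps, uniformly spaced, >= 64 points.
#' @param amplitudes numeric vector of field amplitudes, same length.
#' @return An object of class \code{"thz_trace"}.
#' @export
thz_trace <- function(delays, amplitudes) {
  if (length(delays) != length(amplitudes))
    stop_thz("`delays` and `amplitudes` must have equal length")
  if (length(delays) < 64L)
    stop_thz("a trace needs at least 64 points")
  if (!is_uniform(delays))
    stop_thz("`delays` must be uniformly spaced (relative tolerance 1e-9)")
  structure(list(delays = as.numeric(delays),
                 amplitudes = as.numeric(amplitudes)),
            class = "thz_trace")
}

#' @export
print.thz_trace <- function(x, ...) {
  cat(sprintf("THz time-domain trace: %d points, %.4g ps step, peak |E| = %.4g\n",
              length(x$delays), x$delays[2L] - x$delays[1L],
              max(abs(x$amplitudes))))
  invisible(x)
}

# Noise-free Gaussian-derivative pulse on the instrument grid, peak
# amplitude normalised to 1.
analytic_pulse <- function(instrument) {
  t <- (seq_len(instrument$n_points) - 1L) * instrument$time_step
  tau <- instrument$pulse_width
  u <- (t - instrument$pulse_center) / tau
  e <- -u * exp(-u^2 / 2)
  e <- e / max(abs(e))
  thz_trace(t, e)
}

# Applies the instrument noise model to a clean amplitude vector:
# per-bin multiplicative spectral noise (Hermitian-symmetric, keeps the
# trace real) followed by additive white time-domain noise.
apply_instrument_noise <- function(amplitudes, instrument) {
  n <- length(amplitudes)
  out <- amplitudes
  if (instrument$amplitude_noise_sd > 0) {
    spec <- stats::fft(out)
    half <- n %/% 2L
    eps <- stats::rnorm(half + 1L, 0, instrument$amplitude_noise_sd)
    gain <- rep(1, n)
    gain[1:(half + 1L)] <- 1 + eps
    if (half > 1L) gain[n:(half + 2L)] <- gain[2:half]
    out <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  }
  if (instrument$additive_noise_sd > 0)
    out <- out + stats::rnorm(n, 0, instrument$additive_noise_sd)
  out
}

#' Simulate a reference pulse trace
#'
#' Generates the reference scan: the instrument's single-cycle
#' Gaussian-derivative pulse with the configured noise applied. The pulse
#' spectrum has usable energy across roughly 0.2--2 THz for the default
#' 0.3 ps width.
#'
#' @param instrument a [thz_instrument()].
#' @param seed integer seed; the trace is deterministic given the seed.
#' @return A [thz_trace()].
#' @export
make_reference_pulse <- function(instrument, seed = NULL) {
  stopifnot(inherits(instrument, "thz_instrument"))
  ref <- analytic_pulse(instrument)
  with_seed(seed, {
    ref$amplitudes <- apply_instrument_noise(ref$amplitudes, instrument)
  })
  ref
}

#' Realise the optical properties of one sample
#'
#' Draws one sample's per-frequency refractive index and absorption
#' coefficient from a class profile: the deterministic class curve plus a
#' smooth per-sample random deviation (low-order cosine series), emulating
#' pellet-to-pellet variation in composition and density.
#'
#' @param profile a [class_profile()].
#' @param grid strictly increasing non-negative frequency grid, THz.
#' @param seed integer seed for the per-sample deviation; \code{NULL} uses
#'   the current RNG stream.
#' @param deviation_sd approximate pointwise SD of the smooth absorption
#'   deviation, cm^-1.
#' @param n_deviation_sd approximate pointwise SD of the smooth
#'   refractive-index deviation, dimensionless.
#' @return An object of class \code{"optical_properties"}: frequencies (THz),
#'   n, k and alpha (cm^-1). Negative absorption values are clipped to zero
#'   with a warning.
#' @export
material_properties <- function(profile, grid, seed = NULL,
                                deviation_sd = 3, n_deviation_sd = 0.01) {
  stopifnot(inherits(profile, "class_profile"))
  grid <- as.numeric(grid)
  if (any(grid < 0) || !all(diff(grid) > 0))
    stop_thz("`grid` must be strictly increasing and non-negative")
  realise <- function() {
    alpha <- profile$alpha_offset +
      profile$alpha_slope * (grid - profile$alpha_ref_freq) +
      profile$signal_amplitude * raised_cosine_bump(grid, profile$signal_band) +
      smooth_deviation(grid, deviation_sd)
    if (any(alpha < 0)) {
      warning("negative absorption clipped to 0 at ",
              sum(alpha < 0), " frequency bin(s)", call. = FALSE)
      alpha <- pmax(alpha, 0)
    }
    n <- profile$n_baseline + smooth_deviation(grid, n_deviation_sd)
    list(n = n, alpha = alpha)
  }
  drawn <- if (is.null(seed)) realise() else with_seed(seed, realise())
  structure(list(frequencies = grid, n = drawn$n,
                 k = alpha_to_k(drawn$alpha, grid), alpha = drawn$alpha),
            class = "optical_properties")
}

# Complex single-pass transfer function H(f) of a pellet of thickness d:
# the Fresnel amplitude factor 4n/(n+1)^2 (real index; its k-dependence is
# second order for weakly absorbing pellets and the inversion formulas
# assume the real-index form) times the propagation term with the complex
# index N = n - ik in the exponent. Phases follow the engineering DFT
# convention (a delay of dt multiplies a bin by exp(-i*omega*dt)), so
# propagation through an optically thick sample gives a negative raw phase;
# the extraction side reports phi as the positive phase delay.
forward_transfer <- function(n, k, f_thz, thickness_mm) {
  omega <- 2 * pi * f_thz * 1e12
  N <- complex(real = n, imaginary = -k)
  d_m <- thickness_mm * 1e-3
  h <- 4 * n / (n + 1)^2 * exp(-1i * omega * (N - 1) * d_m / .C_LIGHT)
  h[f_thz == 0] <- 4 * n[f_thz == 0] / (n[f_thz == 0] + 1)^2
  h
}

#' Propagate a reference spectrum through a sample
#'
#' Applies the single-pass pellet transfer function
#' \deqn{H(\omega) = \frac{4n}{(n+1)^2} \exp\{-i\omega(N-1)d/c\}, \quad
#'       N = n - ik,}
#' to a reference frequency spectrum, producing the sample spectrum. The
#' Fresnel amplitude factor uses the real index (its k-dependence is second
#' order for weakly absorbing pellets, and the optical-constant inversion
#' formulas assume the real-index form). The extinction coefficient is
#' derived from absorption via \eqn{k = \alpha c / (2\omega)} (field
#' convention). Etalon echoes from multiple internal reflections are
#' deliberately not modelled.
#'
#' @param reference a \code{"frequency_spectrum"} (see [to_frequency()]).
#' @param props an \code{"optical_properties"} object on the same grid.
#' @param geometry a [sample_geometry()].
#' @return A \code{"frequency_spectrum"} for the sample; zero-amplitude
#'   reference bins stay zero.
#' @examples
#' inst <- thz_instrument(amplitude_noise_sd = 0, additive_noise_sd = 0)
#' ref <- to_frequency(make_reference_pulse(inst))
#' props <- material_properties(class_profile(1, 40), ref$frequencies,
#'                              seed = 1, deviation_sd = 0)
#' sam <- propagate(ref, props, sample_geometry())
#' @export
propagate <- function(reference, props, geometry) {
  stopifnot(inherits(reference, "frequency_spectrum"),
            inherits(props, "optical_properties"),
            inherits(geometry, "sample_geometry"))
  if (!same_grid(reference$frequencies, props$frequencies))
    stop_thz("reference spectrum and optical properties must share the frequency grid")
  h <- forward_transfer(props$n, props$k, props$frequencies,
                        geometry$thickness_mm)
  structure(list(frequencies = reference$frequencies,
                 complex_amplitudes = reference$complex_amplitudes * h),
            class = "frequency_spectrum")
}

# Synthesise a sample time-domain trace from a clean reference trace and the
# sample's transfer function evaluated on the full FFT grid (Hermitian
# mirrored so the result is real).
synthesise_sample_trace <- function(ref_trace, props, geometry) {
  x <- ref_trace$amplitudes
  n <- length(x)
  dt <- ref_trace$delays[2L] - ref_trace$delays[1L]
  half <- n %/% 2L
  f_onesided <- (0:half) / (n * dt)
  n_i <- stats::approx(props$frequencies, props$n, xout = f_onesided, rule = 2)$y
  a_i <- stats::approx(props$frequencies, props$alpha, xout = f_onesided, rule = 2)$y
  h_half <- forward_transfer(n_i, alpha_to_k(a_i, f_onesided), f_onesided,
                             geometry$thickness_mm)
  h_full <- complex(length.out = n)
  h_full[1:(half + 1L)] <- h_half
  if (half > 1L) h_full[n:(half + 2L)] <- Conj(h_half[2:half])
  y <- Re(stats::fft(stats::fft(x) * h_full, inverse = TRUE)) / n
  thz_trace(ref_trace$delays, y)
}

#' Generate a complete labelled THz-TDS dataset
#'
#' Forward-models a measurement campaign: for each of K classes and
#' \code{n_per_class} samples, draws per-sample optical properties from the
#' class profile, propagates the clean reference pulse through the pellet,
#' and records \code{n_scans} independently noisy scans. A fresh noisy
#' reference trace is recorded before every block of three samples,
#' mirroring the usual practice of re-measuring the reference throughout a
#' session. The planted per-sample optical properties are retained in
#' \code{$truth} so extraction accuracy can be audited.
#'
#' @param profiles list of [class_profile()] objects (K >= 2).
#' @param n_per_class samples per class (>= 2).
#' @param instrument a [thz_instrument()].
#' @param geometry a [sample_geometry()].
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @param n_scans repeated scans per sample (default 3).
#' @param deviation_sd,n_deviation_sd per-sample smooth deviation SDs,
#'   passed to [material_properties()].
#' @return An object of class \code{"thz_dataset"}: \code{traces} (per sample,
#'   a list of \code{n_scans} traces), \code{reference_traces},
#'   \code{reference_index} (which reference goes with each sample),
#'   \code{labels}, \code{truth}, plus the configuration used.
#' @examples
#' ds <- generate_dataset(wheat_class_profiles()[1:2], n_per_class = 2,
#'                        seed = 42)
#' length(ds$traces)
#' @export
generate_dataset <- function(profiles, n_per_class = 20,
                             instrument = thz_instrument(),
                             geometry = sample_geometry(),
                             seed = 1, n_scans = 3L,
                             deviation_sd = 3, n_deviation_sd = 0.01) {
  if (length(profiles) < 2L) stop_thz("need at least 2 class profiles")
  if (n_per_class < 2L) stop_thz("`n_per_class` must be >= 2")
  k <- length(profiles)
  n_samples <- k * n_per_class
  ref_clean <- analytic_pulse(instrument)
  dt <- instrument$time_step
  half <- instrument$n_points %/% 2L
  grid_full <- (0:half) / (instrument$n_points * dt)
  with_seed(seed, {
    labels <- integer(n_samples)
    truth <- vector("list", n_samples)
    traces <- vector("list", n_samples)
    reference_index <- integer(n_samples)
    n_blocks <- ceiling(n_samples / 3)
    reference_traces <- lapply(seq_len(n_blocks), function(b) {
      r <- ref_clean
      r$amplitudes <- apply_instrument_noise(r$amplitudes, instrument)
      r
    })
    idx <- 0L
    for (ci in seq_len(k)) {
      for (si in seq_len(n_per_class)) {
        idx <- idx + 1L
        labels[idx] <- profiles[[ci]]$class_id
        props <- material_properties(profiles[[ci]], grid_full,
                                     deviation_sd = deviation_sd,
                                     n_deviation_sd = n_deviation_sd)
        truth[[idx]] <- props
        clean <- synthesise_sample_trace(ref_clean, props, geometry)
        traces[[idx]] <- lapply(seq_len(n_scans), function(s) {
          tr <- clean
          tr$amplitudes <- apply_instrument_noise(tr$amplitudes, instrument)
          tr
        })
        reference_index[idx] <- ((idx - 1L) %/% 3L) + 1L
      }
    }
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    names(labels) <- sample_ids
    names(traces) <- sample_ids
    names(truth) <- sample_ids
    structure(list(
      traces = traces, reference_traces = reference_traces,
      reference_index = reference_index, labels = labels, truth = truth,
      geometry = geometry, instrument = instrument, profiles = profiles,
      n_scans = n_scans, seed = seed,
      deviation_sd = deviation_sd, n_deviation_sd = n_deviation_sd
    ), class = "thz_dataset")
  })
}

#' @export
print.thz_dataset <- function(x, ...) {
  cat(sprintf("Simulated THz-TDS dataset: %d samples, %d classes, %d scans each\n",
              length(x$traces), length(unique(x$labels)), x$n_scans))
  cat(sprintf("  references: %d traces (one per block of 3 samples)\n",
              length(x$reference_traces)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate a spectra matrix directly (no time-domain round trip)
#'
#' Fast path for Monte-Carlo studies: draws each sample's optical properties
#' on the target frequency grid and adds independent per-variable
#' measurement noise, skipping pulse synthesis and extraction. The
#' measurement-noise SD stands in for the residual noise the full
#' time-domain pipeline leaves on the extracted feature after scan
#' averaging.
#'
#' @param profiles list of [class_profile()] objects.
#' @param n_per_class samples per class.
#' @param grid frequency grid, THz (default: 128 variables over
#'   0.2--1.5 THz).
#' @param seed integer seed.
#' @param feature "absorption" (cm^-1) or "refractive_index".
#' @param measurement_noise_sd per-variable iid noise SD, in feature units.
#' @param deviation_sd,n_deviation_sd smooth per-sample deviation SDs.
#' @return A [spectra_matrix()].
#' @export
simulate_spectra_matrix <- function(profiles, n_per_class = 20,
                                    grid = seq(0.2, 1.5, length.out = 128L),
                                    seed = 1,
                                    feature = c("absorption", "refractive_index"),
                                    measurement_noise_sd = 0.8,
                                    deviation_sd = 0,
                                    n_deviation_sd = 0) {
  feature <- match.arg(feature)
  k <- length(profiles)
  n_samples <- k * n_per_class
  p <- length(grid)
  if (feature == "refractive_index" && missing(measurement_noise_sd))
    measurement_noise_sd <- 0.004
  with_seed(seed, {
    x <- matrix(0, n_samples, p)
    y <- integer(n_samples)
    idx <- 0L
    for (ci in seq_len(k)) {
      for (si in seq_len(n_per_class)) {
        idx <- idx + 1L
        props <- material_properties(profiles[[ci]], grid,
                                     deviation_sd = deviation_sd,
                                     n_deviation_sd = n_deviation_sd)
        base <- if (feature == "absorption") props$alpha else props$n
        x[idx, ] <- base + stats::rnorm(p, 0, measurement_noise_sd)
        y[idx] <- profiles[[ci]]$class_id
      }
    }
    spectra_matrix(x, grid, y, sample_ids = sprintf("s%03d", seq_len(n_samples)),
                   feature = feature)
  })
}
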