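#' Average repeated scans of one sample
#'
#' Repeated scans of the same pellet are averaged pointwise before Fourier
#' analysis to suppress random error; averaging m scans reduces white noise
#' SD by \eqn{1/\sqrt m}.
#'
#' @param traces list of [thz_trace()] objects on the same delay grid.
#' @return A single [thz_trace()], the pointwise mean.
#' @export
average_scans <- function(traces) {
  if (length(traces) == 0L) stop_thz("no traces to average")
  ref <- traces[[1L]]
  for (i in seq_along(traces)) {
    if (!inherits(traces[[i]], "thz_trace"))
      stop_thz("element ", i, " is not a thz_trace")
    if (!same_grid(traces[[i]]$delays, ref$delays))
      stop_thz("scan ", i, " is on a different delay grid than scan 1")
  }
  amp <- Reduce(`+`, lapply(traces, `[[`, "amplitudes")) / length(traces)
  thz_trace(ref$delays, amp)
}

#' One-sided Fourier transform of a time-domain trace
#'
#' Computes the discrete Fourier transform of a uniformly sampled trace and
#' returns the one-sided spectrum (0 to Nyquist). Frequencies are in THz
#' (reciprocal picoseconds). Phases follow the engineering DFT convention:
#' delaying a trace by \eqn{\Delta t} multiplies each bin by
#' \eqn{\exp(-i\omega\Delta t)}.
#'
#' @param trace a [thz_trace()].
#' @param zero_pad_to pad the trace with zeros to this length before the
#'   transform (>= the trace length); refines the frequency grid spacing to
#'   1/(zero_pad_to * time_step) THz.
#' @return An object of class \code{"frequency_spectrum"} with
#'   \code{frequencies} (THz) and \code{complex_amplitudes} (raw DFT values,
#'   arbitrary field units).
#' @export
to_frequency <- function(trace, zero_pad_to = NULL) {
  stopifnot(inherits(trace, "thz_trace"))
  n <- length(trace$amplitudes)
  nz <- as.integer(zero_pad_to %||% n)
  if (nz < n)
    stop_thz("`zero_pad_to` (", nz, ") must be >= the trace length (", n, ")")
  dt <- trace$delays[2L] - trace$delays[1L]
  x <- c(trace$amplitudes, numeric(nz - n))
  spec <- stats::fft(x)
  half <- nz %/% 2L
  structure(list(frequencies = (0:half) / (nz * dt),
                 complex_amplitudes = spec[1:(half + 1L)]),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("THz frequency spectrum: %d bins, 0 to %.4g THz (step %.4g THz)\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2L] - x$frequencies[1L]))
  invisible(x)
}

# One-dimensional phase unwrapping plus low-frequency anchoring. After
# unwrapping along increasing frequency the curve still carries an unknown
# integer multiple of 2*pi; a straight line is fitted over the anchor band
# and the 2*pi multiple nearest the intercept is subtracted, so that the
# extrapolation of phi(f) to f -> 0 passes through 0 (the physical phase of
# a non-dispersive slab is proportional to frequency).
anchor_phase <- function(f, phi, anchor_band = c(0.2, 0.5)) {
  sel <- f >= anchor_band[1L] & f <= anchor_band[2L]
  if (sum(sel) < 2L) sel <- seq_len(min(5L, length(f)))
  fit <- stats::lm.fit(cbind(1, f[sel]), phi[sel])
  phi - 2 * pi * round(fit$coefficients[1L] / (2 * pi))
}

#' Transfer function from sample and reference spectra
#'
#' Forms the complex ratio \eqn{H(\omega) = E_{sam}(\omega)/E_{ref}(\omega)}
#' on the requested band and splits it into the amplitude ratio
#' \eqn{\rho(\omega)} and the unwrapped phase delay \eqn{\phi(\omega)}
#' (radians, positive for an optically thick sample). The phase is unwrapped
#' along increasing frequency and anchored so that its linear extrapolation
#' to zero frequency passes through zero, removing the 2\eqn{\pi} ambiguity.
#'
#' @param sample,reference \code{"frequency_spectrum"} objects on the same
#'   grid.
#' @param band c(f_min, f_max) in THz; bins outside are dropped.
#' @param reference_floor reject the computation if any in-band reference
#'   bin has magnitude below \code{reference_floor * max|E_ref|}; those bins
#'   carry no usable signal and deconvolution there is meaningless.
#' @param anchor_band band (THz) used for the zero-frequency phase anchor.
#' @return An object of class \code{"transfer_function"} with
#'   \code{frequencies}, \code{rho} and \code{phi}.
#' @export
transfer_function <- function(sample, reference, band = c(0.2, 1.5),
                              reference_floor = 1e-4,
                              anchor_band = c(0.2, 0.5)) {
  stopifnot(inherits(sample, "frequency_spectrum"),
            inherits(reference, "frequency_spectrum"))
  if (!same_grid(sample$frequencies, reference$frequencies))
    stop_thz("sample and reference spectra must share the frequency grid")
  f <- sample$frequencies
  sel <- f >= band[1L] & f <= band[2L]
  if (!any(sel)) stop_thz("`band` contains no frequency bins")
  ref_mag <- Mod(reference$complex_amplitudes)
  floor_abs <- reference_floor * max(ref_mag)
  dead <- which(sel & ref_mag < floor_abs)
  if (length(dead) > 0L)
    stop_thz("reference magnitude below the noise floor at ", length(dead),
             " in-band bin(s): ",
             paste(utils::head(signif(f[dead], 4), 8L), collapse = ", "),
             " THz")
  ratio <- sample$complex_amplitudes[sel] / reference$complex_amplitudes[sel]
  # engineering convention: propagation delay gives a negative raw phase;
  # report phi as the positive phase delay of the sample
  phi <- -signal::unwrap(Arg(ratio))
  phi <- anchor_phase(f[sel], phi, anchor_band)
  structure(list(frequencies = f[sel], rho = Mod(ratio), phi = phi),
            class = "transfer_function")
}

#' Refractive index from the transfer-function phase
#'
#' Inverts the single-pass propagation phase:
#' \deqn{n(\omega) = 1 + \frac{\phi(\omega)\, c}{\omega\, d}.}
#'
#' @param tf a [transfer_function()].
#' @param geometry a [sample_geometry()].
#' @return Numeric vector of refractive index per in-band frequency bin.
#' @export
refractive_index <- function(tf, geometry) {
  stopifnot(inherits(tf, "transfer_function"),
            inherits(geometry, "sample_geometry"))
  if (any(tf$frequencies <= 0))
    stop_thz("the zero-frequency bin must be excluded before inversion")
  omega <- 2 * pi * tf$frequencies * 1e12
  d_m <- geometry$thickness_mm * 1e-3
  1 + tf$phi * .C_LIGHT / (omega * d_m)
}

#' Absorption coefficient from the transfer-function amplitude
#'
#' Inverts the single-pass amplitude ratio using the thick-sample
#' transmission result
#' \deqn{\alpha(\omega) = \frac{2}{d}\,
#'   \ln\!\frac{4 n(\omega)}{\rho(\omega)\,[n(\omega)+1]^2},}
#' returned in cm^-1. In noise, individual bins may come out slightly
#' negative; they are reported as-is (with a warning), not clipped, so that
#' downstream averaging stays unbiased.
#'
#' @param tf a [transfer_function()].
#' @param n refractive index per bin, e.g. from [refractive_index()].
#' @param geometry a [sample_geometry()].
#' @return Numeric vector of absorption coefficients, cm^-1.
#' @export
absorption_coefficient <- function(tf, n, geometry) {
  stopifnot(inherits(tf, "transfer_function"),
            inherits(geometry, "sample_geometry"))
  if (length(n) != length(tf$rho))
    stop_thz("`n` must have one value per transfer-function bin")
  if (any(tf$rho <= 0))
    stop_thz("`rho` must be positive everywhere (log divergence at rho = 0)")
  if (any(n <= 0)) stop_thz("`n` must be positive")
  d_cm <- geometry$thickness_mm / 10
  alpha <- (2 / d_cm) * log(4 * n / (tf$rho * (n + 1)^2))
  if (any(alpha < 0))
    warning("absorption coefficient negative at ", sum(alpha < 0),
            " bin(s); kept unclipped", call. = FALSE)
  alpha
}

#' Extract optical constants for one sample
#'
#' Convenience wrapper: averages the repeated scans, Fourier-transforms
#' sample and reference, forms the transfer function on the usable band and
#' inverts it for n and alpha.
#'
#' @param scans list of [thz_trace()] scans of one sample.
#' @param reference_trace the matching reference [thz_trace()].
#' @param geometry a [sample_geometry()].
#' @param band usable band c(f_min, f_max), THz.
#' @param zero_pad_to optional FFT padding length.
#' @param ... passed to [transfer_function()].
#' @return An \code{"optical_properties"} object on the in-band FFT grid.
#' @export
extract_sample <- function(scans, reference_trace, geometry,
                           band = c(0.2, 1.5), zero_pad_to = NULL, ...) {
  avg <- average_scans(scans)
  sam <- to_frequency(avg, zero_pad_to)
  ref <- to_frequency(reference_trace, zero_pad_to)
  tf <- transfer_function(sam, ref, band = band, ...)
  n <- refractive_index(tf, geometry)
  alpha <- absorption_coefficient(tf, n, geometry)
  structure(list(frequencies = tf$frequencies, n = n,
                 k = alpha_to_k(alpha, tf$frequencies), alpha = alpha),
            class = "optical_properties")
}

#' Extract optical constants for every sample of a dataset
#'
#' @param dataset a \code{"thz_dataset"} from [generate_dataset()] or
#'   [read_dataset()].
#' @param band usable band, THz.
#' @param ... passed to [extract_sample()].
#' @return Named list of \code{"optical_properties"}, one per sample, with
#'   the class labels attached as \code{attr(, "labels")}.
#' @export
extract_dataset <- function(dataset, band = c(0.2, 1.5), ...) {
  stopifnot(inherits(dataset, "thz_dataset"))
  out <- lapply(seq_along(dataset$traces), function(i) {
    ref <- dataset$reference_traces[[dataset$reference_index[i]]]
    extract_sample(dataset$traces[[i]], ref, dataset$geometry,
                   band = band, ...)
  })
  names(out) <- names(dataset$traces)
  attr(out, "labels") <- dataset$labels
  out
}

#' Spectra matrix container
#'
#' The chemometric input: an n_samples x n_variables matrix of one optical
#' feature on a common frequency grid, with integer class labels 1..K.
#'
#' @param X numeric matrix, samples in rows.
#' @param frequencies variable frequencies, THz (length = ncol(X)).
#' @param y integer class codes, one per row.
#' @param sample_ids optional row identifiers.
#' @param feature which feature the values are ("absorption" or
#'   "refractive_index").
#' @return An object of class \code{"spectra_matrix"}.
#' @export
spectra_matrix <- function(X, frequencies, y, sample_ids = NULL,
                           feature = "absorption") {
  X <- as.matrix(X)
  if (length(frequencies) != ncol(X))
    stop_thz("`frequencies` must have one entry per matrix column")
  if (length(y) != nrow(X))
    stop_thz("`y` must have one class code per matrix row")
  if (anyNA(X)) stop_thz("spectra matrix must not contain missing values")
  y <- as.integer(y)
  if (any(is.na(y) | y < 1L))
    stop_thz("class codes must be positive integers")
  sample_ids <- sample_ids %||% sprintf("s%03d", seq_len(nrow(X)))
  rownames(X) <- sample_ids
  structure(list(X = X, frequencies = as.numeric(frequencies), y = y,
                 sample_ids = sample_ids, feature = feature),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("Spectra matrix: %d samples x %d variables (%s), %.3g-%.3g THz, %d classes\n",
              nrow(x$X), ncol(x$X), x$feature,
              min(x$frequencies), max(x$frequencies),
              length(unique(x$y))))
  invisible(x)
}

#' @export
`[.spectra_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  spectra_matrix(x$X[i, j, drop = FALSE], x$frequencies[j], x$y[i],
                 sample_ids = x$sample_ids[i], feature = x$feature)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$X)

#' Assemble the feature matrix from extracted optical properties
#'
#' Resamples each sample's chosen feature onto a common linear grid of
#' \code{n_variables} points spanning \code{band} (endpoints inclusive,
#' linear interpolation) and stacks them into a [spectra_matrix()].
#'
#' @param samples list of \code{"optical_properties"} objects.
#' @param labels integer class codes, one per sample (taken from
#'   \code{attr(samples, "labels")} when omitted).
#' @param band c(f_min, f_max), THz; every sample must cover it.
#' @param n_variables number of frequency variables (default 128).
#' @param feature "absorption" or "refractive_index".
#' @return A [spectra_matrix()].
#' @export
build_matrix <- function(samples, labels = NULL, band = c(0.2, 1.5),
                         n_variables = 128L,
                         feature = c("absorption", "refractive_index")) {
  feature <- match.arg(feature)
  labels <- labels %||% attr(samples, "labels")
  if (is.null(labels)) stop_thz("`labels` are required")
  if (length(labels) != length(samples))
    stop_thz("`labels` must have one entry per sample")
  grid <- seq(band[1L], band[2L], length.out = as.integer(n_variables))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (min(s$frequencies) > band[1L] + 1e-12 ||
        max(s$frequencies) < band[2L] - 1e-12)
      stop_thz("sample ", i, " does not cover the band ",
               band[1L], "-", band[2L], " THz")
    vals <- if (feature == "absorption") s$alpha else s$n
    stats::approx(s$frequencies, vals, xout = grid)$y
  })
  spectra_matrix(do.call(rbind, rows), grid, labels,
                 sample_ids = names(samples), feature = feature)
}
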