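# Plain-text interchange formats: 2-column trace files, a JSON dataset
# manifest, delimited spectra matrices with a frequency header row and a
# JSON sidecar, and JSON-serialised PLS models.

#' Write / read a time-domain trace file
#'
#' Two-column whitespace-delimited text: delay (ps) and field amplitude
#' (arbitrary units), one row per sample point, no header.
#'
#' @param trace a [thz_trace()].
#' @param path file path.
#' @return \code{read_trace} returns a [thz_trace()];
#'   \code{write_trace} returns \code{path} invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "thz_trace"))
  utils::write.table(
    data.frame(delay_ps = format(trace$delays, digits = 17),
               amplitude = format(trace$amplitudes, digits = 17)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         colClasses = c("numeric", "numeric"))
  thz_trace(d[[1L]], d[[2L]])
}

#' Write a simulated dataset to disk
#'
#' One trace file per scan and per reference, plus a \code{manifest.json}
#' recording sample ids, class labels, scan and reference file paths,
#' geometry and the generating seed.
#'
#' @param dataset a \code{"thz_dataset"}.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "thz_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_files <- sprintf("ref_%03d.txt", seq_along(dataset$reference_traces))
  for (i in seq_along(dataset$reference_traces))
    write_trace(dataset$reference_traces[[i]], file.path(dir, ref_files[i]))
  samples <- lapply(seq_along(dataset$traces), function(i) {
    id <- names(dataset$traces)[i]
    scan_files <- sprintf("%s_scan%d.txt", id,
                          seq_along(dataset$traces[[i]]))
    for (s in seq_along(scan_files))
      write_trace(dataset$traces[[i]][[s]], file.path(dir, scan_files[s]))
    list(sample_id = id,
         class_id = unname(dataset$labels[i]),
         scans = scan_files,
         reference = ref_files[dataset$reference_index[i]])
  })
  manifest <- list(
    samples = samples,
    geometry = list(thickness_mm = dataset$geometry$thickness_mm,
                    diameter_mm = dataset$geometry$diameter_mm),
    seed = dataset$seed,
    n_scans = dataset$n_scans,
    instrument = unclass(dataset$instrument)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Planted-truth optical properties are not part of the interchange format,
#' so \code{$truth} is absent from a re-read dataset.
#'
#' @param dir directory containing \code{manifest.json} and trace files.
#' @return A \code{"thz_dataset"}.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ref_files <- unique(vapply(manifest$samples, function(s) s$reference, ""))
  reference_traces <- lapply(ref_files, function(f)
    read_trace(file.path(dir, f)))
  traces <- list(); labels <- integer(0); reference_index <- integer(0)
  for (s in manifest$samples) {
    traces[[s$sample_id]] <- lapply(unlist(s$scans), function(f)
      read_trace(file.path(dir, f)))
    labels[s$sample_id] <- as.integer(s$class_id)
    reference_index[s$sample_id] <- match(s$reference, ref_files)
  }
  inst <- manifest$instrument
  structure(list(
    traces = traces, reference_traces = reference_traces,
    reference_index = unname(reference_index), labels = labels,
    truth = NULL,
    geometry = sample_geometry(manifest$geometry$thickness_mm,
                               manifest$geometry$diameter_mm %||% 13),
    instrument = if (is.null(inst)) thz_instrument() else
      thz_instrument(inst$time_step, inst$n_points, inst$pulse_center,
                     inst$pulse_width, inst$amplitude_noise_sd,
                     inst$additive_noise_sd,
                     inst$dynamic_range_rolloff_freq),
    n_scans = manifest$n_scans %||% 3L,
    seed = manifest$seed %||% NA_integer_
  ), class = "thz_dataset")
}

#' Write / read a spectra matrix
#'
#' Comma-delimited text with the variable frequencies (THz) as the header
#' row; the first two columns hold sample id and class code. A JSON sidecar
#' (\code{<path>.json}) records the feature type, band and variable count.
#'
#' @param sm a [spectra_matrix()].
#' @param path CSV file path.
#' @return \code{read_spectra_matrix} returns a [spectra_matrix()].
#' @export
write_spectra_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "spectra_matrix"))
  d <- data.frame(sample_id = sm$sample_ids, class = sm$y, sm$X,
                  check.names = FALSE)
  colnames(d) <- c("sample_id", "class", format(sm$frequencies, digits = 12))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(feature = sm$feature,
         band = range(sm$frequencies),
         n_variables = ncol(sm$X),
         n_samples = nrow(sm$X)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spectra_matrix
#' @export
read_spectra_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  side_path <- paste0(path, ".json")
  feature <- if (file.exists(side_path))
    jsonlite::read_json(side_path)$feature else "absorption"
  freqs <- as.numeric(colnames(d)[-(1:2)])
  spectra_matrix(as.matrix(d[, -(1:2)]), freqs, d$class,
                 sample_ids = as.character(d$sample_id), feature = feature)
}

#' Serialise / load a fitted PLS model as JSON
#'
#' Stores everything prediction needs (means, coefficients, loadings,
#' weights, factor count) in portable JSON.
#'
#' @param model a \code{"nipals_pls"} fit.
#' @param path JSON file path.
#' @return \code{read_pls_model} returns a \code{"nipals_pls"} object.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "nipals_pls"))
  payload <- list(
    ncomp = model$ncomp, n = model$n, p = model$p,
    x_mean = unname(model$x_mean), y_mean = model$y_mean,
    coefficients = unname(model$coefficients), intercept = model$intercept,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    frequencies = model$frequencies, feature = model$feature
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = m$coefficients, intercept = m$intercept,
    x_mean = m$x_mean, y_mean = m$y_mean,
    weights = as.matrix(m$weights), x_loadings = as.matrix(m$x_loadings),
    y_loadings = m$y_loadings,
    x_scores = NULL, y_scores = NULL, x_residual = NULL,
    fitted.values = NULL, residuals = NULL, y = NULL,
    ncomp = m$ncomp, n = m$n, p = m$p,
    frequencies = m$frequencies, feature = m$feature,
    call = NULL
  ), class = "nipals_pls")
}
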