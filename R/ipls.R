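#' Partition the variable axis into equal-width intervals
#'
#' Splits \code{n_variables} consecutive variables into blocks of
#' \code{interval_width}; a remainder shorter than a full block is merged
#' into the final interval. Indices are 1-based and inclusive. 128 variables
#' at width 8 give 16 intervals, the 8th spanning variables 57--64.
#'
#' @param n_variables total number of variables.
#' @param interval_width variables per interval (1 <= width <= n_variables).
#' @return An object of class \code{"interval_spec"}: a data frame with
#'   columns \code{interval}, \code{start}, \code{end} plus attributes.
#' @examples
#' partition_intervals(128, 8)[8, ]  # variables 57-64
#' @export
partition_intervals <- function(n_variables, interval_width) {
  n_variables <- as.integer(n_variables)
  interval_width <- as.integer(interval_width)
  if (is.na(interval_width) || interval_width < 1L ||
      interval_width > n_variables)
    stop_thz("`interval_width` must be between 1 and `n_variables`")
  n_full <- n_variables %/% interval_width
  starts <- (seq_len(n_full) - 1L) * interval_width + 1L
  ends <- starts + interval_width - 1L
  ends[n_full] <- n_variables  # remainder merged into the last interval
  spec <- data.frame(interval = seq_len(n_full), start = starts, end = ends)
  structure(spec, class = c("interval_spec", "data.frame"),
            n_variables = n_variables, interval_width = interval_width)
}

#' Frequency range covered by each interval
#'
#' @param spec an [partition_intervals()] result.
#' @param variable_frequencies frequency (THz) of each variable; length must
#'   equal the partition's variable count.
#' @return Data frame with \code{f_lo} and \code{f_hi} per interval (the
#'   frequencies of the first and last member variable).
#' @export
interval_frequencies <- function(spec, variable_frequencies) {
  stopifnot(inherits(spec, "interval_spec"))
  if (length(variable_frequencies) != attr(spec, "n_variables"))
    stop_thz("`variable_frequencies` must have length ",
             attr(spec, "n_variables"))
  data.frame(interval = spec$interval,
             f_lo = variable_frequencies[spec$start],
             f_hi = variable_frequencies[spec$end])
}

#' Interval PLS (iPLS) variable selection
#'
#' Divides the spectrum into equal-width intervals, fits a PLS model with
#' leave-one-out cross-validation on each interval alone, and selects the
#' interval with the lowest RMSECV (ties go to the lowest interval index).
#' The full-spectrum model's RMSECV is included for comparison: when the
#' discriminative signal is confined to a narrow band, the best interval
#' model beats the full-spectrum model by excluding noise-only variables.
#'
#' @param X a [spectra_matrix()].
#' @param y optional numeric response (defaults to the class codes).
#' @param interval_width variables per interval.
#' @param ncomp latent factors; capped per interval at the interval width
#'   and at n-2 (NIPALS cannot extract more components than variables).
#' @return An object of class \code{"ipls_report"}: \code{table} (data frame
#'   with interval indices, frequency range, factors, RMSECV, R),
#'   \code{selected} (interval index), \code{selected_model} (the
#'   [pls_fit()] on the selected interval), \code{selected_cv},
#'   \code{full_rmsecv}, \code{full_r}, \code{spec}.
#' @export
run_ipls <- function(X, y = NULL, interval_width = 8L, ncomp = 5L) {
  stopifnot(inherits(X, "spectra_matrix"))
  spec <- partition_intervals(ncol(X$X), interval_width)
  freq <- interval_frequencies(spec, X$frequencies)
  yy <- if (is.null(y)) as.numeric(X$y) else as.numeric(y)
  n <- nrow(X$X)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    cols <- spec$start[i]:spec$end[i]
    nc <- min(ncomp, length(cols), n - 2L)
    cv <- tryCatch(loo_cv(X$X[, cols, drop = FALSE], yy, ncomp = nc),
                   error = function(e)
                     stop_thz("interval ", i, ": ", conditionMessage(e)))
    data.frame(interval = i, start = spec$start[i], end = spec$end[i],
               f_lo = freq$f_lo[i], f_hi = freq$f_hi[i], factors = nc,
               rmsecv = cv$rmsecv, r = cv$r)
  })
  tab <- do.call(rbind, rows)
  full_nc <- min(ncomp, ncol(X$X), n - 2L)
  full_cv <- loo_cv(X$X, yy, ncomp = full_nc)
  selected <- which.min(tab$rmsecv)
  sel_cols <- spec$start[selected]:spec$end[selected]
  sel_nc <- tab$factors[selected]
  sel_model <- pls_fit(X$X[, sel_cols, drop = FALSE], yy, ncomp = sel_nc)
  sel_cv <- loo_cv(X$X[, sel_cols, drop = FALSE], yy, ncomp = sel_nc)
  structure(list(table = tab, selected = selected,
                 selected_columns = sel_cols,
                 selected_model = sel_model, selected_cv = sel_cv,
                 full_rmsecv = full_cv$rmsecv, full_r = full_cv$r,
                 interval_width = as.integer(interval_width),
                 ncomp = as.integer(ncomp), spec = spec,
                 frequencies = X$frequencies),
            class = "ipls_report")
}

#' @export
print.ipls_report <- function(x, ...) {
  cat(sprintf("iPLS: %d intervals of width %d (%d factors requested)\n",
              nrow(x$table), x$interval_width, x$ncomp))
  sel <- x$table[x$selected, ]
  cat(sprintf("  selected interval %d (variables %d-%d, %.4g-%.4g THz): RMSECV = %.4f, R = %.4f\n",
              sel$interval, sel$start, sel$end, sel$f_lo, sel$f_hi,
              sel$rmsecv, sel$r))
  cat(sprintf("  full-spectrum model:  RMSECV = %.4f, R = %.4f\n",
              x$full_rmsecv, x$full_r))
  invisible(x)
}

#' Bar plot of per-interval RMSECV
#'
#' One bar per interval (height = RMSECV), the dashed horizontal line
#' showing the full-spectrum RMSECV and the selected interval highlighted.
#'
#' @param x an \code{"ipls_report"}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ipls_report <- function(x, ...) {
  cols <- rep("grey70", nrow(x$table))
  cols[x$selected] <- "grey30"
  graphics::barplot(x$table$rmsecv, names.arg = x$table$interval,
                    col = cols, xlab = "interval", ylab = "RMSECV",
                    main = sprintf("iPLS, width %d", x$interval_width), ...)
  graphics::abline(h = x$full_rmsecv, lty = 2)
  invisible(x)
}
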