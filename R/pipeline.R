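#' Default end-to-end run configuration
#'
#' The configuration mirrors the reference experimental design: 8 classes x
#' 20 samples (160 in total), 3 scans each, 1 mm pellets, a 0.2--1.5 THz
#' usable band resampled to 128 variables, 5 PLS factors, a stratified
#' 60/40 calibration/prediction split (96/64 samples) and iPLS at interval
#' widths 4, 8 and 16.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively), e.g. \code{modelling = list(factors = 7)}.
#' @return A nested list of class \code{"thz_run_config"}.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    simulation = list(
      n_per_class = 20L, seed = 101L, n_scans = 3L,
      separation = 1, signal_step = 1.5, equal_offsets = FALSE,
      signal_band = c(0.768, 0.850),
      deviation_sd = 3, n_deviation_sd = 0.01,
      instrument = list(time_step = 0.05, n_points = 1024L,
                        pulse_center = 10, pulse_width = 0.3,
                        amplitude_noise_sd = 0.01,
                        additive_noise_sd = NULL,
                        dynamic_range_rolloff_freq = 1.5),
      geometry = list(thickness = 1, diameter = 13)
    ),
    extraction = list(band = c(0.2, 1.5), n_variables = 128L),
    modelling = list(factors = 5L, calibration_fraction = 0.6,
                     interval_widths = c(4L, 8L, 16L), split_seed = 202L)
  )
  cfg <- merge_config(cfg, list(...))
  validate_run_config(cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  s <- cfg$simulation; e <- cfg$extraction; m <- cfg$modelling
  if (s$n_per_class < 2L) stop_thz("simulation$n_per_class must be >= 2")
  if (length(e$band) != 2L || e$band[1L] >= e$band[2L])
    stop_thz("extraction$band must be c(f_min, f_max) with f_min < f_max")
  if (e$n_variables < 2L) stop_thz("extraction$n_variables must be >= 2")
  if (m$factors < 1L) stop_thz("modelling$factors must be >= 1")
  if (m$calibration_fraction <= 0 || m$calibration_fraction >= 1)
    stop_thz("modelling$calibration_fraction must be in (0, 1)")
  structure(cfg, class = "thz_run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [default_run_config()]; omitted
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return A \code{"thz_run_config"}.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_run_config(merge_config(unclass(default_run_config()), user))
}

config_instrument <- function(cfg) {
  i <- cfg$simulation$instrument
  thz_instrument(i$time_step, i$n_points, i$pulse_center, i$pulse_width,
                 i$amplitude_noise_sd, i$additive_noise_sd,
                 i$dynamic_range_rolloff_freq)
}

config_profiles <- function(cfg) {
  s <- cfg$simulation
  wheat_class_profiles(separation = s$separation,
                       signal_step = s$signal_step,
                       signal_band = s$signal_band,
                       equal_offsets = isTRUE(s$equal_offsets))
}

# Full-spectrum calibration/validation metrics for one feature matrix.
evaluate_feature <- function(sm, cfg) {
  m <- cfg$modelling
  sp <- split_dataset(sm, m$calibration_fraction, seed = m$split_seed)
  fit <- pls_fit(sp$calibration, ncomp = m$factors)
  cv <- loo_cv(sp$calibration, ncomp = m$factors)
  pred <- predict(fit, sp$prediction)
  k <- length(unique(sm$y))
  cls <- assign_class(pred, K = k, labels = sp$prediction$y)
  cls_cv <- assign_class(cv$predictions, K = k, labels = sp$calibration$y)
  list(feature = sm$feature, fit = fit, split = sp,
       metrics = data.frame(
         feature = sm$feature, factors = m$factors,
         r_cal = pearson_r(fit$y, fit$fitted.values),
         rmsec = rmse(fit$y, fit$fitted.values),
         r_cv = cv$r, rmsecv = cv$rmsecv,
         rmsep = rmse(sp$prediction$y, pred),
         accuracy_cv = cls_cv$accuracy,
         accuracy_pred = cls$accuracy))
}

#' Run the full discrimination pipeline
#'
#' Orchestrates one seeded end-to-end experiment: simulate the labelled
#' dataset, extract optical constants, assemble absorption and
#' refractive-index feature matrices, split into calibration and prediction
#' sets, fit and cross-validate the full-spectrum PLS model for both
#' features, run iPLS at the configured interval widths on the
#' better-performing feature, and evaluate the selected interval model on
#' the prediction set. Deterministic given the configuration seeds.
#'
#' @param config a \code{"thz_run_config"} (see [default_run_config()] and
#'   [read_run_config()]).
#' @param out_dir optional directory; when given, the feature matrices,
#'   fitted models and the report JSON are persisted there (trace files too
#'   when \code{persist_traces}).
#' @param persist_traces write every simulated trace file (only with
#'   \code{out_dir}).
#' @param quiet suppress per-stage progress messages.
#' @return An object of class \code{"thz_run_report"}: \code{full_spectrum}
#'   (per-feature metrics data frame), \code{ipls} (list of
#'   \code{"ipls_report"} by width), \code{ipls_table} (summary rows per
#'   width, including prediction-set RMSEP of the selected interval),
#'   \code{best} (best width, interval and metrics), \code{config}.
#' @examples
#' \donttest{
#' cfg <- default_run_config(simulation = list(n_per_class = 4L))
#' rep <- run_thz_pipeline(cfg)
#' print(rep)
#' }
#' @export
run_thz_pipeline <- function(config = default_run_config(), out_dir = NULL,
                             persist_traces = FALSE, quiet = TRUE) {
  config <- validate_run_config(config)
  say <- function(...) if (!quiet) message(...)
  s <- config$simulation; e <- config$extraction; m <- config$modelling

  say("stage 1/5: simulating dataset")
  geometry <- sample_geometry(s$geometry$thickness, s$geometry$diameter)
  dataset <- generate_dataset(config_profiles(config),
                              n_per_class = s$n_per_class,
                              instrument = config_instrument(config),
                              geometry = geometry, seed = s$seed,
                              n_scans = s$n_scans,
                              deviation_sd = s$deviation_sd,
                              n_deviation_sd = s$n_deviation_sd)

  say("stage 2/5: extracting optical constants")
  # widen the deconvolution band by one FFT-grid step on each side so the
  # feature grid endpoints are interpolable, never extrapolated
  df <- 1 / (s$instrument$n_points * s$instrument$time_step)
  extract_band <- c(max(e$band[1L] - 2 * df, df), e$band[2L] + 2 * df)
  props <- extract_dataset(dataset, band = extract_band)
  sm_abs <- build_matrix(props, band = e$band, n_variables = e$n_variables,
                         feature = "absorption")
  sm_ref <- build_matrix(props, band = e$band, n_variables = e$n_variables,
                         feature = "refractive_index")

  say("stage 3/5: full-spectrum PLS for both features")
  eval_abs <- evaluate_feature(sm_abs, config)
  eval_ref <- evaluate_feature(sm_ref, config)
  full_tab <- rbind(eval_abs$metrics, eval_ref$metrics)
  best_eval <- if (eval_abs$metrics$rmsecv <= eval_ref$metrics$rmsecv)
    eval_abs else eval_ref

  say("stage 4/5: iPLS on the ", best_eval$feature, " feature")
  ipls_reports <- list()
  ipls_rows <- list()
  k <- length(unique(sm_abs$y))
  for (w in m$interval_widths) {
    rep_w <- run_ipls(best_eval$split$calibration, interval_width = w,
                      ncomp = m$factors)
    sel <- rep_w$table[rep_w$selected, ]
    pred_sel <- predict(rep_w$selected_model,
                        best_eval$split$prediction$X[, rep_w$selected_columns,
                                                     drop = FALSE])
    acc <- assign_class(pred_sel, K = k,
                        labels = best_eval$split$prediction$y)$accuracy
    ipls_reports[[as.character(w)]] <- rep_w
    ipls_rows[[as.character(w)]] <- data.frame(
      interval_width = w, n_intervals = nrow(rep_w$table),
      selected = sel$interval, f_lo = sel$f_lo, f_hi = sel$f_hi,
      factors = sel$factors, r_cv = sel$r, rmsecv = sel$rmsecv,
      rmsep = rmse(best_eval$split$prediction$y, pred_sel),
      accuracy_pred = acc,
      full_rmsecv = rep_w$full_rmsecv)
  }
  ipls_tab <- if (length(ipls_rows)) do.call(rbind, ipls_rows)
              else data.frame()
  rownames(ipls_tab) <- NULL

  best_row <- if (nrow(ipls_tab) > 0) ipls_tab[which.min(ipls_tab$rmsecv), ]
              else NULL

  say("stage 5/5: assembling report")
  report <- structure(list(
    full_spectrum = full_tab,
    best_feature = best_eval$feature,
    ipls = ipls_reports, ipls_table = ipls_tab, best = best_row,
    config = config, n_samples = nrow(sm_abs$X), n_classes = k
  ), class = "thz_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (persist_traces) write_dataset(dataset, file.path(out_dir, "traces"))
    write_spectra_matrix(sm_abs, file.path(out_dir, "X_absorption.csv"))
    write_spectra_matrix(sm_ref, file.path(out_dir, "X_refractive_index.csv"))
    write_pls_model(best_eval$fit, file.path(out_dir, "full_spectrum_model.json"))
    if (!is.null(best_row))
      write_pls_model(
        ipls_reports[[as.character(best_row$interval_width)]]$selected_model,
        file.path(out_dir, "best_interval_model.json"))
    jsonlite::write_json(
      list(full_spectrum = full_tab, ipls = ipls_tab,
           best_feature = best_eval$feature,
           config = unclass(config)),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Render a pipeline report
#'
#' Prints the full-spectrum calibration/validation table (both features)
#' and the per-width iPLS summary, and returns the underlying data frames.
#'
#' @param report a \code{"thz_run_report"}.
#' @return Invisibly, \code{list(full_spectrum, ipls)} of data frames.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "thz_run_report"))
  cat(sprintf("THz discrimination run: %d samples, %d classes\n\n",
              report$n_samples, report$n_classes))
  cat("Full-spectrum PLS (calibration set, leave-one-out CV):\n")
  print(report$full_spectrum, row.names = FALSE, digits = 4)
  if (nrow(report$ipls_table) > 0) {
    cat(sprintf("\niPLS on the %s feature:\n", report$best_feature))
    print(report$ipls_table, row.names = FALSE, digits = 4)
    cat(sprintf("\nbest configuration: width %d, interval %d (%.4g-%.4g THz), RMSECV %.4f (full spectrum %.4f)\n",
                report$best$interval_width, report$best$selected,
                report$best$f_lo, report$best$f_hi, report$best$rmsecv,
                report$best$full_rmsecv))
  } else {
    cat("\n(no interval widths configured; full-spectrum results only)\n")
  }
  invisible(list(full_spectrum = report$full_spectrum,
                 ipls = report$ipls_table))
}

#' @export
print.thz_run_report <- function(x, ...) {
  render_report(x)
  invisible(x)
}
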