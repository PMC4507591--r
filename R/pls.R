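# NIPALS PLS1 core on pre-centred data. Returns weights W, X-loadings P,
# y-loadings q, scores T and the implied regression vector(s) B. With
# all_components = TRUE, B has one column per cumulative factor count.
# Extraction stops early (ncomp_used < ncomp) when the X residual has
# numerically decorrelated from the y residual -- further components would
# only amplify rounding noise.
nipals_pls1 <- function(Xc, yc, ncomp, all_components = FALSE) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  qvec <- numeric(ncomp)
  Xa <- Xc; ya <- yc
  wn1 <- NULL
  t_scale <- NULL
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    wn <- sqrt(sum(w * w))
    if (a == 1L) {
      if (wn < 1e-300)
        stop_thz("X is entirely uncorrelated with y; no component can be extracted")
      wn1 <- wn
    }
    if (wn < 1e-10 * wn1) break
    w <- w / wn
    t_a <- Xa %*% w
    tt <- sum(t_a * t_a)
    if (a == 1L) t_scale <- tt
    if (tt < 1e-20 * t_scale) break
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    U[, a] <- ya
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; qvec[a] <- q_a
    used <- a
  }
  W <- W[, 1:used, drop = FALSE]; P <- P[, 1:used, drop = FALSE]
  Tm <- Tm[, 1:used, drop = FALSE]; U <- U[, 1:used, drop = FALSE]
  qvec <- qvec[1:used]
  if (all_components) {
    B <- matrix(0, p, used)
    for (a in seq_len(used)) {
      Wa <- W[, 1:a, drop = FALSE]; Pa <- P[, 1:a, drop = FALSE]
      B[, a] <- Wa %*% solve(crossprod(Pa, Wa), qvec[1:a])
    }
  } else {
    B <- W %*% solve(crossprod(P, W), qvec)
  }
  list(W = W, P = P, q = qvec, T = Tm, U = U, B = B, X_residual = Xa,
       ncomp_used = used)
}

# Accept either a spectra_matrix (labels as response) or a plain matrix + y.
resolve_xy <- function(X, y) {
  if (inherits(X, "spectra_matrix")) {
    list(X = X$X, y = if (is.null(y)) as.numeric(X$y) else as.numeric(y),
         frequencies = X$frequencies, feature = X$feature)
  } else {
    if (is.null(y)) stop_thz("`y` is required when `X` is a plain matrix")
    list(X = as.matrix(X), y = as.numeric(y), frequencies = NULL,
         feature = NULL)
  }
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression with a single numeric response, the
#' workhorse calibration model of spectroscopic chemometrics. Latent factors
#' are extracted one at a time by NIPALS: each weight vector maximises the
#' covariance between the X scores and the current y residual, and X is
#' deflated by the fitted rank-one term \eqn{t p^T} after every component
#' (\eqn{X = T P^T + E}, \eqn{y = T q + f}). Class discrimination uses the
#' class code 1..K directly as the numeric response; see [assign_class()]
#' for mapping predictions back to classes.
#'
#' Only mean-centering is applied (no variance scaling): spectral variables
#' share physical units, so their natural scale is informative.
#'
#' @param X a [spectra_matrix()] (its labels become the response unless
#'   \code{y} is given) or a plain numeric matrix, samples in rows.
#' @param y numeric response; defaults to the spectra matrix class codes.
#' @param ncomp number of latent factors (>= 1, <= min(n-1, p)).
#' @return An object of class \code{"nipals_pls"} with components
#'   \code{coefficients} (regression vector on centred data),
#'   \code{intercept}, \code{x_mean}, \code{y_mean}, \code{weights},
#'   \code{x_loadings}, \code{y_loadings}, \code{x_scores},
#'   \code{y_scores}, \code{fitted.values}, \code{residuals}, \code{ncomp}.
#'   Supports \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals} and \code{plot}.
#' @examples
#' sm <- simulate_spectra_matrix(wheat_class_profiles(), n_per_class = 5,
#'                               seed = 7)
#' fit <- pls_fit(sm, ncomp = 5)
#' summary(fit)
#' @export
pls_fit <- function(X, y = NULL, ncomp = 5L) {
  d <- resolve_xy(X, y)
  n <- nrow(d$X); p <- ncol(d$X)
  ncomp <- as.integer(ncomp)
  if (is.na(ncomp) || ncomp < 1L)
    stop_thz("`ncomp` must be a positive integer")
  if (ncomp > min(n - 1L, p))
    stop_thz("`ncomp` (", ncomp, ") exceeds min(n-1, p) = ", min(n - 1L, p))
  if (stats::var(d$y) == 0)
    stop_thz("the response has zero variance")
  x_mean <- colMeans(d$X)
  y_mean <- mean(d$y)
  Xc <- sweep(d$X, 2L, x_mean)
  yc <- d$y - y_mean
  core <- nipals_pls1(Xc, yc, ncomp)
  if (core$ncomp_used < ncomp) {
    warning("only ", core$ncomp_used, " of ", ncomp,
            " requested components could be extracted", call. = FALSE)
    ncomp <- core$ncomp_used
  }
  b <- drop(core$B)
  fitted <- drop(Xc %*% b) + y_mean
  structure(list(
    coefficients = b, intercept = y_mean - sum(x_mean * b),
    x_mean = x_mean, y_mean = y_mean,
    weights = core$W, x_loadings = core$P, y_loadings = core$q,
    x_scores = core$T, y_scores = core$U, x_residual = core$X_residual,
    fitted.values = fitted, residuals = d$y - fitted,
    y = d$y, ncomp = ncomp, n = n, p = p,
    frequencies = d$frequencies, feature = d$feature,
    call = match.call()
  ), class = "nipals_pls")
}

#' @export
print.nipals_pls <- function(x, ...) {
  cat(sprintf("NIPALS PLS1 model: %d factors, %d samples x %d variables\n",
              x$ncomp, x$n, x$p))
  if (!is.null(x$fitted.values))
    cat(sprintf("  RMSEC = %.4g, R = %.4g\n",
                rmse(x$y, x$fitted.values),
                pearson_r(x$y, x$fitted.values)))
  invisible(x)
}

#' @export
summary.nipals_pls <- function(object, ...) {
  tt <- colSums(object$x_scores^2)
  x_var <- tt * colSums(object$x_loadings^2)
  total_x <- sum(x_var) + sum(object$x_residual^2)
  out <- list(
    ncomp = object$ncomp, n = object$n, p = object$p,
    rmsec = rmse(object$y, object$fitted.values),
    r = pearson_r(object$y, object$fitted.values),
    x_variance_explained = x_var / total_x
  )
  class(out) <- "summary.nipals_pls"
  out
}

#' @export
print.summary.nipals_pls <- function(x, ...) {
  cat(sprintf("NIPALS PLS1: %d factors on %d samples x %d variables\n",
              x$ncomp, x$n, x$p))
  cat(sprintf("  calibration: RMSEC = %.4f, R = %.4f\n", x$rmsec, x$r))
  cat("  X variance explained per factor:\n")
  cat("   ", paste(sprintf("%.1f%%", 100 * x$x_variance_explained),
                   collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.nipals_pls <- function(object, intercept = FALSE, ...) {
  if (intercept) c(`(Intercept)` = object$intercept, object$coefficients)
  else object$coefficients
}

#' Predict from a fitted PLS model
#'
#' \eqn{\hat y = (X_{new} - \bar x) B + \bar y}.
#'
#' @param object a \code{"nipals_pls"} fit.
#' @param newdata a matrix or [spectra_matrix()] with the model's variable
#'   count; omitted returns the training fitted values.
#' @param ... unused.
#' @return Numeric vector of real-valued predictions.
#' @export
predict.nipals_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  Xn <- if (inherits(newdata, "spectra_matrix")) newdata$X else as.matrix(newdata)
  if (ncol(Xn) != object$p)
    stop_thz("`newdata` has ", ncol(Xn), " variables; the model expects ",
             object$p)
  drop(sweep(Xn, 2L, object$x_mean) %*% object$coefficients) + object$y_mean
}

#' @export
residuals.nipals_pls <- function(object, ...) object$residuals

#' @export
fitted.nipals_pls <- function(object, ...) object$fitted.values

#' Reference-vs-predicted plot of a PLS fit
#'
#' @param x a \code{"nipals_pls"} fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nipals_pls <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values,
                 xlab = "reference value", ylab = "predicted value",
                 main = sprintf("PLS1, %d factors (RMSEC %.3f)",
                                x$ncomp, rmse(x$y, x$fitted.values)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Root-mean-square error
#'
#' \eqn{\sqrt{\sum_i (y_{r,i} - y_{p,i})^2 / n}}: RMSEC on training
#' residuals, RMSECV on cross-validated predictions, RMSEP on a held-out
#' prediction set.
#'
#' @param y_ref,y_pred reference and predicted values, equal length >= 1.
#' @return Non-negative scalar in response units.
#' @examples
#' rmse(c(1, 2, 3), c(2, 2, 2))  # sqrt(2/3)
#' @export
rmse <- function(y_ref, y_pred) {
  if (length(y_ref) == 0L) stop_thz("empty input")
  if (length(y_ref) != length(y_pred))
    stop_thz("`y_ref` and `y_pred` must have equal length")
  sqrt(mean((y_ref - y_pred)^2))
}

#' Correlation between reference and predicted values
#'
#' Pearson correlation of reference and predicted responses, the R metric
#' of calibration quality.
#'
#' @param y_ref,y_pred equal-length numeric vectors, both non-constant,
#'   n >= 2.
#' @return Scalar in [-1, 1].
#' @export
pearson_r <- function(y_ref, y_pred) {
  if (length(y_ref) != length(y_pred))
    stop_thz("`y_ref` and `y_pred` must have equal length")
  if (length(y_ref) < 2L) stop_thz("need at least 2 observations")
  if (stats::sd(y_ref) == 0 || stats::sd(y_pred) == 0)
    stop_thz("correlation undefined for constant input")
  stats::cor(y_ref, y_pred)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' For each sample, fits the model on the remaining n-1 samples and predicts
#' the held-out one; RMSECV and R are computed from the assembled
#' out-of-fold predictions. LOO is deterministic: there is no randomness in
#' the fold assignment.
#'
#' @param X a [spectra_matrix()] or numeric matrix.
#' @param y numeric response (defaults to spectra-matrix class codes).
#' @param ncomp latent factors per fold.
#' @return An object of class \code{"pls_cv"}: \code{predictions},
#'   \code{rmsecv}, \code{r}, \code{y}, \code{ncomp}.
#' @export
loo_cv <- function(X, y = NULL, ncomp = 5L) {
  d <- resolve_xy(X, y)
  n <- nrow(d$X)
  if (n < 3L) stop_thz("leave-one-out needs at least 3 samples")
  ncomp <- as.integer(ncomp)
  if (ncomp > min(n - 2L, ncol(d$X)))
    stop_thz("`ncomp` too large for leave-one-out on ", n, " samples")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- d$X[-i, , drop = FALSE]
    yi <- d$y[-i]
    x_mean <- colMeans(Xi)
    y_mean <- mean(yi)
    core <- tryCatch(
      nipals_pls1(sweep(Xi, 2L, x_mean), yi - y_mean, ncomp),
      error = function(e) stop_thz("fold ", i, ": ", conditionMessage(e))
    )
    preds[i] <- sum((d$X[i, ] - x_mean) * core$B) + y_mean
  }
  structure(list(predictions = preds, rmsecv = rmse(d$y, preds),
                 r = pearson_r(d$y, preds), y = d$y, ncomp = ncomp, n = n),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV (%d samples, %d factors): RMSECV = %.4f, R = %.4f\n",
              x$n, x$ncomp, x$rmsecv, x$r))
  invisible(x)
}

#' Map real-valued predictions to class codes
#'
#' A prediction is assigned to the nearest class code in 1..K (round half
#' up), with values below 1 and above K clamped to the extreme classes:
#' prediction bands 0.5--1.5, 1.5--2.5, ... correspond to classes 1, 2, ...
#'
#' @param predictions numeric predictions from a class-coded PLS model.
#' @param K number of classes (>= 2).
#' @param labels optional true class codes; when given, the classification
#'   accuracy (fraction correct) is returned alongside.
#' @return List with \code{class} (integer vector) and \code{accuracy}
#'   (scalar, or NULL when \code{labels} is missing).
#' @examples
#' assign_class(c(1.28, 3.0, 8.7), K = 8)$class  # 1 3 8
#' @export
assign_class <- function(predictions, K, labels = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop_thz("`K` must be an integer >= 2")
  cls <- as.integer(pmin(pmax(floor(predictions + 0.5), 1L), K))
  acc <- NULL
  if (!is.null(labels)) {
    if (length(labels) != length(predictions))
      stop_thz("`labels` must match `predictions` in length")
    acc <- mean(cls == as.integer(labels))
  }
  list(class = cls, accuracy = acc)
}

#' Stratified calibration/prediction split
#'
#' Randomly splits a labelled spectra matrix into a calibration and a
#' prediction set, stratified by class so both sets keep the class balance
#' (e.g. 160 samples at fraction 0.6 give the classic 96/64 split).
#'
#' @param X a [spectra_matrix()].
#' @param calibration_fraction fraction of each class assigned to the
#'   calibration set (0 < f < 1).
#' @param seed integer seed; the split is reproducible from it.
#' @return List with \code{calibration} and \code{prediction}, both
#'   [spectra_matrix()] objects.
#' @export
split_dataset <- function(X, calibration_fraction = 0.6, seed = 1) {
  stopifnot(inherits(X, "spectra_matrix"))
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop_thz("`calibration_fraction` must be strictly between 0 and 1")
  idx_cal <- with_seed(seed, {
    unlist(lapply(sort(unique(X$y)), function(cl) {
      members <- which(X$y == cl)
      n_cal <- round(calibration_fraction * length(members))
      if (n_cal < 2L || length(members) - n_cal < 2L)
        stop_thz("class ", cl, " would have fewer than 2 samples in one set")
      sort(sample(members, n_cal))
    }))
  })
  idx_cal <- sort(idx_cal)
  list(calibration = X[idx_cal, ],
       prediction = X[setdiff(seq_len(nrow(X$X)), idx_cal), ])
}

#' Choose the factor count by minimum RMSECV
#'
#' Scans 1..\code{ncomp_max} latent factors and reports the leave-one-out
#' RMSECV of each, selecting the minimum. Each fold is fitted once at
#' \code{ncomp_max}; predictions for smaller factor counts reuse the same
#' NIPALS decomposition.
#'
#' @param X a [spectra_matrix()] or matrix.
#' @param y optional numeric response.
#' @param ncomp_max largest factor count scanned (default 15, capped at
#'   min(n-2, p)).
#' @return List with \code{rmsecv} (vector over factor counts) and
#'   \code{best} (the factor count attaining the minimum; ties go to the
#'   smaller count).
#' @export
select_factors <- function(X, y = NULL, ncomp_max = 15L) {
  d <- resolve_xy(X, y)
  n <- nrow(d$X)
  ncomp_max <- min(as.integer(ncomp_max), n - 2L, ncol(d$X))
  preds <- matrix(0, n, ncomp_max)
  for (i in seq_len(n)) {
    Xi <- d$X[-i, , drop = FALSE]
    yi <- d$y[-i]
    x_mean <- colMeans(Xi)
    y_mean <- mean(yi)
    core <- nipals_pls1(sweep(Xi, 2L, x_mean), yi - y_mean, ncomp_max,
                        all_components = TRUE)
    pr <- drop((d$X[i, ] - x_mean) %*% core$B) + y_mean
    nb <- length(pr)
    preds[i, ] <- if (nb < ncomp_max) c(pr, rep(pr[nb], ncomp_max - nb)) else pr
  }
  rmsecv <- apply(preds, 2L, function(p) rmse(d$y, p))
  list(rmsecv = stats::setNames(rmsecv, seq_len(ncomp_max)),
       best = which.min(rmsecv))
}
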