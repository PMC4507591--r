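# Internal helpers shared across modules.

# speed of light, m/s
.C_LIGHT <- 299792458

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_thz <- function(...) stop(..., call. = FALSE)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Uniform-spacing check with relative tolerance.
is_uniform <- function(x, rtol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  step <- d[1L]
  step > 0 && all(abs(d - step) <= rtol * abs(step))
}

# Checks two numeric grids agree bin-by-bin.
same_grid <- function(a, b, rtol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= rtol * pmax(abs(a), abs(b), 1e-300))
}

# Raised-cosine bump confined to [band[1], band[2]], peak 1 at the centre,
# identically zero outside the band.
raised_cosine_bump <- function(f, band) {
  centre <- mean(band)
  width <- diff(band)
  out <- numeric(length(f))
  inside <- f > band[1L] & f < band[2L]
  out[inside] <- 0.5 * (1 + cos(2 * pi * (f[inside] - centre) / width))
  out
}

# Smooth random curve on a frequency grid: cosine series with independent
# normal coefficients whose SD decays as 1/(m+1), giving a smooth but
# effectively high-dimensional deviation (a handful of latent factors
# cannot project it out). `sd` is the approximate pointwise SD.
# `span` is an absolute frequency scale in THz (not the grid extent), so
# the same draw statistics apply whatever grid the curve is evaluated on.
smooth_deviation <- function(f, sd, n_terms = 12L, span = 2) {
  if (sd <= 0) return(numeric(length(f)))
  lo <- 0
  m <- seq_len(n_terms) - 1L
  decay <- 1 / (m + 1)
  # pointwise variance: var(a_0) + sum_{m>0} var(a_m) * mean(cos^2) and
  # mean(cos^2) = 1/2 over a full period
  w <- ifelse(m == 0L, 1, 0.5)
  scale <- sd / sqrt(sum(decay^2 * w))
  coef <- stats::rnorm(n_terms, 0, scale * decay)
  basis <- vapply(m, function(mm) cos(pi * mm * (f - lo) / span),
                  numeric(length(f)))
  drop(basis %*% coef)
}

# Extinction coefficient from absorption: k = alpha * c / (2 * omega),
# alpha in cm^-1, f in THz; k is 0 at f = 0 by convention.
alpha_to_k <- function(alpha_cm, f_thz) {
  omega <- 2 * pi * f_thz * 1e12
  k <- ifelse(omega > 0, (alpha_cm * 100) * .C_LIGHT / (2 * omega), 0)
  k
}
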