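## Spectral pre-treatments. Each operator accepts either a bare numeric
## vector (one spectrum; axis spacing passed explicitly where it matters)
## or a spectra_set, in which case it is applied row-wise and a spectra_set
## is returned. Set-level (fitted) operators live in treatments.R.

.check_sg_args <- function(n, window, polyorder) {
  if (window %% 2 == 0) stop("'window' must be odd", call. = FALSE)
  if (window < polyorder + 2)
    stop("'window' must be at least polyorder + 2", call. = FALSE)
  if (window > n)
    stop("'window' exceeds the number of spectral points", call. = FALSE)
}

.rowwise <- function(set, f) {
  out <- t(apply(set$matrix, 1L, f))
  spectra_set(out, set$grid, sample_id = set$meta$sample_id,
              replicate = set$meta$replicate,
              breed = set$meta$breed, sex = set$meta$sex)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing (treatment code `SM`). Exact on
#' polynomials of degree `<= polyorder`, including at the spectrum edges,
#' where the shrinking-window transient fit of the Savitzky-Golay projection
#' matrix is used so the output keeps full length.
#'
#' @param x Numeric spectrum or a [spectra_set()] (applied per row).
#' @param window Odd window length (points); default 11.
#' @param polyorder Polynomial order; default 2.
#' @return Same shape as the input.
#' @export
sg_smooth <- function(x, window = 11, polyorder = 2) {
  if (inherits(x, "spectra_set"))
    return(.rowwise(x, function(v) sg_smooth(v, window, polyorder)))
  .check_sg_args(length(x), window, polyorder)
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window, m = 0))
}

#' Savitzky-Golay derivative
#'
#' First or second derivative with respect to the wavenumber axis
#' (treatment codes `DV1`, `DV2`). The derivative is scaled by the grid
#' spacing so units are absorbance per cm^-1 (or per cm^-1 squared).
#'
#' @inheritParams sg_smooth
#' @param order Derivative order, 1 or 2.
#' @param spacing Axis spacing; taken from the grid for a `spectra_set`.
#' @return Same shape as the input.
#' @export
sg_derivative <- function(x, order, window = 11, polyorder = 2, spacing = 1) {
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2", call. = FALSE)
  if (polyorder < order)
    stop("'polyorder' must be >= the derivative order", call. = FALSE)
  if (inherits(x, "spectra_set")) {
    sp <- x$grid$spacing
    return(.rowwise(x, function(v) sg_derivative(v, order, window,
                                                 polyorder, sp)))
  }
  .check_sg_args(length(x), window, polyorder)
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window, m = order,
                                ts = spacing))
}

#' Unit-area normalization
#'
#' Divides a spectrum by its trapezoidal integral over the wavenumber axis
#' (treatment code `NORM`), so the returned spectrum integrates to exactly
#' one. Idempotent.
#'
#' @inheritParams sg_derivative
#' @return Same shape as the input.
#' @export
norm_unit_area <- function(x, spacing = 1) {
  if (inherits(x, "spectra_set")) {
    sp <- x$grid$spacing
    return(.rowwise(x, function(v) norm_unit_area(v, sp)))
  }
  area <- trapz_integral(x, spacing)
  if (abs(area) < 1e-12)
    stop("spectrum has (near-)zero area; cannot normalize", call. = FALSE)
  x / area
}

#' Trapezoidal integral on a uniform axis
#' @param x Numeric vector.
#' @param spacing Axis spacing.
#' @return The integral (scalar).
#' @export
trapz_integral <- function(x, spacing = 1) {
  n <- length(x)
  spacing * (sum(x) - (x[1L] + x[n]) / 2)
}

#' Standard normal variate transform
#'
#' Per-spectrum standardization (treatment code `SNV`): subtract the
#' spectrum mean and divide by its standard deviation (n - 1 denominator).
#' Removes additive offsets and multiplicative gain; the output has mean 0
#' and unit standard deviation.
#'
#' @inheritParams sg_smooth
#' @return Same shape as the input.
#' @export
snv <- function(x) {
  if (inherits(x, "spectra_set")) return(.rowwise(x, snv))
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop("constant spectrum: SNV undefined (zero variance)", call. = FALSE)
  (x - mean(x)) / s
}

#' Asymmetric least squares baseline
#'
#' Whittaker-smoother baseline estimation with asymmetric residual weights:
#' the baseline z minimizes sum(w * (x - z)^2) + lam * sum(diff(z, 2)^2),
#' with w = `p` where x > z and `1 - p` otherwise, re-estimated over
#' `n_iter` reweighting passes. With small `p` the baseline hugs the lower
#' envelope of an absorbance spectrum, leaving peaks in the corrected
#' signal.
#'
#' @param x Numeric spectrum or a [spectra_set()].
#' @param lam Smoothness penalty (> 0) on the squared second differences.
#' @param p Asymmetry in (0, 1); weight given to points above the baseline.
#' @param n_iter Number of reweighting iterations (>= 1).
#' @return For a vector, a list with `baseline` and `corrected` (both the
#'   input length); for a `spectra_set`, the baseline-corrected set.
#' @export
als_baseline <- function(x, lam = 1e5, p = 0.01, n_iter = 10) {
  if (lam <= 0) stop("'lam' must be positive", call. = FALSE)
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)", call. = FALSE)
  if (n_iter < 1) stop("'n_iter' must be >= 1", call. = FALSE)
  if (inherits(x, "spectra_set"))
    return(.rowwise(x, function(v) als_baseline(v, lam, p, n_iter)$corrected))
  n <- length(x)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, n)
  z <- x
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + lam * DtD, w * x))
    w <- ifelse(x > z, p, 1 - p)
  }
  list(baseline = z, corrected = x - z)
}

#' Multiplicative scatter correction
#'
#' Regresses every spectrum on a reference spectrum by ordinary least
#' squares, x ~ a + b * ref, and returns (x - a) / b (treatment code
#' `MSC`). With `reference = "mean"` the reference is the column mean of
#' the rows in `fit_rows` — at prediction time pass the stored calibration
#' reference so no test information leaks into the fit.
#'
#' @param set A [spectra_set()].
#' @param reference `"mean"` or a numeric reference spectrum on the same
#'   grid.
#' @param fit_rows Rows used to form the mean reference (default: all).
#' @return The corrected `spectra_set`, with the reference spectrum
#'   attached as attribute `"msc_reference"`.
#' @export
msc <- function(set, reference = "mean", fit_rows = seq_len(nrow(set$matrix))) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.character(reference) && identical(reference, "mean")) {
    ref <- colMeans(set$matrix[fit_rows, , drop = FALSE])
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != set$grid$n_points)
      stop("reference length does not match the grid", call. = FALSE)
  }
  out <- t(apply(set$matrix, 1L, msc_correct, ref = ref))
  res <- spectra_set(out, set$grid, sample_id = set$meta$sample_id,
                     replicate = set$meta$replicate,
                     breed = set$meta$breed, sex = set$meta$sex)
  attr(res, "msc_reference") <- ref
  res
}

#' Correct a single spectrum against an MSC reference
#' @param x Numeric spectrum.
#' @param ref Reference spectrum of the same length.
#' @return The corrected spectrum (x - intercept) / slope.
#' @export
msc_correct <- function(x, ref) {
  b <- stats::cov(ref, x) / stats::var(ref)
  if (!is.finite(b) || abs(b) < 1e-12)
    stop("degenerate MSC fit: slope versus the reference is ~0",
         call. = FALSE)
  a <- mean(x) - b * mean(ref)
  (x - a) / b
}

#' Decimate a spectrum to every k-th point
#'
#' Variable reduction by keeping indices 1, 1 + k, 1 + 2k, ... (the first
#' point is always retained); the grid spacing is multiplied by `keep_every`.
#' With the default 1501-point grid and `keep_every = 10` this reduces a
#' spectrum to 151 points (10% of the variables).
#'
#' @param x A [spectra_set()] or numeric spectrum.
#' @param keep_every Positive integer stride.
#' @param spacing Axis spacing (vector input only).
#' @return Decimated object of the same kind. For a numeric vector the
#'   decimated values are returned; for a `spectra_set` the grid is updated.
#' @export
decimate <- function(x, keep_every = 10, spacing = 1) {
  keep_every <- as.integer(keep_every)
  if (keep_every < 1) stop("'keep_every' must be >= 1", call. = FALSE)
  if (inherits(x, "spectra_set")) {
    idx <- seq(1L, x$grid$n_points, by = keep_every)
    wn <- x$grid$wavenumbers[idx]
    grid <- if (length(idx) > 1L) as_wavenumber_grid(wn) else
      stop("decimation left fewer than 2 points", call. = FALSE)
    return(spectra_set(x$matrix[, idx, drop = FALSE], grid,
                       sample_id = x$meta$sample_id,
                       replicate = x$meta$replicate,
                       breed = x$meta$breed, sex = x$meta$sex))
  }
  x[seq(1L, length(x), by = keep_every)]
}
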