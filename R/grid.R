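#' Uniform wavenumber grid
#'
#' Constructs the wavenumber axis on which all spectra in a set live: an
#' ascending, uniformly spaced sequence in reciprocal centimetres. The
#' default corresponds to an FT-NIR instrument scanning 4000 to 10000 cm^-1
#' at 4 cm^-1 resolution (1501 points).
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1); must exceed `start`.
#' @param spacing Grid spacing (cm^-1); must be positive and divide
#'   `stop - start` exactly (to within floating-point tolerance).
#' @return An object of class `wavenumber_grid`: a list with elements
#'   `start`, `stop`, `spacing`, `n_points` and the full axis `wavenumbers`.
#' @examples
#' g <- wavenumber_grid()
#' g$n_points  # 1501
#' @export
wavenumber_grid <- function(start = 4000, stop = 10000, spacing = 4) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(spacing),
            length(start) == 1L, length(stop) == 1L, length(spacing) == 1L)
  if (spacing <= 0)
    stop("grid spacing must be positive", call. = FALSE)
  if (stop <= start)
    stop("grid 'stop' must exceed 'start'", call. = FALSE)
  n_float <- (stop - start) / spacing + 1
  n <- round(n_float)
  if (abs(n_float - n) > 1e-8)
    stop("spacing does not divide the range: (stop - start)/spacing ",
         "must be an integer", call. = FALSE)
  structure(
    list(start = start, stop = stop, spacing = spacing,
         n_points = as.integer(n),
         wavenumbers = seq(start, stop, length.out = n)),
    class = "wavenumber_grid"
  )
}

#' Build a grid from an explicit wavenumber axis
#'
#' Validates that the supplied axis is ascending and uniformly spaced and
#' wraps it as a [wavenumber_grid()].
#'
#' @param wn Numeric vector of wavenumbers (cm^-1).
#' @param tol Relative tolerance on spacing uniformity.
#' @return A `wavenumber_grid`.
#' @export
as_wavenumber_grid <- function(wn, tol = 1e-6) {
  wn <- as.numeric(wn)
  if (length(wn) < 2L) stop("need at least 2 wavenumbers", call. = FALSE)
  d <- diff(wn)
  if (any(d <= 0)) stop("wavenumbers must be strictly ascending", call. = FALSE)
  sp <- d[1L]
  if (any(abs(d - sp) > tol * sp))
    stop("non-uniform wavenumber spacing", call. = FALSE)
  wavenumber_grid(wn[1L], wn[length(wn)], sp)
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("Wavenumber grid: %g to %g cm^-1, spacing %g cm^-1 (%d points)\n",
              x$start, x$stop, x$spacing, x$n_points))
  invisible(x)
}

#' @export
format.wavenumber_grid <- function(x, ...) {
  sprintf("[%g..%g @ %g cm^-1]", x$start, x$stop, x$spacing)
}

grids_equal <- function(a, b, tol = 1e-8) {
  a$n_points == b$n_points &&
    abs(a$start - b$start) < tol &&
    abs(a$spacing - b$spacing) < tol
}
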