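#' @title Treatment chains
#' @description Pre-treatment chains are named by hyphen-joined codes, e.g.
#'   `"SNV-DV1"` or `"MSC-SM"`, applied left to right. Vocabulary:
#'   `SM` (Savitzky-Golay smoothing), `NORM` (unit-area normalization),
#'   `ALS` (asymmetric least squares baseline removal), `MSC`
#'   (multiplicative scatter correction), `SNV` (standard normal variate),
#'   `DV1`/`DV2` (first/second Savitzky-Golay derivative).
#' @name treatments
NULL

.treatment_codes <- c("SM", "NORM", "ALS", "MSC", "SNV", "DV1", "DV2")

#' Parse a treatment specification
#'
#' @param spec Either a character scalar of hyphen-joined codes
#'   (`"SNV-DV1"`) or a character vector of codes.
#' @return Character vector of validated codes, class `treatment_spec`.
#' @export
treatment_spec <- function(spec) {
  if (inherits(spec, "treatment_spec")) return(spec)
  codes <- if (length(spec) == 1L) strsplit(spec, "-", fixed = TRUE)[[1L]]
           else as.character(spec)
  codes <- toupper(trimws(codes))
  if (length(codes) == 0L || any(!nzchar(codes)))
    stop("empty treatment specification", call. = FALSE)
  bad <- setdiff(codes, .treatment_codes)
  if (length(bad))
    stop("unknown treatment code(s): ", paste(bad, collapse = ", "),
         "; known codes are ", paste(.treatment_codes, collapse = ", "),
         call. = FALSE)
  structure(codes, class = "treatment_spec")
}

#' @export
format.treatment_spec <- function(x, ...) paste(unclass(x), collapse = "-")

#' @export
print.treatment_spec <- function(x, ...) {
  cat("Treatment:", format(x), "\n")
  invisible(x)
}

#' Default numeric settings for the treatment operators
#'
#' @param window,polyorder Savitzky-Golay window and polynomial order used
#'   by `SM`, `DV1` and `DV2`.
#' @param als_lam,als_p,als_n_iter Asymmetric least squares settings.
#' @return Named list of settings.
#' @export
treatment_control <- function(window = 11, polyorder = 2,
                              als_lam = 1e5, als_p = 0.01, als_n_iter = 10) {
  list(window = window, polyorder = polyorder,
       als_lam = als_lam, als_p = als_p, als_n_iter = als_n_iter)
}

#' Apply a treatment chain to a spectra set
#'
#' Applies the codes of `spec` left to right. Data-dependent operators
#' (currently the MSC mean reference) are fitted on `fit_rows` only and
#' then applied to every row, so a calibration/prediction split never leaks
#' prediction rows into fitted parameters.
#'
#' @param set A [spectra_set()].
#' @param spec A [treatment_spec()] or its string form.
#' @param fit_rows Row indices used to fit data-dependent operators
#'   (default: all rows).
#' @param control Operator settings from [treatment_control()].
#' @return The treated `spectra_set`, with attribute `"fitted"`: a list,
#'   one entry per chain position, holding any fitted parameters (e.g. the
#'   MSC reference spectrum).
#' @export
apply_treatment <- function(set, spec, fit_rows = seq_len(nrow(set$matrix)),
                            control = treatment_control()) {
  stopifnot(inherits(set, "spectra_set"))
  spec <- treatment_spec(spec)
  fitted <- vector("list", length(spec))
  names(fitted) <- unclass(spec)
  for (i in seq_along(spec)) {
    code <- spec[[i]]
    set <- switch(
      code,
      SM   = sg_smooth(set, control$window, control$polyorder),
      NORM = norm_unit_area(set),
      ALS  = als_baseline(set, control$als_lam, control$als_p,
                          control$als_n_iter),
      SNV  = snv(set),
      DV1  = sg_derivative(set, 1L, control$window, control$polyorder),
      DV2  = sg_derivative(set, 2L, control$window,
                           max(control$polyorder, 2L)),
      MSC  = {
        res <- msc(set, reference = "mean", fit_rows = fit_rows)
        fitted[[i]] <- list(msc_reference = attr(res, "msc_reference"))
        res
      }
    )
  }
  attr(set, "fitted") <- fitted
  set
}
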