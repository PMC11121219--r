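#' Regression performance report
#'
#' Calibration diagnostics in the convention of NIR model validation:
#' RMSE of prediction, plus the ordinary least squares regression of the
#' predicted on the observed values — slope and intercept with their
#' standard deviations and two-sided t-tests (both against zero; the slope
#' is additionally tested against one), the coefficient of determination of
#' that regression, and the relative standard error (residual standard
#' error divided by the observation mean). The ideal model attains
#' RMSE 0, R2 1, slope 1 and intercept 0.
#'
#' @param y_true Observed values (>= 3).
#' @param y_pred Predicted values, aligned with `y_true`.
#' @param group `"train"` or `"test"`.
#' @return An object of class `regression_report`: a list with `group`,
#'   `n`, `rmse`, `r2`, `slope`, `slope_sd`, `slope_p` (vs 0),
#'   `slope_p_vs1` (vs 1), `intercept`, `intercept_sd`, `intercept_p`,
#'   `intercept_ns` (logical, p > 0.05) and `rse`.
#' @export
evaluate_regression <- function(y_true, y_pred, group = c("train", "test")) {
  group <- match.arg(group)
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' differ in length", call. = FALSE)
  n <- length(y_true)
  if (n < 3) stop("need at least 3 observation pairs", call. = FALSE)
  if (stats::var(y_true) < 1e-15)
    stop("zero variance in observed values: R2 undefined", call. = FALSE)
  rmse <- sqrt(mean((y_true - y_pred)^2))
  fit <- stats::lm(y_pred ~ y_true)
  ## summary.lm warns on an exactly perfect fit; that is a legitimate
  ## input here (the ideal-model fixed point)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope <- cf["y_true", "Estimate"]
  slope_sd <- cf["y_true", "Std. Error"]
  slope_p <- cf["y_true", "Pr(>|t|)"]
  slope_p_vs1 <- 2 * stats::pt(abs((slope - 1) / slope_sd),
                               df = n - 2, lower.tail = FALSE)
  intercept <- cf["(Intercept)", "Estimate"]
  intercept_sd <- cf["(Intercept)", "Std. Error"]
  intercept_p <- cf["(Intercept)", "Pr(>|t|)"]
  structure(
    list(group = group, n = n, rmse = rmse,
         r2 = sm$r.squared,
         slope = slope, slope_sd = slope_sd, slope_p = slope_p,
         slope_p_vs1 = slope_p_vs1,
         intercept = intercept, intercept_sd = intercept_sd,
         intercept_p = intercept_p,
         intercept_ns = is.na(intercept_p) || intercept_p > 0.05,
         rse = sm$sigma / mean(y_true)),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, digits_rmse = 3, digits_r2 = 4, ...) {
  int <- if (x$intercept_ns) "ns" else
    sprintf("%.3f ± %.3f", x$intercept, x$intercept_sd)
  cat(sprintf("%s (n=%d): RMSE %.*f  R2 %.*f  slope %.3f ± %.3f  intercept %s\n",
              x$group, x$n, digits_rmse, x$rmse, digits_r2, x$r2,
              x$slope, x$slope_sd, int))
  invisible(x)
}

#' Classification performance report
#'
#' Replicate-level accuracy plus per-class sensitivity and specificity from
#' the confusion counts.
#'
#' @param labels_true Observed class labels.
#' @param labels_pred Predicted class labels, aligned.
#' @param group `"train"` or `"test"`.
#' @return An object of class `classification_report`: list with `group`,
#'   `n`, `accuracy` (percent), `accuracy_1dp` (rounded to one decimal for
#'   reporting), `confusion` (true x predicted table), `sensitivity` and
#'   `specificity` (named percent vectors, one per class).
#' @export
evaluate_classification <- function(labels_true, labels_pred,
                                    group = c("train", "test")) {
  group <- match.arg(group)
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length", call. = FALSE)
  lev <- sort(unique(c(as.character(labels_true), as.character(labels_pred))))
  tt <- factor(as.character(labels_true), levels = lev)
  pp <- factor(as.character(labels_pred), levels = lev)
  cm <- table(true = tt, predicted = pp)
  n <- length(tt)
  acc <- 100 * sum(diag(cm)) / n
  sens <- vapply(lev, function(cl) {
    pos <- tt == cl
    if (!any(pos)) return(NA_real_)
    100 * sum(pp[pos] == cl) / sum(pos)
  }, numeric(1L))
  spec <- vapply(lev, function(cl) {
    neg <- tt != cl
    if (!any(neg)) return(NA_real_)
    100 * sum(pp[neg] != cl) / sum(neg)
  }, numeric(1L))
  structure(
    list(group = group, n = n, accuracy = acc,
         accuracy_1dp = round(acc, 1), confusion = cm,
         sensitivity = sens, specificity = spec),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s (n=%d spectra): accuracy %.1f%%\n", x$group, x$n,
              x$accuracy))
  for (cl in names(x$sensitivity))
    cat(sprintf("  %s: sensitivity %.1f%%, specificity %.1f%%\n",
                cl, x$sensitivity[cl], x$specificity[cl]))
  invisible(x)
}

#' Model-selection thresholds
#'
#' The acceptance gates applied to candidate calibration models: the
#' calibration fit must reach both R2 and slope above 0.95; among the
#' survivors the model with the lowest prediction RMSE is chosen, provided
#' its prediction R2 exceeds 0.90 (ties on RMSE go to the higher
#' prediction R2, then the higher slope).
#'
#' @param r2_train_min,slope_train_min,r2_test_min Thresholds in (0, 1].
#' @return Named list of thresholds.
#' @export
model_selection_criteria <- function(r2_train_min = 0.95,
                                     slope_train_min = 0.95,
                                     r2_test_min = 0.90) {
  vals <- c(r2_train_min, slope_train_min, r2_test_min)
  if (any(vals <= 0) || any(vals > 1))
    stop("selection thresholds must lie in (0, 1]", call. = FALSE)
  list(r2_train_min = r2_train_min, slope_train_min = slope_train_min,
       r2_test_min = r2_test_min)
}

#' Select the best calibration model across treatments
#'
#' @param candidates Data frame with one row per candidate (treatment x
#'   cost), columns `treatment`, `best_C`, `rmse_train`, `r2_train`,
#'   `slope_train`, `rmse_test`, `r2_test` (extra columns pass through).
#' @param criteria From [model_selection_criteria()].
#' @return The chosen candidate row (data frame with one row), or `NULL`
#'   when no candidate passes the gates.
#' @export
select_best_model <- function(candidates,
                              criteria = model_selection_criteria()) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("'candidates' is empty", call. = FALSE)
  ok <- candidates$r2_train >= criteria$r2_train_min &
        candidates$slope_train >= criteria$slope_train_min &
        candidates$r2_test > criteria$r2_test_min
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NULL)
  pool <- candidates[ok, , drop = FALSE]
  ord <- order(pool$rmse_test, -pool$r2_test,
               -if ("slope_test" %in% names(pool)) pool$slope_test
                else pool$slope_train)
  pool[ord[1L], , drop = FALSE]
}
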