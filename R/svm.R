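## Linear SVM calibration (regression) and discrimination (classification).
## Feature columns are z-scored with calibration-set statistics inside the
## fit functions; regression targets are standardized as well so the
## epsilon tube has a common meaning across dependent variables. All
## fitted scalings are stored in the model object and undone at prediction.

.fit_scaling <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1  # constant feature: leave centered at 0
  list(center = ctr, scale = scl)
}

.apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

#' Fit a linear support vector regression model
#'
#' Epsilon-insensitive linear SVR. Features are standardized with the
#' calibration statistics; the target is standardized too, so `epsilon` is
#' expressed in target standard deviations. Predictions are returned on
#' the original target scale and are an affine function of the features.
#'
#' @param X Calibration feature matrix (rows = spectra).
#' @param y Numeric target, one value per row of `X`.
#' @param C Cost parameter (> 0).
#' @param epsilon Width of the insensitivity tube on the standardized
#'   target (>= 0); default 0.1.
#' @return An object of class `linear_svr` with a [predict][stats::predict]
#'   method.
#' @export
fit_linear_svr <- function(X, y, C = 1, epsilon = 0.1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 calibration rows", call. = FALSE)
  if (C <= 0) stop("'C' must be positive", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  sc <- .fit_scaling(X)
  y_ctr <- mean(y)
  y_scl <- stats::sd(y)
  if (!is.finite(y_scl) || y_scl < 1e-12) {
    ## constant target: every residual sits inside the tube, the optimum
    ## is the flat function at the target value
    return(structure(list(fit = NULL, scaling = sc, y_center = y_ctr,
                          y_scale = 1, C = C, epsilon = epsilon),
                     class = "linear_svr"))
  }
  fit <- e1071::svm(.apply_scaling(X, sc), (y - y_ctr) / y_scl,
                    type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = epsilon, scale = FALSE)
  structure(list(fit = fit, scaling = sc, y_center = y_ctr, y_scale = y_scl,
                 C = C, epsilon = epsilon),
            class = "linear_svr")
}

#' @export
predict.linear_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(object$fit))
    return(rep(object$y_center, nrow(newdata)))
  z <- stats::predict(object$fit, .apply_scaling(newdata, object$scaling))
  as.numeric(z) * object$y_scale + object$y_center
}

#' Tune the SVR cost parameter
#'
#' Fits the model for every cost in `C_grid` on the calibration rows and
#' returns the grid member with the lowest calibration RMSE; ties go to
#' the smallest cost.
#'
#' @inheritParams fit_linear_svr
#' @param C_grid Numeric vector of candidate costs; default
#'   `c(1, 10, 30, 100)`.
#' @return List with `best_C`, and `rmse` named by cost.
#' @export
tune_C <- function(X, y, C_grid = c(1, 10, 30, 100), epsilon = 0.1) {
  if (length(C_grid) == 0) stop("'C_grid' must be non-empty", call. = FALSE)
  C_grid <- sort(unique(C_grid))
  rmse <- vapply(C_grid, function(C) {
    m <- fit_linear_svr(X, y, C = C, epsilon = epsilon)
    sqrt(mean((y - predict(m, X))^2))
  }, numeric(1L))
  names(rmse) <- C_grid
  ## ties at the minimum go to the smallest C (grid is sorted ascending)
  best <- C_grid[which(rmse <= min(rmse) + 1e-12)[1L]]
  list(best_C = best, rmse = rmse)
}

#' Fit a linear support vector classifier
#'
#' Maximum-margin linear classifier for two-class breed discrimination.
#' Features are standardized with calibration statistics. Default cost 1.
#'
#' @param X Calibration feature matrix.
#' @param labels Class labels (exactly two distinct values).
#' @param C Cost parameter (> 0); default 1.
#' @return An object of class `linear_svc` with a predict method returning
#'   labels.
#' @export
fit_linear_svc <- function(X, labels, C = 1) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("exactly two classes are required, got ", nlevels(labels),
         call. = FALSE)
  if (C <= 0) stop("'C' must be positive", call. = FALSE)
  sc <- .fit_scaling(X)
  fit <- e1071::svm(.apply_scaling(X, sc), labels,
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  structure(list(fit = fit, scaling = sc, levels = levels(labels), C = C),
            class = "linear_svc")
}

#' @export
predict.linear_svc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.character(stats::predict(object$fit,
                              .apply_scaling(newdata, object$scaling)))
}
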