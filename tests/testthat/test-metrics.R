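test_that("perfect prediction is the fixed point (RMSE 0, R2 1, slope 1)", {
  y <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- evaluate_regression(y, y, "train")
  expect_equal(r$rmse, 0)
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_error(evaluate_regression(rep(1, 5), y, "train"), "zero variance")
  expect_error(evaluate_regression(y[1:2], y[1:2], "train"), "at least 3")
})

test_that("regression metrics match closed-form least squares by hand", {
  y_true <- c(1, 2, 3, 4)
  y_pred <- c(1.1, 1.9, 3.2, 3.8)
  r <- evaluate_regression(y_true, y_pred, "test")
  ## the oracle: explicit normal-equation arithmetic, no lm()
  xb <- mean(y_true); yb <- mean(y_pred)
  sxx <- sum((y_true - xb)^2)
  sxy <- sum((y_true - xb) * (y_pred - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  resid <- y_pred - (intercept + slope * y_true)
  sigma2 <- sum(resid^2) / 2
  expect_equal(r$rmse, sqrt(mean((y_true - y_pred)^2)))
  expect_equal(r$slope, slope)
  expect_equal(r$intercept, intercept)
  expect_equal(r$slope_sd, sqrt(sigma2 / sxx))
  expect_equal(r$intercept_sd, sqrt(sigma2 * (1 / 4 + xb^2 / sxx)))
  expect_equal(r$r2, 1 - sum(resid^2) / sum((y_pred - yb)^2))
  expect_equal(r$slope_p,
               2 * pt(abs(slope / sqrt(sigma2 / sxx)), 2, lower.tail = FALSE))
  expect_equal(r$rse, sqrt(sigma2) / xb)
})

test_that("an intercept with p > 0.05 is reported as not significant", {
  set.seed(6)
  y <- 1:30
  pred <- y + rnorm(30, sd = 0.5)  # intercept indistinguishable from 0
  r <- evaluate_regression(y, pred, "train")
  expect_true(r$intercept_p > 0.05)
  expect_true(r$intercept_ns)
  out <- capture.output(print(r))
  expect_match(out, "intercept ns")
})

test_that("replicate-level accuracy follows the confusion counts", {
  # 10 test samples x 3 replicates, exactly one replicate misclassified
  truth <- rep(c("Serrana", "Preta"), each = 15)
  pred <- truth
  pred[7] <- "Preta"
  r <- evaluate_classification(truth, pred, "test")
  expect_equal(r$accuracy_1dp, 96.7)
  expect_equal(sum(r$confusion), 30)
  expect_equal(unname(r$sensitivity["Serrana"]), 100 * 14 / 15)
  expect_equal(unname(r$specificity["Preta"]), 100 * 14 / 15)
  # all-correct case
  r2 <- evaluate_classification(truth, truth, "train")
  expect_equal(r2$accuracy, 100)
  expect_true(all(r2$sensitivity == 100, r2$specificity == 100))
  expect_error(evaluate_classification(truth, pred[1:5], "test"), "length")
})

test_that("classification metrics match a hand-filled 2x2 table", {
  truth <- c("A", "A", "A", "A", "B", "B", "B", "B", "B", "B")
  pred <- c("A", "A", "B", "B", "B", "B", "B", "B", "A", "B")
  r <- evaluate_classification(truth, pred, "test")
  # confusion: A->A 2, A->B 2, B->A 1, B->B 5
  expect_equal(as.vector(r$confusion), c(2, 1, 2, 5))
  expect_equal(r$accuracy, 70)
  expect_equal(unname(r$sensitivity), c(100 * 2 / 4, 100 * 5 / 6))
  expect_equal(unname(r$specificity), c(100 * 5 / 6, 100 * 2 / 4))
})

test_that("model selection gates on calibration quality then test RMSE", {
  base <- data.frame(variable = "v", treatment = c("SM", "DV1"),
                     best_C = 10,
                     rmse_train = c(0.1, 0.1), r2_train = c(0.99, 0.90),
                     slope_train = c(0.97, 0.99),
                     rmse_test = c(0.3, 0.1), r2_test = c(0.95, 0.99))
  # second candidate fails the train R2 gate, the first wins despite RMSE
  pick <- select_best_model(base)
  expect_equal(pick$treatment, "SM")
  # both pass: lower test RMSE wins
  base$r2_train <- c(0.99, 0.99)
  expect_equal(select_best_model(base)$treatment, "DV1")
  # RMSE tie: higher test R2 wins
  base$rmse_test <- c(0.1, 0.1)
  base$r2_test <- c(0.99, 0.95)
  expect_equal(select_best_model(base)$treatment, "SM")
  # nothing passes -> none-found marker
  base$r2_train <- c(0.5, 0.5)
  expect_null(select_best_model(base))
  expect_error(select_best_model(base[0, ]), "empty")
  expect_error(model_selection_criteria(r2_train_min = 1.2), "0, 1")
})
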