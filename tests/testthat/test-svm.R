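test_that("linear SVR fits a noiseless realizable target", {
  set.seed(8)
  X <- matrix(runif(20, -2, 2), ncol = 1)
  y <- 2 * X[, 1] + 1
  fit <- fit_linear_svr(X, y, C = 10, epsilon = 1e-4)
  Xnew <- matrix(seq(-1.5, 1.5, length.out = 7), ncol = 1)
  expect_lt(sqrt(mean((predict(fit, Xnew) - (2 * Xnew[, 1] + 1))^2)), 1e-3)
  # constant target: constant prediction within the tube
  yc <- rep(3, 20)
  fitc <- fit_linear_svr(X, yc, C = 1, epsilon = 0.1)
  expect_lt(max(abs(predict(fitc, X) - 3)), 0.1 + 1e-6)
  expect_error(fit_linear_svr(X[1, , drop = FALSE], 1), "at least 2")
  expect_error(fit_linear_svr(X, y, C = -1), "positive")
})

test_that("SVR agrees with an independently solved dual quadratic program", {
  x <- c(0, 0.7, 1.1, 2.0, 3.2, 4.0)
  y <- 1.5 * x + 0.3 + c(0.05, -0.08, 0.02, 0.1, -0.04, 0.06)
  C <- 10; eps <- 0.1
  fit <- fit_linear_svr(matrix(x, ncol = 1), y, C = C, epsilon = eps)
  ## oracle: the epsilon-insensitive dual solved by a generic QP solver on
  ## the same standardized problem
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  n <- length(xs)
  K <- outer(xs, xs)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  sol <- kernlab::ipop(c(eps - ys, eps + ys), H,
                       matrix(c(rep(1, n), rep(-1, n)), nrow = 1),
                       b = 0, l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                       sigf = 9, maxiter = 80)
  alpha <- kernlab::primal(sol)
  coefd <- alpha[1:n] - alpha[(n + 1):(2 * n)]
  w <- sum(coefd * xs)
  free_up <- which(alpha[1:n] > 1e-6 & alpha[1:n] < C - 1e-6)
  free_dn <- which(alpha[(n + 1):(2 * n)] > 1e-6 &
                   alpha[(n + 1):(2 * n)] < C - 1e-6)
  b <- mean(c(ys[free_up] - w * xs[free_up] - eps,
              ys[free_dn] - w * xs[free_dn] + eps))
  pred_qp <- (w * xs + b) * sd(y) + mean(y)
  expect_equal(predict(fit, matrix(x, ncol = 1)), pred_qp,
               tolerance = 1e-5)
})

test_that("cost tuning minimizes calibration RMSE with ties to smallest C", {
  set.seed(12)
  X <- matrix(rnorm(40), ncol = 2)
  y <- X %*% c(1, -2) + 0.5
  tuned <- tune_C(X, y, C_grid = c(1, 10, 30, 100))
  expect_true(tuned$best_C %in% c(1, 10, 30, 100))
  expect_equal(unname(which.min(tuned$rmse)),
               match(tuned$best_C, sort(unique(c(1, 10, 30, 100)))))
  # singleton grid
  expect_equal(tune_C(X, y, C_grid = 30)$best_C, 30)
  # duplicate-RMSE degenerate case: constant target makes every C tie
  t2 <- tune_C(X, rep(1, 20), C_grid = c(100, 10, 1))
  expect_equal(t2$best_C, 1)
  expect_error(tune_C(X, y, C_grid = numeric()), "non-empty")
})

test_that("linear SVC separates separable classes and respects symmetry", {
  set.seed(21)
  X <- rbind(matrix(rnorm(40, -2), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
  lab <- rep(c("a", "b"), each = 20)
  fit <- fit_linear_svc(X, lab, C = 1)
  expect_equal(mean(predict(fit, X) == lab), 1)
  # swapping the labels swaps the predictions, boundary unchanged
  lab2 <- ifelse(lab == "a", "b", "a")
  fit2 <- fit_linear_svc(X, lab2, C = 1)
  p1 <- predict(fit, X); p2 <- predict(fit2, X)
  expect_true(all((p1 == "a") == (p2 == "b")))
  expect_error(fit_linear_svc(X, rep("a", 40)), "two classes")
})

test_that("no linear separator fits an XOR layout", {
  X <- matrix(c(0, 1, 0, 1,   # diagonal pairs share a class
                0, 1, 1, 0), ncol = 2)
  lab <- c("a", "a", "b", "b")
  fit <- fit_linear_svc(X, lab, C = 100)
  expect_lte(mean(predict(fit, X) == lab), 0.75)
})
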