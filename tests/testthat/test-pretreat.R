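test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  nu <- seq(4000, 4100, 4)
  expect_equal(sg_smooth(rep(3.2, 26)), rep(3.2, 26))
  ramp <- 0.01 * nu
  expect_equal(sg_smooth(ramp), ramp, tolerance = 1e-9)
  expect_error(sg_smooth(ramp, window = 10), "odd")
  expect_error(sg_smooth(ramp, window = 3, polyorder = 2), "polyorder")
})

test_that("smoothing a noisy sine reduces variance around the true curve", {
  nu <- seq(4000, 5200, 4)
  truth <- sin((nu - 4000) / 120)
  set.seed(5)
  noisy <- truth + rnorm(length(nu), sd = 0.1)
  sm <- sg_smooth(noisy, window = 11, polyorder = 2)
  expect_lt(mean((sm - truth)^2), mean((noisy - truth)^2))
  ## matches a direct local quadratic fit at an interior point
  i <- 100
  win <- (i - 5):(i + 5)
  fit <- lm(noisy[win] ~ poly(win, 2, raw = TRUE))
  expect_equal(sm[i], unname(fitted(fit)[6]), tolerance = 1e-8)
})

test_that("unit-area normalization yields trapezoidal integral 1", {
  sp <- 4
  # constant 2.0 on a grid of width W -> constant 1/W
  x <- rep(2, 26); W <- sp * 25
  nx <- norm_unit_area(x, spacing = sp)
  expect_equal(nx, rep(1 / W, 26))
  # random positive spectrum: integral recomputed independently
  set.seed(9)
  y <- runif(151, 0.1, 1)
  ny <- norm_unit_area(y, spacing = sp)
  manual <- sum((ny[-1] + ny[-151]) / 2) * sp  # independent trapezoid
  expect_equal(manual, 1, tolerance = 1e-12)
  # idempotence
  expect_equal(norm_unit_area(ny, spacing = sp), ny, tolerance = 1e-10)
  expect_error(norm_unit_area(rep(0, 10), spacing = sp), "zero area")
})

test_that("SNV standardizes each spectrum and is affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(60)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 3)
    expect_equal(snv(a + b * x), snv(x), tolerance = 1e-10)
    z <- snv(x)
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  expect_error(snv(rep(1, 10)), "constant")
})

test_that("MSC inverts known affine scatter", {
  nu <- seq(4000, 4600, 4)
  base <- 0.3 + 0.4 * exp(-(nu - 4300)^2 / (2 * 80^2))
  grid <- as_wavenumber_grid(nu)
  set.seed(4)
  n <- 8
  a <- runif(n, -0.1, 0.1); b <- runif(n, 0.8, 1.2)
  m <- t(sapply(seq_len(n), function(i) a[i] + b[i] * base))
  set <- spectra_set(m, grid, sample_id = sprintf("S%d", 1:n),
                     replicate = 1)
  corr <- msc(set, reference = base)
  for (i in seq_len(n))
    expect_equal(unname(corr$matrix[i, ]), base, tolerance = 1e-8)
  # spectrum equal to the reference passes through unchanged
  expect_equal(msc_correct(base, base), base)
  # 2*ref + 5 maps onto ref exactly
  expect_equal(msc_correct(2 * base + 5, base), base, tolerance = 1e-10)
  expect_error(msc_correct(rep(1, length(base)), base), "degenerate")
})

test_that("ALS baseline tracks smooth input and recovers peaks", {
  nu <- seq(4000, 6000, 4)
  # smooth slowly varying input with symmetric weights -> corrected ~ 0
  s <- 0.3 + 0.1 * sin((nu - 4000) / 800)
  r <- als_baseline(s, lam = 1e5, p = 0.5, n_iter = 10)
  expect_lt(max(abs(r$corrected)), 1e-3)
  expect_length(r$baseline, length(nu))
  # linear baseline + 3 Gaussian peaks
  baseline <- 0.2 + 1e-4 * (nu - 4000)
  pk <- function(c0, w, A) A * exp(-(nu - c0)^2 / (2 * w^2))
  peaks <- pk(4400, 40, 0.5) + pk(5000, 50, 0.8) + pk(5600, 45, 0.6)
  r2 <- als_baseline(baseline + peaks, lam = 1e5, p = 0.01, n_iter = 10)
  for (c0 in c(4400, 5000, 5600)) {
    i <- which.min(abs(nu - c0))
    expect_lt(abs(r2$corrected[i] - peaks[i]) / peaks[i], 0.05)
  }
  expect_error(als_baseline(s, lam = -1), "positive")
  expect_error(als_baseline(s, p = 1.2), "0, 1")
})

test_that("Savitzky-Golay derivatives annihilate low-order polynomials", {
  nu <- seq(4000, 4200, 4)
  expect_equal(sg_derivative(rep(2, 51), order = 1), rep(0, 51))
  # ramp 0.5 * nu -> constant first derivative 0.5 everywhere
  d1 <- sg_derivative(0.5 * nu, order = 1, spacing = 4)
  expect_equal(d1, rep(0.5, length(nu)), tolerance = 1e-8)
  # quadratic -> constant, analytically known second derivative
  q <- 3e-6 * nu^2
  d2 <- sg_derivative(q, order = 2, window = 11, polyorder = 3, spacing = 4)
  expect_equal(d2, rep(6e-6, length(nu)), tolerance = 1e-8)
  expect_error(sg_derivative(q, order = 2, polyorder = 1), "derivative order")
  expect_error(sg_derivative(q, order = 3), "1 or 2")
})

test_that("decimation keeps every k-th point starting at the first", {
  x <- seq_len(1501)
  expect_length(decimate(x, 10), 151L)
  expect_identical(decimate(x, 1), x)
  expect_equal(decimate(seq_len(11), 10), c(1L, 11L))
  set <- tiny_set(n_points = 1501)
  dec <- decimate(set, 10)
  expect_equal(dec$grid$n_points, 151L)
  expect_equal(dec$grid$wavenumbers[1], set$grid$wavenumbers[1])
  expect_equal(dec$grid$spacing, 40)
})

test_that("treatment chains compose left to right", {
  set <- tiny_set(n_samples = 4, replicates = 2, n_points = 151)
  # SNV-SM equals snv then smoothing, manually chained
  t1 <- apply_treatment(set, "SNV-SM")
  manual <- sg_smooth(snv(set))
  expect_equal(t1$matrix, manual$matrix)
  # MSC-DV1 equals msc then derivative
  t2 <- apply_treatment(set, "MSC-DV1")
  manual2 <- sg_derivative(msc(set), order = 1)
  expect_equal(t2$matrix, manual2$matrix)
  # SM on constant rows leaves them unchanged
  cset <- spectra_set(matrix(2, 2, set$grid$n_points), set$grid,
                      sample_id = c("a", "b"))
  expect_equal(apply_treatment(cset, "SM")$matrix, cset$matrix)
  expect_error(apply_treatment(set, "SNV-XX"), "unknown treatment")
  expect_error(treatment_spec(""), "empty")
})

test_that("fitted treatment parameters never read held-out rows", {
  set <- tiny_set(n_samples = 6, replicates = 2, n_points = 51)
  fit_rows <- 1:8
  a <- apply_treatment(set, "MSC-DV1", fit_rows = fit_rows)
  # corrupt the held-out rows arbitrarily; the fitted reference must not move
  set2 <- set
  set2$matrix[9:12, ] <- set2$matrix[9:12, ] * 7 + 3
  b <- apply_treatment(set2, "MSC-DV1", fit_rows = fit_rows)
  expect_identical(attr(a, "fitted")$MSC$msc_reference,
                   attr(b, "fitted")$MSC$msc_reference)
  expect_equal(a$matrix[fit_rows, ], b$matrix[fit_rows, ])
})
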