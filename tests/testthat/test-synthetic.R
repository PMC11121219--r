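test_that("generation is deterministic for a fixed (config, seed)", {
  cfg <- synthetic_config(n_samples_per_breed = 4, replicates = 2)
  a <- simulate_dataset(cfg, seed = 5)
  b <- simulate_dataset(cfg, seed = 5)
  expect_identical(a$reference, b$reference)
  expect_identical(a$carcass, b$carcass)
  expect_identical(a$spectra$matrix, b$spectra$matrix)
  c <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(a$spectra$matrix, c$spectra$matrix))
})

test_that("zero constituent spread collapses samples onto breed means", {
  cfg <- synthetic_config(n_samples_per_breed = 3, sd_scale = 0)
  refs <- generate_references(cfg, seed = 1)$reference
  ap <- attribute_parameters()
  for (b in study_breeds()) {
    imf <- refs$IMF[refs$breed == b]
    expect_equal(imf, rep(ap[[b]][ap$attribute == "IMF"], 3))
  }
})

test_that("large samples recover the generating attribute means", {
  cfg <- synthetic_config(n_samples_per_breed = 4000)
  refs <- generate_references(cfg, seed = 99)$reference
  ap <- attribute_parameters()
  ser <- refs$breed == study_breeds()[1]
  # IMF is truncated at 0.05: the expected sample mean is the analytic
  # truncated-normal mean, not the untruncated 1.20
  s <- 0.162 * 4
  a <- (0.05 - 1.20) / s
  trunc_mean <- 1.20 + s * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(refs$IMF[ser]), trunc_mean, tolerance = 0.02)
  expect_equal(mean(refs$Protein[ser]), 21.06, tolerance = 0.01)
  expect_equal(mean(refs$pH[!ser]), 5.88, tolerance = 0.01)
})

test_that("carcass tables respect the weight ordering invariant", {
  carc <- default_sim()$carcass
  expect_true(all(carc$ccw <= carc$hcw))
  expect_true(all(carc$hcw <= carc$lws))
  expect_true(all(carcass_yield(carc$ccw, carc$lws) > 0 &
                  carcass_yield(carc$ccw, carc$lws) <= 100))
})

test_that("noise-free, scatter-free replicates equal the clean spectra", {
  cfg <- synthetic_config(n_samples_per_breed = 3, noise_sd = 0,
                          scatter_gain_sd = 0, scatter_offset_sd = 0)
  sim <- simulate_dataset(cfg, seed = 2)
  gt <- sim$ground_truth
  idx <- match(sim$spectra$meta$sample_id, sim$reference$sample_id)
  expect_equal(sim$spectra$matrix, gt$clean[idx, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("known scatter corruption is invertible and MSC recovers it", {
  cfg <- synthetic_config(n_samples_per_breed = 2, replicates = 3,
                          noise_sd = 0)
  sim <- simulate_dataset(cfg, seed = 3)
  gt <- sim$ground_truth
  idx <- match(sim$spectra$meta$sample_id, sim$reference$sample_id)
  # direct inversion with the generator-held gain/offset
  inverted <- (sim$spectra$matrix - gt$offset) / gt$gain
  expect_equal(inverted, gt$clean[idx, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # MSC against the known clean spectrum of one sample
  rows <- which(sim$spectra$meta$sample_id == sim$reference$sample_id[1])
  one <- subset_rows(sim$spectra, rows)
  corr <- msc(one, reference = gt$clean[1, ])
  for (r in seq_along(rows))
    expect_equal(unname(corr$matrix[r, ]), unname(gt$clean[1, ]),
                 tolerance = 1e-8)
})

test_that("tuned SVR on SNV-DV1 spectra recovers encoded constituents", {
  sim <- default_sim()
  set <- decimate(sim$spectra, 10)
  refs <- sim$reference
  part <- split_spectra(set, refs, n_train = 20)
  tr <- part$train_rows; te <- part$test_rows
  treated <- apply_treatment(set, "SNV-DV1", fit_rows = tr)
  r2_te <- sapply(c("Protein", "IMF", "C16:0", "C18:1n-9",
                    "Moisture", "pH"), function(v) {
    y <- refs[[v]][match(set$meta$sample_id, refs$sample_id)]
    tuned <- tune_C(treated$matrix[tr, ], y[tr], epsilon = 0.01)
    fit <- fit_linear_svr(treated$matrix[tr, ], y[tr], C = tuned$best_C,
                          epsilon = 0.01)
    cor(y[te], predict(fit, treated$matrix[te, ]))^2
  })
  # fat, protein and fatty-acid signatures are sharply identifiable
  expect_true(all(r2_te[c("Protein", "IMF", "C16:0", "C18:1n-9")] >= 0.99))
  # the dominant absorber (moisture) loses part of its signal to the SNV
  # closure; pH is encoded through a single weak band
  expect_true(all(r2_te[c("Moisture", "pH")] >= 0.95))
})

test_that("well-separated breeds are linearly classifiable from spectra", {
  sim <- default_sim()
  set <- decimate(sim$spectra, 10)
  part <- split_spectra(set, sim$reference, n_train = 20)
  treated <- apply_treatment(set, "SNV-DV1", fit_rows = part$train_rows)
  fit <- fit_linear_svc(treated$matrix[part$train_rows, ],
                        set$meta$breed[part$train_rows], C = 1)
  pred_te <- predict(fit, treated$matrix[part$test_rows, ])
  expect_equal(mean(pred_te == set$meta$breed[part$test_rows]), 1)
})
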