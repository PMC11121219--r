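## Shared fixtures, built in code. The default synthetic dataset is
## generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_dataset(synthetic_config(), seed = seed)
  .fixture_env[[key]]
}

## tiny spectra set on a small grid, deterministic
tiny_set <- function(n_samples = 3, replicates = 2, n_points = 25,
                     seed = 11) {
  grid <- wavenumber_grid(4000, 4000 + 4 * (n_points - 1), 4)
  nu <- grid$wavenumbers
  base <- 0.2 + 0.5 * exp(-(nu - mean(nu))^2 / (2 * 30^2))
  set.seed(seed)
  n <- n_samples * replicates
  m <- matrix(rep(base, each = n), nrow = n) *
    (1 + 0.1 * stats::rnorm(n)) + 0.05 * stats::rnorm(n)
  breed_per_sample <- rep(c("A", "B"), length.out = n_samples)
  spectra_set(m, grid,
              sample_id = rep(sprintf("S%02d", seq_len(n_samples)),
                              each = replicates),
              replicate = rep(seq_len(replicates), n_samples),
              breed = rep(breed_per_sample, each = replicates),
              sex = "M")
}

## Independent naive max-min selection (the Kennard-Stone oracle):
## explicit loops, no shared code with the implementation.
naive_maxmin <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best_pair <- c(1L, 2L); best_d <- -Inf
  for (j in 2:n) for (i in 1:(j - 1)) {
    if (d(i, j) > best_d + 1e-15) { best_d <- d(i, j); best_pair <- c(i, j) }
  }
  sel <- best_pair
  while (length(sel) < k) {
    rem <- setdiff(seq_len(n), sel)
    score <- sapply(rem, function(c) min(sapply(sel, function(s) d(c, s))))
    sel <- c(sel, rem[which.max(score)])
  }
  sel
}

## Serrana breed-mean fatty-acid profile (printed column means)
serrana_profile <- function() {
  fp <- fatty_acid_parameters()
  stats::setNames(fp[["Serrana"]], fp$fa)
}
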