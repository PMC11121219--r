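## Synthetic two-breed goat-meat NIR datasets. A clean spectrum per sample
## is built by linear constituent mixing over a Gaussian band library
## (Beer-Lambert-like additivity) on top of a fixed instrument baseline;
## replicates add multiplicative gain, additive offset and iid noise; the
## two breeds are separated by a fixed band-shaped spectral offset. The
## generator returns its ground truth (clean spectra, per-replicate gain
## and offset) so downstream operators can be tested against known answers.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

## truncated-normal sampling by inverse-CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Gaussian band library for constituent mixing
#'
#' Each row places one Gaussian absorption band: the contribution of a
#' constituent with value v to the clean spectrum is
#' `coef * v * exp(-(nu - center)^2 / (2 width^2))`. Centers sit in
#' plausible NIR overtone/combination regions (O-H bands for moisture,
#' N-H for protein, C-H for fat and the major fatty acids); `coef` is
#' scaled so each constituent contributes absorbances of realistic
#' magnitude (~0.05-0.3 AU) at its typical value.
#'
#' @param constituents Optional subset of constituent names to keep;
#'   `NULL` keeps the full library. Useful for encoding a single
#'   constituent when studying parameter recovery.
#' @return Data frame: `constituent`, `center` (cm^-1), `width` (cm^-1),
#'   `coef` (AU per unit of the constituent).
#' @export
band_library <- function(constituents = NULL) {
  df <- read.csv(text = '
constituent,center,width,coef
Moisture,5150,150,0.008
Moisture,6900,200,0.005
Protein,4590,120,0.008
Protein,6510,180,0.005
IMF,4260,80,0.05
IMF,5800,120,0.04
IMF,8560,150,0.02
C16:0,4330,100,0.004
C16:0,5680,130,0.003
C18:1n-9,4660,110,0.003
C18:1n-9,5900,140,0.002
pH,6200,180,0.01
', stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(constituents)) {
    df <- df[df$constituent %in% constituents, , drop = FALSE]
    if (nrow(df) == 0) stop("no bands left for the requested constituents",
                            call. = FALSE)
  }
  df
}

#' Synthetic dataset configuration
#'
#' Study conditions of the emulated two-breed experiment: 16 samples per
#' breed (8 per sex), 3 replicate spectra per sample on the default
#' 1501-point grid; constituents drawn from the per-breed truncated-normal
#' distributions of [attribute_parameters()] and [fatty_acid_parameters()]
#' (SD = SEM * sqrt(16)); replicate scatter gain ~ N(1, 0.05) and offset
#' ~ N(0, 0.02 AU); iid absorbance noise SD 1e-4 AU (typical FT-NIR
#' root-mean-square noise). `class_separation`
#' scales a fixed six-band breed offset of base amplitude 0.01 AU; the
#' default 3 puts the between-breed offset at roughly three times the
#' within-breed clean-spectrum variation, a clearly NIR-discriminable
#' regime.
#'
#' @param n_samples_per_breed Samples per breed (sexes balanced).
#' @param replicates Replicate spectra per sample.
#' @param grid A [wavenumber_grid()].
#' @param bands Band library, see [band_library()].
#' @param scatter_gain_sd,scatter_offset_sd Replicate scatter parameters.
#' @param noise_sd Absorbance noise SD (AU).
#' @param sd_scale Multiplier on every constituent SD (0 collapses each
#'   sample onto its breed mean).
#' @param class_separation Scale of the breed-specific spectral offset.
#' @param seed Default seed used by [simulate_dataset()].
#' @return Named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples_per_breed = 16, replicates = 3,
                             grid = wavenumber_grid(),
                             bands = band_library(),
                             scatter_gain_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 1e-4,
                             sd_scale = 1,
                             class_separation = 3,
                             seed = 42) {
  stopifnot(n_samples_per_breed >= 1, replicates >= 1,
            scatter_gain_sd >= 0, scatter_offset_sd >= 0, noise_sd >= 0,
            sd_scale >= 0, class_separation >= 0)
  if (any(bands$center < grid$start | bands$center > grid$stop))
    stop("band centers must lie inside the wavenumber grid", call. = FALSE)
  structure(list(n_samples_per_breed = n_samples_per_breed,
                 replicates = as.integer(replicates), grid = grid,
                 bands = bands, scatter_gain_sd = scatter_gain_sd,
                 scatter_offset_sd = scatter_offset_sd, noise_sd = noise_sd,
                 sd_scale = sd_scale,
                 class_separation = class_separation, seed = seed),
            class = "synthetic_config")
}

#' Generate per-sample reference and carcass tables
#'
#' Draws every physicochemical attribute and fatty acid from its per-breed
#' truncated normal distribution, derives chroma/hue from the sampled a*
#' and b*, and builds the carcass table (age, daily gain, live and carcass
#' weights) from the per-breed-and-sex cells; the hot carcass weight is set
#' to CCW / 0.96 (about 4% chill loss) and the cold weight derives from a
#' sampled dressing yield so CCW <= HCW <= LWS always holds.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return List with data frames `reference` (one row per sample: ids,
#'   breed, sex, attributes, fatty acids) and `carcass`.
#' @export
generate_references <- function(cfg = synthetic_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    n_b <- cfg$n_samples_per_breed
    breeds <- study_breeds()
    n <- 2L * n_b
    breed <- rep(breeds, each = n_b)
    sex <- rep(rep(c("M", "F"), each = ceiling(n_b / 2))[seq_len(n_b)], 2L)
    sample_id <- paste0(rep(c("SER", "PRE"), each = n_b),
                        sprintf("%02d", rep(seq_len(n_b), 2L)))
    ref <- data.frame(sample_id = sample_id, breed = breed, sex = sex,
                      stringsAsFactors = FALSE, check.names = FALSE)
    ap <- attribute_parameters()
    for (i in seq_len(nrow(ap))) {
      sd_i <- ap$sem[i] * sqrt(16) * cfg$sd_scale
      vals <- numeric(n)
      for (b in breeds) {
        rows <- breed == b
        vals[rows] <- rtruncnorm(sum(rows), ap[[b]][i], sd_i,
                                 ap$lower[i], ap$upper[i])
      }
      ref[[ap$attribute[i]]] <- vals
    }
    ch <- chroma_hue(ref$a_star, ref$b_star)
    ref$C_star <- ch$C_star
    ref$H_star <- ch$H_star
    fp <- fatty_acid_parameters()
    for (i in seq_len(nrow(fp))) {
      sd_i <- fp$sem[i] * sqrt(16) * cfg$sd_scale
      vals <- numeric(n)
      for (b in breeds) {
        rows <- breed == b
        vals[rows] <- rtruncnorm(sum(rows), fp[[b]][i], sd_i, lower = 0)
      }
      ref[[fp$fa[i]]] <- vals
    }
    cp <- carcass_parameters()
    cell <- paste(ifelse(breed == breeds[1L], "Serrana", "Preta"), sex,
                  sep = ".")
    carcass <- data.frame(sample_id = sample_id, breed = breed, sex = sex,
                          stringsAsFactors = FALSE)
    for (trait in c("age", "dg", "lws")) {
      r <- cp[cp$trait == trait, ]
      means <- as.numeric(r[1L, cell])
      sd_t <- r$sem * sqrt(8) * cfg$sd_scale
      carcass[[trait]] <- vapply(seq_len(n), function(k)
        rtruncnorm(1L, means[k], sd_t, lower = 1), numeric(1L))
    }
    r <- cp[cp$trait == "yield", ]
    ymeans <- as.numeric(r[1L, cell])
    ysd <- r$sem * sqrt(8) * cfg$sd_scale
    yield <- vapply(seq_len(n), function(k)
      rtruncnorm(1L, ymeans[k], ysd, lower = 40, upper = 65), numeric(1L))
    carcass$ccw <- yield * carcass$lws / 100
    carcass$hcw <- carcass$ccw / 0.96
    list(reference = ref, carcass = carcass)
  })
}

.gauss_band <- function(wn, center, width) exp(-(wn - center)^2 / (2 * width^2))

.instrument_baseline <- function(wn) {
  0.10 + 3e-6 * (wn - wn[1L]) + 0.02 * .gauss_band(wn, 7500, 900)
}

.breed_offset_shape <- function(wn) {
  centers <- c(4400, 5000, 5600, 6700, 7800, 9000)
  signs <- c(1, -1, 1, 1, -1, 1)
  shape <- numeric(length(wn))
  for (k in seq_along(centers))
    shape <- shape + signs[k] * 0.01 * .gauss_band(wn, centers[k], 150)
  shape
}

#' Generate replicate NIR spectra for a reference table
#'
#' Builds one clean spectrum per sample by linear constituent mixing over
#' the configured band library plus a fixed instrument baseline and the
#' breed offset, then corrupts each replicate with multiplicative gain,
#' additive offset and iid noise. The replicate noise matrix is drawn once
#' per seed and scaled by `noise_sd`, so datasets generated from the same
#' seed at different noise levels share the same noise realization (a
#' "seed family": prediction error is then monotone in `noise_sd` by
#' construction).
#'
#' @param refs Reference table from [generate_references()] (its
#'   `$reference` element or the list itself).
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A [spectra_set()] with attribute `"ground_truth"`: list with
#'   `clean` (n_samples x n_points matrix), `gain`, `offset` (per
#'   replicate spectrum) and `noise_sd`.
#' @export
generate_spectra <- function(refs, cfg = synthetic_config(),
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.list(refs) && !is.data.frame(refs) && !is.null(refs$reference))
    refs <- refs$reference
  wn <- cfg$grid$wavenumbers
  n_s <- nrow(refs)
  breeds <- study_breeds()
  base <- .instrument_baseline(wn)
  offset_shape <- .breed_offset_shape(wn) * cfg$class_separation
  clean <- matrix(rep(base, each = n_s), nrow = n_s)
  for (i in seq_len(nrow(cfg$bands))) {
    con <- cfg$bands$constituent[i]
    if (!con %in% names(refs))
      stop("band constituent '", con, "' is not a reference column",
           call. = FALSE)
    shape <- .gauss_band(wn, cfg$bands$center[i], cfg$bands$width[i])
    clean <- clean + cfg$bands$coef[i] * outer(refs[[con]], shape)
  }
  breed_sign <- ifelse(refs$breed == breeds[1L], 0.5, -0.5)
  clean <- clean + outer(breed_sign, offset_shape)
  n_rep <- cfg$replicates
  n_spec <- n_s * n_rep
  with_seed(seed, {
    gain <- stats::rnorm(n_spec, 1, cfg$scatter_gain_sd)
    offs <- stats::rnorm(n_spec, 0, cfg$scatter_offset_sd)
    Z <- matrix(stats::rnorm(n_spec * length(wn)), nrow = n_spec)
    idx <- rep(seq_len(n_s), each = n_rep)
    m <- clean[idx, , drop = FALSE] * gain + offs + cfg$noise_sd * Z
    set <- spectra_set(m, cfg$grid,
                       sample_id = refs$sample_id[idx],
                       replicate = rep(seq_len(n_rep), times = n_s),
                       breed = refs$breed[idx], sex = refs$sex[idx])
    attr(set, "ground_truth") <- list(clean = clean, gain = gain,
                                      offset = offs,
                                      noise_sd = cfg$noise_sd)
    set
  })
}

#' Generate and optionally write a full synthetic dataset
#'
#' Convenience wrapper: references + carcass + spectra from one seed. When
#' `dir` is given, writes `spectra.csv`, `reference.csv`, `carcass.csv`
#' and `ground_truth.json` (generating means, per-replicate gain/offset,
#' clean spectra) there.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param dir Optional output directory (created if needed).
#' @return List with `spectra` (a [spectra_set()]), `reference`, `carcass`
#'   and `ground_truth`.
#' @export
simulate_dataset <- function(cfg = synthetic_config(), seed = cfg$seed,
                             dir = NULL) {
  tabs <- generate_references(cfg, seed)
  set <- generate_spectra(tabs$reference, cfg, seed = seed + 1L)
  gt <- attr(set, "ground_truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spectra_csv(set, file.path(dir, "spectra.csv"))
    utils::write.csv(tabs$reference, file.path(dir, "reference.csv"),
                     row.names = FALSE)
    utils::write.csv(tabs$carcass, file.path(dir, "carcass.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, clean = gt$clean, gain = gt$gain,
           offset = gt$offset, noise_sd = gt$noise_sd),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  list(spectra = set, reference = tabs$reference, carcass = tabs$carcass,
       ground_truth = gt)
}
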