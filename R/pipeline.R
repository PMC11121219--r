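## Pipeline orchestration: configuration, the quantification and
## discrimination workflows, and rendering of the report tables.

.default_treatments <- c("SM", "DV1", "DV2", "NORM-DV1", "MSC-SM",
                         "MSC-DV1", "SNV-SM", "ALS-SM", "SNV-DV1")

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end workflow. `spectra` and
#' `reference` may be in-memory objects (a [spectra_set()], a data frame)
#' or CSV paths; paths are read lazily when a run function is called.
#'
#' @param spectra A `spectra_set` or path to a spectra CSV.
#' @param reference Per-sample reference data frame or CSV path (must
#'   carry `sample_id`).
#' @param treatments Character vector of treatment chains to try; default
#'   is the nine-chain vocabulary
#'   `SM, DV1, DV2, NORM-DV1, MSC-SM, MSC-DV1, SNV-SM, ALS-SM, SNV-DV1`.
#' @param keep_every Decimation stride (default 10: 1501 -> 151 points).
#' @param n_train Calibration samples for the Kennard-Stone split
#'   (default 20, leaving 10 prediction samples of a 30-sample run).
#' @param feature_space Kennard-Stone feature space, `"reference"` or
#'   `"spectra"`.
#' @param C_grid Candidate SVM costs.
#' @param epsilon SVR tube width on the standardized target.
#' @param svc_C Cost of the linear classifier (default 1).
#' @param criteria Model-selection thresholds,
#'   [model_selection_criteria()].
#' @param control Treatment operator settings, [treatment_control()].
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the config also drives
#'   simulation).
#' @param out_dir Optional directory for report CSV/JSON files.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra, reference = NULL,
                            treatments = .default_treatments,
                            keep_every = 10, n_train = 20,
                            feature_space = c("reference", "spectra"),
                            C_grid = c(1, 10, 30, 100), epsilon = 0.1,
                            svc_C = 1,
                            criteria = model_selection_criteria(),
                            control = treatment_control(),
                            seed = 42, out_dir = NULL) {
  feature_space <- match.arg(feature_space)
  if (length(treatments) == 0)
    stop("'treatments' must name at least one chain", call. = FALSE)
  lapply(treatments, treatment_spec)  # validate codes early
  if (is.character(spectra) && !file.exists(spectra))
    stop("spectra file not found: ", spectra, call. = FALSE)
  if (is.character(reference) && !file.exists(reference))
    stop("reference file not found: ", reference, call. = FALSE)
  structure(list(spectra = spectra, reference = reference,
                 treatments = treatments, keep_every = keep_every,
                 n_train = n_train, feature_space = feature_space,
                 C_grid = C_grid, epsilon = epsilon, svc_C = svc_C,
                 criteria = criteria, control = control, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.load_spectra <- function(config) {
  if (inherits(config$spectra, "spectra_set")) config$spectra
  else read_spectra_csv(config$spectra)
}

.load_reference <- function(config) {
  if (is.null(config$reference))
    stop("a reference table is required for this run", call. = FALSE)
  if (is.data.frame(config$reference)) config$reference
  else utils::read.csv(config$reference, check.names = FALSE,
                       stringsAsFactors = FALSE)
}

.prepare_split <- function(config) {
  set <- .load_spectra(config)
  refs <- .load_reference(config)
  dec <- decimate(set, config$keep_every)
  part <- split_spectra(dec, refs, n_train = config$n_train,
                        feature_space = config$feature_space)
  list(set = dec, refs = refs, part = part)
}

#' Run the quantification workflow
#'
#' For every dependent variable and every treatment chain: decimate the
#' spectra, apply the chain (fitting any data-dependent operator on the
#' calibration rows only), tune the SVR cost on the calibration group,
#' and evaluate calibration and prediction performance; then gate the
#' candidates through the model-selection criteria and keep the best
#' chain per variable.
#'
#' @param config A [pipeline_config()].
#' @param variables Character vector of reference columns to model;
#'   default: every numeric reference column.
#' @return List of class `quantification_result`: `candidates` (all
#'   variable x treatment rows), `selected` (best row per variable, or
#'   none when no candidate passed), `partition`, and `config`. Writes
#'   `quantification_candidates.csv`, `quantification_selected.csv` and
#'   `quantification.json` to `config$out_dir` when set.
#' @export
run_quantification <- function(config, variables = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ctx <- .prepare_split(config)
  set <- ctx$set; refs <- ctx$refs; part <- ctx$part
  if (is.null(variables)) {
    num <- vapply(refs, is.numeric, logical(1L))
    variables <- setdiff(names(refs)[num], c("replicate"))
  }
  missing <- setdiff(variables, names(refs))
  if (length(missing))
    stop("quantification: variable(s) not in the reference table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  train <- part$train_rows; test <- part$test_rows
  y_all <- function(v) refs[[v]][match(set$meta$sample_id, refs$sample_id)]
  rows <- list()
  for (tr in config$treatments) {
    treated <- tryCatch(
      apply_treatment(set, tr, fit_rows = train, control = config$control),
      error = function(e) stop("treatment ", tr, ": ", conditionMessage(e),
                               call. = FALSE))
    X_train <- treated$matrix[train, , drop = FALSE]
    X_test <- treated$matrix[test, , drop = FALSE]
    for (v in variables) {
      y <- y_all(v)
      if (stats::var(y[train]) < 1e-15) next  # constant target: no model
      tuned <- tune_C(X_train, y[train], C_grid = config$C_grid,
                      epsilon = config$epsilon)
      fit <- fit_linear_svr(X_train, y[train], C = tuned$best_C,
                            epsilon = config$epsilon)
      rep_tr <- evaluate_regression(y[train], predict(fit, X_train), "train")
      rep_te <- evaluate_regression(y[test], predict(fit, X_test), "test")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, treatment = tr, best_C = tuned$best_C,
        rmse_train = rep_tr$rmse, r2_train = rep_tr$r2,
        slope_train = rep_tr$slope, slope_sd_train = rep_tr$slope_sd,
        intercept_train = rep_tr$intercept,
        intercept_sd_train = rep_tr$intercept_sd,
        intercept_p_train = rep_tr$intercept_p,
        rmse_test = rep_te$rmse, r2_test = rep_te$r2,
        slope_test = rep_te$slope, slope_sd_test = rep_te$slope_sd,
        rse_train = rep_tr$rse, rse_test = rep_te$rse,
        stringsAsFactors = FALSE)
    }
  }
  candidates <- do.call(rbind, rows)
  selected <- do.call(rbind, lapply(split(candidates, candidates$variable),
                                    select_best_model,
                                    criteria = config$criteria))
  res <- structure(list(candidates = candidates, selected = selected,
                        partition = part, config = config),
                   class = "quantification_result")
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    utils::write.csv(candidates,
                     file.path(d, "quantification_candidates.csv"),
                     row.names = FALSE)
    utils::write.csv(render_regression_table(selected),
                     file.path(d, "quantification_selected.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(candidates = candidates, selected = selected),
                         file.path(d, "quantification.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  res
}

#' Render selected models as a publication-style table
#'
#' One row per dependent variable with the columns of a NIR calibration
#' report: data treatment, best cost, RMSE (3 decimals), R2 (4 decimals),
#' slope +/- its SD, and intercept +/- SD or `ns` when the intercept is
#' not significantly different from zero (p > 0.05).
#'
#' @param selected The `selected` data frame of a
#'   [run_quantification()] result.
#' @param group `"train"` or `"test"` metrics.
#' @return Data frame with character-rendered columns.
#' @export
render_regression_table <- function(selected, group = c("train", "test")) {
  group <- match.arg(group)
  if (is.null(selected) || nrow(selected) == 0)
    return(data.frame(Parameters = character(), `Data Treatment` = character(),
                      `Best C` = numeric(), RMSE = character(),
                      R2 = character(), `Slope ± s` = character(),
                      `Intercept ± s` = character(), check.names = FALSE))
  g <- function(stem) selected[[paste0(stem, "_", group)]]
  out <- data.frame(
    Parameters = selected$variable,
    `Data Treatment` = selected$treatment,
    `Best C` = selected$best_C,
    RMSE = sprintf("%.3f", g("rmse")),
    R2 = sprintf("%.4f", g("r2")),
    `Slope ± s` = sprintf("%.3f ± %.3f", g("slope"), g("slope_sd")),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (group == "train") {
    out$`Intercept ± s` <- ifelse(
      selected$intercept_p_train > 0.05, "ns",
      sprintf("%.3f ± %.3f", selected$intercept_train,
              selected$intercept_sd_train))
  }
  rownames(out) <- NULL
  out
}

#' Run the breed-discrimination workflow
#'
#' Applies one treatment chain (default `SNV-DV1`), fits the linear
#' classifier on the calibration replicate spectra and reports
#' replicate-level accuracy, sensitivity and specificity for both groups.
#'
#' @param config A [pipeline_config()].
#' @param treatment Treatment chain for the classifier input.
#' @return List of class `discrimination_result`: `train`, `test`
#'   (classification reports), `model`, `partition`, `treatment`. Writes
#'   `discrimination.json` to `config$out_dir` when set.
#' @export
run_discrimination <- function(config, treatment = "SNV-DV1") {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(unique(.load_spectra(config)$meta$breed)) != 2)
    stop("discrimination requires exactly two breeds, got ",
         length(unique(.load_spectra(config)$meta$breed)), call. = FALSE)
  ctx <- .prepare_split(config)
  set <- ctx$set; part <- ctx$part
  treated <- apply_treatment(set, treatment, fit_rows = part$train_rows,
                             control = config$control)
  X <- treated$matrix
  lab <- set$meta$breed
  train <- part$train_rows; test <- part$test_rows
  model <- fit_linear_svc(X[train, , drop = FALSE], lab[train],
                          C = config$svc_C)
  rep_tr <- evaluate_classification(lab[train],
                                    predict(model, X[train, , drop = FALSE]),
                                    "train")
  rep_te <- evaluate_classification(lab[test],
                                    predict(model, X[test, , drop = FALSE]),
                                    "test")
  res <- structure(list(train = rep_tr, test = rep_te, model = model,
                        partition = part, treatment = treatment,
                        config = config),
                   class = "discrimination_result")
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    jsonlite::write_json(
      list(treatment = treatment, C = config$svc_C,
           train = list(accuracy = rep_tr$accuracy,
                        sensitivity = rep_tr$sensitivity,
                        specificity = rep_tr$specificity,
                        confusion = as.data.frame(rep_tr$confusion)),
           test = list(accuracy = rep_te$accuracy,
                       sensitivity = rep_te$sensitivity,
                       specificity = rep_te$specificity,
                       confusion = as.data.frame(rep_te$confusion))),
      file.path(d, "discrimination.json"), digits = NA, auto_unbox = TRUE)
  }
  res
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("Breed discrimination (", x$treatment, ", linear SVC C = ",
      x$config$svc_C, ")\n", sep = "")
  print(x$train); print(x$test)
  invisible(x)
}

#' Append quality indices to a reference table
#'
#' Computes chroma and hue from a*/b*, the fatty-acid family sums and
#' ratios, and the lipid nutritional indices for every sample row, and
#' reports per-breed means under both aggregation orders: mean of the
#' per-sample indices, and indices evaluated on the per-breed mean
#' profile. The two differ whenever the index is a nonlinear (ratio)
#' function of the profile.
#'
#' @param reference Data frame or CSV path with per-sample `a_star`,
#'   `b_star` and fatty-acid columns (named as in
#'   [fatty_acid_families()]); a `breed` column enables the per-breed
#'   summaries.
#' @param out Optional path for the augmented CSV.
#' @return List: `table` (input plus `C_star`, `H_star`, family sums,
#'   ratios, `ia`, `it`, `h_over_H` columns), `by_breed_mean_of_indices`,
#'   `by_breed_index_of_means`.
#' @export
run_indices <- function(reference, out = NULL) {
  refs <- if (is.data.frame(reference)) reference
          else utils::read.csv(reference, check.names = FALSE,
                               stringsAsFactors = FALSE)
  fam <- fatty_acid_families()
  fa_cols <- intersect(fam$fa, names(refs))
  if (length(fa_cols) == 0)
    stop("reference table has no fatty-acid columns (expected names like ",
         "\"C16:0\")", call. = FALSE)
  if (all(c("a_star", "b_star") %in% names(refs))) {
    ch <- chroma_hue(refs$a_star, refs$b_star)
    refs$C_star <- ch$C_star
    refs$H_star <- ch$H_star
  }
  ## fa_sums_ratios and lipid_indices overlap in n6_n3/pufa_sfa; keep one
  index_row <- function(p) {
    v <- c(fa_sums_ratios(p), lipid_indices(p))
    v[!duplicated(names(v))]
  }
  per_row <- as.data.frame(t(vapply(seq_len(nrow(refs)), function(i)
    index_row(unlist(refs[i, fa_cols])), numeric(10L))))
  refs <- cbind(refs, per_row)
  by_mean_idx <- by_idx_mean <- NULL
  if ("breed" %in% names(refs)) {
    idx_cols <- names(per_row)
    by_mean_idx <- do.call(rbind, lapply(split(refs, refs$breed), function(d)
      data.frame(breed = d$breed[1L], t(colMeans(d[idx_cols])),
                 check.names = FALSE)))
    by_idx_mean <- do.call(rbind, lapply(split(refs, refs$breed), function(d) {
      data.frame(breed = d$breed[1L], t(index_row(colMeans(d[fa_cols]))),
                 check.names = FALSE)
    }))
    rownames(by_mean_idx) <- rownames(by_idx_mean) <- NULL
  }
  if (!is.null(out)) utils::write.csv(refs, out, row.names = FALSE)
  list(table = refs, by_breed_mean_of_indices = by_mean_idx,
       by_breed_index_of_means = by_idx_mean)
}
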