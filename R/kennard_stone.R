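#' Kennard-Stone sample selection
#'
#' Deterministic space-filling selection with the Euclidean metric: the
#' first two selected points are the pair at maximal distance; every
#' further point is the candidate whose minimum distance to the already
#' selected set is largest (max-min). Ties are broken by the smallest row
#' index so the selection is fully reproducible.
#'
#' @param features Numeric matrix or data frame, one row per sample.
#' @param n_select Number of samples to select (2 .. `nrow(features)`).
#' @param standardize If `TRUE`, columns are z-scored before distances are
#'   computed; use for feature tables on mixed units, leave off for
#'   spectra.
#' @return Integer vector of selected row indices in selection order.
#' @examples
#' X <- cbind(c(0, 1, 2, 6, 10))
#' kennard_stone(X, 3)  # farthest pair {1, 5}, then the max-min point
#' @export
kennard_stone <- function(features, n_select, standardize = FALSE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (anyNA(X)) stop("'features' contains missing values", call. = FALSE)
  if (n_select < 2) stop("'n_select' must be at least 2", call. = FALSE)
  if (n_select > n)
    stop("'n_select' exceeds the number of samples", call. = FALSE)
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds < 1e-12))
      stop("constant feature column: cannot standardize", call. = FALSE)
    X <- scale(X)
  }
  D <- as.matrix(stats::dist(X))
  ## seed: pair at maximal distance; ties -> smallest (i, j) in row-major
  ## scan order, which which.max delivers on the column-stacked matrix only
  ## for the lower triangle scan below
  best <- c(1L, 2L); best_d <- -Inf
  for (j in 2:n) for (i in 1:(j - 1L)) {
    if (D[i, j] > best_d + 1e-15) { best_d <- D[i, j]; best <- c(i, j) }
  }
  selected <- best
  remaining <- setdiff(seq_len(n), selected)
  min_d <- pmin(D[, selected[1L]], D[, selected[2L]])
  while (length(selected) < n_select) {
    cand_d <- min_d[remaining]
    pick <- remaining[which.max(cand_d)]  # which.max takes the first max
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    min_d <- pmin(min_d, D[, pick])
  }
  selected
}

#' Kennard-Stone calibration/prediction partition
#'
#' @param sample_ids Character vector of ids aligned with the feature rows.
#' @param selected Integer indices as returned by [kennard_stone()].
#' @return A `partition_result`: list with `train_sample_ids`,
#'   `test_sample_ids` and `selection_order`.
#' @export
partition_result <- function(sample_ids, selected) {
  sample_ids <- as.character(sample_ids)
  structure(
    list(train_sample_ids = sample_ids[sort(selected)],
         test_sample_ids = sample_ids[setdiff(seq_along(sample_ids),
                                              selected)],
         selection_order = sample_ids[selected]),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Kennard-Stone partition: %d calibration / %d prediction samples\n",
              length(x$train_sample_ids), length(x$test_sample_ids)))
  invisible(x)
}

#' Replicate-aware calibration/prediction split
#'
#' Runs Kennard-Stone at the sample level — on the per-sample reference
#' table (`feature_space = "reference"`, the default) or on
#' replicate-averaged spectra (`feature_space = "spectra"`) — and assigns
#' every replicate spectrum of a sample to its sample's group, so no sample
#' straddles the split.
#'
#' @param set A [spectra_set()].
#' @param refs Data frame of per-sample reference values with a
#'   `sample_id` column (required for `feature_space = "reference"`);
#'   non-numeric columns are ignored as features.
#' @param n_train Number of calibration samples.
#' @param feature_space `"reference"` or `"spectra"`.
#' @param standardize Standardize features before distances; defaults to
#'   `TRUE` for reference features (mixed units), `FALSE` for spectra.
#' @return A `partition_result` (see [partition_result()]) with additional
#'   elements `train_rows` and `test_rows`: row indices into `set`.
#' @export
split_spectra <- function(set, refs = NULL, n_train,
                          feature_space = c("reference", "spectra"),
                          standardize = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  feature_space <- match.arg(feature_space)
  ids <- unique(set$meta$sample_id)
  if (n_train >= length(ids))
    stop("'n_train' must be smaller than the number of samples",
         call. = FALSE)
  if (feature_space == "reference") {
    if (is.null(refs) || !"sample_id" %in% names(refs))
      stop("'refs' with a sample_id column is required for ",
           "feature_space = \"reference\"", call. = FALSE)
    refs <- refs[match(ids, as.character(refs$sample_id)), , drop = FALSE]
    if (anyNA(refs$sample_id))
      stop("reference table is missing some sample ids", call. = FALSE)
    num <- vapply(refs, is.numeric, logical(1L))
    X <- as.matrix(refs[, num & names(refs) != "replicate", drop = FALSE])
    ## constant reference columns carry no distance information and would
    ## break z-scoring; drop them
    keep <- apply(X, 2L, stats::sd) > 1e-12
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0)
      stop("all reference feature columns are constant", call. = FALSE)
    if (is.null(standardize)) standardize <- TRUE
  } else {
    X <- average_replicates(set)$matrix
    if (is.null(standardize)) standardize <- FALSE
  }
  sel <- kennard_stone(X, n_train, standardize = standardize)
  part <- partition_result(ids, sel)
  part$train_rows <- which(set$meta$sample_id %in% part$train_sample_ids)
  part$test_rows <- which(set$meta$sample_id %in% part$test_sample_ids)
  part
}
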