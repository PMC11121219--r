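#' Spectra set container
#'
#' Bundles an absorbance matrix (one row per measured spectrum) with its
#' shared [wavenumber_grid()] and the per-row metadata the workflow needs:
#' sample identifier, replicate index, breed and sex. Replicate spectra of
#' one sample share a `sample_id`; breed and sex must be constant within a
#' sample.
#'
#' @param matrix Numeric matrix, `n_spectra x n_points`, absorbance.
#' @param grid A `wavenumber_grid` whose `n_points` matches `ncol(matrix)`.
#' @param sample_id Character or integer vector, one per row.
#' @param replicate Integer replicate index per row (1-based).
#' @param breed,sex Character labels per row (recycled if length 1).
#' @return An object of class `spectra_set`: list with `grid`, `matrix` and
#'   a data frame `meta` (columns `sample_id`, `replicate`, `breed`, `sex`).
#' @export
spectra_set <- function(matrix, grid, sample_id, replicate = NULL,
                        breed = NA_character_, sex = NA_character_) {
  matrix <- as.matrix(matrix)
  if (!inherits(grid, "wavenumber_grid"))
    stop("'grid' must be a wavenumber_grid", call. = FALSE)
  n <- nrow(matrix)
  if (ncol(matrix) != grid$n_points)
    stop("matrix has ", ncol(matrix), " columns but grid has ",
         grid$n_points, " points", call. = FALSE)
  if (!all(is.finite(matrix)))
    stop("absorbance values must all be finite", call. = FALSE)
  sample_id <- as.character(rep_len(sample_id, n))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n), sample_id, FUN = seq_along)
  }
  meta <- data.frame(sample_id = sample_id,
                     replicate = as.integer(rep_len(replicate, n)),
                     breed = as.character(rep_len(breed, n)),
                     sex = as.character(rep_len(sex, n)),
                     stringsAsFactors = FALSE)
  ## breed/sex must not vary within a sample; replicate counts must agree
  for (col in c("breed", "sex")) {
    n_lab <- tapply(meta[[col]], meta$sample_id,
                    function(v) length(unique(v)))
    if (any(n_lab > 1L))
      stop("'", col, "' varies within a sample_id", call. = FALSE)
  }
  reps <- table(meta$sample_id)
  if (length(unique(as.integer(reps))) > 1L)
    stop("all samples must carry the same number of replicate spectra",
         call. = FALSE)
  dimnames(matrix) <- NULL
  structure(list(grid = grid, matrix = matrix, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("Spectra set: %d spectra (%d samples x %d replicates) on %s\n",
              nrow(x$matrix), length(unique(x$meta$sample_id)),
              max(x$meta$replicate), format(x$grid)))
  if (!all(is.na(x$meta$breed)))
    cat("  breeds:", paste(names(table(x$meta$breed)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

#' Subset a spectra set by rows
#'
#' @param set A `spectra_set`.
#' @param rows Integer or logical row index.
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_rows <- function(set, rows) {
  stopifnot(inherits(set, "spectra_set"))
  spectra_set(set$matrix[rows, , drop = FALSE], set$grid,
              sample_id = set$meta$sample_id[rows],
              replicate = set$meta$replicate[rows],
              breed = set$meta$breed[rows], sex = set$meta$sex[rows])
}

#' Average replicate spectra within each sample
#'
#' @param set A `spectra_set`.
#' @return A `spectra_set` with one (mean) spectrum per sample, replicate
#'   index 1, sample order as first occurrence in `set`.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$meta$sample_id)
  m <- t(vapply(ids, function(id) {
    colMeans(set$matrix[set$meta$sample_id == id, , drop = FALSE])
  }, numeric(set$grid$n_points)))
  first <- match(ids, set$meta$sample_id)
  spectra_set(m, set$grid, sample_id = ids, replicate = 1L,
              breed = set$meta$breed[first], sex = set$meta$sex[first])
}

.meta_cols <- c("sample_id", "replicate", "breed", "sex")

#' Read spectra from CSV
#'
#' Expects the on-disk layout written by [write_spectra_csv()]: metadata
#' columns `sample_id`, `replicate`, `breed`, `sex` followed by one numeric
#' column per wavenumber, headers being the wavenumbers themselves in
#' ascending order. The wavenumber axis must be uniformly spaced.
#'
#' @param path CSV file path.
#' @return A `spectra_set`; row order is preserved.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.meta_cols, names(df))
  if (length(missing))
    stop("spectra CSV is missing metadata column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  wn_cols <- setdiff(names(df), .meta_cols)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn))
    stop("non-numeric wavenumber column header(s): ",
         paste(wn_cols[is.na(wn)][1:3], collapse = ", "), call. = FALSE)
  grid <- as_wavenumber_grid(wn)
  m <- as.matrix(df[, wn_cols, drop = FALSE])
  storage.mode(m) <- "double"
  spectra_set(m, grid, sample_id = df$sample_id, replicate = df$replicate,
              breed = df$breed, sex = df$sex)
}

#' Write spectra to CSV
#'
#' @param set A `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  m <- as.data.frame(set$matrix)
  names(m) <- format(set$grid$wavenumbers, trim = TRUE, scientific = FALSE)
  out <- cbind(set$meta, m)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
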