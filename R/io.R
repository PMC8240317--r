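#' Read a sample-by-taxon count matrix from delimited text
#'
#' Reads a TSV or CSV file (dialect auto-detected from the extension) whose
#' first column holds identifiers and whose header row names the remaining
#' columns, and returns a numeric matrix oriented samples x taxa.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param orientation Either `"samples-in-rows"` (default) or
#'   `"taxa-in-rows"`; in the latter case the parsed matrix is transposed so
#'   the result is always samples x taxa.
#' @return A numeric matrix with unique `rownames` (sample ids) and
#'   `colnames` (taxon ids). All entries are non-negative; fractional values
#'   are allowed so that pre-normalized matrices can be read.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_count_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))), tf)
#' read_count_matrix(tf)
#' @export
read_count_matrix <- function(path,
                              orientation = c("samples-in-rows", "taxa-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_delimited(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated row ids in ", path, call. = FALSE)
  body <- df[, -1, drop = FALSE]
  for (cn in names(body)) {
    if (!is.numeric(body[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[cn]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   cn, bad, path), call. = FALSE)
    }
  }
  M <- as.matrix(body)
  rownames(M) <- ids
  if (orientation == "taxa-in-rows") M <- t(M)
  validate_count_matrix(M)
  M
}

#' Write a count matrix as delimited text
#'
#' @param M Numeric matrix with row and column names.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param id_column Name for the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(M, path, id_column = "sample_id") {
  df <- tibble::as_tibble(M, rownames = id_column)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

read_delimited <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

validate_count_matrix <- function(M) {
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop("count matrix must carry sample and taxon ids as dimnames",
         call. = FALSE)
  }
  if (nrow(M) < 2L || ncol(M) < 2L) {
    stop("need at least 2 samples and 2 taxa", call. = FALSE)
  }
  if (anyDuplicated(rownames(M)) || anyDuplicated(colnames(M))) {
    stop("sample and taxon ids must be unique", call. = FALSE)
  }
  if (anyNA(M)) stop("count matrix contains missing values", call. = FALSE)
  if (any(M < 0)) {
    idx <- which(M < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(M)[idx[1]], colnames(M)[idx[2]]), call. = FALSE)
  }
  invisible(M)
}

# Coerce a data frame (first column = sample ids) or a named matrix to the
# internal samples x taxa matrix representation.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    M <- as.matrix(counts[, -1, drop = FALSE])
    rownames(M) <- ids
  } else {
    M <- as.matrix(counts)
    if (is.null(rownames(M))) rownames(M) <- paste0("sample", seq_len(nrow(M)))
    if (is.null(colnames(M))) colnames(M) <- paste0("taxon", seq_len(ncol(M)))
  }
  validate_count_matrix(M)
  M
}

#' Normalize each sample to a common library size of 1e6
#'
#' Rescales every row of the count matrix so that it sums to 10^6, putting all
#' samples on the same scale regardless of sequencing depth. The original row
#' totals (library sizes) are kept in the `"library_sizes"` attribute for
#' back-transformation and for use as a sample covariate.
#'
#' @param M Samples x taxa count matrix (see [read_count_matrix()]).
#' @return The normalized matrix; every row sums to 10^6. Attribute
#'   `library_sizes` holds the input row sums, named by sample.
#' @export
normalize_counts <- function(M) {
  M <- as_count_matrix(M)
  ls <- rowSums(M)
  if (any(ls <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(M)[ls <= 0], collapse = ", "), call. = FALSE)
  }
  out <- 1e6 * M / ls
  attr(out, "library_sizes") <- setNames(ls, rownames(M))
  out
}

#' Log10-transform normalized counts into strictly positive abundances
#'
#' Applies `log10(x + 1.01)` elementwise. The pseudocount 1.01 guarantees
#' every abundance is strictly positive (a zero count maps to
#' `log10(1.01) ~ 0.0043`), which the downstream Gamma mixture component
#' requires.
#'
#' @param Mn Normalized (or raw, if normalization was skipped) count matrix
#'   with no negative entries.
#' @return Matrix of the same shape on the log10 scale; all entries
#'   `>= log10(1.01) > 0`. Attributes of `Mn` (library sizes) are preserved.
#' @export
log_transform <- function(Mn) {
  if (any(Mn < 0)) stop("negative entries cannot be log-transformed",
                        call. = FALSE)
  out <- log10(Mn + 1.01)
  attr(out, "library_sizes") <- attr(Mn, "library_sizes")
  out
}

#' Drop taxa observed in too few samples
#'
#' Keeps taxa whose fraction of non-zero counts across samples is at least
#' `min_nonzero_fraction`. The default 0 keeps everything; 0.1 reproduces the
#' common "at least 10% non-zero" prefilter.
#'
#' @param M Samples x taxa count matrix.
#' @param min_nonzero_fraction Required non-zero fraction in `[0, 1]`.
#' @return The filtered count matrix.
#' @export
filter_taxa <- function(M, min_nonzero_fraction = 0) {
  M <- as_count_matrix(M)
  stopifnot(min_nonzero_fraction >= 0, min_nonzero_fraction <= 1)
  frac <- colMeans(M > 0)
  keep <- frac >= min_nonzero_fraction
  if (!any(keep)) stop("filter removed every taxon", call. = FALSE)
  M[, keep, drop = FALSE]
}
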