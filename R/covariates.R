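#' Assemble the sample covariate matrix
#'
#' Builds the design matrix of sample covariates used both by the mixture
#' model (normal-component mean) and by the imputation model: an intercept
#' column, optionally the log10 library size, and any user covariates.
#' Categorical user columns are expanded to indicator columns with one
#' reference level dropped.
#'
#' @param covariates Optional data frame (or path to a TSV/CSV whose first
#'   column holds sample ids) of user covariates, one row per sample in the
#'   same order as the count matrix.
#' @param library_sizes Positive per-sample totals; entered on the log10
#'   scale so the covariate is commensurate with the log10 abundances.
#' @param include_libsize Add the library-size column? Default `TRUE`.
#' @param sample_ids Sample identifiers, used for row alignment checks.
#' @return An `n x q` numeric matrix; first column is the intercept.
#' @export
build_covariates <- function(covariates = NULL, library_sizes,
                             include_libsize = TRUE, sample_ids = NULL) {
  n <- length(library_sizes)
  stopifnot(n >= 2, all(library_sizes > 0))
  if (is.null(sample_ids)) sample_ids <- names(library_sizes)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))

  X <- matrix(1, n, 1, dimnames = list(sample_ids, "(Intercept)"))
  if (include_libsize) {
    X <- cbind(X, log10_libsize = log10(library_sizes))
  }
  if (!is.null(covariates)) {
    if (is.character(covariates) && length(covariates) == 1L) {
      covariates <- read_delimited(covariates)
      covariates <- as.data.frame(covariates[, -1, drop = FALSE],
                                  row.names = as.character(covariates[[1]]))
    }
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop(sprintf("covariate table has %d rows but there are %d samples",
                   nrow(covariates), n), call. = FALSE)
    }
    if (anyNA(covariates)) stop("covariate table contains missing values",
                                call. = FALSE)
    for (cn in names(covariates)) {
      if (is.character(covariates[[cn]])) {
        covariates[[cn]] <- factor(covariates[[cn]])
      }
    }
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    rownames(mm) <- sample_ids
    X <- cbind(X, mm)
  }
  degenerate <- apply(X[, -1, drop = FALSE], 2, function(v) var(v) == 0)
  if (any(degenerate)) {
    stop("zero-variance covariate column(s): ",
         paste(colnames(X)[-1][degenerate], collapse = ", "), call. = FALSE)
  }
  X
}
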