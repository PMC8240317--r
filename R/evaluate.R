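#' Mean squared error between two abundance matrices
#'
#' @param A,B Matrices of identical shape (log10 scale).
#' @param entries `"all"` (default) or a logical matrix selecting the
#'   entries to average over (e.g. a truth mask to score only the imputed
#'   positions).
#' @return Non-negative scalar.
#' @export
mse <- function(A, B, entries = "all") {
  stopifnot(all(dim(A) == dim(B)))
  d2 <- (A - B)^2
  if (is.matrix(entries)) {
    stopifnot(all(dim(entries) == dim(A)))
    mean(d2[entries])
  } else {
    mean(d2)
  }
}

#' Per-taxon Pearson correlation between two abundance matrices
#'
#' Columns with zero variance in either matrix have no defined correlation;
#' they are returned as `NA` and excluded from the mean.
#'
#' @param A,B Matrices of identical shape.
#' @return List with `per_taxon` (length-m vector, `NA` where undefined),
#'   `mean` (over defined taxa), and `n_undefined`.
#' @export
per_taxon_pearson <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  r <- vapply(seq_len(ncol(A)), function(j) {
    if (sd(A[, j]) == 0 || sd(B[, j]) == 0) return(NA_real_)
    cor(A[, j], B[, j])
  }, numeric(1))
  names(r) <- colnames(A)
  list(per_taxon = r, mean = mean(r, na.rm = TRUE),
       n_undefined = sum(is.na(r)))
}

#' Wasserstein distance between taxon mean/SD-ratio distributions
#'
#' For each matrix, every taxon is summarized by its abundance mean divided
#' by its abundance standard deviation across samples; the statistic is the
#' 1-D empirical Wasserstein-1 distance between the two resulting m-vectors
#' (for equal sizes, the mean absolute difference of the sorted vectors).
#' Zero-SD taxa are excluded pairwise.
#'
#' @param A,B Matrices of identical shape.
#' @return Non-negative scalar.
#' @export
wasserstein_mean_sd <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  ratio <- function(M, keep) colMeans(M[, keep, drop = FALSE]) /
    apply(M[, keep, drop = FALSE], 2, sd)
  keep <- apply(A, 2, sd) > 0 & apply(B, 2, sd) > 0
  if (!any(keep)) stop("no taxon has positive SD in both matrices",
                       call. = FALSE)
  mean(abs(sort(ratio(A, keep)) - sort(ratio(B, keep))))
}

#' Sensitivity and specificity of missing-entry detection
#'
#' @param mask_predicted An `mb_mask` or logical matrix of flagged entries.
#' @param truth_mask Logical matrix of truly injected entries.
#' @return List with `sensitivity` (fraction of true injections flagged;
#'   `NA` when the truth set is empty) and `specificity` (fraction of
#'   untouched entries left unflagged).
#' @export
detection_scores <- function(mask_predicted, truth_mask) {
  pred <- if (inherits(mask_predicted, "mb_mask")) {
    mask_predicted$flags
  } else {
    mask_predicted
  }
  stopifnot(all(dim(pred) == dim(truth_mask)))
  pos <- sum(truth_mask)
  neg <- sum(!truth_mask)
  list(sensitivity = if (pos == 0) NA_real_ else sum(pred & truth_mask) / pos,
       specificity = if (neg == 0) NA_real_ else sum(!pred & !truth_mask) / neg)
}

#' Pearson correlation of two whole matrices
#'
#' Correlation of the flattened matrices, the log-scale summary used for
#' the downsampling-recovery experiment.
#'
#' @param A,B Matrices of identical shape.
#' @return Scalar in `[-1, 1]`.
#' @export
matrix_pearson <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  a <- as.numeric(A)
  b <- as.numeric(B)
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance", call. = FALSE)
  cor(a, b)
}

#' Full evaluation report for an imputation run
#'
#' @param complete Complete (ground-truth) log10 abundance matrix.
#' @param observed Zero-inflated observed matrix (before imputation).
#' @param imputed Imputed matrix.
#' @param truth_mask Logical matrix of injected entries, or `NULL`.
#' @param mask_predicted Optional `mb_mask`/logical matrix of flags.
#' @return One-row tibble: MSE of observed and imputed vs complete (all
#'   entries and, when a truth mask is given, injected entries only), mean
#'   per-taxon Pearson correlations, Wasserstein mean/SD distances, matrix
#'   correlations, and detection scores when available.
#' @export
evaluate_imputation <- function(complete, observed, imputed,
                                truth_mask = NULL, mask_predicted = NULL) {
  out <- tibble::tibble(
    mse_observed = mse(complete, observed),
    mse_imputed = mse(complete, imputed),
    mean_pearson_observed = per_taxon_pearson(complete, observed)$mean,
    mean_pearson_imputed = per_taxon_pearson(complete, imputed)$mean,
    wasserstein_observed = wasserstein_mean_sd(complete, observed),
    wasserstein_imputed = wasserstein_mean_sd(complete, imputed),
    matrix_pearson_observed = matrix_pearson(complete, observed),
    matrix_pearson_imputed = matrix_pearson(complete, imputed))
  if (!is.null(truth_mask) && any(truth_mask)) {
    out$mse_observed_masked <- mse(complete, observed, truth_mask)
    out$mse_imputed_masked <- mse(complete, imputed, truth_mask)
  }
  if (!is.null(mask_predicted) && !is.null(truth_mask)) {
    sc <- detection_scores(mask_predicted, truth_mask)
    out$detection_sensitivity <- sc$sensitivity
    out$detection_specificity <- sc$specificity
  }
  out
}

#' Downsampling-recovery experiment
#'
#' Starting from a complete count matrix, reduces depth by proportional
#' downsampling ([downsample()]), runs the full two-step pipeline on the
#' downsampled counts, and reports how many of the introduced zeros were
#' flagged and how much the log-scale correlation with the complete data
#' recovered.
#'
#' @param counts_complete Complete samples x taxa count matrix.
#' @param keep_fraction Fraction of non-zero counts retained per sample
#'   (0.6 = 40% removal).
#' @param covariates,tree Passed through to [mbimpute()].
#' @param seed Seed for the downsampling draw and the pipeline.
#' @param ... Further arguments to [mbimpute()].
#' @return One-row tibble: removal rate, fraction of introduced zeros
#'   flagged, and log-scale matrix correlations with the complete data
#'   before and after imputation.
#' @export
run_downsample_experiment <- function(counts_complete, keep_fraction = 0.6,
                                      covariates = NULL, tree = NULL,
                                      seed = 1L, ...) {
  M <- as_count_matrix(counts_complete)
  ds <- downsample(M, keep_fraction, seed = seed)
  fit <- mbimpute(ds$counts, covariates = covariates, tree = tree,
                  seed = seed, ...)
  Y_complete <- log_transform(normalize_counts(M))
  sc <- detection_scores(fit$mask, ds$truth_mask)
  tibble::tibble(
    keep_fraction = keep_fraction,
    removal_rate = 1 - keep_fraction,
    n_zeros_introduced = sum(ds$truth_mask),
    flagged_fraction = sc$sensitivity,
    cor_before = matrix_pearson(Y_complete, fit$Y),
    cor_after = matrix_pearson(Y_complete, fit$Y_imputed))
}
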