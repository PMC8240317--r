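#' Impute the flagged entries of an abundance matrix
#'
#' Entries not flagged are copied through unchanged; each flagged entry
#' `(i, j)` is replaced by the fitted linear prediction
#' `sum_j' Y[i, j'] kappa[j', j] + sum_i' Y[i', j] tau[i, i'] + X[i, ] zeta[j, ]`,
#' using the observed (pre-imputation) abundances as predictors, and clamped
#' below at `log10(1.01)` so back-transformed counts are non-negative.
#'
#' @param Y Log10 abundance matrix.
#' @param model An `mb_model` from [fit_penalized()].
#' @param mask An `mb_mask` or logical flag matrix.
#' @param X Covariate matrix matching the model (or `NULL`).
#' @return Matrix of the same shape; unflagged entries bit-identical to `Y`.
#' @export
impute <- function(Y, model, mask, X = NULL) {
  flags <- if (inherits(mask, "mb_mask")) mask$flags else mask
  stopifnot(all(dim(flags) == dim(Y)))
  Yhat <- as.matrix(Y %*% model$kappa) + as.matrix(model$tau %*% Y)
  if (ncol(model$zeta) > 0) {
    stopifnot(!is.null(X), ncol(X) == ncol(model$zeta))
    Yhat <- Yhat + X %*% t(model$zeta)
  }
  out <- Y
  out[flags] <- pmax(Yhat[flags], LOG_FLOOR)
  out
}

#' Back-transform imputed log abundances to count scales
#'
#' Inverts the log10(x + 1.01) transform and, given the original library
#' sizes, rescales from the common 1e6 total back to each sample's depth.
#'
#' @param Y_imputed Imputed log10 abundance matrix.
#' @param library_sizes Per-sample totals recorded by [normalize_counts()];
#'   `NULL` returns only the normalized scale.
#' @return List with `counts_normalized` (rows on the 1e6 scale) and
#'   `counts_original_scale` (`NULL` when library sizes are not supplied).
#' @export
back_transform <- function(Y_imputed, library_sizes = NULL) {
  counts_normalized <- pmax(10^Y_imputed - 1.01, 0)
  counts_original_scale <- NULL
  if (!is.null(library_sizes)) {
    stopifnot(length(library_sizes) == nrow(Y_imputed))
    counts_original_scale <- counts_normalized * library_sizes / 1e6
  }
  list(counts_normalized = counts_normalized,
       counts_original_scale = counts_original_scale)
}
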