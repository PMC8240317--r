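#' Identify and impute non-biological zeros in a microbiome count matrix
#'
#' The full two-step pipeline. Step 1 fits, per taxon, a Gamma-normal
#' mixture (low Gamma mode for non-biological zeros and falsely low counts,
#' covariate-dependent normal for genuine abundances), screens it against a
#' normal-only model by likelihood-ratio test, and flags entries whose
#' posterior probability of belonging to the Gamma mode is at least
#' `d_thre`. Step 2 trains a joint L1-penalized linear model on the
#' unflagged entries — borrowing information from each taxon's `k`
#' phylogenetically nearest taxa, from the other samples, and from sample
#' covariates, with taxon-taxon penalty weights `D^psi` — and predicts the
#' flagged entries. Unflagged entries are never altered.
#'
#' @param counts Sample-by-taxon counts: a numeric matrix with sample
#'   rownames and taxon colnames, or a data frame whose first column holds
#'   sample ids, or a path to a TSV/CSV file.
#' @param covariates Optional per-sample covariate data frame (or TSV/CSV
#'   path); categorical columns are dummy-coded. Row order must match the
#'   samples.
#' @param tree Optional phylogeny (`phylo`, newick string, or file); used
#'   for branch-count distances.
#' @param distance Optional pre-computed taxon distance matrix (overrides
#'   `tree`). With neither, all between-taxon distances are 1.
#' @param normalize Scale every sample to a total of 1e6 first? Set `FALSE`
#'   for matrices already on a common scale.
#' @param include_libsize Add log10 library size as a covariate (default
#'   `TRUE`).
#' @param min_nonzero_fraction Optional taxon prefilter (see
#'   [filter_taxa()]); default 0 keeps all taxa.
#' @param k Neighbor taxa per taxon; defaults to 5 with a tree/distance,
#'   `min(m - 1, 20)` without.
#' @param d_thre Posterior threshold for flagging (default 0.5).
#' @param alpha_lrt Level of the likelihood-ratio screen (default 0.05).
#' @param psi_grid,n_lambda,lambda_min_ratio,cv_folds Tuning-grid controls
#'   passed to [fit_penalized()].
#' @param seed Integer seed for cross-validation fold assignment.
#' @return An object of class `mbimpute_fit` with elements `Y` (observed
#'   log10 abundances), `Y_imputed`, `counts_normalized`,
#'   `counts_original_scale`, `mask` (`mb_mask`), `model` (`mb_model`),
#'   `X`, `D`, `library_sizes`. Use [imputed_counts()], [tidy()],
#'   [glance()], and [autoplot()] to inspect it.
#' @examples
#' sim <- simulate_dataset(n = 20, m = 15, seed = 1)
#' fit <- mbimpute(sim$counts, covariates = sim$covariates,
#'                 tree = sim$newick, normalize = FALSE, seed = 1)
#' glance(fit)
#' @export
mbimpute <- function(counts, covariates = NULL, tree = NULL, distance = NULL,
                     normalize = TRUE, include_libsize = TRUE,
                     min_nonzero_fraction = 0, k = NULL,
                     d_thre = 0.5, alpha_lrt = 0.05,
                     psi_grid = c(0, 0.5, 1, 2), n_lambda = 30L,
                     lambda_min_ratio = 1e-3, cv_folds = 5L, seed = 1L) {
  M <- if (is.character(counts) && length(counts) == 1L) {
    read_count_matrix(counts)
  } else {
    as_count_matrix(counts)
  }
  if (min_nonzero_fraction > 0) M <- filter_taxa(M, min_nonzero_fraction)

  library_sizes <- rowSums(M)
  Mn <- if (normalize) normalize_counts(M) else M
  Y <- log_transform(Mn)

  X <- build_covariates(covariates, library_sizes,
                        include_libsize = include_libsize,
                        sample_ids = rownames(M))
  D <- phylo_distances(tree = tree, distance = distance,
                       taxon_ids = colnames(M))

  mask <- identify_missing(Y, X, d_thre = d_thre, alpha_lrt = alpha_lrt)
  if (!any(mask$flags)) {
    Y_imputed <- Y
    model <- NULL
  } else {
    model <- fit_penalized(Y, X, mask, D, k = k, psi_grid = psi_grid,
                           n_lambda = n_lambda,
                           lambda_min_ratio = lambda_min_ratio,
                           cv_folds = cv_folds, seed = seed)
    Y_imputed <- impute(Y, model, mask, X)
  }
  bt <- back_transform(Y_imputed, if (normalize) library_sizes else NULL)

  structure(list(Y = Y, Y_imputed = Y_imputed,
                 counts_normalized = bt$counts_normalized,
                 counts_original_scale = bt$counts_original_scale,
                 mask = mask, model = model, X = X, D = D,
                 library_sizes = library_sizes, normalize = normalize,
                 params = list(k = if (is.null(model)) k else model$k,
                               d_thre = d_thre, alpha_lrt = alpha_lrt,
                               seed = seed)),
            class = "mbimpute_fit")
}

#' Extract the imputed matrix as a tibble
#'
#' @param fit An `mbimpute_fit`.
#' @param scale `"log"` (log10 abundances), `"normalized"` (rows on the 1e6
#'   scale), or `"original"` (back at each sample's library size; requires
#'   the fit to have normalized internally).
#' @return A tibble with a leading `sample_id` column and one column per
#'   taxon.
#' @export
imputed_counts <- function(fit, scale = c("log", "normalized", "original")) {
  scale <- match.arg(scale)
  M <- switch(scale,
              log = fit$Y_imputed,
              normalized = fit$counts_normalized,
              original = fit$counts_original_scale)
  if (is.null(M)) {
    stop("original-scale counts unavailable: input was not normalized",
         call. = FALSE)
  }
  tibble::as_tibble(M, rownames = "sample_id")
}

#' @exportS3Method base::print
print.mbimpute_fit <- function(x, ...) {
  cat(sprintf("mbimpute fit: %d samples x %d taxa\n",
              nrow(x$Y), ncol(x$Y)))
  print(x$mask)
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' Per-taxon step-1 diagnostics of an mbimpute fit
#'
#' @param x An `mbimpute_fit`.
#' @param ... Unused.
#' @return Tibble with one row per taxon: LRT statistic and p-value,
#'   mixture estimates, and flag counts.
#' @export
tidy.mbimpute_fit <- function(x, ...) x$mask$screen

#' One-row summary of an mbimpute fit
#'
#' @param x An `mbimpute_fit`.
#' @param ... Unused.
#' @export
glance.mbimpute_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$Y), n_taxa = ncol(x$Y), n_covariates = ncol(x$X),
    n_flagged = sum(x$mask$flags), prop_flagged = mean(x$mask$flags),
    n_mixture_taxa = sum(x$mask$screen$use_mixture),
    k = if (is.null(x$model)) NA_integer_ else x$model$k,
    psi = if (is.null(x$model)) NA_real_ else x$model$psi,
    lambda = if (is.null(x$model)) NA_real_ else x$model$lambda,
    cv_error = if (is.null(x$model)) NA_real_ else x$model$cv_error)
}

#' Diagnostic plots for an mbimpute fit
#'
#' `type = "posteriors"` shows the distribution of per-entry posterior
#' missingness probabilities (typically concentrated near 0 and 1, which is
#' why the flagging threshold matters little); `type = "abundance"` overlays
#' the observed and imputed abundance distributions.
#'
#' @param object An `mbimpute_fit`.
#' @param type Plot flavor.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbimpute_fit <- function(object,
                                  type = c("posteriors", "abundance"), ...) {
  type <- match.arg(type)
  if (type == "posteriors") {
    df <- tibble::tibble(d = as.numeric(object$mask$posteriors))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
      ggplot2::geom_histogram(bins = 50, fill = "grey30") +
      ggplot2::geom_vline(xintercept = object$mask$d_thre,
                          linetype = "dashed", colour = "red") +
      ggplot2::labs(x = "posterior probability of missingness",
                    y = "entries",
                    title = "Step 1: posterior missingness probabilities") +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::bind_rows(
      tibble::tibble(stage = "observed", y = as.numeric(object$Y)),
      tibble::tibble(stage = "imputed", y = as.numeric(object$Y_imputed)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$y, colour = .data$stage)) +
      ggplot2::geom_density() +
      ggplot2::labs(x = "log10 abundance", y = "density",
                    title = "Abundance distribution before and after imputation") +
      ggplot2::theme_minimal()
  }
}
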