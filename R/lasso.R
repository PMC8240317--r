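# Weighted-L1 solver interface. Objective:
#   ||y - A beta||^2 + lambda * sum_p w_p |beta_p|
# Columns with w_p = 0 (the covariate block) are never penalized.

wlasso_path <- function(A, y, weights, lambdas, tol = NULL, maxit = 10000L) {
  A <- as(A, "CsparseMatrix")
  if (is.null(tol)) tol <- 1e-9 * sum(y^2)
  wlasso_path_cpp(A, as.numeric(y), as.numeric(weights),
                  as.numeric(lambdas), tol, as.integer(maxit))
}

# Smallest lambda at which every penalized coefficient is zero: from the
# stationarity condition |2 a_p' r0| <= lambda * w_p, with r0 the residual
# after least-squares on the unpenalized (zeta) block alone.
lambda_max_value <- function(A, y, weights) {
  unpen <- which(weights == 0)
  r0 <- y
  if (length(unpen)) {
    A0 <- A[, unpen, drop = FALSE]
    # the zeta block is block-diagonal per taxon, so the normal equations
    # are small and sparse
    G <- Matrix::crossprod(A0)
    b <- Matrix::crossprod(A0, y)
    coef0 <- tryCatch(as.numeric(Matrix::solve(G, b)),
                      error = function(e) {
                        as.numeric(Matrix::solve(
                          G + Matrix::Diagonal(ncol(A0), 1e-10), b))
                      })
    r0 <- y - as.numeric(A0 %*% coef0)
  }
  grad <- sparse_crossprod_cpp(as(A, "CsparseMatrix"), as.numeric(r0))
  pen <- weights > 0
  max(2 * abs(grad[pen]) / weights[pen])
}

lambda_grid <- function(lmax, n_lambda = 30L, lambda_min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Deterministic fold assignment over training entries: entries are put in
# canonical (sample id, taxon id) order before the seeded shuffle, so
# permuting the input rows/columns leaves the folds unchanged.
assign_folds <- function(rows, sample_ids, taxon_ids, n_folds, seed) {
  key <- order(sample_ids[rows$i], taxon_ids[rows$j])
  folds <- integer(nrow(rows))
  base <- rep_len(seq_len(n_folds), nrow(rows))
  shuffled <- withr::with_seed(seed, sample(base))
  folds[key] <- shuffled
  folds
}

# Canonical rank of each training entry; summing validation errors in this
# order keeps tuning selection invariant to sample/taxon permutations.
canonical_rank <- function(rows, sample_ids, taxon_ids) {
  order(order(sample_ids[rows$i], taxon_ids[rows$j]))
}

#' Fit the phylogeny-weighted L1 imputation model with cross-validated tuning
#'
#' Solves the joint penalized regression over all training entries: squared
#' error plus an L1 penalty whose weight on each taxon-taxon coefficient is
#' the phylogenetic distance raised to the power `psi` (sample-sample
#' coefficients carry weight 1; covariate coefficients are unpenalized). For
#' each `psi` in the grid, a path of `n_lambda` log-spaced penalties from
#' `lambda_max` down is solved by warm-started coordinate descent; `(psi,
#' lambda)` is chosen to minimize mean validation squared error over
#' `cv_folds` folds of training entries, then the model is refit on all
#' training entries at the selected pair.
#'
#' @param Y Log10 abundance matrix.
#' @param X Covariate matrix, or `NULL` for the covariate-free variant.
#' @param mask An `mb_mask` from [identify_missing()], or a logical matrix
#'   of flags.
#' @param D Taxon distance matrix.
#' @param k Number of neighbor taxa per taxon; default 5 when a non-trivial
#'   distance matrix is given, else `min(m - 1, 20)`.
#' @param psi_grid Candidate penalty-weight exponents.
#' @param n_lambda,lambda_min_ratio Length and depth of the lambda path.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `mb_model`: sparse `kappa` (m x m, `kappa[j2, j]`
#'   is the weight of taxon `j2` for predicting taxon `j`), sparse `tau`
#'   (n x n, `tau[i, i2]` the weight of sample `i2` for predicting sample
#'   `i`), `zeta` (m x q), `lambda`, `psi`, `k`, `cv_table` (tibble), and
#'   the `neighbors` matrix.
#' @export
fit_penalized <- function(Y, X, mask, D, k = NULL,
                          psi_grid = c(0, 0.5, 1, 2),
                          n_lambda = 30L, lambda_min_ratio = 1e-3,
                          cv_folds = 5L, seed = 1L) {
  flags <- if (inherits(mask, "mb_mask")) mask$flags else mask
  n <- nrow(Y)
  m <- ncol(Y)
  stopifnot(cv_folds >= 2L, length(psi_grid) >= 1L)
  if (is.null(k)) {
    trivial <- all(abs(D[upper.tri(D)] - 1) < 1e-12)
    k <- if (trivial) min(m - 1L, 20L) else min(m - 1L, 5L)
  }
  neighbors <- select_neighbor_taxa(D, k)

  # predictor values are identical across psi; only penalty weights change
  base <- build_design(Y, X, flags, neighbors, D, psi = 0)
  folds <- assign_folds(base$rows, rownames(Y), colnames(Y), cv_folds, seed)
  canon <- canonical_rank(base$rows, rownames(Y), colnames(Y))

  cv_rows <- list()
  paths <- list()
  for (pi in seq_along(psi_grid)) {
    psi <- psi_grid[pi]
    w <- psi_weights(base, D, psi)
    lmax <- lambda_max_value(base$A, base$y, w)
    lams <- lambda_grid(lmax, n_lambda, lambda_min_ratio)
    errs <- matrix(NA_real_, cv_folds, n_lambda)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      B <- wlasso_path(base$A[tr, , drop = FALSE], base$y[tr], w, lams)
      va <- which(!tr)[order(canon[!tr])]
      pred <- as.matrix(base$A[va, , drop = FALSE] %*% B)
      errs[f, ] <- colMeans((base$y[va] - pred)^2)
    }
    paths[[pi]] <- list(psi = psi, weights = w, lams = lams,
                        err = colMeans(errs))
    cv_rows[[pi]] <- tibble::tibble(psi = psi, lambda = lams,
                                    cv_error = colMeans(errs))
  }

  # select (psi, lambda): minimal CV error, with errors within a small
  # relative tolerance treated as tied (tie-break: smaller psi, then larger
  # lambda, i.e. the simpler model), so solver-noise-level differences
  # cannot make the selection depend on input ordering
  cv_table <- dplyr::bind_rows(cv_rows)
  tol <- 1e-5
  best_err <- min(cv_table$cv_error)
  tied <- cv_table$cv_error <= best_err + tol * (abs(best_err) + 1)
  cand <- cv_table[tied, ]
  cand <- cand[order(cand$psi, -cand$lambda), ][1, ]
  pi <- match(cand$psi, psi_grid)
  b <- match(cand$lambda, paths[[pi]]$lams)
  best <- list(err = cand$cv_error, psi = cand$psi, lambda = cand$lambda)

  # refit on all training entries at the selected pair, warm-started down
  # the path to the selected lambda
  Bfull <- wlasso_path(base$A, base$y, paths[[pi]]$weights,
                       paths[[pi]]$lams[seq_len(b)])
  beta <- Bfull[, b]
  unpack_model(beta, base, Y, X, best, cv_table, neighbors)
}

#' Covariate-free variant of the imputation model
#'
#' Identical pipeline with the covariate block absent: the design has
#' `mk + n(n-1)` columns and imputations use only neighbor taxa and other
#' samples.
#'
#' @inheritParams fit_penalized
#' @export
fit_no_covariates <- function(Y, mask, D, k = NULL,
                              psi_grid = c(0, 0.5, 1, 2),
                              n_lambda = 30L, lambda_min_ratio = 1e-3,
                              cv_folds = 5L, seed = 1L) {
  fit_penalized(Y, X = NULL, mask = mask, D = D, k = k, psi_grid = psi_grid,
                n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                cv_folds = cv_folds, seed = seed)
}

psi_weights <- function(design, D, psi) {
  w <- design$weights
  kap <- design$col_map$block == "kappa"
  w[kap] <- D[cbind(design$col_map$a[kap], design$col_map$b[kap])]^psi
  w
}

unpack_model <- function(beta, design, Y, X, best, cv_table, neighbors) {
  cm <- design$col_map
  n <- design$n; m <- design$m; q <- design$q
  kap <- cm$block == "kappa"
  tau <- cm$block == "tau"
  zet <- cm$block == "zeta"
  kappa <- Matrix::sparseMatrix(i = cm$b[kap], j = cm$a[kap],
                                x = beta[kap], dims = c(m, m))
  tmat <- Matrix::sparseMatrix(i = cm$a[tau], j = cm$b[tau],
                               x = beta[tau], dims = c(n, n))
  zeta <- if (q > 0L) {
    matrix(beta[zet], nrow = m, ncol = q, byrow = TRUE,
           dimnames = list(colnames(Y), colnames(X)))
  } else {
    matrix(0, m, 0)
  }
  kappa <- Matrix::drop0(kappa)
  tmat <- Matrix::drop0(tmat)
  dimnames(kappa) <- list(colnames(Y), colnames(Y))
  dimnames(tmat) <- list(rownames(Y), rownames(Y))
  structure(list(kappa = kappa, tau = tmat, zeta = zeta,
                 lambda = best$lambda, psi = best$psi, k = design$k,
                 cv_error = best$err, cv_table = cv_table,
                 neighbors = neighbors),
            class = "mb_model")
}

#' @exportS3Method base::print
print.mb_model <- function(x, ...) {
  cat(sprintf(
    "mb_model: k = %d neighbor taxa, selected psi = %g, lambda = %.4g\n",
    x$k, x$psi, x$lambda))
  cat(sprintf("  nonzero coefficients: %d taxon-taxon, %d sample-sample\n",
              Matrix::nnzero(x$kappa), Matrix::nnzero(x$tau)))
  invisible(x)
}

#' @export
tidy.mb_model <- function(x, ...) {
  kap <- Matrix::summary(x$kappa)
  tau <- Matrix::summary(x$tau)
  dplyr::bind_rows(
    tibble::tibble(block = "kappa", target = kap$j, source = kap$i,
                   estimate = kap$x),
    tibble::tibble(block = "tau", target = tau$i, source = tau$j,
                   estimate = tau$x),
    if (ncol(x$zeta) > 0) {
      tibble::tibble(block = "zeta",
                     target = rep(seq_len(nrow(x$zeta)), ncol(x$zeta)),
                     source = rep(seq_len(ncol(x$zeta)),
                                  each = nrow(x$zeta)),
                     estimate = as.numeric(x$zeta))
    })
}
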