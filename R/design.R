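#' Select each taxon's k phylogenetically nearest neighbors
#'
#' For each taxon, the `k` other taxa with smallest phylogenetic distance,
#' excluding the taxon itself, with ties broken by ascending taxon index.
#' Restricting the taxon-taxon coefficient block to these neighbors reduces
#' the imputation model from `m(m-1) + n(n-1) + mq` to
#' `mk + n(n-1) + mq` parameters.
#'
#' @param D Taxon distance matrix from [phylo_distances()].
#' @param k Number of neighbors, `1 <= k <= m - 1`.
#' @return Integer matrix `m x k`; row `j` holds the neighbor indices of
#'   taxon `j` in ascending-distance order.
#' @export
select_neighbor_taxa <- function(D, k) {
  m <- nrow(D)
  if (k < 1 || k > m - 1) {
    stop("k must be between 1 and m - 1 = ", m - 1, call. = FALSE)
  }
  nb <- matrix(0L, m, k)
  idx <- seq_len(m)
  for (j in idx) {
    others <- idx[-j]
    ord <- others[order(D[j, others], others)]  # distance, then index
    nb[j, ] <- ord[seq_len(k)]
  }
  rownames(nb) <- rownames(D)
  nb
}

#' Build the sparse training design for the joint imputation model
#'
#' One row per training entry `(i, j)` (entries not flagged for imputation).
#' The response is `Y[i, j]`; the predictors place the abundances of taxon
#' `j`'s `k` neighbor taxa in sample `i` (kappa block), taxon `j`'s
#' abundances in the other `n - 1` samples (tau block), and sample `i`'s
#' covariates (zeta block, per-taxon coefficients). Penalty weights are
#' `D[j, j']^psi` for kappa columns, 1 for tau columns, and 0 (unpenalized)
#' for zeta columns. Predictor values at flagged positions carry the
#' observed pre-imputation abundances.
#'
#' @param Y Log10 abundance matrix.
#' @param X Covariate matrix, or `NULL` for the covariate-free model.
#' @param flags Logical n x m matrix (`TRUE` = flagged for imputation).
#' @param neighbors From [select_neighbor_taxa()].
#' @param D Taxon distance matrix (for penalty weights).
#' @param psi Penalty-weight exponent (>= 0).
#' @return List of class `mb_design`: `A` (sparse `|Omega| x P`), `y`,
#'   `weights`, `rows` (tibble with `i`, `j`), `col_map` (tibble with
#'   `block`, `a`, `b`), dims `n`, `m`, `k`, `q`.
#' @export
build_design <- function(Y, X, flags, neighbors, D, psi) {
  n <- nrow(Y)
  m <- ncol(Y)
  k <- ncol(neighbors)
  q <- if (is.null(X)) 0L else ncol(X)
  stopifnot(psi >= 0, nrow(neighbors) == m, all(dim(flags) == dim(Y)))

  keep <- which(!flags)  # column-major linear indices = Omega
  if (!length(keep)) stop("nothing to train on: every entry is flagged",
                          call. = FALSE)
  ii <- ((keep - 1L) %% n) + 1L
  jj <- ((keep - 1L) %/% n) + 1L
  L <- length(keep)

  P_kappa <- m * k
  P_tau <- n * (n - 1L)
  P <- P_kappa + P_tau + m * q

  rows_i <- integer(0); cols <- integer(0); vals <- numeric(0)
  # kappa block: column (j-1)*k + r holds Y[, neighbors[j, r]]
  for (r in seq_len(k)) {
    rows_i <- c(rows_i, seq_len(L))
    cols <- c(cols, (jj - 1L) * k + r)
    vals <- c(vals, Y[cbind(ii, neighbors[jj, r])])
  }
  # tau block: for sample i, n-1 columns over samples i' != i (ascending)
  for (s in seq_len(n - 1L)) {
    ip <- ifelse(s < ii, s, s + 1L)
    rows_i <- c(rows_i, seq_len(L))
    cols <- c(cols, P_kappa + (ii - 1L) * (n - 1L) + s)
    vals <- c(vals, Y[cbind(ip, jj)])
  }
  # zeta block: per-taxon covariate coefficients, unpenalized
  if (q > 0L) {
    for (l in seq_len(q)) {
      rows_i <- c(rows_i, seq_len(L))
      cols <- c(cols, P_kappa + P_tau + (jj - 1L) * q + l)
      vals <- c(vals, X[ii, l])
    }
  }
  A <- Matrix::sparseMatrix(i = rows_i, j = cols, x = vals, dims = c(L, P))

  col_map <- dplyr::bind_rows(
    tidyr::expand_grid(a = seq_len(m), r = seq_len(k)) |>
      dplyr::mutate(block = "kappa", b = neighbors[cbind(.data$a, .data$r)]) |>
      dplyr::select("block", "a", "b"),
    tidyr::expand_grid(a = seq_len(n), s = seq_len(n - 1L)) |>
      dplyr::mutate(block = "tau",
                    b = ifelse(.data$s < .data$a, .data$s, .data$s + 1L)) |>
      dplyr::select("block", "a", "b"),
    if (q > 0L) {
      tidyr::expand_grid(a = seq_len(m), b = seq_len(q)) |>
        dplyr::mutate(block = "zeta") |>
        dplyr::select("block", "a", "b")
    })

  weights <- numeric(P)
  kap <- col_map$block == "kappa"
  weights[kap] <- D[cbind(col_map$a[kap], col_map$b[kap])]^psi
  weights[col_map$block == "tau"] <- 1
  # zeta weights stay 0: the covariate block is unpenalized

  structure(list(A = A, y = Y[keep], weights = weights,
                 rows = tibble::tibble(i = ii, j = jj),
                 col_map = col_map, n = n, m = m, k = k, q = q, psi = psi),
            class = "mb_design")
}
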