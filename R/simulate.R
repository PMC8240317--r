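#' Configuration for the synthetic abundance generator
#'
#' The generator produces complete log10 abundance matrices whose structure
#' can be encoded in three sources of signal — sample covariates, latent
#' sample clusters, and phylogenetically adjacent taxon blocks — gated by
#' `scheme`, and then injects non-biological zeros from a low Gamma mode
#' whose per-taxon rate increases for less abundant taxa.
#'
#' @param n,m,q Numbers of samples, taxa, and user covariates (all >= 2
#'   except `q >= 0`).
#' @param scheme Which signal sources are active: `"covariates"`,
#'   `"samples"`, `"taxa"`, or `"all"`.
#' @param base_mean_range Range of per-taxon baseline log10 abundances.
#' @param covariate_sd Standard deviation of per-taxon covariate effects.
#' @param sample_sd Standard deviation of latent sample-cluster effects.
#' @param taxon_sd Standard deviation of per-sample taxon-block effects.
#' @param noise_sd Residual noise standard deviation.
#' @param n_sample_clusters,n_taxon_blocks Numbers of latent clusters.
#' @param missing_rate Target average missing rate; per-taxon rates follow a
#'   logistic link that increases for lower-mean taxa.
#' @param missing_slope Slope of that logistic link.
#' @param gamma_shape,gamma_rate Parameters of the low (missing) Gamma mode.
#' @param hard_zero If `TRUE`, injected entries are set to `log10(1.01)`
#'   exactly (a zero count) instead of a Gamma draw.
#' @param seed Run seed; independent streams are derived from it for the
#'   tree, the signal, the noise, and the missingness, so the same config
#'   and seed always reproduce the same dataset.
#' @return A list of class `mb_sim_config`.
#' @export
simulate_config <- function(n = 50L, m = 60L, q = 2L,
                            scheme = c("all", "covariates", "samples", "taxa"),
                            base_mean_range = c(2, 4.5),
                            covariate_sd = 0.4, sample_sd = 0.8,
                            taxon_sd = 0.8, noise_sd = 0.5,
                            n_sample_clusters = 3L, n_taxon_blocks = 6L,
                            missing_rate = 0.3, missing_slope = 0.8,
                            gamma_shape = 2, gamma_rate = 20,
                            hard_zero = FALSE, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 2, m >= 2, q >= 0, missing_rate > 0, missing_rate < 1)
  structure(as.list(environment()), class = "mb_sim_config")
}

#' Random taxon phylogeny and branch-count distance matrix
#'
#' @param m Number of leaf taxa (>= 2).
#' @param seed Integer seed.
#' @param taxon_ids Optional leaf labels; default `taxon1..taxonm`.
#' @return List with `tree` (`phylo`), `newick` (string), and `D`
#'   (branch-count distance matrix in `taxon_ids` order).
#' @export
gen_tree_and_distances <- function(m, seed = 1L, taxon_ids = NULL) {
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(m))
  stopifnot(m >= 2, length(taxon_ids) == m)
  tree <- withr::with_seed(seed, ape::rtree(m, tip.label = taxon_ids))
  newick <- ape::write.tree(tree)
  D <- phylo_distances(tree = tree, taxon_ids = taxon_ids)
  list(tree = tree, newick = newick, D = D)
}

#' Generate the complete (zero-free) part of a synthetic dataset
#'
#' `Y_complete[i, j] = mu_j + a_i + u[i, block(j)] + Z[i, ] g[, j] + noise`,
#' floored at `log10(1.01)`. The sample effect `a_i` is shared across taxa
#' within latent sample clusters; the taxon-block effect `u` is a per-sample
#' latent factor shared by taxa adjacent in the phylogeny, so same-block
#' taxa are correlated across samples; the covariate effect is linear in the
#' user covariates. `scheme` gates which of the three are nonzero.
#'
#' @param config From [simulate_config()].
#' @return List of class `mb_sim` with `Y_complete`, `covariates` (tibble of
#'   user covariates), `tree`, `newick`, `D`, and `params` (ground truth,
#'   including the three realized `effects` matrices and the `noise`
#'   matrix).
#' @export
gen_complete <- function(config) {
  stopifnot(inherits(config, "mb_sim_config"))
  n <- config$n; m <- config$m; q <- config$q
  sample_ids <- paste0("sample", seq_len(n))
  taxon_ids <- paste0("taxon", seq_len(m))

  tr <- gen_tree_and_distances(m, seed = config$seed, taxon_ids = taxon_ids)
  blocks <- stats::cutree(stats::hclust(stats::as.dist(tr$D), "average"),
                          k = min(config$n_taxon_blocks, m))

  sig <- withr::with_seed(config$seed + 1L, {
    mu <- runif(m, config$base_mean_range[1], config$base_mean_range[2])
    cl <- sample(rep_len(seq_len(config$n_sample_clusters), n))
    v <- rnorm(config$n_sample_clusters, 0, config$sample_sd)
    u <- matrix(rnorm(n * max(blocks), 0, config$taxon_sd), n, max(blocks))
    Z <- matrix(rnorm(n * max(q, 1)), n, max(q, 1))[, seq_len(q), drop = FALSE]
    g <- matrix(rnorm(max(q, 1) * m, 0, config$covariate_sd),
                max(q, 1), m)[seq_len(q), , drop = FALSE]
    list(mu = mu, cl = cl, v = v, u = u, Z = Z, g = g)
  })
  eps <- withr::with_seed(config$seed + 2L,
                          matrix(rnorm(n * m, 0, config$noise_sd), n, m))

  gate <- config$scheme
  cov_on <- gate %in% c("all", "covariates") && q > 0
  sam_on <- gate %in% c("all", "samples")
  tax_on <- gate %in% c("all", "taxa")

  zero <- matrix(0, n, m)
  effects <- list(
    sample = if (sam_on) matrix(sig$v[sig$cl], n, m) else zero,
    taxon = if (tax_on) sig$u[, blocks] else zero,
    covariate = if (cov_on) sig$Z %*% sig$g else zero)
  Y <- matrix(rep(sig$mu, each = n), n, m) +
    effects$sample + effects$taxon + effects$covariate
  Y <- pmax(Y + eps, LOG_FLOOR)
  dimnames(Y) <- list(sample_ids, taxon_ids)

  covariates <- if (q > 0) {
    stats::setNames(tibble::as_tibble(sig$Z, .name_repair = "minimal"),
                    paste0("cov", seq_len(q)))
  } else {
    NULL
  }
  structure(list(Y_complete = Y, covariates = covariates, tree = tr$tree,
                 newick = tr$newick, D = tr$D,
                 params = c(sig, list(blocks = blocks, effects = effects,
                                      noise = eps, config = config))),
            class = "mb_sim")
}

#' Inject non-biological zeros into a complete synthetic dataset
#'
#' Each entry of taxon `j` is independently replaced with probability `p_j`
#' by a draw from the low Gamma mode (truncated to `>= log10(1.01)`), or by
#' exactly `log10(1.01)` in `hard_zero` mode. `p_j` follows a logistic link
#' that increases for taxa with lower baseline abundance, mimicking the
#' depth-dependence of real zero patterns.
#'
#' @param sim An `mb_sim` from [gen_complete()].
#' @return The same object, extended with `Y_observed`, `truth_mask`
#'   (logical, `TRUE` where an entry was replaced), `p_missing` (per-taxon
#'   rates), and observed/complete count matrices `counts`,
#'   `counts_complete` (inverse of the log transform, so
#'   `mbimpute(..., normalize = FALSE)` reproduces `Y_observed` exactly).
#' @export
inject_missing <- function(sim) {
  config <- sim$params$config
  n <- config$n; m <- config$m
  mu <- sim$params$mu
  p_j <- plogis(qlogis(config$missing_rate) +
                  config$missing_slope * (mean(mu) - mu))
  p_j <- pmin(pmax(p_j, 0.02), 0.8)

  out <- withr::with_seed(config$seed + 3L, {
    mask <- matrix(runif(n * m), n, m) < rep(p_j, each = n)
    low <- if (config$hard_zero) {
      rep(LOG_FLOOR, sum(mask))
    } else {
      draw_truncated_gamma(sum(mask), config$gamma_shape, config$gamma_rate)
    }
    list(mask = mask, low = low)
  })
  Y_obs <- sim$Y_complete
  Y_obs[out$mask] <- out$low
  dimnames(out$mask) <- dimnames(Y_obs)

  sim$Y_observed <- Y_obs
  sim$truth_mask <- out$mask
  sim$p_missing <- p_j
  sim$counts <- pmax(10^Y_obs - 1.01, 0)
  sim$counts_complete <- pmax(10^sim$Y_complete - 1.01, 0)
  sim
}

# Gamma draws conditioned to lie above the log floor (the low mode must stay
# a valid positive abundance)
draw_truncated_gamma <- function(nn, shape, rate) {
  x <- rgamma(nn, shape = shape, rate = rate)
  for (tries in 1:100) {
    bad <- x < LOG_FLOOR
    if (!any(bad)) break
    x[bad] <- rgamma(sum(bad), shape = shape, rate = rate)
  }
  pmax(x, LOG_FLOOR)
}

#' Generate a complete-plus-zero-inflated synthetic dataset
#'
#' Convenience wrapper: [simulate_config()], [gen_complete()], then
#' [inject_missing()].
#'
#' @param ... Passed to [simulate_config()].
#' @return An `mb_sim`; see [inject_missing()] for the fields.
#' @examples
#' sim <- simulate_dataset(n = 20, m = 15, seed = 7)
#' mean(sim$truth_mask)
#' @export
simulate_dataset <- function(...) {
  inject_missing(gen_complete(simulate_config(...)))
}

#' Proportional downsampling of a count matrix
#'
#' Emulates reduced sequencing depth: within each sample, a fraction
#' `keep_fraction` of the non-zero taxon counts is retained, sampled without
#' replacement with inclusion probability proportional to the count (larger
#' counts are more likely to survive); unsampled counts are set to zero and
#' recorded in the returned mask. `keep_fraction` 0.6 and 0.3 correspond to
#' removal rates of 40% and 70%.
#'
#' @param M Samples x taxa count matrix.
#' @param keep_fraction Fraction of non-zero entries to keep, in `(0, 1]`.
#' @param seed Integer seed.
#' @return List with `counts` (downsampled matrix) and `truth_mask`
#'   (logical, `TRUE` where a non-zero count was zeroed).
#' @export
downsample <- function(M, keep_fraction, seed = 1L) {
  M <- as_count_matrix(M)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  mask <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
  if (keep_fraction == 1) return(list(counts = M, truth_mask = mask))
  out <- M
  withr::with_seed(seed, {
    for (i in seq_len(nrow(M))) {
      nz <- which(M[i, ] > 0)
      n_keep <- ceiling(keep_fraction * length(nz))
      if (n_keep >= length(nz)) next
      kept <- sample(nz, n_keep, prob = M[i, nz])
      dropped <- setdiff(nz, kept)
      out[i, dropped] <- 0
      mask[i, dropped] <- TRUE
    }
  })
  list(counts = out, truth_mask = mask)
}

#' Append outlier samples to a synthetic dataset
#'
#' Outlier samples carry large abundances for a chosen set of lowly
#' abundant taxa and zeros everywhere else, emulating gross library
#' artifacts used to probe robustness.
#'
#' @param sim An `mb_sim` with injected missingness.
#' @param n_outliers Number of outlier samples to append (0 = no-op).
#' @param n_boosted_taxa Number of lowly abundant taxa boosted in each
#'   outlier (must be < m).
#' @param seed Integer seed.
#' @return The extended `mb_sim`; `outlier_samples` names the appended
#'   rows. Appended rows are marked `FALSE` throughout `truth_mask`.
#' @export
gen_outlier_samples <- function(sim, n_outliers, n_boosted_taxa, seed = 1L) {
  if (n_outliers == 0) return(sim)
  m <- ncol(sim$Y_observed)
  stopifnot(n_boosted_taxa < m)
  low_taxa <- order(sim$params$mu)[seq_len(n_boosted_taxa)]
  ids <- paste0("outlier", seq_len(n_outliers))
  rows <- withr::with_seed(seed, {
    R <- matrix(LOG_FLOOR, n_outliers, m)
    R[, low_taxa] <- runif(n_outliers * n_boosted_taxa, 3.5, 4.5)
    R
  })
  rownames(rows) <- ids
  colnames(rows) <- colnames(sim$Y_observed)

  grow <- function(M) {
    out <- rbind(M, rows)
    out
  }
  sim$Y_observed <- grow(sim$Y_observed)
  sim$Y_complete <- grow(sim$Y_complete)
  falsemask <- matrix(FALSE, n_outliers, m, dimnames = dimnames(rows))
  sim$truth_mask <- rbind(sim$truth_mask, falsemask)
  sim$counts <- pmax(10^sim$Y_observed - 1.01, 0)
  sim$counts_complete <- pmax(10^sim$Y_complete - 1.01, 0)
  if (!is.null(sim$covariates)) {
    extra <- withr::with_seed(seed + 1L, {
      as.data.frame(matrix(rnorm(n_outliers * ncol(sim$covariates)),
                           n_outliers))
    })
    names(extra) <- names(sim$covariates)
    sim$covariates <- dplyr::bind_rows(sim$covariates, extra)
  }
  sim$outlier_samples <- ids
  sim
}
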