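#' Control parameters for the Gamma-normal mixture EM
#'
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param p_min Lower/upper clip for the mixing weight: `p` is kept in
#'   `[p_min, 1 - p_min]` each iteration.
#' @param shape_max Upper cap on the Gamma shape, guarding against the
#'   unbounded likelihood when the low mode degenerates to a point mass
#'   (e.g. a spike of identical zero counts).
#' @param gamma_mean_max Largest admissible mean of the Gamma component on
#'   the log10 abundance scale. The Gamma mode models non-biological zeros
#'   and falsely low counts, so its mean must be close to zero; the default
#'   1 corresponds to roughly ten reads per million. A "mixture" whose low
#'   component sits above this (e.g. one fitting the lower tail of a
#'   unimodal normal) is rejected in favor of the normal-only boundary
#'   solution.
#' @return A list of class `mb_em_control`.
#' @export
em_control <- function(tol = 1e-6, max_iter = 100L, p_min = 1e-6,
                       shape_max = 1e4, gamma_mean_max = 1) {
  structure(list(tol = tol, max_iter = max_iter, p_min = p_min,
                 shape_max = shape_max, gamma_mean_max = gamma_mean_max),
            class = "mb_em_control")
}

#' Normal linear model fit for one taxon (maximum likelihood)
#'
#' Fits `y ~ N(X gamma, sigma^2)` by least squares with the MLE variance
#' (divisor n). This is the null model of the per-taxon likelihood-ratio
#' screen.
#'
#' @param y Strictly positive abundances (one taxon across samples).
#' @param X Covariate matrix from [build_covariates()].
#' @return List with `coefs`, `sd`, `fitted`, `loglik`.
#' @export
fit_normal <- function(y, X) {
  n <- length(y)
  q <- ncol(X)
  stopifnot(n > q)
  fit <- lm.fit(X, y)
  if (fit$rank < q) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("covariate matrix is rank deficient (collinear: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  mu <- drop(X %*% fit$coefficients)
  s2 <- mean((y - mu)^2)
  s <- sqrt(s2)
  if (s < 1e-6) {
    warning("zero residual variance; sd floored at 1e-6")
    s <- 1e-6
  }
  structure(list(coefs = fit$coefficients, sd = s, fitted = mu,
                 loglik = sum(dnorm(y, mu, s, log = TRUE))),
            class = "mb_normal_fit")
}

# Responsibility-weighted Gamma MLE. Profile likelihood in the shape:
# log(a) - digamma(a) = log(weighted mean y) - weighted mean log y,
# solved by Newton iterations; rate = shape / weighted mean.
weighted_gamma_mle <- function(y, w, shape_max = 1e4) {
  sw <- sum(w)
  ybar <- sum(w * y) / sw
  lbar <- sum(w * log(y)) / sw
  s <- log(ybar) - lbar
  if (!is.finite(s) || s <= 1e-12) {
    # (near-)degenerate spike: push shape to its cap
    a <- shape_max
  } else {
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # moment start
    for (it in 1:50) {
      g <- log(a) - digamma(a) - s
      h <- 1 / a - trigamma(a)
      step <- g / h
      a_new <- a - step
      if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
      if (abs(a_new - a) < 1e-10 * a) {
        a <- a_new
        break
      }
      a <- a_new
    }
  }
  a <- min(max(a, 1e-3), shape_max)
  list(shape = a, rate = a / ybar)
}

#' Fit the Gamma-normal mixture for one taxon by EM
#'
#' Models a taxon's log abundances as a two-component mixture: with
#' probability `p` a draw from a Gamma distribution (the low mode of
#' non-biological zeros and falsely low counts, mean close to zero) and with
#' probability `1 - p` a draw from a normal whose mean is a linear function
#' of the sample covariates. The E-step computes the posterior probability
#' that each point belongs to the Gamma component; the M-step updates `p` as
#' the mean responsibility, the normal coefficients by responsibility-
#' weighted least squares, and the Gamma parameters by responsibility-
#' weighted maximum likelihood (Newton iterations on the shape).
#'
#' The observed-data log-likelihood is non-decreasing across iterations, and
#' the final fit is always compared against the boundary solution
#' `p = p_min` (effectively the normal-only model): the better of the two is
#' returned, so the mixture log-likelihood never falls below the nested
#' normal fit. A fitted "Gamma" component whose mean exceeds the average
#' normal mean is rejected as label switching and replaced by the boundary
#' solution.
#'
#' @inheritParams fit_normal
#' @param control See [em_control()].
#' @return List of class `mb_mixture_fit`: `p`, `gamma_shape`, `gamma_rate`,
#'   `normal_coefs`, `normal_sd`, `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`, `boundary` (TRUE if the normal-only boundary solution won).
#' @export
fit_mixture_em <- function(y, X, control = em_control()) {
  n <- length(y)
  q <- ncol(X)
  stopifnot(n > q + 3, all(y > 0))
  nfit <- fit_normal(y, X)

  boundary <- function(converged = TRUE, trace = numeric()) {
    structure(list(p = control$p_min, gamma_shape = 1, gamma_rate = 100,
                   normal_coefs = nfit$coefs, normal_sd = nfit$sd,
                   loglik = nfit$loglik, loglik_trace = trace,
                   converged = converged, n_iter = length(trace),
                   boundary = TRUE),
              class = "mb_mixture_fit")
  }

  # initial responsibilities: entries close to the zero floor are assigned
  # to the Gamma component; fall back to the lower 20% quantile split
  r <- as.numeric(y < LOG_FLOOR + 0.3)
  if (all(r == 0) || all(r == 1)) {
    r <- as.numeric(y <= quantile(y, 0.2))
    if (all(r == 0) || all(r == 1)) return(boundary())
  }

  p <- min(max(mean(r), control$p_min), 1 - control$p_min)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  est <- NULL
  for (iter in seq_len(control$max_iter)) {
    # M-step
    p <- min(max(mean(r), control$p_min), 1 - control$p_min)
    gm <- tryCatch(weighted_gamma_mle(y, pmax(r, 1e-12), control$shape_max),
                   error = function(e) NULL)
    if (is.null(gm)) return(boundary(converged = FALSE, trace = trace))
    w <- pmax(1 - r, 1e-12)
    wfit <- lm.fit(X * sqrt(w), y * sqrt(w))
    if (wfit$rank < q || anyNA(wfit$coefficients)) {
      return(boundary(converged = FALSE, trace = trace))
    }
    mu <- drop(X %*% wfit$coefficients)
    s <- sqrt(sum(w * (y - mu)^2) / sum(w))
    if (!is.finite(s) || s < 1e-6) s <- 1e-6
    est <- list(p = p, shape = gm$shape, rate = gm$rate,
                coefs = wfit$coefficients, sd = s, mu = mu)
    # E-step
    lg <- dgamma(y, shape = gm$shape, rate = gm$rate, log = TRUE) + log(p)
    ln <- dnorm(y, mu, s, log = TRUE) + log1p(-p)
    mx <- pmax(lg, ln)
    r <- exp(lg - mx) / (exp(lg - mx) + exp(ln - mx))
    ll <- sum(mx + log(exp(lg - mx) + exp(ln - mx)))
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < control$tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (is.null(est)) return(boundary(converged = FALSE, trace = trace))
  ll <- trace[length(trace)]

  # label-switching guard: the Gamma component must be the low mode, and a
  # low mode that is not actually near zero is no missingness component
  gamma_mean <- est$shape / est$rate
  if (gamma_mean > mean(est$mu) || gamma_mean > control$gamma_mean_max) {
    return(boundary(trace = trace))
  }
  # boundary candidate: keep the mixture only if it beats normal-only
  if (!is.finite(ll) || ll < nfit$loglik) {
    return(boundary(converged = converged, trace = trace))
  }
  structure(list(p = est$p, gamma_shape = est$shape, gamma_rate = est$rate,
                 normal_coefs = est$coefs, normal_sd = est$sd,
                 loglik = ll, loglik_trace = trace, converged = converged,
                 n_iter = length(trace), boundary = FALSE),
            class = "mb_mixture_fit")
}

#' Likelihood-ratio screen of mixture vs normal-only model
#'
#' The mixture has `q + 4` free parameters (mixing weight, Gamma shape and
#' rate, `q` normal-mean coefficients, normal sd) against `q + 1` for the
#' plain normal model, so the statistic is referred to a chi-square
#' distribution with 3 degrees of freedom.
#'
#' @param mix An `mb_mixture_fit` from [fit_mixture_em()].
#' @param norm An `mb_normal_fit` from [fit_normal()] on the same data.
#' @return List with `stat` (non-negative), `df`, `pvalue`.
#' @export
lrt_screen <- function(mix, norm) {
  q <- length(norm$coefs)
  df <- (q + 4L) - (q + 1L)
  stat <- max(2 * (mix$loglik - norm$loglik), 0)
  list(stat = stat, df = df,
       pvalue = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Posterior probability of membership in the Gamma (missing) component
#'
#' For each observation, the posterior that it was generated by the low
#' Gamma mode of the fitted mixture, evaluated through log densities for
#' numerical stability.
#'
#' @inheritParams fit_normal
#' @param mix An `mb_mixture_fit`.
#' @return Numeric vector in `[0, 1]`, one value per observation.
#' @export
posterior_missing <- function(y, X, mix) {
  mu <- drop(X %*% mix$normal_coefs)
  lg <- dgamma(y, shape = mix$gamma_shape, rate = mix$gamma_rate,
               log = TRUE) + log(mix$p)
  ln <- dnorm(y, mu, mix$normal_sd, log = TRUE) + log1p(-mix$p)
  mx <- pmax(lg, ln)
  d <- exp(lg - mx) / (exp(lg - mx) + exp(ln - mx))
  pmin(pmax(d, 0), 1)
}

#' Identify entries that need imputation (step 1)
#'
#' Runs the per-taxon screen over the whole abundance matrix: fit the normal
#' model and the Gamma-normal mixture, compare them by likelihood-ratio
#' test, and — for taxa where the mixture wins at level `alpha_lrt` — flag
#' every entry whose posterior probability of belonging to the Gamma
#' component is at least `d_thre`. Taxa where the normal model is retained
#' contribute no flags (all posteriors set to 0). Taxa whose fit fails for
#' numerical reasons fall back to the normal-only model rather than aborting
#' the run.
#'
#' @param Y Log10 abundance matrix from [log_transform()].
#' @param X Covariate matrix from [build_covariates()].
#' @param d_thre Posterior threshold above which an entry is flagged
#'   (default 0.5).
#' @param alpha_lrt Significance level of the likelihood-ratio screen
#'   (default 0.05).
#' @param control See [em_control()].
#' @return An object of class `mb_mask`: list with `flags` (n x m logical,
#'   `TRUE` = impute), `posteriors` (n x m numeric), `screen` (per-taxon
#'   tibble of LRT statistics, p-values, and mixture estimates), `d_thre`,
#'   `alpha_lrt`.
#' @export
identify_missing <- function(Y, X, d_thre = 0.5, alpha_lrt = 0.05,
                             control = em_control()) {
  n <- nrow(Y)
  m <- ncol(Y)
  q <- ncol(X)
  stopifnot(nrow(X) == n)
  D <- matrix(0, n, m, dimnames = dimnames(Y))
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    y <- Y[, j]
    res <- screen_taxon(y, X, alpha_lrt, control)
    if (res$use_mixture) D[, j] <- res$d
    rows[[j]] <- tibble::tibble(
      taxon = colnames(Y)[j], lrt_stat = res$stat, lrt_pvalue = res$pvalue,
      use_mixture = res$use_mixture, p_hat = res$p,
      gamma_shape = res$shape, gamma_rate = res$rate,
      normal_sd = res$sd, em_converged = res$converged)
  }
  screen <- dplyr::bind_rows(rows)
  flags <- D >= d_thre
  screen$n_flagged <- colSums(flags)
  structure(list(flags = flags, posteriors = D, screen = screen,
                 d_thre = d_thre, alpha_lrt = alpha_lrt),
            class = "mb_mask")
}

screen_taxon <- function(y, X, alpha_lrt, control) {
  q <- ncol(X)
  fallback <- list(use_mixture = FALSE, d = numeric(length(y)),
                   stat = 0, pvalue = 1, p = NA_real_, shape = NA_real_,
                   rate = NA_real_, sd = NA_real_, converged = FALSE)
  if (length(y) < q + 4 || var(y) == 0) return(fallback)
  out <- tryCatch({
    norm <- fit_normal(y, X)
    mix <- fit_mixture_em(y, X, control)
    lrt <- lrt_screen(mix, norm)
    use <- lrt$pvalue <= alpha_lrt && !mix$boundary
    d <- if (use) posterior_missing(y, X, mix) else numeric(length(y))
    list(use_mixture = use, d = d, stat = lrt$stat, pvalue = lrt$pvalue,
         p = mix$p, shape = mix$gamma_shape, rate = mix$gamma_rate,
         sd = mix$normal_sd, converged = mix$converged)
  }, error = function(e) fallback)
  out
}

#' @exportS3Method base::print
print.mb_mask <- function(x, ...) {
  cat(sprintf(
    "mb_mask: %d of %d entries flagged for imputation (%.1f%%), d_thre = %g\n",
    sum(x$flags), length(x$flags), 100 * mean(x$flags), x$d_thre))
  cat(sprintf("  %d of %d taxa screened into the mixture model\n",
              sum(x$screen$use_mixture), nrow(x$screen)))
  invisible(x)
}

#' @export
tidy.mb_mask <- function(x, ...) x$screen
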