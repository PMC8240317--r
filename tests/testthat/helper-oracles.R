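# Independent oracles used to verify the package's numerics. These are
# deliberately implemented with different algorithms than the package code.

# Proximal-gradient (FISTA) solver for the weighted-L1 least-squares
# objective ||y - A b||^2 + lambda * sum(w |b|), on a dense matrix.
fista_wlasso <- function(A, y, w, lambda, iters = 50000L, tol = 1e-12) {
  A <- as.matrix(A)
  P <- ncol(A)
  L <- 2 * max(eigen(crossprod(A), symmetric = TRUE,
                     only.values = TRUE)$values)
  b <- numeric(P)
  z <- b
  t_k <- 1
  obj_old <- Inf
  for (it in seq_len(iters)) {
    grad <- -2 * crossprod(A, y - A %*% z)
    x <- z - grad / L
    thr <- lambda * w / L
    b_new <- sign(x) * pmax(abs(x) - thr, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    b <- b_new
    t_k <- t_new
    if (it %% 200 == 0) {
      obj <- sum((y - A %*% b)^2) + lambda * sum(w * abs(b))
      if (abs(obj_old - obj) < tol * (abs(obj) + 1)) break
      obj_old <- obj
    }
  }
  drop(b)
}

wlasso_objective <- function(A, y, w, lambda, b) {
  sum((y - as.matrix(A) %*% b)^2) + lambda * sum(w * abs(b))
}

# Wasserstein-1 distance between two empirical distributions via the CDF
# difference integral (exact for step functions), independent of the
# sorted-vector formulation used in the package.
w1_cdf_oracle <- function(a, b) {
  br <- sort(unique(c(a, b)))
  if (length(br) == 1) return(0)
  Fa <- stats::ecdf(a)
  Fb <- stats::ecdf(b)
  mids <- head(br, -1)
  widths <- diff(br)
  sum(abs(Fa(mids) - Fb(mids)) * widths)
}

# Pearson correlation from the raw covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Upper-tail chi-square probability by numerical integration of the density.
chisq_tail_oracle <- function(x, df) {
  stats::integrate(function(t) stats::dchisq(t, df), x, Inf,
                   rel.tol = 1e-10)$value
}

# Small abundance matrix + covariates fixture with known dimensions.
tiny_instance <- function(n = 6, m = 5, q = 1, seed = 42) {
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * m, 3, 0.6), n, m,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("t", seq_len(m))))
    X <- cbind("(Intercept)" = 1,
               matrix(rnorm(n * q), n, q,
                      dimnames = list(NULL, paste0("x", seq_len(q)))))
    D <- as.matrix(stats::dist(matrix(rnorm(m * 2), m, 2))) + 1
    diag(D) <- 0
    dimnames(D) <- list(colnames(Y), colnames(Y))
    flags <- matrix(FALSE, n, m, dimnames = dimnames(Y))
    flags[cbind(sample(n, 6, replace = TRUE), sample(m, 6, replace = TRUE))] <- TRUE
    list(Y = Y, X = X, D = D, flags = flags)
  })
}
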