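test_that("normal fit reproduces the two-point MLE and the normal equations", {
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_normal(c(0.004, 2), X)  # y must only be positive downstream
  expect_equal(unname(f$coefs), 1.002)
  expect_equal(f$sd, 0.998)

  withr::with_seed(9, {
    X2 <- cbind(1, rnorm(50), runif(50))
    y <- drop(X2 %*% c(3, 0.4, -0.2)) + rnorm(50, 0, 0.3)
    f2 <- fit_normal(y, X2)
    # residuals orthogonal to every column of X
    expect_lt(max(abs(crossprod(X2, y - f2$fitted))), 1e-8)
  })

  X3 <- cbind("(Intercept)" = rep(1, 10), dup = rep(1, 10))
  expect_error(fit_normal(rnorm(10, 3), X3), "rank deficient")
})

test_that("normal fit recovers known coefficients on simulated data", {
  withr::with_seed(11, {
    n <- 2000
    X <- cbind(1, rnorm(n))
    gamma_true <- c(3, 0.7)
    y <- drop(X %*% gamma_true) + rnorm(n, 0, 0.5)
    f <- fit_normal(y, X)
    expect_lt(max(abs(f$coefs - gamma_true)), 0.05)
    expect_lt(abs(f$sd - 0.5), 0.05)
  })
})

test_that("EM recovers mixture parameters on seeded single-taxon data", {
  withr::with_seed(101, {
    n <- 1000
    miss <- runif(n) < 0.3
    y <- ifelse(miss, rgamma(n, shape = 2, rate = 20), rnorm(n, 3, 0.5))
    y <- pmax(y, 1e-4)
  })
  X <- matrix(1, 1000, 1)
  fit <- fit_mixture_em(y, X)
  expect_false(fit$boundary)
  expect_lt(abs(fit$p - 0.3), 0.05)
  expect_lt(abs(fit$gamma_shape / fit$gamma_rate - 0.1), 0.05)
  expect_lt(abs(unname(fit$normal_coefs[1]) - 3), 0.1)
  expect_lt(abs(fit$normal_sd - 0.5), 0.1)
})

test_that("EM log-likelihood is monotone non-decreasing across iterations", {
  for (seed in c(7, 21, 33)) {
    withr::with_seed(seed, {
      n <- 300
      miss <- runif(n) < 0.25
      y <- pmax(ifelse(miss, rgamma(n, 2, 20), rnorm(n, 3.5, 0.4)), 1e-4)
    })
    fit <- fit_mixture_em(y, matrix(1, length(y), 1))
    tr <- fit$loglik_trace
    expect_gte(min(diff(tr)), -1e-7 * (abs(tr[1]) + 1))
  }
})

test_that("unimodal normal data drives the mixture to the boundary", {
  withr::with_seed(5, y <- rnorm(500, 5, 0.5))
  fit <- fit_mixture_em(y, matrix(1, 500, 1))
  norm <- fit_normal(y, matrix(1, 500, 1))
  expect_lte(fit$p, 0.01)
  expect_gte(fit$loglik, norm$loglik)  # nested-model dominance
})

test_that("mixture log-likelihood never falls below the normal fit", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- 120
      frac <- runif(1, 0, 0.5)
      y <- pmax(ifelse(runif(n) < frac, rgamma(n, 2, 20),
                       rnorm(n, runif(1, 2, 5), 0.5)), 1e-4)
    })
    X <- matrix(1, length(y), 1)
    expect_gte(fit_mixture_em(y, X)$loglik, fit_normal(y, X)$loglik)
  }
})

test_that("LRT uses chi-square with 3 df for any number of covariates", {
  withr::with_seed(13, {
    n <- 400
    for (q_extra in 0:3) {
      X <- cbind(1, matrix(rnorm(n * q_extra), n, q_extra))
      y <- pmax(ifelse(runif(n) < 0.3, rgamma(n, 2, 20),
                       drop(X %*% runif(ncol(X), 0.5, 1)) + rnorm(n, 2, 0.4)),
                1e-4)
      lrt <- lrt_screen(fit_mixture_em(y, X), fit_normal(y, X))
      expect_identical(lrt$df, 3L)
      expect_equal(lrt$pvalue,
                   pchisq(lrt$stat, 3, lower.tail = FALSE))
    }
  })
})

test_that("LRT edge values match an independent chi-square tail evaluation", {
  mk <- function(ll) list(loglik = ll, coefs = c(0))
  eq <- lrt_screen(structure(mk(-10), class = "mb_mixture_fit"),
                   structure(mk(-10), class = "mb_normal_fit"))
  expect_equal(eq$stat, 0)
  expect_equal(eq$pvalue, 1)

  lrt <- lrt_screen(structure(mk(-10), class = "mb_mixture_fit"),
                    structure(mk(-10 - 11.34 / 2), class = "mb_normal_fit"))
  expect_equal(lrt$stat, 11.34)
  expect_equal(lrt$pvalue, chisq_tail_oracle(11.34, 3), tolerance = 1e-8)
  expect_equal(lrt$pvalue, 0.01, tolerance = 0.005)
})

test_that("posterior missingness matches direct density-ratio evaluation", {
  mix <- structure(list(p = 0.3, gamma_shape = 2, gamma_rate = 20,
                        normal_coefs = c(3), normal_sd = 0.5,
                        boundary = FALSE),
                   class = "mb_mixture_fit")
  X <- matrix(1, 2, 1)
  d <- posterior_missing(c(0.05, 3.0), X, mix)
  ratio <- function(y) {
    num <- 0.3 * dgamma(y, 2, 20)
    num / (num + 0.7 * dnorm(y, 3, 0.5))
  }
  expect_equal(d, ratio(c(0.05, 3.0)), tolerance = 1e-12)
  expect_gt(d[1], 0.99)
  expect_lt(d[2], 1e-6)

  # monotone non-increasing between the Gamma mode and the normal mean
  grid <- seq(0.05, 3, length.out = 200)
  dg <- posterior_missing(grid, matrix(1, 200, 1), mix)
  expect_true(all(diff(dg) <= 1e-12))
  expect_true(all(dg >= 0 & dg <= 1))

  # degenerate mixture: p at its floor gives near-zero posteriors
  mix$p <- 1e-6
  expect_lt(max(posterior_missing(seq(1, 4, 0.5), matrix(1, 7, 1), mix)),
            0.05)
})

test_that("identify_missing flags injected entries and spares normal taxa", {
  withr::with_seed(23, {
    n <- 200
    Y <- cbind(rnorm(n, 4, 0.3),                       # pure normal taxon
               pmax(ifelse(runif(n) < 0.3, rgamma(n, 2, 20),
                           rnorm(n, 3, 0.5)), 1e-4))
    dimnames(Y) <- list(paste0("s", 1:n), c("clean", "inflated"))
  })
  X <- matrix(1, 200, 1, dimnames = list(rownames(Y), "(Intercept)"))
  mask <- identify_missing(Y, X)
  expect_s3_class(mask, "mb_mask")
  expect_equal(sum(mask$flags[, "clean"]), 0)
  expect_gt(sum(mask$flags[, "inflated"]), 0)
  expect_false(mask$screen$use_mixture[1])
  expect_true(mask$screen$use_mixture[2])
  # posteriors of a retained-normal taxon are all zero
  expect_true(all(mask$posteriors[, "clean"] == 0))
  expect_true(all(mask$posteriors >= 0 & mask$posteriors <= 1))
  expect_identical(dim(mask$flags), dim(Y))
  expect_s3_class(tidy(mask), "tbl_df")
})

test_that("LRT type-I rejection rate on normal-only taxa stays in a loose band", {
  withr::with_seed(77, {
    n <- 200
    Y <- matrix(rnorm(n * 200, mean = rep(runif(200, 3, 5), each = n),
                      sd = 0.4), n, 200)
    dimnames(Y) <- list(paste0("s", 1:n), paste0("t", 1:200))
  })
  X <- matrix(1, 200, 1, dimnames = list(rownames(Y), "(Intercept)"))
  mask <- identify_missing(Y, X)
  rej <- mean(mask$screen$use_mixture)
  expect_gte(rej, 0)
  expect_lte(rej, 0.10)
})

test_that("flagging is robust to the posterior threshold", {
  sim <- simulate_dataset(n = 50, m = 60, seed = 19)
  X <- build_covariates(sim$covariates, rowSums(sim$counts))
  m4 <- identify_missing(sim$Y_observed, X, d_thre = 0.4)
  m6 <- identify_missing(sim$Y_observed, X, d_thre = 0.6)
  changed <- mean(m4$flags != m6$flags)
  expect_lt(changed, 0.05)
})
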