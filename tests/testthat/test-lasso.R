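# the tiny instance of the solver checks: n=6 samples, m=5 taxa, k=2
# neighbors, q=1 user covariate, |Omega| = 24 training entries
tiny_problem <- function(seed = 42, psi = 1) {
  inst <- tiny_instance(n = 6, m = 5, q = 1, seed = seed)
  inst$flags[] <- FALSE
  inst$flags[cbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 1))] <- TRUE
  nb <- select_neighbor_taxa(inst$D, 2)
  des <- build_design(inst$Y, inst$X, inst$flags, nb, inst$D, psi = psi)
  list(inst = inst, nb = nb, des = des)
}

test_that("coordinate descent matches the proximal-gradient oracle on the tiny instance", {
  tp <- tiny_problem()
  des <- tp$des
  expect_equal(nrow(des$A), 24)
  lmax <- mbimpute:::lambda_max_value(des$A, des$y, des$weights)
  lambda <- 0.5 * lmax
  b_cd <- mbimpute:::wlasso_path(des$A, des$y, des$weights, lambda,
                                 tol = 1e-14 * sum(des$y^2))[, 1]
  b_or <- fista_wlasso(des$A, des$y, des$weights, lambda, iters = 100000L)
  expect_lt(max(abs(b_cd - b_or)), 1e-4)
  # and the two objectives agree even more tightly
  expect_equal(wlasso_objective(des$A, des$y, des$weights, lambda, b_cd),
               wlasso_objective(des$A, des$y, des$weights, lambda, b_or),
               tolerance = 1e-8)
})

test_that("training objective is non-increasing along the decreasing-lambda path", {
  tp <- tiny_problem(seed = 7)
  des <- tp$des
  lmax <- mbimpute:::lambda_max_value(des$A, des$y, des$weights)
  lams <- mbimpute:::lambda_grid(lmax, 12)
  B <- mbimpute:::wlasso_path(des$A, des$y, des$weights, lams)
  rss <- apply(B, 2, function(b) sum((des$y - as.numeric(des$A %*% b))^2))
  expect_true(all(diff(rss) <= 1e-8 * (rss[-length(rss)] + 1)))
})

test_that("solution agrees with glmnet under the objective mapping", {
  tp <- tiny_problem(seed = 12)
  des <- tp$des
  lmax <- mbimpute:::lambda_max_value(des$A, des$y, des$weights)
  lambda <- 0.3 * lmax
  b_cd <- mbimpute:::wlasso_path(des$A, des$y, des$weights, lambda,
                                 tol = 1e-14 * sum(des$y^2))[, 1]
  N <- length(des$y)
  P <- ncol(des$A)
  gfit <- glmnet::glmnet(des$A, des$y, family = "gaussian",
                         alpha = 1, standardize = FALSE, intercept = FALSE,
                         penalty.factor = des$weights,
                         lambda = lambda * sum(des$weights) / (2 * N * P),
                         thresh = 1e-14)
  expect_lt(max(abs(b_cd - as.numeric(gfit$beta))), 1e-4)
})

test_that("at lambda >= lambda_max only the covariate block survives", {
  inst <- tiny_instance(n = 8, m = 6, q = 1, seed = 4)
  flags <- matrix(FALSE, 8, 6, dimnames = dimnames(inst$Y))
  flags[1, 2] <- TRUE
  model <- fit_penalized(inst$Y, inst$X, flags, inst$D, k = 2,
                         psi_grid = 1, n_lambda = 1,
                         cv_folds = 3, seed = 1)
  # with the path pinned at lambda_max, kappa and tau vanish (up to the
  # coordinate-descent convergence tolerance at the boundary)
  expect_lt(max(abs(model$kappa)), 1e-5)
  expect_lt(max(abs(model$tau)), 1e-5)
  # and predictions equal per-taxon OLS on the covariates over Omega
  pred <- impute(inst$Y, model, flags, inst$X)
  j <- 2
  keep <- !flags[, j]
  ols <- lm.fit(inst$X[keep, , drop = FALSE], inst$Y[keep, j])$coefficients
  expect_equal(pred[1, 2], unname(drop(inst$X[1, ] %*% ols)),
               tolerance = 1e-6)
})

test_that("increasing one pair's distance never increases its coefficient", {
  tp <- tiny_problem(seed = 20, psi = 1)
  des <- tp$des
  lmax <- mbimpute:::lambda_max_value(des$A, des$y, des$weights)
  lambda <- 0.1 * lmax
  solve_at <- function(D) {
    w <- mbimpute:::psi_weights(des, D, psi = 1)
    mbimpute:::wlasso_path(des$A, des$y, w, lambda,
                           tol = 1e-13 * sum(des$y^2))[, 1]
  }
  cm <- tp$des$col_map
  target <- which(cm$block == "kappa")[1]
  j <- cm$a[target]; jp <- cm$b[target]
  b0 <- solve_at(tp$inst$D)
  vals <- abs(b0[target])
  for (mult in c(2, 5, 20)) {
    D2 <- tp$inst$D
    D2[j, jp] <- D2[jp, j] <- tp$inst$D[j, jp] * mult
    vals <- c(vals, abs(solve_at(D2)[target]))
  }
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("covariate-free variant drops the zeta block and shrinks to zero", {
  inst <- tiny_instance(n = 6, m = 5, q = 1, seed = 31)
  flags <- matrix(FALSE, 6, 5, dimnames = dimnames(inst$Y))
  flags[2, 3] <- TRUE
  nb <- select_neighbor_taxa(inst$D, 2)
  des <- build_design(inst$Y, NULL, flags, nb, inst$D, psi = 0)
  expect_equal(ncol(des$A), 5 * 2 + 6 * 5)  # mk + n(n-1)

  model <- fit_no_covariates(inst$Y, flags, inst$D, k = 2, psi_grid = 0,
                             n_lambda = 1, cv_folds = 3, seed = 2)
  expect_equal(ncol(model$zeta), 0)
  # full shrinkage with no intercept block: raw predictions are zero, so
  # imputed values sit at the positivity floor
  pred <- impute(inst$Y, model, flags)
  expect_equal(pred[2, 3], log10(1.01))
})

test_that("centered responses make covariate and covariate-free fits agree", {
  inst <- tiny_instance(n = 8, m = 6, q = 1, seed = 55)
  # center each taxon over its training entries: the intercept-only
  # covariate block then has nothing to absorb
  flags <- matrix(FALSE, 8, 6, dimnames = dimnames(inst$Y))
  flags[cbind(1:3, 1:3)] <- TRUE
  Yc <- inst$Y
  for (j in 1:6) Yc[, j] <- inst$Y[, j] - mean(inst$Y[!flags[, j], j])
  Xi <- matrix(1, 8, 1, dimnames = list(rownames(Yc), "(Intercept)"))
  m_cov <- fit_penalized(Yc, Xi, flags, inst$D, k = 2, psi_grid = 1,
                         n_lambda = 10, cv_folds = 3, seed = 3)
  m_no <- fit_no_covariates(Yc, flags, inst$D, k = 2, psi_grid = 1,
                            n_lambda = 10, cv_folds = 3, seed = 3)
  expect_equal(m_cov$lambda, m_no$lambda)
  expect_lt(max(abs(m_cov$zeta)), 1e-3)  # fitted intercepts are ~0
  # unclamped linear predictions of the two variants agree
  ph_c <- as.matrix(Yc %*% m_cov$kappa) + as.matrix(m_cov$tau %*% Yc) +
    Xi %*% t(m_cov$zeta)
  ph_n <- as.matrix(Yc %*% m_no$kappa) + as.matrix(m_no$tau %*% Yc)
  expect_lt(max(abs(ph_c[flags] - ph_n[flags])), 1e-3)
})
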