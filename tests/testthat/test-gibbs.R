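# small G kernel reused across sampler tests
gibbs_kernel <- function(n = 60) {
  ds <- small_dataset()
  unclass(ds$G)[seq_len(n), seq_len(n)]
}

test_that("chains are reproducible under the same seed", {
  G <- gibbs_kernel(40)
  set.seed(2); y <- rnorm(40)
  f1 <- fit_gibbs(y, NULL, list(G = G), mcmc = mcmc_config(400, 100, 2, seed = 7))
  f2 <- fit_gibbs(y, NULL, list(G = G), mcmc = mcmc_config(400, 100, 2, seed = 7))
  expect_identical(f1$var_draws, f2$var_draws)
  expect_identical(f1$effects, f2$effects)
})

test_that("with an identity kernel the model reduces to Bayesian ridge", {
  n <- 50
  set.seed(5)
  y <- rnorm(n, 1, 1)
  su <- 0.6; se <- 0.4
  fit <- fit_gibbs(y, NULL, list(G = diag(n)),
                   mcmc = mcmc_config(30000, 2000, 1, seed = 3),
                   fixed_variances = list(G = su, e = se))
  # closed form at fixed variances: shrink centered y by su/(su+se)
  b <- mean(y)  # flat prior on the intercept -> posterior mean ~ ybar
  ridge <- su / (su + se) * (y - b)
  expect_gt(cor(fit$effects$G, ridge), 0.999)
  expect_lt(max(abs(fit$effects$G - ridge)), 0.05)
})

test_that("fixed-variance posterior mean matches the mixed-model-equation solution", {
  n <- 60
  G <- gibbs_kernel(n)
  set.seed(8)
  su <- 0.5; se <- 0.5
  u_true <- drop(chol(G + diag(1e-8, n)) %*% rnorm(n)) * sqrt(su)
  y <- 2 + u_true + rnorm(n, 0, sqrt(se))
  X <- matrix(1, n, 1)
  fit <- fit_gibbs(y, X, list(G = G), mcmc = mcmc_config(12000, 2000, 1, seed = 1),
                   fixed_variances = list(G = su, e = se))
  ed <- eigen(G, symmetric = TRUE)
  lam <- pmax(ed$values, 1e-8 * max(ed$values))
  Ginv <- ed$vectors %*% (t(ed$vectors) / lam)
  V <- G * su + diag(se, n)
  bhat <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  uhat <- solve(diag(n) + Ginv * se / su, y - drop(X %*% bhat))
  expect_gt(cor(fit$effects$G, uhat), 0.99)
  expect_lt(sqrt(mean((fit$effects$G - uhat)^2)), 0.05 * sd(uhat))
})

test_that("null-signal heritability posterior matches exact grid integration", {
  # independent oracle: 2-D grid integration of the exact marginal
  # posterior of (sigma2_u, sigma2_e), intercept integrated out
  n <- 120
  G <- gibbs_kernel(n)
  ed <- eigen(G, symmetric = TRUE)
  lam <- pmax(ed$values, 1e-8 * max(ed$values))
  set.seed(19)
  y <- rnorm(n)
  yt <- drop(crossprod(ed$vectors, y - mean(y)))
  vy <- var(y); df0 <- 5
  s0 <- vy * 0.5 * (df0 + 2)  # total prior scale per component
  logpost <- function(su, se) {
    v <- lam * su + se
    -0.5 * sum(log(v)) - 0.5 * sum(yt^2 / v) +
      (-(df0 / 2 + 1)) * (log(su) + log(se)) - s0 / (2 * su) - s0 / (2 * se)
  }
  grd <- expand.grid(su = seq(0.005, 2.5, length.out = 100),
                     se = seq(0.05, 2.5, length.out = 100))
  w <- exp(mapply(logpost, grd$su, grd$se))
  w <- w / sum(w)
  h2_oracle <- sum(w * grd$su / (grd$su + grd$se))

  fit <- fit_gibbs(y, NULL, list(G = G), mcmc = mcmc_config(8000, 2000, 2, seed = 3))
  h2_gibbs <- mean(variance_ratios(fit)$h2)
  expect_lt(abs(h2_gibbs - h2_oracle), 0.05)
  # pure noise pulls h2 well below the prior's equal-split allocation
  expect_lt(h2_gibbs, 0.4)
})

test_that("the sampler is scale equivariant", {
  n <- 40
  G <- gibbs_kernel(n)
  set.seed(6); y <- rnorm(n)
  c_scale <- 3.7
  f1 <- fit_gibbs(y, NULL, list(G = G), mcmc = mcmc_config(500, 100, 1, seed = 11))
  f2 <- fit_gibbs(c_scale * y, NULL, list(G = G),
                  mcmc = mcmc_config(500, 100, 1, seed = 11))
  expect_equal(f2$effects$G, c_scale * f1$effects$G, tolerance = 1e-8)
  expect_equal(f2$var_draws, c_scale^2 * f1$var_draws, tolerance = 1e-8)
  expect_equal(f2$beta_mean, c_scale * f1$beta_mean, tolerance = 1e-8)
})

test_that("consistent permutation of animals permutes effects and leaves variances alike", {
  n <- 60
  G <- gibbs_kernel(n)
  set.seed(13)
  u <- drop(chol(G + diag(1e-8, n)) %*% rnorm(n)) * sqrt(0.5)
  y <- u + rnorm(n, 0, sqrt(0.5))
  perm <- sample(n)
  f1 <- fit_gibbs(y, NULL, list(G = G), mcmc = mcmc_config(8000, 2000, 2, seed = 2))
  f2 <- fit_gibbs(y[perm], NULL, list(G = G[perm, perm]),
                  mcmc = mcmc_config(8000, 2000, 2, seed = 2))
  expect_lt(max(abs(colMeans(f1$var_draws) - colMeans(f2$var_draws))), 0.02)
  expect_gt(cor(f1$effects$G[perm], f2$effects$G), 0.98)
})

test_that("degenerate inputs are rejected", {
  G <- gibbs_kernel(20)
  y <- rnorm(20)
  X_bad <- cbind(1, 1)[rep(1, 20), ]
  expect_error(fit_gibbs(y, X_bad, list(G = G)), "full column rank")
  expect_error(fit_gibbs(y, NULL, list(G)), "named list")
  bad <- G; bad[1, 2] <- bad[1, 2] + 1
  expect_error(fit_gibbs(y, NULL, list(G = bad)), "symmetric")
})

test_that("predictions decompose linearly and project through the kernel", {
  ds <- small_dataset()
  n_train <- 60
  train <- ds$population$animal_id[1:n_train]
  val <- ds$population$animal_id[61:70]
  Gf <- unclass(ds$G); Mf <- unclass(ds$M)
  y <- ds$phenotypes$ADG[1:n_train]
  fit <- fit_gibbs(y, NULL, list(G = Gf[train, train], M = Mf[train, train]),
                   mcmc = mcmc_config(1200, 400, 2, seed = 4))
  kernels <- list(G = Gf, M = Mf)
  p_ebv <- predict(fit, "EBV", val, kernels)
  p_emv <- predict(fit, "EMV", val, kernels)
  p_both <- predict(fit, "EBV+EMV", val, kernels)
  expect_equal(p_both, p_ebv + p_emv, tolerance = 1e-12)
  # projection equals the hand-computed K_vt K_tt^-1 u
  ed <- eigen(Gf[train, train], symmetric = TRUE)
  lam <- pmax(ed$values, 1e-8 * max(ed$values))
  kinv_u <- ed$vectors %*% (crossprod(ed$vectors, fit$effects$G) / lam)
  by_hand <- unname(drop(Gf[val, train] %*% kinv_u))
  expect_equal(unname(p_ebv), by_hand, tolerance = 1e-10)
  # zero covariance row -> prediction 0
  kern0 <- kernels
  kern0$G[val, train] <- 0
  kern0$M[val, train] <- 0
  expect_equal(unname(predict(fit, "EBV+EMV", val, kern0)), rep(0, 10))
  # unsupported component
  fit_g <- fit_gibbs(y, NULL, list(G = Gf[train, train]),
                     mcmc = mcmc_config(300, 100, 1, seed = 1))
  expect_error(predict(fit_g, "EMV"), "needs kernel")
})

test_that("adjust_phenotypes subtracts the posterior-mean fixed effects", {
  n <- 50
  G <- gibbs_kernel(n)
  set.seed(3)
  y <- 5 + rnorm(n)
  X <- matrix(1, n, 1)
  fit <- fit_gibbs(y, X, list(G = G), mcmc = mcmc_config(800, 200, 2, seed = 2))
  ys <- adjust_phenotypes(fit, y, X)
  expect_equal(ys, y - fit$beta_mean[1])
  expect_lt(abs(mean(ys)), 0.3)
  expect_error(adjust_phenotypes(fit, y, cbind(X, X)), "dimension")
  # beta = 0 leaves y unchanged
  fit0 <- fit
  fit0$beta_mean[] <- 0
  expect_equal(adjust_phenotypes(fit0, y, X), y)
})

test_that("variance ratios are the draw-wise fractions", {
  fake <- structure(list(var_draws = cbind(G = rep(1, 10), M = rep(1, 10),
                                           e = rep(1, 10))),
                    class = "holopred_fit")
  vr <- variance_ratios(fake)
  expect_equal(vr$h2, rep(1 / 3, 10))
  expect_equal(vr$m2, rep(1 / 3, 10))
  fake_micro <- structure(list(var_draws = cbind(M = c(2, 4), e = c(2, 4))),
                          class = "holopred_fit")
  vr2 <- variance_ratios(fake_micro)
  expect_equal(vr2$h2, c(0, 0))
  expect_equal(vr2$m2, c(0.5, 0.5))
})

test_that("joint masked fit agrees with kernel projection", {
  ds <- small_dataset()
  ids <- ds$population$animal_id
  train <- ids[1:100]; val <- ids[101:120]
  Gf <- unclass(ds$G)
  y_all <- ds$phenotypes$ADG
  names(y_all) <- ids
  idx <- c(train, val)
  fit_p <- fit_gibbs(y_all[train], NULL, list(G = Gf[train, train]),
                     mcmc = mcmc_config(4000, 1000, 2, seed = 5))
  pred_p <- predict(fit_p, "EBV", val, list(G = Gf))
  fit_j <- fit_gibbs(y_all[idx], NULL, list(G = Gf[idx, idx]),
                     mcmc = mcmc_config(4000, 1000, 2, seed = 5),
                     mask = c(rep(FALSE, 100), rep(TRUE, 20)))
  pred_j <- predict(fit_j, "EBV", val)
  expect_gt(cor(pred_p, pred_j), 0.9)
})
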