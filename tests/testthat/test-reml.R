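## Fixture: small A-structured dataset with known generating values
make_reml_fixture <- function(seed = 1, nrep = 3, s2a = 2, s2e = 1) {
  set.seed(seed)
  ped <- data.frame(clone = letters[1:10],
                    sire = c(NA, NA, NA, NA, "a", "a", "a", "e", "e", "f"),
                    dam = c(NA, NA, NA, NA, "b", "c", "d", "b", "f", "g"))
  A <- amat_tetra(ped)
  obs <- data.frame(clone = rep(ped$clone, nrep), trait = "t", value = NA,
                    year = 2014, block = rep(seq_len(nrep), each = 10),
                    replicate = rep(seq_len(nrep), each = 10))
  Z <- outer(obs$clone, ped$clone, "==") * 1
  X <- stats::model.matrix(~ factor(block), obs)
  a <- drop(t(chol(s2a * A)) %*% rnorm(10))
  obs$value <- drop(X %*% seq_len(ncol(X))) + drop(Z %*% a) +
    rnorm(nrow(obs), 0, sqrt(s2e))
  list(ped = ped, A = A, obs = obs, X = X, Z = Z)
}

test_that("AI-REML matches a brute-force likelihood maximisation", {
  fx <- make_reml_fixture(seed = 11)
  fit <- diallel_blup(fx$obs, fx$A, pedigree = fx$ped, line = FALSE,
                      family = FALSE, fixed = ~block_year)
  ## independent oracle: optimise the explicit REML likelihood over V
  obj <- function(lt) {
    th <- exp(lt)
    V <- th[1] * fx$Z %*% fx$A %*% t(fx$Z) + th[2] * diag(nrow(fx$obs))
    m2ll_direct(fx$obs$value, fx$X, V)
  }
  opt <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(fit$m2ll, opt$value, tolerance = 1e-6)
  expect_equal(unname(fit$vc[c("sigma2_a", "sigma2_e")]), exp(opt$par),
               tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("identity-covariance REML reproduces balanced one-way ANOVA and lme4", {
  set.seed(21)
  q <- 15; r <- 4
  g <- factor(rep(seq_len(q), each = r))
  y <- 5 + rep(rnorm(q, 0, sqrt(3)), each = r) + rnorm(q * r, 0, 1)
  ped <- data.frame(clone = levels(g), sire = NA, dam = NA)
  I <- diag(q); dimnames(I) <- list(levels(g), levels(g))
  obs <- data.frame(clone = as.character(g), trait = "t", value = y)
  fit <- diallel_blup(obs, I, pedigree = ped, line = FALSE, family = FALSE,
                      fixed = ~1)
  ## closed-form REML on balanced data
  msb <- r * var(tapply(y, g, mean))
  msw <- sum((y - ave(y, g))^2) / (q * (r - 1))
  expect_equal(unname(fit$vc["sigma2_e"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$vc["sigma2_a"]), (msb - msw) / r, tolerance = 1e-6)
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$vc["sigma2_a"]), vc$vcov[1], tolerance = 1e-5)
  expect_equal(unname(fit$vc["sigma2_e"]), vc$vcov[2], tolerance = 1e-5)
})

test_that("REML is invariant to record order and phenotype translation", {
  fx <- make_reml_fixture(seed = 31)
  fit <- diallel_blup(fx$obs, fx$A, pedigree = fx$ped, line = FALSE,
                      family = FALSE)
  set.seed(1)
  perm <- sample(nrow(fx$obs))
  fit_p <- diallel_blup(fx$obs[perm, ], fx$A, pedigree = fx$ped, line = FALSE,
                        family = FALSE)
  expect_equal(fit$vc, fit_p$vc, tolerance = 1e-6)
  expect_equal(fit$m2ll, fit_p$m2ll, tolerance = 1e-6)
  obs_sh <- fx$obs; obs_sh$value <- obs_sh$value + 100
  fit_s <- diallel_blup(obs_sh, fx$A, pedigree = fx$ped, line = FALSE,
                        family = FALSE)
  expect_equal(fit$vc, fit_s$vc, tolerance = 1e-5)
  expect_equal(fit$ebv, fit_s$ebv, tolerance = 1e-5)
})

test_that("pure-noise data drives the additive variance to the boundary", {
  ## under a true sigma2_a of 0 the REML estimator has half its mass exactly
  ## at the boundary and the rest near it (half-normal asymptotics)
  ped <- quick_sim(seed = 1)$pedigree
  A <- amat_tetra(ped)
  nseed <- 20
  ratio <- vapply(seq_len(nseed), function(s) {
    set.seed(300 + s)
    obs <- data.frame(clone = rep(ped$clone, 2), trait = "t",
                      value = rnorm(2 * nrow(ped)))
    fit <- suppressWarnings(
      diallel_blup(obs, A, pedigree = ped, line = FALSE, family = FALSE,
                   fixed = ~1))
    unname(fit$vc["sigma2_a"] / fit$vc["sigma2_e"])
  }, numeric(1))
  expect_gte(mean(ratio < 1e-2), 0.40)   # mass exactly at the floor
  expect_gte(mean(ratio < 0.15), 0.95)   # essentially no additive variance
})

test_that("BLUP solve equals brute-force GLS on a toy instance", {
  fx <- make_reml_fixture(seed = 41, nrep = 2)
  th <- c(1.7, 0.9)
  sol <- diallel_blup(fx$obs, fx$A, pedigree = fx$ped, line = FALSE,
                      family = FALSE, fixed = ~block_year,
                      vc = c(sigma2_a = th[1], sigma2_e = th[2]))
  V <- th[1] * fx$Z %*% fx$A %*% t(fx$Z) + th[2] * diag(nrow(fx$obs))
  oracle <- gls_blup(fx$obs$value, fx$X, fx$Z, fx$A, th[1], V)
  expect_equal(unname(sol$beta), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(unname(sol$ebv[fx$ped$clone]), unname(oracle$ebv),
               tolerance = 1e-6)
})

test_that("clone without records or relatives shrinks to the prior", {
  ped <- data.frame(clone = c("a", "b", "lonely"), sire = NA, dam = NA)
  A <- amat_tetra(ped)
  obs <- data.frame(clone = c("a", "b", "a", "b"), trait = "t",
                    value = c(1.2, -0.8, 1.0, -1.1))
  s2a <- 1.5; s2e <- 0.5
  sol <- diallel_blup(obs, A, pedigree = ped, line = FALSE, family = FALSE,
                      fixed = ~1, vc = c(sigma2_a = s2a, sigma2_e = s2e))
  expect_equal(unname(sol$ebv["lonely"]), 0)
  expect_equal(unname(sol$pev["lonely"]), s2a * A["lonely", "lonely"],
               tolerance = 1e-10)
})

test_that("duplicating every record keeps fixed effects, shrinks PEV", {
  ## exact fixed-effect invariance holds in the exchangeable balanced case;
  ## PEVs strictly decrease with the doubled information in either case
  set.seed(51)
  q <- 12
  ped <- data.frame(clone = paste0("c", seq_len(q)), sire = NA, dam = NA)
  I <- diag(q); dimnames(I) <- list(ped$clone, ped$clone)
  obs <- data.frame(clone = rep(ped$clone, 2), trait = "t",
                    value = rnorm(2 * q) + rep(rnorm(q), 2),
                    year = 2014, block = rep(1:2, each = q),
                    replicate = rep(1:2, each = q))
  vc <- c(sigma2_a = 1.3, sigma2_e = 0.7)
  sol1 <- diallel_blup(obs, I, pedigree = ped, line = FALSE, family = FALSE,
                       fixed = ~block_year, vc = vc)
  sol2 <- diallel_blup(rbind(obs, obs), I, pedigree = ped, line = FALSE,
                       family = FALSE, fixed = ~block_year, vc = vc)
  expect_equal(sol1$beta, sol2$beta, tolerance = 1e-10)
  expect_true(all(sol2$pev < sol1$pev))
  ## PEV monotonicity also under a pedigree covariance structure
  fx <- make_reml_fixture(seed = 52, nrep = 2)
  vca <- c(sigma2_a = 2, sigma2_e = 1)
  s1 <- diallel_blup(fx$obs, fx$A, pedigree = fx$ped, line = FALSE,
                     family = FALSE, fixed = ~block_year, vc = vca)
  s2 <- diallel_blup(rbind(fx$obs, fx$obs), fx$A, pedigree = fx$ped,
                     line = FALSE, family = FALSE, fixed = ~block_year,
                     vc = vca)
  expect_true(all(s2$pev < s1$pev))
})

test_that("the full model (additive + line + family) recovers structure", {
  sim <- quick_sim(seed = 61, n_parents = 8, off = 12)
  A <- amat_tetra(sim$pedigree)
  fit <- diallel_blup(sim$pheno, A, pedigree = sim$pedigree)
  expect_true(fit$converged)
  expect_named(fit$vc, c("sigma2_a", "sigma2_l", "sigma2_f", "sigma2_e"))
  ## EBVs track the simulated breeding values
  tv <- sim$truth$bv[names(fit$ebv), 1]
  expect_gt(cor(fit$ebv, tv), 0.4)
  ## PEV within its theoretical bounds
  expect_true(all(fit$pev >= 0))
  expect_true(all(fit$pev <= fit$vc["sigma2_a"] * max(diag(A)) + 1e-8))
})
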