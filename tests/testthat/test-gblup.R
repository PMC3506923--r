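test_that("REML matches an independent direct maximizer of the restricted likelihood", {
  # small cohort; oracle maximizes the untransformed restricted likelihood
  # (dense V, generalized determinant form) with optim -- a fully separate
  # computational route from the eigen-rotated profile/EM fit
  sim <- quick_sim(seed = 171, n_breeds = 1, sires = 12, progeny = 15,
                   n_snps = 400, n_x_snps = 0, missing_rate = 0)
  fc <- fit_cohort(sim, epsilon = 0.01)
  fit <- fc$fit
  y <- fit$y; X <- fit$X
  G <- fc$grm$G[fit$ids, fit$ids]
  n <- length(y); p <- ncol(X)
  negrll <- function(par) {
    sa <- exp(par[1]); se <- exp(par[2])
    V <- sa * G + se * diag(n)
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1] +
             as.numeric(t(r) %*% Vi %*% r))
  }
  o <- optim(log(c(0.1, 0.3)), negrll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))
  sa_o <- exp(o$par[1]); se_o <- exp(o$par[2])
  expect_equal(fit$sigma2_a, sa_o, tolerance = 1e-4)
  expect_equal(fit$sigma2_e, se_o, tolerance = 1e-4)
  expect_equal(fit$h2, sa_o / (sa_o + se_o), tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("restricted log-likelihood is monotone over the EM refinements", {
  sim <- quick_sim(seed = 181, n_snps = 300, n_x_snps = 0, missing_rate = 0)
  fit <- fit_cohort(sim)$fit
  expect_true(all(diff(fit$trace$loglik) > -1e-6))
})

test_that("a cohort with no genetic signal yields near-zero heritability", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(breeds = "A", sires_per_breed = 25L, progeny_per_sire = 40L,
                      n_snps = 1000, n_x_snps = 0, dense_regions = list(),
                      qtl = list(), h2 = 0, var_a = 0, var_e0 = 0.4,
                      mean_wbsf = 4.4, missing_rate = 0, seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    fit <- fit_cohort(sim)$fit
    if (fit$h2 < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("scaling the phenotype scales variances but not h2 or t-statistics", {
  sim <- quick_sim(seed = 191, n_breeds = 1, sires = 8, progeny = 12,
                   n_snps = 250, n_x_snps = 0, missing_rate = 0)
  fc <- fit_cohort(sim)
  ph2 <- fc$pheno; ph2$wbsf <- ph2$wbsf * 3
  fit2 <- suppressWarnings(gblup(wbsf ~ cg, ph2, fc$grm))
  expect_equal(fit2$sigma2_a, 9 * fc$fit$sigma2_a, tolerance = 1e-3)
  expect_equal(fit2$sigma2_e, 9 * fc$fit$sigma2_e, tolerance = 1e-3)
  expect_equal(fit2$h2, fc$fit$h2, tolerance = 1e-4)
  a1 <- backsolve_ase(fc$fit, fc$design, fc$geno$map)
  a2 <- backsolve_ase(fit2, fc$design, fc$geno$map)
  expect_equal(a2$t_stat, a1$t_stat, tolerance = 1e-3)
})

test_that("boundary fits are flagged rather than erroring", {
  # phenotype independent of genotype, tiny n: sigma2_a often pinned near 0
  set.seed(9)
  geno <- matrix(rbinom(30 * 200, 2, 0.5), 30, 200)
  g <- toy_geno(geno, pos = seq_len(200) * 1000)
  grm <- regularize_grm(build_grm(g), 0.01)
  ph <- data.frame(animal_id = g$animals$animal_id, cg = "c1",
                   wbsf = rnorm(30))
  fit <- gblup(wbsf ~ 1, ph, grm)
  expect_true(is.finite(fit$loglik))
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
})

test_that("non-positive-definite G is rejected with guidance", {
  geno <- rbind(c(2L, 0L), c(2L, 0L), c(0L, 2L))
  g <- toy_geno(geno)
  grm <- build_grm(g, p = c(0.6, 0.35))
  ph <- data.frame(animal_id = g$animals$animal_id, cg = "c1", wbsf = c(1, 2, 3))
  expect_error(gblup(wbsf ~ 1, ph, grm), "regularize_grm")
})

test_that("singleton contemporary groups are dropped with a warning", {
  sim <- quick_sim(seed = 201, n_breeds = 1, sires = 5, progeny = 10,
                   n_snps = 200, n_x_snps = 0, missing_rate = 0)
  fc0 <- fit_cohort(sim)
  ph <- fc0$pheno
  ph$cg[1] <- "lonely_cell"
  keep_n <- sum(table(ph$cg)[table(ph$cg) >= 2])
  expect_warning(fit <- gblup(wbsf ~ cg, ph, fc0$grm), "singleton")
  expect_equal(fit$n, keep_n)
})

test_that("genetic sample size is N * sqrt(h2) to one decimal", {
  expect_equal(genetic_sample_size(1095, 0.17), 451.5)
  expect_equal(genetic_sample_size(100, 1.0), 100.0)
  expect_equal(genetic_sample_size(0, 0.5), 0.0)
})
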