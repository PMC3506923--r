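test_that("single-SNP GLS test reduces to the OLS added-variable F when V = I", {
  sim <- quick_sim(seed = 241, n_breeds = 1, sires = 3, progeny = 4,
                   n_snps = 60, n_x_snps = 0, missing_rate = 0)
  fc <- fit_cohort(sim)
  ctx <- gls_context(fc$fit, sigma2_a = 0, sigma2_e = 1)
  dose <- fc$geno$geno[ctx$ids, 5]
  res <- single_snp_test(ctx, dose)
  # OLS oracle via lm / anova on the same 12 records
  df <- data.frame(y = fc$fit$y, cg = fc$pheno$cg[match(ctx$ids, fc$pheno$animal_id)],
                   dose = dose)
  a <- anova(lm(y ~ cg, df), lm(y ~ cg + dose, df))
  expect_equal(res$F, a$F[2], tolerance = 1e-10)
  expect_equal(res$neglog10p, -log10(a$`Pr(>F)`[2]), tolerance = 1e-8)
  expect_equal(res$ase, unname(coef(lm(y ~ cg + dose, df))["dose"]),
               tolerance = 1e-10)
})

test_that("monomorphic or collinear SNPs give NA results", {
  sim <- quick_sim(seed = 251, n_breeds = 1, sires = 3, progeny = 6,
                   n_snps = 80, n_x_snps = 0, missing_rate = 0)
  fc <- fit_cohort(sim)
  ctx <- gls_context(fc$fit)
  expect_true(is.na(single_snp_test(ctx, rep(1L, ctx$n))$F))
  # dosage collinear with an existing contemporary-group column
  cgm <- fc$pheno$cg[match(ctx$ids, fc$pheno$animal_id)]
  dose <- as.integer(cgm == cgm[1])
  expect_true(is.na(single_snp_test(ctx, dose)$F))
})

test_that("null calibration: permuted dosages give uniform P-values", {
  sim <- quick_sim(seed = 261, n_breeds = 1, sires = 10, progeny = 30,
                   n_snps = 500, n_x_snps = 0, missing_rate = 0)
  fc <- fit_cohort(sim)
  ctx <- gls_context(fc$fit)
  set.seed(17)
  cols <- which(apply(fc$geno$geno[ctx$ids, ], 2, var) > 0)[1:400]
  pvals <- vapply(cols, function(j) {
    dose <- sample(fc$geno$geno[ctx$ids, j])
    r <- single_snp_test(ctx, dose)
    10^(-r$neglog10p)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 380L)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("percent_variance matches a hand-computed 8-record toy", {
  # 8 records, 2 CG levels, 2 haplotype levels; V = I
  y <- c(10, 12, 11, 13, 20, 22, 21, 23)
  cg <- rep(c("c1", "c2"), each = 4)
  hap <- rep(c(0, 1), 4)  # dosage of the non-reference haplotype
  fit0 <- lm(y ~ cg)
  fit1 <- lm(y ~ cg + hap)
  ss_mean <- length(y) * mean(y)^2
  ss_total <- sum(y^2)
  ss_cg <- sum(fitted(fit0)^2) - ss_mean
  ss_red <- ss_mean + ss_cg
  ss_full <- sum(y^2) - sum(resid(fit1)^2)
  pv <- percent_variance(ss_full, ss_red, ss_total, ss_cg, ss_mean)
  # hand arithmetic: hap effect 2 -> window SS = 4 * 2^2 / 2 = 8;
  # phenotypic SS (total corrected for mean and CG) = 10; pv = 80%
  expect_equal(pv, 100 * (sum(resid(fit0)^2) - sum(resid(fit1)^2)) /
                 sum(resid(fit0)^2), tolerance = 1e-10)
  expect_equal(pv, 80, tolerance = 1e-10)
  expect_equal(percent_variance(5, 5, 100, 10), 0)
  expect_equal(percent_variance(90, 0, 100, 10, 0), 100)
  expect_error(percent_variance(5, 4, 10, 10), "positive")
})

test_that("rare haplotypes pool deterministically and never raise df", {
  cnt <- c(h1 = 100L, h2 = 50L, h3 = 2L, h4 = 1L)
  mp <- pool_rare_haplotypes(cnt, 5)
  expect_equal(sort(unique(mp)), c("h1", "h2", "pooled"))
  expect_equal(unname(mp[c("h3", "h4")]), c("pooled", "pooled"))
  expect_equal(pool_rare_haplotypes(c(a = 9L, b = 8L), 5),
               c(a = "a", b = "b"))
  set.seed(5)
  for (i in 1:20) {
    cnt <- setNames(rpois(8, 6), paste0("h", 1:8))
    mp <- pool_rare_haplotypes(cnt, 5)
    expect_lte(length(unique(mp)), length(cnt))
  }
})

test_that("window scan centres, counts and degenerate windows are right", {
  sim <- quick_sim(seed = 271, n_breeds = 1, sires = 6, progeny = 20,
                   n_snps = 150, n_x_snps = 0, missing_rate = 0,
                   dense = list(list(chrom = "7", start = 50e6, end = 52e6,
                                     n_snp = 12L)))
  fc <- fit_cohort(sim)
  ctx <- gls_context(fc$fit)
  h <- phase_impute(fc$geno, seed = 6)
  # any 12 contiguous SNPs of one chromosome form a 12-SNP region
  region <- head(fc$geno$map$snp_id[fc$geno$map$chrom == "7"], 12)
  expect_length(region, 12L)
  scan <- window_scan(ctx, h, region, window = 9)
  expect_equal(nrow(scan), 4L)
  expect_equal(scan$centre_snp, region[5:8])
  expect_true(all(scan$pct_var >= 0))
  expect_error(window_scan(ctx, h, region, window = 8), "odd")
  # a window where every animal carries the same haplotype: one level beyond
  # the intercept cannot be fit -> F is NA and no variance is explained
  h1 <- list(h1 = matrix(1L, ctx$n, 9,
                         dimnames = list(ctx$ids, paste0("m", 1:9))),
             h2 = matrix(1L, ctx$n, 9),
             map = data.frame(snp_id = paste0("m", 1:9), chrom = "9",
                              pos = (1:9) * 1e5),
             animals = data.frame(animal_id = ctx$ids))
  class(h1) <- "phased_haps"
  rownames(h1$h2) <- ctx$ids
  sc1 <- window_scan(ctx, h1, paste0("m", 1:9), window = 9)
  expect_true(is.na(sc1$F))
  expect_equal(sc1$pct_var, 0)
  expect_equal(sc1$n_haplotypes, 1L)
})

test_that("the max-F and max-percent-variance windows are both reported", {
  sim <- quick_sim(seed = 281, n_breeds = 1, sires = 8, progeny = 25,
                   n_snps = 300, n_x_snps = 0, missing_rate = 0,
                   dense = list(list(chrom = "7", start = 50e6, end = 53e6,
                                     n_snp = 20L)),
                   qtl = list(list(chrom = "7", pos = 51.5e6, frac_var = 0.05)))
  fc <- fit_cohort(sim)
  ctx <- gls_context(fc$fit)
  h <- phase_impute(fc$geno, seed = 8)
  region <- fc$geno$map$snp_id[fc$geno$map$chrom == "7" &
                                 fc$geno$map$pos >= 50e6 & fc$geno$map$pos <= 53e6]
  scan <- window_scan(ctx, h, region)
  mx <- scan_maxima(scan)
  expect_s3_class(mx$best_p, "data.frame")
  expect_true(mx$best_vp$pct_var >= max(scan$pct_var) - 1e-12)
  # nesting: model SS never decreases, so pct_var >= 0 everywhere
  expect_true(all(scan$pct_var >= 0))
})
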