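test_that("genotype coding matches the centred allele-count scheme", {
  expect_equal(code_genotype("AA", 0.25, "F", "1"), 1.5)   # 2q
  expect_equal(code_genotype("AB", 0.25, "F", "1"), 0.5)   # q - p
  expect_equal(code_genotype("BB", 0.25, "F", "1"), -0.5)  # -2p
  expect_equal(code_genotype("AY", 0.25, "M", "X"), 0.75)  # q
  expect_equal(code_genotype("BY", 0.25, "M", "X"), -0.25) # -p
  # pseudoautosomal region uses the diploid coding
  expect_equal(code_genotype("AA", 0.25, "M", "XY"), 1.5)
  expect_error(code_genotype("AY", 0.25, "M", "1"), "X loci")
  expect_error(code_genotype(NA_character_, 0.25, "F", "1"), "missing")
})

test_that("marker_design reproduces code_genotype cell by cell, X included", {
  sim <- quick_sim(seed = 121, n_snps = 150, n_x_snps = 30, missing_rate = 0)
  g <- apply_qc(sim$geno)$geno
  des <- marker_design(g)
  p <- des$p
  lab <- c("BB", "AB", "AA")
  for (i in c(1, 7)) {
    for (j in c(2, ncol(g$geno))) {
      sex <- g$animals$sex[i]; ch <- g$map$chrom[j]
      code <- if (ch == "X" && sex == "M") c("BY", "AY")[g$geno[i, j] + 1]
      else lab[g$geno[i, j] + 1]
      expect_equal(des$M[i, j], code_genotype(code, p[j], sex, ch))
    }
  }
  expect_equal(des$scale, 2 * sum(p * (1 - p)))
  # alternative X scaling counts X SNPs as pq
  des2 <- marker_design(g, x_scale = "pq")
  xs <- g$map$chrom == "X"
  expect_equal(des2$scale, 2 * sum(p[!xs] * (1 - p[!xs])) + sum(p[xs] * (1 - p[xs])))
})

test_that("column sums of M vanish with in-sample frequencies (diploid data)", {
  sim <- quick_sim(seed = 131, n_snps = 200, n_x_snps = 0, missing_rate = 0)
  des <- marker_design(sim$geno)
  expect_lt(max(abs(colSums(des$M))), 1e-9)
})

test_that("hand-computed 3x2 microexample matches to 12 digits", {
  # genotypes (A-dosage): animals x SNPs; p fixed externally
  geno <- rbind(c(2L, 1L), c(1L, 0L), c(0L, 2L))
  p <- c(0.5, 0.25)
  g <- toy_geno(geno)
  des <- marker_design(g, p = p)
  M <- rbind(c(1.0, 0.5), c(0.0, -0.5), c(-1.0, 1.5))
  expect_equal(des$M, M, ignore_attr = TRUE, tolerance = 1e-12)
  cc <- 2 * (0.25 + 0.1875)
  G <- M %*% t(M) / cc
  grm <- build_grm(g, p = p)
  expect_equal(grm$G, G, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(grm$scale, cc)
})

test_that("duplicate genotypes give identical G rows; monomorphic SNPs error", {
  geno <- rbind(c(2L, 0L, 1L), c(2L, 0L, 1L), c(0L, 1L, 2L))
  g <- toy_geno(geno)
  grm <- build_grm(g, p = c(0.6, 0.2, 0.55))
  expect_equal(grm$G[1, ], grm$G[2, ], ignore_attr = TRUE)
  expect_equal(grm$G[1, 2], grm$G[1, 1])
  g_mono <- toy_geno(cbind(geno, 2L))  # fixed SNP: in-sample p = 1
  expect_error(build_grm(g_mono), "monomorphic")
})

test_that("mean diagonal of G is ~1 for HWE-unrelated animals", {
  set.seed(55)
  n <- 400; m <- 20000
  p <- runif(m, 0.05, 0.95)
  geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  g <- toy_geno(geno, pos = seq_len(m) * 100)
  grm <- build_grm(g)
  expect_gt(mean(diag(grm$G)), 0.95)
  expect_lt(mean(diag(grm$G)), 1.05)
})

test_that("G is invariant to allele-label flips when frequency flips too", {
  sim <- quick_sim(seed = 141, n_snps = 120, n_x_snps = 20, missing_rate = 0)
  g <- apply_qc(sim$geno)$geno
  G1 <- build_grm(g)$G
  flip <- c(3, 10, 25)
  g2 <- g
  for (j in flip) {
    xs <- g$map$chrom[j] == "X"
    mx <- g$animals$sex == "M" & xs
    g2$geno[, j] <- ifelse(mx, 1L - g$geno[, j], 2L - g$geno[, j])
  }
  G2 <- build_grm(g2)$G
  expect_equal(G2, G1, tolerance = 1e-12)
})

test_that("regularization blends toward identity and fixes singular G", {
  geno <- rbind(c(2L, 0L), c(2L, 0L), c(0L, 2L))  # duplicate animals
  g <- toy_geno(geno)
  grm <- build_grm(g, p = c(0.6, 0.35))
  expect_lt(min(eigen(grm$G, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  reg <- regularize_grm(grm, 0.01)
  expect_gt(min(eigen(reg$G, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(reg$epsilon, 0.01)
  # epsilon = 0 leaves a full-rank G untouched
  sim <- quick_sim(seed = 151, n_breeds = 1, sires = 4, progeny = 10,
                   n_snps = 300, n_x_snps = 0, missing_rate = 0)
  gpoly <- sim$geno[, {p <- snp_freqs(sim$geno); p > 0 & p < 1}]
  grm2 <- build_grm(gpoly)
  expect_identical(regularize_grm(grm2, 0)$G, grm2$G)
})

test_that("back-solved ASEs are insensitive to the regularization amount", {
  sim <- quick_sim(seed = 161, n_breeds = 1, sires = 10, progeny = 15,
                   n_snps = 400, n_x_snps = 0, missing_rate = 0)
  f1 <- fit_cohort(sim, epsilon = 0.01)
  f2 <- fit_cohort(sim, epsilon = 0.001)
  a1 <- backsolve_ase(f1$fit, f1$design, f1$geno$map)
  a2 <- backsolve_ase(f2$fit, f2$design, f2$geno$map)
  expect_gt(cor(a1$ase_kg, a2$ase_kg), 0.999)
})
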