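test_that("packaged 79-region table loads and matches its published anchors", {
  t2 <- table2_fixture()
  expect_equal(nrow(t2), 79L)
  last <- t2[t2$bta == 29 & t2$start == 44042363, ]
  expect_equal(last$end, 44087629)
  expect_equal(unname(unlist(last[c("rank_angus", "rank_hereford", "rank_charolais",
                                    "rank_limousin", "rank_simmental")])),
               c(1L, 4L, 1L, 30L, 1L))
  rk <- as.matrix(t2[, grep("^rank_", names(t2))])
  expect_true(all(rk >= 1L & rk == round(rk)))
})

test_that("breed support counting matches published per-row examples", {
  t2 <- table2_fixture()
  sh <- detect_shared_qtl(t2, threshold = 500, min_breeds = 3)
  r1 <- sh[sh$bta == 7 & sh$snp_pos == 98579574, ]   # CAST region row
  expect_equal(r1$n_breeds_support, 5L)
  r2 <- sh[sh$bta == 1 & sh$start == 155725361, ]
  expect_equal(r2$n_breeds_support, 3L)
  expect_equal(r2$breeds_support, "H,L,S")
  # empty in, empty out
  empty <- t2[0, ]
  expect_equal(nrow(detect_shared_qtl(empty)), 0L)
})

test_that("support histograms are threshold-monotone and partition the entries", {
  t2 <- table2_fixture()
  s500 <- summarize_support(t2, 500)
  s999 <- summarize_support(t2, 999)
  expect_equal(unname(s500$support_counts[c("3", "4", "5")]), c(42L, 29L, 8L))
  expect_equal(unname(s999$support_counts[c("3", "4", "5")]), c(21L, 41L, 17L))
  # five entries per region split into <= and > threshold
  expect_equal(5L * s500$n_regions, (5L * 79L - s500$n_over) + s500$n_over)
  expect_equal(s500$n_over, 113L)
  expect_equal(5L * 79L - s500$n_over, 282L)
  # monotonicity of support in the threshold, row by row
  rk <- as.matrix(t2[, setdiff(grep("^rank_", names(t2), value = TRUE), "rank_all")])
  expect_true(all(rowSums(rk <= 500) <= rowSums(rk <= 999)))
})

test_that("rank thresholds behave as rank <= k on dense ordinal ranks", {
  t <- c(0.5, 3.1, 3.1, 0.2)
  rk <- rank_ase(t, rep("1", 4), 1:4)
  expect_equal(rk, c(3L, 1L, 2L, 4L))
  expect_equal(sum(rk <= 2), 2L)
})

test_that("region construction merges, extends and caps as specified", {
  # 8 SNPs on one chromosome; seeds at 2 Mb and 8.5 Mb (> gap_max apart)
  pos <- c(1e6, 2e6, 2.4e6, 3e6, 8.5e6, 9e6, 30e6, 31e6)
  across <- data.frame(snp_id = sprintf("s%d", 1:8), chrom = "5", pos = pos,
                       rank = c(900L, 10L, 700L, 450L, 20L, 800L, 999L, 998L))
  within <- list(
    b1 = c(5000L, 600L, 30L, 700L, 450L, 5000L, 5000L, 5000L),
    b2 = rep(6000L, 8))
  reg <- build_regions(across, within, top_k = 500, gap_max = 1e6, max_span = 5.7e6)
  expect_equal(nrow(reg), 2L)
  r1 <- reg[1, ]
  # seeds s2 and s4 merge (0.6 Mb < gap), extend to within-hit s3 (already
  # inside) and stay within the span cap
  expect_equal(r1$start, 2e6)
  expect_equal(r1$end, 3e6)
  expect_equal(r1$snp, "s2")
  expect_equal(r1$rank_b1, 30L)
  r2 <- reg[2, ]
  # single seed s5 extends left only as far as the span cap allows? s5 at
  # 8.5 Mb has a within-hit at 2.4 Mb, 6.1 Mb away -> beyond max_span, not added
  expect_equal(c(r2$start, r2$end), c(8.5e6, 8.5e6))
  expect_equal(r2$n_snp, 1L)
  # two seeds 6 Mb apart with gap_max 1 Mb stay two regions
  across2 <- data.frame(snp_id = c("a", "b"), chrom = "2", pos = c(1e6, 7e6),
                        rank = c(1L, 2L))
  reg2 <- build_regions(across2, list(b1 = c(5000L, 5000L)), 500, 1e6, 5.7e6)
  expect_equal(nrow(reg2), 2L)
  expect_error(build_regions(across2, list(b1 = c(1L, 2L)), 500,
                             gap_max = 2e6, max_span = 1e6), "max_span")
})

test_that("a planted major QTL is localized by exactly one detected region", {
  # downscaled study: 3 breeds x 750 half-sib progeny, 1000 SNPs; thresholds
  # scaled to the SNP count (seeds = top 1.2%, breed support = top 5%,
  # support in 2 of 3 breeds)
  hits <- 0L; n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    sim <- quick_sim(seed = 3000 + s, n_breeds = 3, sires = 15, progeny = 50,
                     n_snps = 1000, n_x_snps = 0, h2 = 0.4, var_a = 0.2,
                     qtl = list(list(chrom = "7", pos = 98.4e6, frac_var = 0.02)),
                     dense = list(list(chrom = "7", start = 96.8e6, end = 99.7e6,
                                       n_snp = 30L)),
                     missing_rate = 0)
    # QC keeps only SNPs polymorphic in every breed, so the across- and
    # within-breed analyses share one SNP set
    sim$geno <- apply_qc(sim$geno)$geno
    runs <- list(all = fit_cohort(sim))
    for (b in c("A", "B", "C")) runs[[b]] <- fit_cohort(sim, breed = b)
    ase <- lapply(runs, function(r) backsolve_ase(r$fit, r$design, r$geno$map))
    reg <- build_regions(ase$all, ase[c("A", "B", "C")], top_k = 12L,
                         gap_max = 1e6, max_span = 5.7e6)
    shared <- detect_shared_qtl(reg, threshold = 46L, min_breeds = 2L)
    qpos <- sim$truth$qtl$pos[1]
    covering <- shared$chrom == "7" & shared$start <= qpos & shared$end >= qpos
    if (sum(covering) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
})

test_that("interval spans match published printed arithmetic", {
  s <- interval_span(44062694, 44070881)
  expect_equal(s$bp, 8187)
  s2 <- interval_span(97861341, 98538952)
  expect_equal(s2$bp, 677611)
  expect_equal(s2$kb, 678)
  s3 <- interval_span(98495888, 98579574)
  expect_equal(s3$kb, 83.7)
  expect_equal(interval_span(5, 5)$bp, 0)
  expect_error(interval_span(10, 9), "start")
})
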