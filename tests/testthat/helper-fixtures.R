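# Small in-code fixtures shared across test files.

# Compact multi-breed cohort for fast end-to-end checks.
quick_sim <- function(seed = 1, n_breeds = 3, sires = 8, progeny = 20,
                      n_snps = 800, n_x_snps = 40, h2 = 0.4, var_a = 0.2,
                      qtl = list(), dense = list(), missing_rate = 0.0089, ...) {
  cfg <- sim_config(breeds = LETTERS[seq_len(n_breeds)],
                    sires_per_breed = rep(sires, n_breeds),
                    progeny_per_sire = rep(progeny, n_breeds),
                    n_snps = n_snps, n_x_snps = n_x_snps,
                    dense_regions = dense, qtl = qtl,
                    h2 = rep(h2, n_breeds), var_a = rep(var_a, n_breeds),
                    mean_wbsf = rep(4.4, n_breeds),
                    missing_rate = missing_rate, seed = seed, ...)
  simulate_cohort(cfg)
}

# Tiny hand-built genotype matrix: `geno` is animals x SNPs dosage of A.
toy_geno <- function(geno, chrom = NULL, pos = NULL, breed = NULL, sex = NULL,
                     unique_map = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(m)),
                    chrom = if (is.null(chrom)) rep("1", m) else chrom,
                    pos = if (is.null(pos)) seq_len(m) * 1000 else pos,
                    unique_map = if (is.null(unique_map)) TRUE else unique_map)
  animals <- data.frame(animal_id = sprintf("a%03d", seq_len(n)),
                        breed = if (is.null(breed)) rep("B1", n) else breed,
                        sex = if (is.null(sex)) rep("F", n) else sex)
  geno_matrix(geno, map, animals)
}

# Fit the genomic animal model on a simulated cohort (complete genotypes).
# Drops SNPs monomorphic in the analysis subset (as filter_snps would).
fit_cohort <- function(sim, epsilon = 0.01, breed = NULL) {
  g <- sim$geno
  if (!is.null(breed)) g <- g[g$animals$breed %in% breed, ]
  stopifnot(!anyNA(g$geno))
  p <- snp_freqs(g)
  g <- g[, p > 0 & p < 1]
  des <- marker_design(g)
  grm <- regularize_grm(build_grm(g, design = des), epsilon)
  ph <- sim$pheno[match(g$animals$animal_id, sim$pheno$animal_id), ]
  fit <- suppressWarnings(gblup(wbsf ~ cg, ph, grm))
  list(fit = fit, design = des, grm = grm, geno = g, pheno = ph)
}
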