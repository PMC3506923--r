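#' Filter SNPs on mapping, call rate and within-breed MAF
#'
#' Retains SNPs that (a) map uniquely to an autosome or the X chromosome,
#' (b) have call rate strictly greater than `call_rate_min`, and (c) have
#' minor allele frequency strictly greater than `maf_min` within every breed.
#' MAF is computed from observed genotypes only; male X cells contribute one
#' allele. The exclusion log records the first failing rule per dropped SNP
#' (rules tested in the order above).
#'
#' @param g a [geno_matrix()].
#' @param call_rate_min call-rate threshold (strict; default 0.89).
#' @param maf_min within-breed MAF threshold (strict; default 0.01).
#' @return list with `keep` (retained SNP ids) and `log` (data frame
#'   `snp_id`, `reason` for the dropped SNPs).
#' @export
filter_snps <- function(g, call_rate_min = 0.89, maf_min = 0.01) {
  breeds <- if (is.factor(g$animals$breed)) levels(g$animals$breed) else
    unique(g$animals$breed)
  if (length(breeds) == 0L ||
      any(table(factor(g$animals$breed, levels = breeds)) == 0L))
    stop("every breed must have at least one animal (within-breed MAF undefined)")
  call_rate <- colMeans(!is.na(g$geno))
  pbr <- snp_freqs(g, by_breed = TRUE)
  if (length(breeds) == 1L) pbr <- matrix(pbr, ncol = 1L)
  maf <- pmin(pbr, 1 - pbr)
  min_maf <- apply(maf, 1L, function(x) min(x, na.rm = FALSE))
  # strict thresholds on count ratios; 1e-9 guards against representation
  # error when a ratio lands exactly on the threshold (e.g. 1/100 vs 0.01)
  reason <- rep(NA_character_, ncol(g$geno))
  reason[!g$map$unique_map] <- "nonunique_map"
  fail_cr <- is.na(reason) & !(call_rate > call_rate_min + 1e-9)
  reason[fail_cr] <- "call_rate"
  fail_maf <- is.na(reason) & !(!is.na(min_maf) & min_maf > maf_min + 1e-9)
  reason[fail_maf] <- "maf"
  keep <- g$map$snp_id[is.na(reason)]
  log <- data.frame(snp_id = g$map$snp_id[!is.na(reason)],
                    reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  list(keep = keep, log = log)
}

#' Filter animals on individual genotype call rate
#'
#' Retains animals whose call rate is greater than or equal to
#' `call_rate_min` (animals strictly below the threshold are excluded).
#'
#' @param g a [geno_matrix()].
#' @param call_rate_min call-rate threshold (inclusive; default 0.85).
#' @return Character vector of retained animal ids.
#' @export
filter_animals <- function(g, call_rate_min = 0.85) {
  call_rate <- rowMeans(!is.na(g$geno))
  g$animals$animal_id[call_rate >= call_rate_min - 1e-9]
}

#' Apply SNP then animal filters in one pass
#'
#' The SNP filter uses call rates over all genotyped animals; the animal
#' filter then uses the retained SNPs. A single pass (no iteration): re-running
#' on the filtered output is a no-op under the same thresholds.
#'
#' @inheritParams filter_snps
#' @param animal_call_rate_min animal call-rate threshold (inclusive).
#' @return list with the filtered `geno_matrix` and the SNP exclusion `log`.
#' @export
apply_qc <- function(g, call_rate_min = 0.89, maf_min = 0.01,
                     animal_call_rate_min = 0.85) {
  fs <- filter_snps(g, call_rate_min, maf_min)
  if (!length(fs$keep)) stop("no SNPs retained by QC filters")
  g2 <- g[, fs$keep]
  keep_an <- filter_animals(g2, animal_call_rate_min)
  if (!length(keep_an)) stop("no animals retained by QC filters")
  list(geno = g2[keep_an, ], log = fs$log)
}
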