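#' Back-solve SNP allele substitution effects from GBLUP breeding values
#'
#' Computes `alpha = c^-1 M' G^-1 u_hat`, the GBLUP of the vector of SNP
#' allele substitution effects, together with the per-SNP standard deviation
#' `sigma_M = sqrt(sigma2_A / c)` (from the SNP variance component
#' `sigma2_M = sigma2_A / (2 sum p q)`), the t-like statistic
#' `t_i = |alpha_i| / sigma_M`, and the within-analysis rank (1 = largest t,
#' ties broken by genome order).
#'
#' @param fit a [gblup()] fit.
#' @param design the [marker_design()] used to build the GRM the fit was run
#'   with (same SNPs, same frequencies).
#' @param map SNP map (`snp_id`, `chrom`, `pos`) for the design columns.
#' @return Data frame of class `ase_table`: `snp_id`, `chrom`, `pos`, `p_a`,
#'   `ase_kg`, `t_stat`, `rank`.
#' @export
backsolve_ase <- function(fit, design, map) {
  stopifnot(inherits(fit, "gblup"), inherits(design, "marker_design"),
            nrow(map) == ncol(design$M))
  M <- design$M
  if (!all(fit$ids %in% rownames(M))) stop("design and fit animals differ")
  M <- M[fit$ids, , drop = FALSE]
  if (nrow(M) != fit$n) stop("dimension mismatch between design and fit")
  # G^-1 u via the stored eigen-decomposition of G
  Ginv_u <- fit$eigen$U %*% (crossprod(fit$eigen$U, fit$u) / fit$eigen$d)
  alpha <- as.numeric(crossprod(M, Ginv_u)) / design$scale
  sigma_m <- sqrt(fit$sigma2_a / design$scale)
  t_stat <- if (sigma_m > 0) abs(alpha) / sigma_m else rep(0, length(alpha))
  out <- data.frame(snp_id = map$snp_id, chrom = as.character(map$chrom),
                    pos = map$pos, p_a = design$p, ase_kg = alpha,
                    t_stat = t_stat, stringsAsFactors = FALSE)
  out$rank <- rank_ase(out$t_stat, out$chrom, out$pos)
  class(out) <- c("ase_table", "data.frame")
  out
}

#' Dense ordinal ranks of t-statistics
#'
#' Rank 1 is the largest t; ties are broken deterministically by genome order
#' (chromosome, then position), so ranks are a permutation of `1..n`.
#'
#' @param t_stat numeric vector.
#' @param chrom,pos genome coordinates used for tie-breaking.
#' @return Integer rank vector.
#' @export
rank_ase <- function(t_stat, chrom, pos) {
  ord <- order(-t_stat, chrom_order(chrom), pos)
  rk <- integer(length(t_stat))
  rk[ord] <- seq_along(t_stat)
  rk
}

#' Plot-ready Manhattan table of t-statistics
#'
#' Computes cumulative genome coordinates (chromosomes laid end to end in
#' karyotype order) for the normalized allele substitution effects.
#'
#' @param ase an [backsolve_ase()] table.
#' @return Data frame `snp_id`, `chrom`, `pos`, `pos_cum`, `t_stat`.
#' @export
export_manhattan <- function(ase) {
  stopifnot(inherits(ase, "ase_table") || all(c("chrom", "pos", "t_stat") %in% names(ase)))
  ord <- order(chrom_order(ase$chrom), ase$pos)
  ase <- ase[ord, , drop = FALSE]
  chroms <- unique(ase$chrom)
  lens <- vapply(chroms, function(ch) max(ase$pos[ase$chrom == ch]), numeric(1))
  offs <- stats::setNames(cumsum(c(0, lens[-length(lens)])), chroms)
  data.frame(snp_id = ase$snp_id, chrom = ase$chrom, pos = ase$pos,
             pos_cum = ase$pos + offs[ase$chrom], t_stat = ase$t_stat,
             row.names = NULL, stringsAsFactors = FALSE)
}
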