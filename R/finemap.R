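#' Generalized-least-squares context with frozen variance components
#'
#' Assembles the fixed covariance `V = G sigma2_a + I sigma2_e` from a
#' previously estimated fit (the variance components are frozen, not
#' re-estimated per test), whitens the phenotype and the contemporary-group
#' design by `V^{-1/2}`, and precomputes the sums of squares reused by every
#' single-SNP and haplotype-window test. Sums of squares are defined on the
#' whitened scale, which reduces exactly to ordinary least squares when V is
#' proportional to the identity.
#'
#' @param fit a [gblup()] fit (supplies y, the fixed design, the variance
#'   components and the eigen-decomposition of G).
#' @param sigma2_a,sigma2_e optional overrides of the frozen variance
#'   components (e.g. `sigma2_a = 0` gives ordinary least squares).
#' @return Object of class `gls_context`: whitened response `wy` and design
#'   `wX`, the whitening matrix `W`, residual sums of squares of the null
#'   (contemporary-group) model, and the corrected phenotypic sum of squares
#'   (total SS corrected for the mean and contemporary-group SS).
#' @export
gls_context <- function(fit, sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e) {
  stopifnot(inherits(fit, "gblup"))
  v <- sigma2_a * fit$eigen$d + sigma2_e
  if (any(v <= 0)) stop("V is not positive definite")
  W <- fit$eigen$U %*% (t(fit$eigen$U) / sqrt(v))  # V^{-1/2}, symmetric
  wy <- as.numeric(W %*% fit$y)
  wX <- W %*% fit$X
  q0 <- qr(wX)
  rss0 <- sum(qr.resid(q0, wy)^2)
  # mean + contemporary-group decomposition on the whitened scale
  w1 <- W %*% rep(1, fit$n)
  rss_mean <- sum(qr.resid(qr(w1), wy)^2)
  ss_total <- sum(wy^2)
  ss_mean <- ss_total - rss_mean
  ss_cg <- rss_mean - rss0  # CG sum of squares beyond the mean
  structure(list(wy = wy, wX = wX, W = W, qr0 = q0, rss0 = rss0,
                 ss_total = ss_total, ss_mean = ss_mean, ss_cg = ss_cg,
                 ss_pheno = rss0,  # total SS corrected for mean and CG
                 n = fit$n, rank0 = q0$rank, ids = fit$ids,
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e),
            class = "gls_context")
}

#' @export
print.gls_context <- function(x, ...) {
  cat("gls_context:", x$n, "records; frozen sigma2_A =",
      format(x$sigma2_a, digits = 4), ", sigma2_E =",
      format(x$sigma2_e, digits = 4), "\n")
  invisible(x)
}

# F-test of extra columns added to the null design, on the whitened scale.
gls_ftest <- function(ctx, extra) {
  q1 <- qr(cbind(ctx$wX, extra))
  df1 <- q1$rank - ctx$rank0
  if (df1 < 1L) return(list(F = NA_real_, df1 = 0L, df2 = NA_integer_,
                            neglog10p = NA_real_, ss = 0))
  rss1 <- sum(qr.resid(q1, ctx$wy)^2)
  df2 <- ctx$n - q1$rank
  Fv <- ((ctx$rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       neglog10p = -stats::pf(Fv, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10),
       ss = ctx$rss0 - rss1)
}

#' Single-SNP generalized-least-squares test
#'
#' Adds an allele (dosage) effect to the contemporary-group model under the
#' frozen covariance and F-tests it against the null from the difference in
#' model sums of squares; the ASE estimate is the fitted dosage coefficient.
#'
#' @param ctx a [gls_context()].
#' @param dosage per-animal allele dosage (0/1/2; 0/1 for male X), in the
#'   order of `ctx$ids`.
#' @return list: `ase` (allele substitution effect, kg), `F`, `df1`, `df2`,
#'   `neglog10p`, `pct_var`. Monomorphic or collinear SNPs give `NA` results.
#' @export
single_snp_test <- function(ctx, dosage) {
  stopifnot(inherits(ctx, "gls_context"), length(dosage) == ctx$n)
  if (anyNA(dosage) || stats::var(dosage) == 0)
    return(list(ase = NA_real_, F = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_, neglog10p = NA_real_, pct_var = NA_real_))
  wd <- as.numeric(ctx$W %*% dosage)
  ft <- gls_ftest(ctx, wd)
  if (ft$df1 < 1L)
    return(list(ase = NA_real_, F = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_, neglog10p = NA_real_, pct_var = NA_real_))
  cf <- qr.coef(qr(cbind(ctx$wX, wd)), ctx$wy)
  list(ase = unname(cf[length(cf)]), F = ft$F, df1 = ft$df1, df2 = ft$df2,
       neglog10p = ft$neglog10p,
       pct_var = percent_variance(ctx$ss_mean + ctx$ss_cg + ft$ss,
                                  ctx$ss_mean + ctx$ss_cg,
                                  ctx$ss_total, ctx$ss_cg, ctx$ss_mean))
}

#' Percent of phenotypic variance explained
#'
#' `100 * (ss_full - ss_reduced) / (ss_total - ss_mean - ss_cg)`: the window
#' (or SNP) sum of squares — the difference between model sums of squares
#' including and excluding the tested effect — over the phenotypic sum of
#' squares, i.e. the total sum of squares corrected for the mean and the
#' contemporary-group sums of squares.
#'
#' @param ss_full model SS including the tested effect.
#' @param ss_reduced model SS excluding it (must not exceed `ss_full`).
#' @param ss_total total (uncorrected) sum of squares.
#' @param ss_cg contemporary-group sum of squares (beyond the mean).
#' @param ss_mean sum of squares due to the mean (0 if `ss_total` is already
#'   mean-corrected).
#' @return Percentage in [0, 100].
#' @export
percent_variance <- function(ss_full, ss_reduced, ss_total, ss_cg, ss_mean = 0) {
  if (ss_full < ss_reduced - 1e-8) stop("ss_full must be >= ss_reduced")
  denom <- ss_total - ss_mean - ss_cg
  if (denom <= 0) stop("phenotypic sum of squares must be positive")
  100 * max(ss_full - ss_reduced, 0) / denom
}

#' Pool rare haplotypes into a single level
#'
#' Haplotypes carried by fewer than `min_count` animals are merged into one
#' pooled level; the mapping is deterministic (levels ordered by decreasing
#' carrier count, ties by haplotype label).
#'
#' @param counts named integer vector of carrier counts per haplotype.
#' @param min_count minimum carrier count for a haplotype to keep its own
#'   level (default 5).
#' @return Named character vector mapping haplotype to level; pooled
#'   haplotypes map to `"pooled"`.
#' @export
pool_rare_haplotypes <- function(counts, min_count = 5L) {
  stopifnot(min_count >= 1L)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  lvl <- ifelse(counts >= min_count, names(counts), "pooled")
  stats::setNames(lvl, names(counts))
}

#' Sliding haplotype-window association scan
#'
#' Slides a window of `window` contiguous SNPs through a region one SNP at a
#' time; the distinct haplotypes observed in the window (after rare-haplotype
#' pooling) become levels of a fixed effect added to the contemporary-group
#' model, F-tested under the frozen covariance. The percent of phenotypic
#' variance explained by each window is computed with [percent_variance()].
#' All statistics are assigned to the centre SNP of the window (the 5th of 9
#' by default); windows never cross the supplied region boundary.
#'
#' @param ctx a [gls_context()].
#' @param haps a [phase_impute()] result covering the region SNPs.
#' @param region_snps SNP ids of the region, in map order (at least `window`
#'   of them).
#' @param window odd window width >= 3 (default 9).
#' @param min_count rare-haplotype pooling threshold (carriers).
#' @return Data frame of class `window_scan`, one row per window position:
#'   `centre_snp`, `pos`, `win_start`, `win_end` (bp of the first and last
#'   window SNP), `n_haplotypes` (levels fit), `F`, `df1`, `df2`,
#'   `neglog10p`, `pct_var`.
#' @export
window_scan <- function(ctx, haps, region_snps, window = 9L, min_count = 5L) {
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  stopifnot(inherits(haps, "phased_haps"))
  j <- match(region_snps, colnames(haps$h1))
  if (anyNA(j)) stop("region SNPs missing from phased haplotypes")
  if (length(j) < window) stop("region has fewer SNPs than the window")
  rows <- match(ctx$ids, rownames(haps$h1))
  if (anyNA(rows)) stop("animals in context missing from phased haplotypes")
  H1 <- haps$h1[rows, j, drop = FALSE]
  H2 <- haps$h2[rows, j, drop = FALSE]
  n <- length(rows)
  out <- vector("list", length(j) - window + 1L)
  for (s in seq_len(length(j) - window + 1L)) {
    cols <- s:(s + window - 1L)
    k1 <- apply(H1[, cols, drop = FALSE], 1L, paste, collapse = "")
    k2 <- apply(H2[, cols, drop = FALSE], 1L, paste, collapse = "")
    k2[is.na(H2[, cols[1L]])] <- NA  # male X: single haplotype
    # carrier counts (animals carrying >= 1 copy)
    haps_all <- unique(c(k1, k2[!is.na(k2)]))
    carrier <- vapply(haps_all, function(h)
      sum(k1 == h | (!is.na(k2) & k2 == h)), integer(1))
    lvl_map <- pool_rare_haplotypes(carrier, min_count)
    l1 <- lvl_map[k1]
    l2 <- ifelse(is.na(k2), NA, lvl_map[k2])
    lvls <- sort(unique(c(l1, l2[!is.na(l2)])))
    centre <- cols[(window + 1L) %/% 2L]
    base <- list(centre_snp = region_snps[centre],
                 pos = haps$map$pos[j[centre]],
                 win_start = haps$map$pos[j[cols[1L]]],
                 win_end = haps$map$pos[j[cols[window]]])
    if (length(lvls) < 2L) {
      out[[s]] <- data.frame(base, n_haplotypes = length(lvls), F = NA_real_,
                             df1 = 0L, df2 = NA_integer_, neglog10p = NA_real_,
                             pct_var = 0, stringsAsFactors = FALSE)
      next
    }
    # dosage design over haplotype levels, reference = most frequent level
    D <- matrix(0, n, length(lvls), dimnames = list(NULL, lvls))
    D[cbind(seq_len(n), match(l1, lvls))] <- D[cbind(seq_len(n), match(l1, lvls))] + 1
    ok2 <- !is.na(l2)
    D[cbind(which(ok2), match(l2[ok2], lvls))] <-
      D[cbind(which(ok2), match(l2[ok2], lvls))] + 1
    ref <- which.max(colSums(D))
    extra <- ctx$W %*% D[, -ref, drop = FALSE]
    ft <- gls_ftest(ctx, extra)
    pv <- if (is.na(ft$F)) 0 else
      percent_variance(ctx$ss_mean + ctx$ss_cg + ft$ss, ctx$ss_mean + ctx$ss_cg,
                       ctx$ss_total, ctx$ss_cg, ctx$ss_mean)
    out[[s]] <- data.frame(base, n_haplotypes = length(lvls), F = ft$F,
                           df1 = ft$df1, df2 = ft$df2, neglog10p = ft$neglog10p,
                           pct_var = pv, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("window_scan", "data.frame")
  res
}

#' The two reported maxima of a window scan
#'
#' The window with the largest F (equivalently smallest P) and the window
#' explaining the most phenotypic variance; the two can differ because the
#' numerator degrees of freedom vary with the number of haplotypes fit.
#'
#' @param scan a [window_scan()] result.
#' @return list with rows `best_p` (max F) and `best_vp` (max percent
#'   variance).
#' @export
scan_maxima <- function(scan) {
  stopifnot(nrow(scan) >= 1L)
  list(best_p = scan[which.max(replace(scan$F, is.na(scan$F), -Inf)), ],
       best_vp = scan[which.max(scan$pct_var), ])
}
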