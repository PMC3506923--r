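#' Phase and impute genotypes with an overlapping-window EM
#'
#' Estimates local haplotype frequencies by maximum likelihood (EM over the
#' compatible haplotype pairs of each genotype, assuming random pairing)
#' within sliding windows along each chromosome, then assigns every animal
#' its maximum-posterior haplotype pair and imputes missing genotypes from
#' the same posterior. Consecutive windows overlap and are stitched by
#' choosing the haplotype orientation most consistent with the already-phased
#' overlap. Females (and autosomes) are treated as diploid; males contribute
#' a single haplotype at X-linked SNPs. The method is a desk-scale local
#' phaser: downstream haplotype-window tests only require phase consistency
#' within windows of the analysis size.
#'
#' @param g a [geno_matrix()] (QC filters already applied).
#' @param window window width in SNPs (default 9, the analysis window).
#' @param n_starts random EM restarts per window; the highest-likelihood
#'   solution is kept.
#' @param seed integer seed; output is deterministic given it.
#' @param overlap SNPs shared between consecutive windows (used for
#'   stitching).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `phased_haps`: matrices `h1`, `h2` (0/1 alleles,
#'   animals x SNPs; `h2` is `NA` at male X cells), the complete imputed
#'   genotype matrix `geno`, a `posterior` matrix holding the posterior
#'   probability of the imputed genotype at originally-missing cells (`NA`
#'   elsewhere), plus the `map` and `animals` tables.
#' @export
phase_impute <- function(g, window = 9L, n_starts = 2L, seed = 1L,
                         overlap = 3L, max_iter = 30L, tol = 1e-4) {
  if (window < 2L) stop("window must be at least 2 SNPs")
  stopifnot(overlap >= 1L, overlap < window, n_starts >= 1L)
  set.seed(seed)
  n <- nrow(g$geno); m <- ncol(g$geno)
  h1 <- matrix(NA_integer_, n, m, dimnames = dimnames(g$geno))
  h2 <- h1
  post <- matrix(NA_real_, n, m, dimnames = dimnames(g$geno))
  male <- g$animals$sex == "M"
  p_all <- snp_freqs(g)

  for (ch in unique(g$map$chrom)) {
    cols <- which(g$map$chrom == ch)
    haploid_rows <- if (ch == "X") male else rep(FALSE, n)
    mc <- length(cols)
    w <- min(window, mc)
    starts <- if (mc <= w) 1L else
      unique(c(seq(1L, mc - w + 1L, by = w - overlap), mc - w + 1L))
    assigned <- 0L  # columns 1..assigned (within chromosome) already phased
    for (s in starts) {
      idx <- cols[s:(s + w - 1L)]
      fitw <- em_phase_window(g$geno[, idx, drop = FALSE], haploid_rows,
                              p_all[idx], n_starts, max_iter, tol)
      ov <- if (assigned == 0L) integer(0) else seq_len(max(0L, assigned - s + 1L))
      new <- setdiff(seq_len(w), ov)
      if (length(ov)) {
        keep_score <- rowSums(fitw$a1[, ov, drop = FALSE] == h1[, idx[ov], drop = FALSE], na.rm = TRUE) +
          rowSums(fitw$a2[, ov, drop = FALSE] == h2[, idx[ov], drop = FALSE], na.rm = TRUE)
        swap_score <- rowSums(fitw$a1[, ov, drop = FALSE] == h2[, idx[ov], drop = FALSE], na.rm = TRUE) +
          rowSums(fitw$a2[, ov, drop = FALSE] == h1[, idx[ov], drop = FALSE], na.rm = TRUE)
        do_swap <- swap_score > keep_score & !haploid_rows
        if (any(do_swap)) {
          tmp <- fitw$a1[do_swap, , drop = FALSE]
          fitw$a1[do_swap, ] <- fitw$a2[do_swap, , drop = FALSE]
          fitw$a2[do_swap, ] <- tmp
        }
      }
      if (length(new)) {
        h1[, idx[new]] <- fitw$a1[, new, drop = FALSE]
        h2[, idx[new]] <- fitw$a2[, new, drop = FALSE]
        post[, idx[new]] <- fitw$post[, new, drop = FALSE]
      }
      assigned <- s + w - 1L
    }
    if (any(haploid_rows)) h2[haploid_rows, cols] <- NA_integer_
  }
  imputed <- h1 + ifelse(is.na(h2), 0L, h2)
  # observed genotypes must be preserved exactly
  obs <- !is.na(g$geno)
  stopifnot(all(imputed[obs] == g$geno[obs]))
  post[obs] <- NA_real_
  structure(list(h1 = h1, h2 = h2, geno = imputed, posterior = post,
                 map = g$map, animals = g$animals),
            class = "phased_haps")
}

#' @export
print.phased_haps <- function(x, ...) {
  cat("phased_haps:", nrow(x$h1), "animals x", ncol(x$h1), "SNPs\n")
  cat("  imputed cells:", sum(!is.na(x$posterior)), "\n")
  invisible(x)
}

# Enumerate the compatible ordered haplotype pairs of one genotype pattern.
# gv: genotypes 0/1/2/NA over L SNPs. Returns list(h1, h2) of bit-codes.
# If the combination count would exceed `cap`, the least informative missing
# positions are fixed at their frequency-expected genotype first.
enumerate_pairs <- function(gv, p, cap = 4096L) {
  L <- length(gv)
  nmiss <- sum(is.na(gv))
  nhet <- sum(!is.na(gv) & gv == 1L)
  while (2^nhet * 4^nmiss > cap && nmiss > 0L) {
    j <- which(is.na(gv))[1L]
    gv[j] <- round(2 * p[j])
    nmiss <- nmiss - 1L
    nhet <- nhet + (gv[j] == 1L)
  }
  opt_a <- list(0, c(0, 1), 1, c(0, 0, 1, 1))  # by genotype 0/1/2/missing
  opt_b <- list(0, c(1, 0), 1, c(0, 1, 0, 1))
  gi <- ifelse(is.na(gv), 4L, gv + 1L)
  hA <- 0; hB <- 0
  for (j in seq_len(L)) {
    bit <- 2^(j - 1L)
    a <- opt_a[[gi[j]]]; b <- opt_b[[gi[j]]]
    k <- length(a)
    hA <- rep(hA, each = k) + rep(a, times = length(hA)) * bit
    hB <- rep(hB, each = k) + rep(b, times = length(hB)) * bit
  }
  list(h1 = hA, h2 = hB)
}

# Enumerate compatible haplotypes for a haploid (male X) pattern.
enumerate_haps <- function(gv, p, cap = 1024L) {
  L <- length(gv)
  av <- ifelse(is.na(gv), NA, pmin(gv, 1L))
  nmiss <- sum(is.na(av))
  while (2^nmiss > cap && nmiss > 0L) {
    j <- which(is.na(av))[1L]
    av[j] <- as.integer(p[j] >= 0.5)
    nmiss <- nmiss - 1L
  }
  h <- 0
  for (j in seq_len(L)) {
    bit <- 2^(j - 1L)
    a <- if (is.na(av[j])) c(0, 1) else av[j]
    h <- rep(h, each = length(a)) + rep(a, times = length(h)) * bit
  }
  h
}

code_to_alleles <- function(code, L) {
  vapply(seq_len(L), function(j) as.integer(bitwAnd(as.integer(code), bitwShiftL(1L, j - 1L)) != 0L),
         integer(length(code)))
}

# EM over haplotype frequencies for one window.
# gw: n x L genotypes; haploid_rows: logical, single-haplotype animals.
# Returns per-animal phased alleles a1, a2 (a2 = allele duplicated 0 for
# haploid rows prior to masking) and per-cell posterior of the imputation.
em_phase_window <- function(gw, haploid_rows, p, n_starts, max_iter, tol) {
  n <- nrow(gw); L <- ncol(gw)
  key <- apply(gw, 1L, function(r) paste(ifelse(is.na(r), 3L, r), collapse = ""))
  key <- paste0(ifelse(haploid_rows, "h", "d"), key)
  upat <- !duplicated(key)
  pat_of <- match(key, key[upat])
  rows_u <- which(upat)
  cnt <- tabulate(pat_of, nbins = length(rows_u))

  # candidate pairs per unique pattern
  l1 <- vector("list", length(rows_u)); l2 <- l1; lh <- l1
  for (k in seq_along(rows_u)) {
    gv <- gw[rows_u[k], ]
    if (haploid_rows[rows_u[k]]) {
      hs <- enumerate_haps(gv, p)
      l1[[k]] <- hs; l2[[k]] <- rep(NA_real_, length(hs))
      lh[[k]] <- rep(TRUE, length(hs))
    } else {
      pr <- enumerate_pairs(gv, p)
      l1[[k]] <- pr$h1; l2[[k]] <- pr$h2
      lh[[k]] <- rep(FALSE, length(pr$h1))
    }
  }
  sizes <- lengths(l1)
  pair_pat <- rep(seq_along(rows_u), sizes)
  pair_h1 <- unlist(l1, use.names = FALSE)
  pair_h2 <- unlist(l2, use.names = FALSE)
  pair_hap <- unlist(lh, use.names = FALSE)
  hap_codes <- sort(unique(c(pair_h1, pair_h2[!is.na(pair_h2)])))
  i1 <- match(pair_h1, hap_codes)
  i2 <- match(pair_h2, hap_codes)
  H <- length(hap_codes)
  wt <- cnt[pair_pat]

  # precomputed index machinery so each EM iteration is pure vector work:
  # pairs are contiguous by pattern, so per-pattern sums are cumsum diffs;
  # haplotype accumulation uses one precomputed sort.
  ends_pat <- cumsum(tabulate(pair_pat, nbins = length(rows_u)))
  pat_sizes <- diff(c(0L, ends_pat))
  sel2 <- !pair_hap
  i2d <- ifelse(pair_hap, H + 1L, i2)  # dummy hap with frequency 1
  acc_idx <- c(i1, i2[sel2])
  ord_acc <- order(acc_idx)
  perm <- c(seq_along(pair_pat), which(sel2))[ord_acc]
  acc_sorted <- acc_idx[ord_acc]
  ends_acc <- which(c(acc_sorted[-1L] != acc_sorted[-length(acc_sorted)], TRUE))
  hap_at_ends <- acc_sorted[ends_acc]

  run_em <- function(f) {
    ll_old <- -Inf; ll <- -Inf
    for (it in seq_len(max_iter)) {
      fe <- c(f, 1)
      w <- fe[i1] * fe[i2d]
      s <- pmax(diff(c(0, cumsum(w)[ends_pat])), 1e-300)
      ll <- sum(cnt * log(s))
      post <- w / rep.int(s, pat_sizes)
      val <- post * wt
      vv <- val[perm]
      sums <- diff(c(0, cumsum(vv)[ends_acc]))
      f_new <- numeric(H)
      f_new[hap_at_ends] <- sums
      f <- f_new / sum(f_new)
      if (ll - ll_old < tol) break
      ll_old <- ll
    }
    list(f = f, ll = ll)
  }
  best <- NULL
  for (st in seq_len(n_starts)) {
    f0 <- if (st == 1L) rep(1 / H, H) else {
      x <- stats::rexp(H); x / sum(x)
    }
    fit <- run_em(f0)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  f <- best$f

  # max-posterior pair per pattern + per-cell genotype posterior
  fe <- c(f, 1)
  w <- fe[i1] * fe[i2d]
  s <- pmax(diff(c(0, cumsum(w)[ends_pat])), 1e-300)
  post_pair <- w / rep.int(s, pat_sizes)
  sel_list <- split(seq_along(pair_pat), pair_pat)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  postm <- matrix(NA_real_, n, L)
  A1 <- code_to_alleles(pair_h1, L)
  if (is.null(dim(A1))) A1 <- matrix(A1, nrow = 1L)
  A2 <- matrix(NA_integer_, length(pair_h2), L)
  ok2 <- !is.na(pair_h2)
  if (any(ok2)) {
    tmp <- code_to_alleles(pair_h2[ok2], L)
    if (is.null(dim(tmp))) tmp <- matrix(tmp, nrow = 1L)
    A2[ok2, ] <- tmp
  }
  for (k in seq_along(rows_u)) {
    sel <- sel_list[[k]]
    bestp <- sel[which.max(post_pair[sel])]
    rows <- which(pat_of == k)
    b1 <- A1[bestp, ]; b2 <- A2[bestp, ]
    if (pair_hap[bestp]) b2 <- rep(0L, L)
    a1[rows, ] <- matrix(b1, length(rows), L, byrow = TRUE)
    a2[rows, ] <- matrix(b2, length(rows), L, byrow = TRUE)
    gv <- gw[rows_u[k], ]
    if (anyNA(gv)) {
      gdose <- A1[sel, , drop = FALSE] +
        ifelse(is.na(A2[sel, , drop = FALSE]), 0L, A2[sel, , drop = FALSE])
      chosen <- gdose[which.max(post_pair[sel]), ]
      for (j in which(is.na(gv))) {
        pj <- sum(post_pair[sel][gdose[, j] == chosen[j]])
        postm[rows, j] <- pj
      }
    }
  }
  list(a1 = a1, a2 = a2, post = postm, f = f, hap_codes = hap_codes, ll = best$ll)
}
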