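#' Build candidate QTL regions from across- and within-breed ASE ranks
#'
#' Seed SNPs are those whose across-breed rank is at most `top_k`. Seeds on
#' the same chromosome are merged when separated by at most `gap_max`, and
#' each merged region is then extended outwards to the SNPs whose rank in any
#' within-breed analysis is at most `top_k`, nearest first, as long as the
#' region span stays within `max_span`. Per-breed minimum ranks are taken
#' over all SNPs inside the final interval.
#'
#' @param across an `ase_table` (or data frame with `snp_id`, `chrom`, `pos`,
#'   `rank`) from the across-breed analysis.
#' @param within named list of rank vectors (or `ase_table`s), one per breed,
#'   over the same SNPs in the same order.
#' @param top_k rank threshold defining seed and extension SNPs (default 500).
#' @param gap_max maximum gap (bp) between seeds merged into one region.
#' @param max_span maximum region span in bp (end - start).
#' @return Data frame of class `region_table`: `chrom`, `start`, `end`,
#'   `snp` and `snp_pos` (tag SNP: best across-breed rank in the interval),
#'   `n_snp`, `n_top_across`, one `rank_<breed>` column per breed with the
#'   minimum within-breed rank in the interval, and `rank_all` (minimum
#'   across-breed rank).
#' @export
build_regions <- function(across, within, top_k = 500L, gap_max = 1e6,
                          max_span = 5.7e6) {
  if (max_span < gap_max) stop("max_span must be at least gap_max")
  rk_of <- function(x) if (is.data.frame(x)) x$rank else x
  a_rank <- rk_of(across)
  w_ranks <- lapply(within, rk_of)
  stopifnot(all(vapply(w_ranks, length, integer(1)) == length(a_rank)))
  snp <- data.frame(snp_id = across$snp_id, chrom = as.character(across$chrom),
                    pos = across$pos, a_rank = a_rank, stringsAsFactors = FALSE)
  W <- do.call(cbind, w_ranks)
  w_hit <- apply(W <= top_k, 1L, any)
  out <- list()
  for (ch in unique(snp$chrom)) {
    ix <- which(snp$chrom == ch)
    ix <- ix[order(snp$pos[ix])]
    seeds <- ix[snp$a_rank[ix] <= top_k]
    if (!length(seeds)) next
    gap <- c(Inf, diff(snp$pos[seeds]))
    grp <- cumsum(gap > gap_max)
    bounds <- list()
    for (g in unique(grp)) {
      sg <- seeds[grp == g]
      lo <- min(snp$pos[sg]); hi <- max(snp$pos[sg])
      # extend with within-breed hits, nearest first, under the span cap
      cand <- ix[w_hit[ix] & (snp$pos[ix] < lo | snp$pos[ix] > hi)]
      if (length(cand)) {
        dist <- pmin(abs(snp$pos[cand] - lo), abs(snp$pos[cand] - hi))
        for (cidx in cand[order(dist)]) {
          nlo <- min(lo, snp$pos[cidx]); nhi <- max(hi, snp$pos[cidx])
          if (nhi - nlo <= max_span) { lo <- nlo; hi <- nhi }
        }
      }
      bounds[[length(bounds) + 1L]] <- c(lo, hi)
    }
    # coalesce regions left overlapping after extension (same locus) when
    # the union still respects the span cap
    i <- 1L
    while (i < length(bounds)) {
      a <- bounds[[i]]; b <- bounds[[i + 1L]]
      if (b[1] <= a[2] && max(a[2], b[2]) - a[1] <= max_span) {
        bounds[[i]] <- c(a[1], max(a[2], b[2]))
        bounds[[i + 1L]] <- NULL
      } else i <- i + 1L
    }
    for (bd in bounds) {
      lo <- bd[1]; hi <- bd[2]
      inreg <- ix[snp$pos[ix] >= lo & snp$pos[ix] <= hi]
      tag <- inreg[which.min(snp$a_rank[inreg])]
      row <- data.frame(chrom = ch, start = lo, end = hi,
                        snp = snp$snp_id[tag], snp_pos = snp$pos[tag],
                        n_snp = length(inreg),
                        n_top_across = sum(snp$a_rank[inreg] <= top_k),
                        stringsAsFactors = FALSE)
      for (b in names(w_ranks))
        row[[paste0("rank_", tolower(b))]] <- min(W[inreg, b])
      row$rank_all <- min(snp$a_rank[inreg])
      out[[length(out) + 1L]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(res) <- NULL
  class(res) <- c("region_table", "data.frame")
  res
}

region_rank_cols <- function(regions) {
  setdiff(grep("^rank_", names(regions), value = TRUE), "rank_all")
}

#' Filter regions to those supported in enough breeds
#'
#' A region is declared to harbour a QTL when the number of breeds whose
#' minimum within-breed rank inside the interval is at most `threshold`
#' reaches `min_breeds`.
#'
#' @param regions a `region_table` with per-breed minimum-rank columns.
#' @param threshold within-breed rank threshold (default 500).
#' @param min_breeds minimum number of supporting breeds (default 3).
#' @return The supported subset, with `n_breeds_support` and
#'   `breeds_support` columns added.
#' @export
detect_shared_qtl <- function(regions, threshold = 500L, min_breeds = 3L) {
  cols <- region_rank_cols(regions)
  if (!nrow(regions)) {
    regions$n_breeds_support <- integer(0)
    regions$breeds_support <- character(0)
    return(regions)
  }
  rk <- as.matrix(regions[, cols, drop = FALSE])
  hit <- rk <= threshold
  regions$n_breeds_support <- rowSums(hit)
  bl <- toupper(substr(sub("^rank_", "", cols), 1L, 1L))
  regions$breeds_support <- apply(hit, 1L, function(h) paste(bl[h], collapse = ","))
  out <- regions[regions$n_breeds_support >= min_breeds, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_table", "data.frame")
  out
}

#' Summarize breed support and over-threshold ranks for a region table
#'
#' Tabulates regions by number of supporting breeds at `threshold`, and
#' counts and averages the per-breed minimum-rank entries that exceed the
#' threshold.
#'
#' @param regions a `region_table` with per-breed minimum-rank columns.
#' @param threshold within-breed rank threshold.
#' @return list: `n_regions`, `support_counts` (named vector over supporting
#'   breed counts), `n_over` (rank entries above the threshold), `mean_over`
#'   (their arithmetic mean, rounded to integer for reporting) and
#'   `mean_over_raw`.
#' @export
summarize_support <- function(regions, threshold = 500L) {
  cols <- region_rank_cols(regions)
  rk <- as.matrix(regions[, cols, drop = FALSE])
  supp <- rowSums(rk <= threshold)
  counts <- table(factor(supp, levels = 0:length(cols)))
  over <- rk[rk > threshold]
  list(n_regions = nrow(regions),
       support_counts = stats::setNames(as.integer(counts), names(counts)),
       n_over = length(over),
       mean_over = if (length(over)) round(mean(over)) else NA_integer_,
       mean_over_raw = if (length(over)) mean(over) else NA_real_)
}

#' Span of a genomic interval
#'
#' Returns `end - start` in bp (matching the printed arithmetic of published
#' interval sizes) plus a kb value rounded to the nearest integer kb, or to
#' one decimal when below 100 kb.
#'
#' @param start,end 1-based bp coordinates, `start <= end`.
#' @return Data frame with columns `bp` and `kb` (vectorized).
#' @export
interval_span <- function(start, end) {
  if (any(start > end)) stop("start must not exceed end")
  bp <- end - start
  kb <- ifelse(bp < 1e5, round(bp / 1000, 1), round(bp / 1000))
  data.frame(bp = bp, kb = kb)
}
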