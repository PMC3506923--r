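#' Real-valued marker code for a single genotype
#'
#' Centred allele-count coding used in the marker incidence matrix M: at
#' diploid loci (autosomes and the pseudoautosomal region) `AA`, `AB`, `BB`
#' map to `2q`, `q - p`, `-2p`; at non-pseudoautosomal X-linked loci in males
#' `AY`, `BY` map to `q`, `-p`, where `p` is the A-allele frequency and
#' `q = 1 - p`.
#'
#' @param genotype one of `"AA"`, `"AB"`, `"BB"`, `"AY"`, `"BY"`.
#' @param p A-allele frequency, in (0, 1).
#' @param sex `"M"` or `"F"`.
#' @param chrom chromosome class: autosome name, `"X"`, or `"XY"`
#'   (pseudoautosomal).
#' @return The real-valued code.
#' @export
code_genotype <- function(genotype, p, sex, chrom) {
  stopifnot(length(genotype) == 1L, p > 0, p < 1)
  q <- 1 - p
  hemi <- genotype %in% c("AY", "BY")
  if (is.na(genotype) || !(genotype %in% c("AA", "AB", "BB", "AY", "BY")))
    stop("missing or invalid genotype code; impute before building M")
  if (hemi && !(chrom == "X" && sex == "M"))
    stop("AY/BY codes are only valid for males at non-pseudoautosomal X loci")
  switch(genotype,
         AA = 2 * q, AB = q - p, BB = -2 * p,
         AY = q, BY = -p)
}

#' Build the marker incidence matrix M and its scaling constant
#'
#' Columns are the centred codes of [code_genotype()]; the scaling constant
#' is `c = 2 * sum(p * q)` over all SNPs in the analysis. By default X-linked
#' SNPs also contribute `2pq` to the sum (the single scalar applies jointly
#' to autosomes and X); set `x_scale = "pq"` to let them contribute `pq`.
#'
#' @param g a [geno_matrix()] with no missing genotypes.
#' @param p optional A-allele frequencies; defaults to in-sample frequencies
#'   of the animals in `g`.
#' @param x_scale `"2pq"` (default) or `"pq"`: X-linked contribution to the
#'   scaling constant.
#' @return list of class `marker_design`: `M` (animals x SNPs), `p`, `scale`
#'   (the constant `c`), `x_scale`.
#' @export
marker_design <- function(g, p = NULL, x_scale = c("2pq", "pq")) {
  x_scale <- match.arg(x_scale)
  if (anyNA(g$geno)) stop("missing genotypes present; run phase_impute() first")
  if (is.null(p)) p <- snp_freqs(g)
  stopifnot(length(p) == ncol(g$geno))
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP(s) in analysis set; apply filter_snps() first")
  M <- sweep(g$geno, 2L, 2 * p)  # diploid: x - 2p
  xs <- is_x_snp(g$map)
  mx <- g$animals$sex == "M"
  if (any(xs) && any(mx))
    M[mx, xs] <- sweep(g$geno[mx, xs, drop = FALSE], 2L, p[xs])  # hemizygous: x - p
  pq <- p * (1 - p)
  const <- if (x_scale == "2pq") 2 * sum(pq) else 2 * sum(pq[!xs]) + sum(pq[xs])
  structure(list(M = M, p = p, scale = const, x_scale = x_scale),
            class = "marker_design")
}

#' Genomic relationship matrix (VanRaden method 1, X-aware)
#'
#' `G = M M' / c` with `c = 2 * sum(p * q)`, where M carries the centred
#' genotype codes including the hemizygous male X coding.
#'
#' @inheritParams marker_design
#' @param design optionally a precomputed [marker_design()] (overrides `g`).
#' @return Object of class `grm`: `G` (n x n symmetric), `scale`, `p`,
#'   `epsilon` (regularization applied so far, initially 0).
#' @export
build_grm <- function(g, p = NULL, x_scale = c("2pq", "pq"), design = NULL) {
  if (is.null(design)) design <- marker_design(g, p, x_scale)
  G <- tcrossprod(design$M) / design$scale
  structure(list(G = G, scale = design$scale, p = design$p, epsilon = 0),
            class = "grm")
}

#' Blend a GRM with the identity to guarantee invertibility
#'
#' Returns `(1 - epsilon) G + epsilon I`. Duplicate genotypes (e.g. from
#' half-sib cohorts with identical-by-state animals) can make G singular;
#' the back-solve of SNP effects requires its inverse.
#'
#' @param grm a [build_grm()] result.
#' @param epsilon blending weight in [0, 1); default 0.01.
#' @return The regularized `grm`; `epsilon` records the total blend applied.
#' @export
regularize_grm <- function(grm, epsilon = 0.01) {
  stopifnot(inherits(grm, "grm"), epsilon >= 0, epsilon < 1)
  if (epsilon > 0) {
    grm$G <- (1 - epsilon) * grm$G
    diag(grm$G) <- diag(grm$G) + epsilon
    grm$epsilon <- 1 - (1 - grm$epsilon) * (1 - epsilon)
  }
  grm
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$G), "animals; scale c =", format(x$scale),
      "; epsilon =", x$epsilon, "\n")
  cat("  mean diagonal:", format(mean(diag(x$G)), digits = 4), "\n")
  invisible(x)
}

#' Write a GRM as a dense TSV with ids in the header
#' @param grm a `grm` object.
#' @param path output file.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(animal_id = rownames(grm$G), grm$G, check.names = FALSE)
  attr_line <- sprintf("# scale=%.10g epsilon=%.10g", grm$scale, grm$epsilon)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path input file.
#' @return A `grm` object.
#' @export
read_grm <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[0-9.eE+-]+", hdr))[[1]]
  vals <- stats::setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df[[1]]
  structure(list(G = G, scale = vals[["scale"]], p = NULL,
                 epsilon = vals[["epsilon"]]), class = "grm")
}
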