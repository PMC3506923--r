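#' Genotype matrix container
#'
#' Bundles an animals-by-SNPs dosage matrix with its SNP map and animal table.
#' Genotypes are stored as the count of the A allele: 0 (BB), 1 (AB), 2 (AA)
#' at diploid loci, and 0 (BY) or 1 (AY) at non-pseudoautosomal X-linked loci
#' in males. Missing genotypes are `NA`.
#'
#' @param geno integer matrix, animals in rows and SNPs in columns. Dimnames
#'   are taken from `animals$animal_id` and `map$snp_id` if absent.
#' @param map data frame with columns `snp_id`, `chrom` (autosome `"1"`..`"29"`,
#'   `"X"`, or `"XY"` for the pseudoautosomal region), `pos` (1-based bp) and
#'   optionally `unique_map` (logical, default `TRUE`).
#' @param animals data frame with columns `animal_id`, `breed`, `sex`
#'   (`"M"`/`"F"`) and optionally `sire_id`, `herd`, `slaughter_date`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, map, animals) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map)
  animals <- as.data.frame(animals)
  if (is.null(map$unique_map)) map$unique_map <- TRUE
  stopifnot(
    nrow(geno) == nrow(animals), ncol(geno) == nrow(map),
    all(c("snp_id", "chrom", "pos") %in% names(map)),
    all(c("animal_id", "breed", "sex") %in% names(animals))
  )
  map$chrom <- as.character(map$chrom)
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids")
  if (anyDuplicated(animals$animal_id)) stop("duplicate animal ids")
  rownames(geno) <- as.character(animals$animal_id)
  colnames(geno) <- as.character(map$snp_id)
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  # male non-PAR X cells carry at most one allele copy
  mx <- animals$sex == "M"
  xs <- map$chrom == "X"
  if (any(mx) && any(xs)) {
    bad <- geno[mx, xs, drop = FALSE] == 2L
    if (any(bad, na.rm = TRUE)) stop("male X genotypes must be hemizygous (0/1/NA)")
  }
  structure(list(geno = geno, map = map, animals = animals),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs\n")
  cat("  breeds:", paste(sort(unique(x$animals$breed)), collapse = ", "), "\n")
  nm <- sum(is.na(x$geno))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nm, 100 * nm / length(x$geno)))
  invisible(x)
}

#' Subset a genotype matrix by animals and/or SNPs
#'
#' @param x a [geno_matrix()].
#' @param i animal ids, indices or logical vector.
#' @param j SNP ids, indices or logical vector.
#' @param ... unused.
#' @return A `geno_matrix` restricted to the selected animals and SNPs.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(i)) i <- match(i, x$animals$animal_id)
  if (is.character(j)) j <- match(j, x$map$snp_id)
  geno_matrix(x$geno[i, j, drop = FALSE], x$map[j, , drop = FALSE],
              x$animals[i, , drop = FALSE])
}

is_x_snp <- function(map) map$chrom == "X"

chrom_order <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  n[chrom == "X"] <- 30L
  n[chrom == "XY"] <- 31L
  n
}

#' Per-SNP allele frequencies
#'
#' Frequency of the A allele computed from observed (non-missing) genotypes;
#' male non-pseudoautosomal X cells contribute a single allele.
#'
#' @param g a [geno_matrix()].
#' @param by_breed if `TRUE`, return a SNPs-by-breeds matrix of within-breed
#'   frequencies; otherwise a single pooled frequency vector.
#' @return Numeric vector (or matrix) of A-allele frequencies.
#' @export
snp_freqs <- function(g, by_breed = FALSE) {
  copies <- matrix(2, nrow(g$geno), ncol(g$geno))
  if (any(g$animals$sex == "M") && any(is_x_snp(g$map)))
    copies[g$animals$sex == "M", is_x_snp(g$map)] <- 1
  copies[is.na(g$geno)] <- 0
  dose <- g$geno
  dose[is.na(dose)] <- 0L
  one <- function(rows) {
    num <- colSums(dose[rows, , drop = FALSE])
    den <- colSums(copies[rows, , drop = FALSE])
    ifelse(den > 0, num / den, NA_real_)
  }
  if (!by_breed) return(one(seq_len(nrow(g$geno))))
  breeds <- sort(unique(as.character(g$animals$breed)))
  out <- vapply(breeds, function(b) one(which(g$animals$breed == b)),
                numeric(ncol(g$geno)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, breeds))
  rownames(out) <- g$map$snp_id
  out
}

# --- TSV dialect -----------------------------------------------------------

#' Write a table in the package TSV dialect
#'
#' UTF-8, tab-separated, header row, '.' decimal separator, "NA" for missing,
#' no quoting or row names.
#'
#' @param x data frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Read a table written by [write_tsv()]
#' @param path input file.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write a genotype matrix as three TSV files
#'
#' Writes `<prefix>.geno.tsv` (animal_id + one dosage column per SNP),
#' `<prefix>.map.tsv` and `<prefix>.animals.tsv`.
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_geno_tsv <- function(g, prefix) {
  write_tsv(data.frame(animal_id = g$animals$animal_id, g$geno,
                       check.names = FALSE), paste0(prefix, ".geno.tsv"))
  write_tsv(g$map, paste0(prefix, ".map.tsv"))
  write_tsv(g$animals, paste0(prefix, ".animals.tsv"))
  invisible(prefix)
}

#' Read a genotype matrix written by [write_geno_tsv()]
#' @param prefix path prefix used when writing.
#' @return A [geno_matrix()].
#' @export
read_geno_tsv <- function(prefix) {
  gt <- read_tsv(paste0(prefix, ".geno.tsv"))
  geno <- as.matrix(gt[, -1, drop = FALSE])
  geno_matrix(geno, read_tsv(paste0(prefix, ".map.tsv")),
              read_tsv(paste0(prefix, ".animals.tsv")))
}

# --- PLINK ped/map ---------------------------------------------------------

#' Write a genotype matrix as PLINK .ped/.map text files
#'
#' Alleles are written in A/B space (`A`/`B` letters, `0` for missing); male
#' X genotypes are written as the single allele doubled, following the PLINK
#' hemizygote convention. The family column carries the breed and the
#' paternal-id column the sire.
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix (writes `<prefix>.ped` and `<prefix>.map`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  map <- data.frame(chrom = g$map$chrom, snp_id = g$map$snp_id,
                    cm = 0, pos = g$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  a1 <- matrix("0", nrow(g$geno), ncol(g$geno))
  a2 <- a1
  a1[!is.na(g$geno) & g$geno >= 1L] <- "A"
  a1[!is.na(g$geno) & g$geno == 0L] <- "B"
  a2[!is.na(g$geno) & g$geno == 2L] <- "A"
  a2[!is.na(g$geno) & g$geno <= 1L] <- "B"
  # male X hemizygotes: repeat the single allele
  mx <- g$animals$sex == "M"
  xs <- is_x_snp(g$map)
  if (any(mx) && any(xs)) a2[mx, xs] <- a1[mx, xs]
  gcols <- matrix("", nrow(g$geno), 2L * ncol(g$geno))
  gcols[, seq(1L, ncol(gcols), 2L)] <- a1
  gcols[, seq(2L, ncol(gcols), 2L)] <- a2
  sire <- if (is.null(g$animals$sire_id)) "0" else as.character(g$animals$sire_id)
  ped <- cbind(as.character(g$animals$breed), as.character(g$animals$animal_id),
               sire, "0", ifelse(g$animals$sex == "M", "1", "2"), "-9", gcols)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK .ped/.map text files
#'
#' Expects biallelic genotypes in A/B space as written by [write_plink()].
#'
#' @param prefix path prefix (reads `<prefix>.ped` and `<prefix>.map`).
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character", "numeric", "integer"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(map)
  stopifnot(ncol(ped) == 6L + 2L * m)
  a1 <- as.matrix(ped[, 6L + seq(1L, 2L * m, 2L), drop = FALSE])
  a2 <- as.matrix(ped[, 6L + seq(2L, 2L * m, 2L), drop = FALSE])
  geno <- (a1 == "A") + (a2 == "A")
  geno[a1 == "0" | a2 == "0"] <- NA
  animals <- data.frame(animal_id = ped[[2]], breed = ped[[1]],
                        sex = ifelse(ped[[5]] == "1", "M", "F"),
                        sire_id = ped[[3]], stringsAsFactors = FALSE)
  # male X: PLINK writes the single allele twice; collapse back to 0/1
  mx <- animals$sex == "M"
  xs <- map$chrom == "X"
  if (any(mx) && any(xs)) {
    sub <- geno[mx, xs, drop = FALSE]
    sub[sub == 2L] <- 1L
    geno[mx, xs] <- sub
  }
  geno_matrix(geno, map[, c("snp_id", "chrom", "pos")], animals)
}
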