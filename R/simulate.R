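#' Configuration for the half-sib cohort simulator
#'
#' Defaults emulate the multi-breed Carcass Merit design the package is built
#' around: five breeds genotyped at ~40k autosomal + X SNPs, half-sib families
#' (18-29 sires per breed), breed-divergent allele frequencies, contemporary
#' group fixed effects (breed x herd x sex x slaughter date), per-breed
#' additive variances/heritabilities spanning 0.08-0.52, and one or two major
#' QTL inside locally densified SNP regions mimicking the *CAST* (BTA7) and
#' *CAPN1* (BTA29) intervals, each explaining one to a few percent of
#' phenotypic variance.
#'
#' @param breeds breed names.
#' @param sires_per_breed integer vector, sires per breed.
#' @param progeny_per_sire integer vector, half-sib family size per breed.
#' @param n_snps total SNP count, including X-linked and dense-region SNPs.
#' @param n_x_snps number of X-linked SNPs.
#' @param chr_lengths named vector of chromosome lengths in bp (29 autosomes
#'   plus X).
#' @param dense_regions list of `list(chrom, start, end, n_snp)` locally
#'   densified intervals; within them gametes are drawn from a small founder
#'   haplotype pool so that local LD (beyond family structure) exists.
#' @param n_founder_haps founder haplotypes per breed in each dense region.
#' @param dense_recomb expected ancestral crossovers per dense region per
#'   gamete; controls how fast local LD decays along the region.
#' @param breed_fst Balding-Nichols divergence of breed allele frequencies
#'   around the shared ancestral frequency, in [0, 1).
#' @param qtl list of `list(chrom, pos, effect=)` or `list(chrom, pos,
#'   frac_var=)`: additive QTL placed at the SNP nearest `pos`, either with an
#'   allele substitution effect in kg or a target fraction of pooled
#'   phenotypic variance.
#' @param h2 per-breed heritability, each in (0, 1).
#' @param var_a per-breed additive genetic variance (kg^2); QTL variance is
#'   carved out of it, the remainder is polygenic.
#' @param var_e0 residual variance (kg^2) used for a breed whose `var_a` or
#'   `h2` is zero (otherwise the residual is `var_a * (1 - h2) / h2`).
#' @param mean_wbsf per-breed phenotype mean (kg).
#' @param n_herds,n_dates numbers of herds and slaughter dates per breed.
#' @param cg_sd standard deviation (kg) of contemporary-group effects.
#' @param dam_breed optional vector: breed whose allele frequencies dam
#'   gametes are drawn from (defaults to the sire's breed; set e.g. all
#'   `"Angus"` to emulate Continental crosses on commercial Angus cows).
#' @param missing_rate missing-completely-at-random genotype rate.
#' @param n_low_call_animals animals (cohort-wide) planted with elevated
#'   missingness so that animal call-rate filtering has known casualties.
#' @param low_call_rate call rate given to those planted animals.
#' @param seed integer seed; all output is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(breeds = c("Angus", "Charolais", "Hereford", "Limousin", "Simmental"),
                       sires_per_breed = c(20L, 18L, 29L, 23L, 24L),
                       progeny_per_sire = c(33L, 39L, 41L, 12L, 22L),
                       n_snps = 40000L,
                       n_x_snps = 1200L,
                       chr_lengths = NULL,
                       dense_regions = list(
                         list(chrom = "7", start = 96.8e6, end = 99.7e6, n_snp = 44L),
                         list(chrom = "29", start = 43.0e6, end = 46.1e6, n_snp = 100L)),
                       n_founder_haps = 16L,
                       dense_recomb = 3,
                       breed_fst = 0.10,
                       qtl = list(list(chrom = "29", pos = 44.07e6, frac_var = 0.0185),
                                  list(chrom = "7", pos = 98.4e6, frac_var = 0.0102)),
                       h2 = c(0.52, 0.46, 0.17, 0.09, 0.08),
                       var_a = c(0.22, 0.23, 0.15, 0.07, 0.06),
                       var_e0 = 0.25,
                       mean_wbsf = c(3.74, 4.41, 4.75, 4.28, 4.36),
                       n_herds = 3L, n_dates = 4L, cg_sd = 0.35,
                       dam_breed = NULL,
                       missing_rate = 0.0089,
                       n_low_call_animals = 0L, low_call_rate = 0.60,
                       seed = 1L) {
  nb <- length(breeds)
  rep_to <- function(x) if (length(x) == 1L) rep(x, nb) else x
  sires_per_breed <- rep_to(sires_per_breed)
  progeny_per_sire <- rep_to(progeny_per_sire)
  h2 <- rep_to(h2); var_a <- rep_to(var_a); mean_wbsf <- rep_to(mean_wbsf)
  if (is.null(dam_breed)) dam_breed <- breeds
  dam_breed <- rep_to(dam_breed)
  if (is.null(chr_lengths)) {
    chr_lengths <- c(round(seq(161e6, 51e6, length.out = 29)), 149e6)
    names(chr_lengths) <- c(as.character(1:29), "X")
  }
  cfg <- list(breeds = breeds, sires_per_breed = as.integer(sires_per_breed),
              progeny_per_sire = as.integer(progeny_per_sire),
              n_snps = as.integer(n_snps), n_x_snps = as.integer(n_x_snps),
              chr_lengths = chr_lengths, dense_regions = dense_regions,
              n_founder_haps = as.integer(n_founder_haps),
              dense_recomb = dense_recomb,
              breed_fst = breed_fst, qtl = qtl, h2 = h2, var_a = var_a,
              var_e0 = var_e0,
              mean_wbsf = mean_wbsf, n_herds = as.integer(n_herds),
              n_dates = as.integer(n_dates), cg_sd = cg_sd,
              dam_breed = dam_breed, missing_rate = missing_rate,
              n_low_call_animals = as.integer(n_low_call_animals),
              low_call_rate = low_call_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  nb <- length(cfg$breeds)
  stopifnot(
    nb >= 1L, all(cfg$sires_per_breed >= 1L), all(cfg$progeny_per_sire >= 1L),
    cfg$n_snps >= 1L, cfg$n_x_snps >= 0L, cfg$n_x_snps < cfg$n_snps,
    length(cfg$sires_per_breed) == nb, length(cfg$progeny_per_sire) == nb,
    length(cfg$h2) == nb, length(cfg$var_a) == nb,
    all(cfg$h2 > 0 & cfg$h2 < 1) || all(cfg$var_a == 0),
    all(cfg$h2 >= 0 & cfg$h2 < 1), all(cfg$var_a >= 0),
    cfg$breed_fst >= 0, cfg$breed_fst < 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    all(cfg$dam_breed %in% cfg$breeds)
  )
  for (dr in cfg$dense_regions) {
    L <- cfg$chr_lengths[[as.character(dr$chrom)]]
    if (is.null(L) || dr$start < 1 || dr$end > L || dr$start >= dr$end)
      stop("dense region outside declared chromosome length: ", dr$chrom)
  }
  for (q in cfg$qtl) {
    if (is.null(cfg$chr_lengths[[as.character(q$chrom)]]))
      stop("QTL on undeclared chromosome: ", q$chrom)
    if (is.null(q$effect) && is.null(q$frac_var))
      stop("QTL needs either an effect (kg) or frac_var")
  }
  invisible(cfg)
}

# Build the SNP map: uniform placement across autosomes + X, with dense
# regions getting their declared extra SNP counts.
build_sim_map <- function(cfg) {
  n_dense <- sum(vapply(cfg$dense_regions, function(d) as.integer(d$n_snp), integer(1)))
  n_bg <- cfg$n_snps - cfg$n_x_snps - n_dense
  if (n_bg < 1L) stop("n_snps too small for the X and dense-region SNP counts")
  auto <- cfg$chr_lengths[names(cfg$chr_lengths) != "X"]
  n_per <- pmax(round(n_bg * auto / sum(auto)), 1L)
  rows <- list()
  for (ch in names(auto)) {
    pos <- sort(sample.int(auto[[ch]], n_per[[ch]]))
    rows[[ch]] <- data.frame(chrom = ch, pos = pos)
  }
  if (cfg$n_x_snps > 0L)
    rows[["X"]] <- data.frame(chrom = "X",
                              pos = sort(sample.int(cfg$chr_lengths[["X"]], cfg$n_x_snps)))
  for (k in seq_along(cfg$dense_regions)) {
    d <- cfg$dense_regions[[k]]
    pos <- sort(sample(seq(d$start, d$end), d$n_snp))
    rows[[paste0("dense", k)]] <- data.frame(chrom = as.character(d$chrom), pos = pos)
  }
  map <- do.call(rbind, rows)
  map <- map[!duplicated(map[c("chrom", "pos")]), ]
  map <- map[order(chrom_order(map$chrom), map$pos), ]
  map$snp_id <- sprintf("snp%06d", seq_len(nrow(map)))
  map$unique_map <- TRUE
  rownames(map) <- NULL
  map[, c("snp_id", "chrom", "pos", "unique_map")]
}

# Vectorized gamete sampling for all progeny of one sire: hap1/hap2 are the
# sire's two haplotype vectors (length m); returns n x m matrix.
# Recombination follows a Haldane-style Markov switch along each chromosome.
sire_gametes <- function(hap1, hap2, switch_prob, n) {
  m <- length(hap1)
  sw <- matrix(stats::rbinom(n * m, 1L, prob = rep(switch_prob, each = n)), n, m)
  state <- t(apply(sw, 1L, cumsum)) %% 2L
  H1 <- matrix(hap1, n, m, byrow = TRUE)
  H2 <- matrix(hap2, n, m, byrow = TRUE)
  ifelse(state == 0L, H1, H2)
}

#' Simulate a multi-breed half-sib cohort with known truth
#'
#' Sire haplotypes are drawn from breed allele frequencies (Balding-Nichols
#' divergence around a shared ancestral frequency); each progeny inherits one
#' recombined sire gamete and one dam gamete drawn from the dam breed's
#' frequencies (dams themselves are unobserved). Within declared dense
#' regions, all gametes are copies of a small per-breed founder haplotype
#' pool, creating local LD. Phenotypes are
#' `y = mean + contemporary group + sum(QTL dosage * effect) + polygenic + residual`,
#' with the polygenic variance set per breed so that total additive variance
#' (QTL included) matches `var_a` and heritability `var_a / (var_a + var_e)`
#' matches `h2`. Males are hemizygous at X-linked SNPs (paternal X goes to
#' daughters only).
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `geno` (a [geno_matrix()]), `pheno` (data
#'   frame with `animal_id`, `breed`, `sex`, `sire_id`, `herd`,
#'   `slaughter_date`, `cg`, `wbsf`) and `truth` (list: per-breed allele
#'   frequencies, QTL table, true breeding values, polygenic values,
#'   per-breed variance components, contemporary-group effects, planted
#'   low-call-rate animal ids, sire genotypes, and true dense-region
#'   haplotypes).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- build_sim_map(cfg)
  m <- nrow(map)
  nb <- length(cfg$breeds)
  xs <- map$chrom == "X"

  # ancestral and per-breed allele frequencies (Balding-Nichols)
  p0 <- stats::runif(m, 0.05, 0.95)
  Fst <- cfg$breed_fst
  pb <- matrix(0, m, nb, dimnames = list(map$snp_id, cfg$breeds))
  for (b in seq_len(nb)) {
    pb[, b] <- if (Fst > 0)
      stats::rbeta(m, p0 * (1 - Fst) / Fst, (1 - p0) * (1 - Fst) / Fst)
    else p0
    pb[, b] <- pmin(pmax(pb[, b], 0.001), 0.999)
  }

  # planted QTL sites: resolve to the nearest mapped SNP now, and force an
  # intermediate frequency in every breed so the QTL segregates cohort-wide
  # (the shared-QTL scenario the across-breed concordance procedure targets)
  qtl_idx <- integer(0)
  if (length(cfg$qtl)) {
    qtl_idx <- vapply(cfg$qtl, function(q) {
      cand <- which(map$chrom == as.character(q$chrom))
      if (!length(cand)) stop("no SNPs on QTL chromosome ", q$chrom)
      cand[which.min(abs(map$pos[cand] - q$pos))]
    }, integer(1))
    pb[qtl_idx, ] <- stats::runif(length(qtl_idx) * nb, 0.3, 0.7)
  }

  # dense-region founder haplotype pools (per breed per region)
  dense_idx <- lapply(cfg$dense_regions, function(d)
    which(map$chrom == as.character(d$chrom) & map$pos >= d$start & map$pos <= d$end))
  pools <- lapply(seq_along(dense_idx), function(k) {
    idx <- dense_idx[[k]]
    lapply(seq_len(nb), function(b) {
      H <- matrix(stats::rbinom(cfg$n_founder_haps * length(idx), 1L, rep(pb[idx, b], each = cfg$n_founder_haps)),
                  cfg$n_founder_haps, length(idx))
      w <- stats::rexp(cfg$n_founder_haps)
      w <- w / sum(w)
      # keep planted QTL columns at usable pooled frequency despite the
      # small founder pool
      for (j in intersect(idx, qtl_idx)) {
        col <- match(j, idx)
        for (try in 1:50) {
          f <- sum(w * H[, col])
          if (f >= 0.2 && f <= 0.8) break
          H[, col] <- stats::rbinom(cfg$n_founder_haps, 1L, pb[j, b])
        }
      }
      list(H = H, w = w)
    })
  })
  # gametes from a dense-region pool are mosaics of founder haplotypes with
  # a few ancestral crossovers per region, so local LD decays along the
  # region instead of being complete across it
  draw_pool_haps <- function(k, b, n) {
    pool <- pools[[k]][[b]]
    L <- ncol(pool$H)
    K <- nrow(pool$H)
    if (L == 1L)
      return(pool$H[sample.int(K, n, replace = TRUE, prob = pool$w), , drop = FALSE])
    r <- cfg$dense_recomb / (L - 1L)
    out <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      sw <- which(stats::runif(L - 1L) < r)
      cuts <- c(1L, sw + 1L, L + 1L)
      for (sseg in seq_len(length(cuts) - 1L)) {
        hap <- sample.int(K, 1L, prob = pool$w)
        out[i, cuts[sseg]:(cuts[sseg + 1L] - 1L)] <- pool$H[hap, cuts[sseg]:(cuts[sseg + 1L] - 1L)]
      }
    }
    out
  }
  # overwrite dense-region columns of a haplotype matrix with pool draws
  apply_pools <- function(H, b) {
    for (k in seq_along(dense_idx))
      H[, dense_idx[[k]]] <- draw_pool_haps(k, b, nrow(H))
    H
  }

  # recombination switch probabilities between adjacent SNPs (1 cM/Mb),
  # independent assortment at chromosome starts
  d_bp <- c(0, diff(map$pos))
  first <- !duplicated(map$chrom)
  switch_prob <- pmin(0.5, 0.5 * (1 - exp(-2 * d_bp * 1e-8)))
  switch_prob[first] <- 0.5

  draw_breed_haps <- function(b, n) {
    matrix(stats::rbinom(n * m, 1L, rep(pb[, b], each = n)), n, m, byrow = FALSE)
  }

  animals <- list(); H_pat <- list(); H_mat <- list()
  sire_geno <- list(); sire_ids_all <- character(0)
  var_p_breed <- ifelse(cfg$var_a > 0 & cfg$h2 > 0,
                        cfg$var_a / pmax(cfg$h2, 1e-12), cfg$var_a + cfg$var_e0)
  for (b in seq_len(nb)) {
    ns <- cfg$sires_per_breed[b]
    npr <- cfg$progeny_per_sire[b]
    dam_b <- match(cfg$dam_breed[b], cfg$breeds)
    s1 <- apply_pools(matrix(stats::rbinom(ns * m, 1L, rep(pb[, b], each = ns)), ns, m, byrow = FALSE), b)
    s2 <- apply_pools(matrix(stats::rbinom(ns * m, 1L, rep(pb[, b], each = ns)), ns, m, byrow = FALSE), b)
    # sires are male: single X haplotype, stored in both strands so that the
    # transmitted gamete always carries it
    s2[, xs] <- s1[, xs]
    sire_ids <- sprintf("%s_sire%02d", cfg$breeds[b], seq_len(ns))
    sg <- s1 + s2
    sg[, xs] <- s1[, xs]
    rownames(sg) <- sire_ids
    sire_geno[[b]] <- sg
    sire_ids_all <- c(sire_ids_all, sire_ids)
    for (s in seq_len(ns)) {
      pat <- sire_gametes(s1[s, ], s2[s, ], switch_prob, npr)
      mat <- apply_pools(draw_breed_haps(dam_b, npr), dam_b)
      ids <- sprintf("%s_s%02d_p%03d", cfg$breeds[b], s, seq_len(npr))
      animals[[length(animals) + 1L]] <- data.frame(
        animal_id = ids, breed = cfg$breeds[b],
        sex = sample(c("M", "F"), npr, replace = TRUE),
        sire_id = sire_ids[s],
        herd = sprintf("herd%d", sample.int(cfg$n_herds, npr, replace = TRUE)),
        slaughter_date = sprintf("d%d", sample.int(cfg$n_dates, npr, replace = TRUE)),
        stringsAsFactors = FALSE)
      H_pat[[length(H_pat) + 1L]] <- pat
      H_mat[[length(H_mat) + 1L]] <- mat
    }
  }
  animals <- do.call(rbind, animals)
  H_pat <- do.call(rbind, H_pat)
  H_mat <- do.call(rbind, H_mat)
  n <- nrow(animals)
  male <- animals$sex == "M"
  # males: no paternal X (they receive the sire's Y)
  if (any(xs)) H_pat[male, xs] <- 0L
  geno <- H_pat + H_mat
  if (any(xs)) geno[male, xs] <- H_mat[male, xs]
  rownames(geno) <- animals$animal_id
  colnames(geno) <- map$snp_id
  bidx <- match(animals$breed, cfg$breeds)

  # --- QTL effects ---------------------------------------------------------
  qtl_tab <- NULL
  qtl_val <- numeric(n)
  if (length(cfg$qtl)) {
    qrows <- lapply(seq_along(cfg$qtl), function(qi) {
      q <- cfg$qtl[[qi]]
      j <- qtl_idx[qi]
      dose <- geno[, j]
      vd <- stats::var(dose)
      if (vd <= 0) stop("QTL SNP is monomorphic in the simulated cohort")
      eff <- if (!is.null(q$effect)) q$effect else sqrt(q$frac_var * mean(var_p_breed) / vd)
      data.frame(snp_id = map$snp_id[j], chrom = map$chrom[j], pos = map$pos[j],
                 effect = eff, idx = j)
    })
    qtl_tab <- do.call(rbind, qrows)
    qtl_val <- as.numeric(geno[, qtl_tab$idx, drop = FALSE] %*% qtl_tab$effect)
  }

  # per-breed polygenic variance = var_a minus realized QTL variance
  var_qtl_b <- vapply(seq_len(nb), function(b) {
    if (is.null(qtl_tab)) return(0)
    stats::var(qtl_val[bidx == b])
  }, numeric(1))
  var_poly_b <- cfg$var_a - var_qtl_b
  if (any(var_poly_b < -1e-12))
    stop("infeasible config: QTL variance exceeds the additive variance in breed(s) ",
         paste(cfg$breeds[var_poly_b < -1e-12], collapse = ", "))
  var_poly_b <- pmax(var_poly_b, 0)

  # polygenic values from genome-wide marker effects, so that the realized
  # genomic relationships carry the simulated additive covariance; scaled
  # within breed to hit the per-breed polygenic variance
  b_eff <- stats::rnorm(m)
  if (!is.null(qtl_tab)) b_eff[qtl_tab$idx] <- 0
  poly_raw <- as.numeric(geno %*% b_eff)
  poly <- numeric(n)
  for (b in seq_len(nb)) {
    rows <- which(bidx == b)
    pr <- poly_raw[rows] - mean(poly_raw[rows])
    vr <- stats::var(pr)
    poly[rows] <- if (vr > 0) pr * sqrt(var_poly_b[b] / vr) else 0
  }

  # contemporary groups and residuals
  cg <- interaction(animals$breed, animals$herd, animals$sex,
                    animals$slaughter_date, drop = TRUE)
  cg_eff <- stats::rnorm(nlevels(cg), 0, cfg$cg_sd)
  names(cg_eff) <- levels(cg)
  var_e_b <- ifelse(cfg$var_a > 0 & cfg$h2 > 0,
                    cfg$var_a * (1 - cfg$h2) / pmax(cfg$h2, 1e-12),
                    cfg$var_e0)
  resid <- stats::rnorm(n, 0, sqrt(var_e_b[bidx]))
  qtl_centered <- qtl_val - stats::ave(qtl_val, animals$breed)
  tbv <- qtl_centered + poly
  wbsf <- cfg$mean_wbsf[bidx] + cg_eff[as.character(cg)] + qtl_val + poly + resid

  # --- missingness ---------------------------------------------------------
  low_call <- character(0)
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < cfg$missing_rate, n, m)
    geno[miss] <- NA
  }
  if (cfg$n_low_call_animals > 0L) {
    low_call <- sample(animals$animal_id, cfg$n_low_call_animals)
    rows <- match(low_call, animals$animal_id)
    extra <- matrix(stats::runif(length(rows) * m) < (1 - cfg$low_call_rate), length(rows), m)
    gsub <- geno[rows, , drop = FALSE]
    gsub[extra] <- NA
    geno[rows, ] <- gsub
  }

  g <- geno_matrix(geno, map, animals)
  pheno <- data.frame(animals, cg = as.character(cg), wbsf = wbsf,
                      stringsAsFactors = FALSE)
  truth <- list(
    freqs = pb, qtl = if (is.null(qtl_tab)) qtl_tab else qtl_tab[, 1:4],
    tbv = stats::setNames(tbv, animals$animal_id),
    polygenic = stats::setNames(poly, animals$animal_id),
    var_a = stats::setNames(cfg$var_a, cfg$breeds),
    var_e = stats::setNames(var_e_b, cfg$breeds),
    var_poly = stats::setNames(var_poly_b, cfg$breeds),
    cg_effects = cg_eff, low_call_animals = low_call,
    sire_geno = do.call(rbind, sire_geno),
    dense_haps = lapply(dense_idx, function(idx)
      list(snp_id = map$snp_id[idx],
           pat = H_pat[, idx, drop = FALSE], mat = H_mat[, idx, drop = FALSE]))
  )
  list(geno = g, pheno = pheno, truth = truth)
}

#' Load the packaged 79-region across-breed concordance table
#'
#' Returns the packaged transcription of the published table of genomic
#' regions detected as harbouring WBSF QTL in at least three of five breeds:
#' chromosome, interval boundaries, tag SNP (the most strongly associated SNP
#' in the across-breed analysis) and coordinate, SNP counts, supporting breed
#' list and the six minimum t-statistic rank columns (five within-breed plus
#' across-breed).
#'
#' @return A `region_table` data frame with 79 rows.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2.tsv", package = "tenderqtl")
  if (path == "" || !file.exists(path)) stop("packaged fixture table2.tsv not found")
  t2 <- read_tsv(path)
  need <- c("bta", "start", "end", "snp", "snp_pos", "n_snp", "n_top500", "breeds",
            "rank_angus", "rank_hereford", "rank_charolais", "rank_limousin",
            "rank_simmental", "rank_all")
  if (!all(need %in% names(t2)) || nrow(t2) != 79L)
    stop("packaged fixture table2.tsv is corrupt")
  rk <- as.matrix(t2[, grep("^rank_", names(t2))])
  if (any(rk < 1L) || any(rk != round(rk))) stop("fixture ranks must be positive integers")
  class(t2) <- c("region_table", "data.frame")
  t2
}
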