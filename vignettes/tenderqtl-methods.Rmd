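---
title: "Methods: genomic association and fine-mapping for beef tenderness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic association and fine-mapping for beef tenderness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Warner–Bratzler shear force (WBSF, kg) is measured once per animal on
cohorts of half-sib families from several beef breeds. The analysis asks
three questions: how heritable is WBSF within each breed; which SNPs carry
the largest allele substitution effects (ASEs) within and across breeds; and
do the same genomic regions surface across breeds, in particular around the
calpain-1/calpastatin proteolysis axis. `tenderqtl` implements that chain —
genotype QC, phasing/imputation, genomic relationship matrix (GRM), REML,
GBLUP back-solving, rank concordance, haplotype-window fine-mapping — with a
cohort simulator providing ground truth for validation.

# The animal model and REML

The single-trait model is `y = X beta + u + e` with one record per animal,
`Var(u) = G sigma2_A` and `Var(e) = I sigma2_E`. `X` codes contemporary
groups (breed x herd of origin x sex x slaughter date); levels with fewer
than two records are dropped with a warning, since a singleton cell is
confounded with its own residual. Aliased columns are removed by QR so `X`
has full column rank.

`gblup()` eigendecomposes `G = U D U'` once and rotates the model by `U'`,
making both covariances diagonal. For a given heritability `h2` the total
variance profiles out analytically, so the restricted likelihood is a
one-dimensional function of `h2`; it is maximized exactly by Brent search,
then refined with EM-REML steps until two successive `h2` iterates agree to
`tol_sigfigs` (default 4) significant figures — operationalized as both
rounding to the same 4-significant-digit value. The EM steps guarantee a
non-decreasing restricted log-likelihood (asserted in the unit tests), and
starting them at the Brent optimum makes convergence fast and deterministic.
Estimates of `sigma2_A` at the boundary are clamped at `1e-12` and flagged
(`boundary = TRUE`) rather than raised as errors. A non-positive-definite
`G` is an error that points the user to `regularize_grm()`.

This costs one `O(n^3)` eigendecomposition plus `O(n p^2)` per likelihood
evaluation, comfortable for cohorts of a few thousand animals.

# GRM construction and the X chromosome

`marker_design()` codes diploid genotypes `AA`, `AB`, `BB` as `2q`, `q - p`,
`-2p` (frequency of the A allele `p`, computed from the animals in the
current analysis: within-breed runs use within-breed frequencies, the
across-breed run pooled frequencies). Males at non-pseudoautosomal X-linked
SNPs are hemizygous and coded `q` / `-p`; pseudoautosomal SNPs use the
diploid coding in both sexes. The GRM is `G = M M' / c`.

The scaling constant defaults to `c = 2 * sum(p_i q_i)` over **all** SNPs,
X-linked ones included at `2 p q`. The source analysis writes a single
scalar for autosomes and X jointly without specifying the X contribution; we
adopt the joint `2pq` convention as default and expose the alternative
(`pq` per X SNP, the expected variance of a locus that is diploid in only
half the population) via `marker_design(x_scale = "pq")`. The choice shifts
every ASE by a common factor and therefore never changes `t_i` rankings.

Half-sib cohorts can contain genotype-identical animals, making `G`
singular while the ASE back-solve needs `G^-1`. `regularize_grm()` blends
`(1 - eps) G + eps I` with default `eps = 0.01` — large enough to make the
smallest eigenvalue comfortably positive, small enough that back-solved
ASEs are essentially unchanged (correlation > 0.999 between `eps` 0.01 and
0.001 on simulated cohorts, asserted in tests). The exactness checks
(GBLUP/SNP-BLUP equivalence, `M alpha = u`) use `eps = 0` on full-rank
simulated `G`, where both identities hold to 1e-8.

# ASEs, t-statistics and ranks

`backsolve_ase()` computes `alpha = c^-1 M' G^-1 u_hat`, the per-SNP
variance `sigma2_M = sigma2_A / c`, and `t_i = |alpha_i| / sigma_M`. When
`sigma2_A` is estimated at the boundary (`sigma_M = 0`), all `t_i` are
defined as 0 rather than NaN. Ranks are dense ordinals (1 = largest `t_i`)
with ties broken by genome order (chromosome, then position) so outputs are
reproducible; `rank_ase()` always returns a permutation of `1..n`.

# Genotype QC

`filter_snps()` keeps SNPs that map uniquely to an autosome or X, have call
rate strictly above 0.89 and minor allele frequency strictly above 0.01
within **every** breed (MAF from observed genotypes; male X cells count one
allele). The exclusion log records the first failing rule per SNP, in that
order. `filter_animals()` keeps animals with call rate at or above 0.85 (the
exclusion rule is "below 0.85"). Threshold comparisons carry a 1e-9 guard so
a count ratio that lands exactly on the threshold (e.g. 1 minor allele in
100) is classified by its exact rational value, not floating-point noise.

The order of operations is a documented choice: the SNP filter computes call
rates over all genotyped animals, then the animal filter uses the retained
SNPs, in a single pass. Re-running QC on its own output is a no-op in
practice; the alternative order is not iterated.

# Phasing and imputation

`phase_impute()` is a deliberately local phaser: windows of `window`
(default 9) SNPs slide along each chromosome with `overlap` (default 3)
shared SNPs; within a window, haplotype frequencies are estimated by EM over
each genotype's compatible haplotype pairs (random pairing assumed), with
`n_starts` restarts keeping the best likelihood; every animal then receives
its maximum-posterior pair, missing genotypes are imputed from the same
posterior, and windows are stitched by choosing the orientation most
consistent with the already-phased overlap. Males contribute a single
haplotype at X-linked SNPs. Observed genotypes are never altered — the
collapse of the haplotype pair back to the unordered genotype is asserted on
every call.

Combinatorial caps keep the EM bounded: a pattern whose compatible-pair
count would exceed 4096 has its least-informative missing cells fixed at the
frequency-expected genotype first. EM stops when the log-likelihood gains
less than `tol = 1e-4` or after `max_iter = 30` iterations; haplotype
frequencies only feed local phase assignment, so loose tolerances cost
little accuracy. Downstream haplotype tests only require phase that is
consistent *within* 9-SNP windows, which is exactly what the window EM
provides; no pedigree information or reference panel is used, and long-range
switch errors between windows are possible and harmless for this use.

# Across-breed region concordance

`build_regions()` operationalizes a procedure the source describes only
narratively. Seed SNPs are those with across-breed rank at most `top_k`
(default 500). Seeds on a chromosome merge when separated by at most
`gap_max` (default 1 Mb, our choice). Each merged cluster extends outward to
SNPs whose rank in *any* within-breed analysis is at most `top_k`, nearest
first, while the span stays within `max_span` (default 5.7 Mb, the largest
span the source reports). Regions still overlapping after extension describe
the same locus and are coalesced when their union respects the span cap. All
three knobs are exposed in `run_config()`.

`detect_shared_qtl()` declares a region shared when at least `min_breeds`
(default 3) breeds have a within-breed minimum rank at or below the
threshold; "top 500" means rank <= 500 and "< 1000" means rank <= 999 —
ranks are dense ordinals, so no ties straddle a boundary.
`summarize_support()` returns the support histogram and the count and mean
of over-threshold rank entries. Interval spans are `end - start` in bp
(matching the printed arithmetic of the published interval sizes), with kb
rounded to one decimal below 100 kb and to integers above.

# Fine-mapping

`gls_context()` freezes `V = G sigma2_A + I sigma2_E` at previously
estimated variance components — per-window REML would let the tested effect
absorb genetic variance and is deliberately avoided — and whitens the data
by `V^{-1/2}` from the stored eigendecomposition. All sums of squares are
defined on the whitened scale, which reduces exactly to ordinary least
squares when `V` is proportional to `I` (asserted against `lm()`/`anova()`
in tests) and keeps the F ratio pivotal.

`single_snp_test()` F-tests an allele-dosage column added to the
contemporary-group model (the fitted coefficient is the ASE).
`window_scan()` slides an odd-width window (default 9) through a region one
SNP at a time; observed window haplotypes become levels of a fixed effect
after pooling haplotypes carried by fewer than `min_count` (default 5)
animals — the source does not state how rare haplotypes were handled, so the
pooling rule is ours. Statistics attach to the centre SNP. Two maxima are
reported per region: the max-F window and the max-percent-variance window;
they can differ because the numerator degrees of freedom vary with the
number of haplotypes fit, which is the stated motivation for the
percent-variance statistic

    pct_var = 100 * (model SS with window - model SS without) /
              (total SS - mean SS - contemporary-group SS).

P-values come from the F distribution and are reported as -log10; no
multiple-testing adjustment enters any decision rule, matching the
rank-based reporting of the source. Monomorphic or collinear predictors
yield `NA` rather than errors.

# The cohort simulator

`simulate_cohort()` emulates the study design the package targets; its
defaults are the study conditions: five breeds (Angus, Charolais, Hereford,
Limousin, Simmental) with 18–29 sires each and family sizes reproducing the
published per-breed totals, ~40k autosomal + X SNPs plus two locally
densified regions mimicking the *CAST* (44 SNPs / 2.9 Mb on BTA7) and
*CAPN1* (100 SNPs / 3.1 Mb on BTA29) intervals, per-breed additive variances
0.06–0.23 kg² and heritabilities 0.08–0.52, per-breed mean WBSF 3.74–4.75
kg, contemporary groups of breed x herd x sex x slaughter date with effect
SD 0.35 kg (our choice; the source does not report it), QTL explaining 1–2%
of phenotypic variance, and 0.89% missing genotypes, missing completely at
random. Breed allele frequencies diverge from a shared ancestral frequency
by a Balding–Nichols draw with one parameter (`breed_fst`, default 0.10, a
typical between-breed fixation index for taurine cattle). Dams are
unobserved; progeny receive one recombined sire gamete (Haldane model, 1
cM/Mb) and one dam gamete drawn from the dam breed's frequencies, so X
genotypes in males are maternal and hemizygous.

Three design choices matter for interpretation:

* **Polygenic values are marker effects.** Every SNP receives a small
  normal effect and the resulting genetic values are rescaled within breed
  to the target polygenic variance (`var_a` minus realized QTL variance; a
  config whose QTL variance exceeds `var_a` is rejected). The realized
  genomic relationships therefore carry the simulated additive covariance,
  which is the covariance structure GBLUP assumes — parameter-recovery
  tests measure estimation error, not model misspecification.
* **Planted QTL segregate everywhere.** QTL-designated SNPs get per-breed
  frequencies in (0.3, 0.7) (and dense-region founder pools are rebalanced
  to keep them between 0.2 and 0.8). This is the shared-QTL scenario the
  across-breed concordance procedure is designed to detect; without it the
  causal SNP is frequently near fixation in some breed and silently removed
  by the within-breed MAF filter.
* **Dense regions have decaying local LD.** Within a dense region, gametes
  are mosaics of a small per-breed founder-haplotype pool
  (`n_founder_haps`, default 16) with `dense_recomb` (default 3) expected
  ancestral crossovers per region. Without the mosaics, every 9-SNP window
  would tag a causal variant equally well across the whole region and
  localization would be undefined; with them, tagging decays with distance
  as it does in real data.

What the simulator does **not** emulate: genome-wide ancestral LD (outside
dense regions, LD comes only from family structure and drift), carcass
misidentification and its resolution, genotyping-error structure
(missingness is MCAR, optionally with planted low-call-rate animals for QC
tests), and dominance or epistasis. Passing tests therefore demonstrate the
estimation machinery under the model's own assumptions at realistic sizes —
they do not certify behaviour under LD patterns or error processes the
simulator does not generate.

# Validation strategy and problem sizes

The raw carcass data behind the source analysis are not deposited, so its
data-dependent numbers (per-breed heritabilities, -log10 P values, window
percentages) cannot be recomputed. Validation splits accordingly:

* **Exact fixtures**: the packaged 79-region concordance table reproduces
  every published summary (79 regions at three-breed support; 42/29/8 and
  21/41/17 support histograms at the 500 and sub-1000 rank rules; 113
  over-threshold rank instances with mean 2551), and the printed interval
  arithmetic (8187 bp, 678 kb, 83.7 kb) and Hereford genetic sample size
  (1095 x sqrt(0.17) = 451.5) are recomputed by the same functions users
  call.
* **Identities**: GBLUP/SNP-BLUP equivalence and `M alpha = u` at relative
  tolerance 1e-8; REML against an independent dense-matrix maximizer;
  whitened F-tests against OLS when `V` is proportional to `I`.
* **Generative truth**: REML recovers a simulated `h2 = 0.4` within 0.1 at
  n = 2000 (5000 SNPs, 20 seeds, >= 90%); permuted dosages give uniform
  single-SNP P-values (KS test, 1000 SNPs); a planted 2%-of-variance QTL is
  localized by exactly one detected shared region (3 breeds x 750 progeny,
  1000 SNPs, thresholds scaled to the SNP count); and the max-percent-
  variance window covers a planted off-array causal variant in >= 80% of 20
  seeds at n = 1200 with the QTL fraction (0.135) chosen to match the
  F-test non-centrality of a ~5% signal at the full study size of 3240
  animals — at desk scale the statistic's sampling noise, not the
  implementation, otherwise dominates window choice.

These sizes are the package's chosen validation scale; the machinery itself
has no embedded limits beyond memory for the `n x n` eigendecomposition.

# Known limitations

* The phaser is local by design; it is not a substitute for pedigree-aware
  or reference-panel phasing when long-range haplotypes matter.
* Region construction is one reasonable operationalization of a narrative
  procedure; boundary placement (seed merging, extension order, overlap
  coalescing) is documented and configurable but not canonical.
* The percent-variance statistic is not penalized for the number of
  haplotype levels fit; with many levels and modest n it drifts upward for
  every window, so only *differences* across windows within one region are
  meaningful, and comparisons across cohort sizes are not.
* Variance components in `gls_context()` are frozen by design; standard
  errors of window effects do not propagate REML uncertainty.
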