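---
title: "Models and methods for replicated hybrid-zone analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for replicated hybrid-zone analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybzone)
```

# Scope

`hybzone` analyses SNP data from hybrid zones between two parental species —
the motivating system is the interior spruce complex, where white spruce
(*Picea glauca*) and Engelmann spruce (*P. engelmannii*) hybridise along both
broad latitudinal gradients and narrow elevational transects. The package
covers the desk side of such a study: site filtering and linkage-map
anchoring, hybrid-index estimation and ancestry classification, per-SNP
divergence scans, genotype–environment association (GEA) with a composite
environmental predictor, Bayesian genomic clines, and the machinery for
comparing two transects (shared-SNP correlation, chromosomal autocorrelation,
candidate-gene overlap). Raw-read processing and variant calling are out of
scope; the entry point is a filtered genotype matrix.

Because the interesting claims are about parameter recovery, the package
ships a synthetic hybrid-zone generator with known truth. Every analysis
stage is tested against that truth or against an independent oracle.

# The genomic-cline model

The central object is the per-locus genomic cline. An individual with hybrid
index $h \in [0,1]$ (the proportion of its genome from the parent-A pool)
contributes alleles that descend from pool A with probability

$$\phi_l(h) = h + 2h(1-h)\,\big[\alpha_l + \beta_l(2h - 1)\big],$$

truncated to $[0,1]$. The truncation is required for $\phi$ to be a
probability; the boundary values $\phi(0)=0$ and $\phi(1)=1$ hold for all
finite parameters, so pure individuals are never distorted. $\alpha_l$ shifts
the cline (directional introgression: positive values mean excess parent-A
ancestry relative to the genome-wide expectation), $\beta_l$ changes its
steepness (positive values mean faster-than-genome-wide ancestry transition).
Conditional on ancestry, the allele is the counted allele with its pool's
frequency, and the two alleles of a diploid are independent ancestry draws,
so dosage at locus $l$ is binomial with success probability
$q_l = \phi_l p_{A,l} + (1-\phi_l)p_{B,l}$.

Useful identities, asserted in the tests: with $\alpha=\beta=0$,
$\phi(h) = h$; and relabelling the pools maps
$(h, \alpha, \beta, p_A, p_B) \to (1-h, -\alpha, \beta, p_B, p_A)$ while
leaving every likelihood unchanged.

# Hybrid index

`estimate_hybrid_index()` maximises
$\sum_l \log \mathrm{Binom}(g_l \mid 2, q_l(h))$ with
$q_l(h) = h\,p_{A,l} + (1-h)\,p_{B,l}$ over $h \in [0,1]$ by bounded
golden-section search (tolerance $10^{-6}$); the likelihood is unimodal in
$h$, so a derivative-free bracketed search is reliable and cheap. Parental
frequencies are clamped to $[10^{-4}, 1-10^{-4}]$ so fixed loci cannot
produce $\log 0$. Individuals with fewer than 50 usable calls (missing
genotype or undefined panel frequency excluded) are reported `NA` — below
that the estimate is dominated by noise.

This maximum-likelihood index stands in for the admixture coefficient of a
two-cluster model-based analysis. With pure reference panels the two agree
closely (genotype PCA's first axis correlates with the index at > 0.99 in
both our simulations and published spruce data), and the substitution keeps
the pipeline free of an external variational-inference dependency. Panel
polarity is set by the designated parent-A panel, and the same polarity must
be used across datasets being compared. Panels can either be supplied or
derived from the index itself (`define_parental_panels()`, pure at
$h \ge 0.95$ / $h \le 0.05$); by default a single pass is used rather than
iterating estimate–repartition, which avoids circularity in testing.

Ancestry categories follow the conventional five-way partition of $[0,1]$:
pure parent A ($h \ge 0.95$), parent-A dominant ($0.60 \le h < 0.95$),
balanced ($0.40 < h < 0.60$), parent-B dominant ($0.05 \le h \le 0.40$),
pure parent B ($h < 0.05$).

# Divergence statistics

`wc_fst()` implements the Weir–Cockerham (1984) method-of-moments estimator
per site from the among-population ($a$), among-individual ($b$) and
within-individual ($c$) variance components, computed from observed allele
frequencies and heterozygote counts. Two modes are provided: the
$r$-population estimator (`multipop`, the default, and what the commonly
cited per-SNP implementation computes) and the average of all two-population
pairwise estimates (`mean_pairwise`, how that implementation is often
described); the two coincide exactly at $r = 2$. Sites where $a+b+c = 0$ or
where fewer than two populations have calls are reported `NA`, never zero —
treating undefined sites as zero would bias every downstream summary.

One numerical point matters for simulation recovery: the *mean of per-site
ratios* $\overline{a/(a+b+c)}$ is biased downward at high divergence because
the ratio is a concave function of its noisy numerator; at a generating
divergence of $F = 0.3$ the per-site mean settles near $F/(1+F) \approx
0.23$. The multi-locus ratio-of-sums form $\sum_l a_l / \sum_l (a+b+c)_l$
(reported as `fst_global` / `global`) is the standard genome-wide estimator
and recovers the generating parameter; recovery tests therefore use it,
while the per-site mean remains available for comparison with per-SNP
summaries of real data.

`pi_dxy()` computes within-group diversity and between-group divergence per
site on called alleles only (each diploid contributes up to two alleles, no
imputation): $\pi$ is the fraction of differing pairs among called alleles
within a group, and $d_{xy} = p_A(1-p_B) + p_B(1-p_A)$. These are
per-variant-site values; genome-scale $d_{xy}$ would additionally need the
count of invariant sites, which a SNP matrix does not carry.

# Environmental predictor and GEA

Environmental variables are pruned greedily in their supplied priority
order: a variable is dropped when its absolute Pearson correlation with any
already-retained variable reaches 0.7 (`prune_env()`). Terrain slope and
aspect come from Horn's eight-neighbour finite differences on a DEM grid
(`slope_aspect()`; aspect is the compass bearing of the downslope direction,
undefined on flat cells). Snow-melt day is the first day in the second half
of a snow year with at least 15 snow-free days among the previous 30
(`snow_melt_day()`); for synthetic series the snow year is days 1–365 with
the second half starting at day 183. Melt-day grids can be smoothed by
averaging each pixel with its up-to-8 neighbours (`smooth_neighbors()`).

With a single response, redundancy analysis reduces to ordinary least
squares: `fit_rda1()` regresses the hybrid index on the standardised
retained variables; the RDA1 score is the centred fitted value, the loadings
are standardised coefficients, and the proportion of hybrid-index variance
explained is $R^2$. The reduction is tested against an independent
normal-equations solve to $10^{-10}$.

`gea_lrt()` models per-individual allele dosage as binomial (two trials,
logit link) on the RDA1 predictor, because a likelihood on 0/1/2 dosages
yields an exact nested likelihood-ratio test. The plain variant compares
intercept-only against intercept + predictor (1 df). The structure-corrected
variant takes intercept + PC1 as the null and adds the predictor and its
PC1 interaction (2 df); reading the corrected model as main effects plus
interaction follows standard model-formula semantics, and a 1-df
no-interaction variant is switchable. P-values come from the $\chi^2$ upper
tail. Fits are ridge-stabilised with a penalty of $10^{-6}$ on non-intercept
coefficients so that separated loci (perfect clines) remain finite and
deterministic; the penalty is far below the likelihood scale, and the LRT is
invariant to affine rescaling of the predictor to within that tolerance.
GEA outliers are loci at or below the empirical 1st percentile of defined
p-values, with ties at the cutoff all included.

When the structure axis coincides with the environmental gradient — the
chronic confound of hybrid-zone GEA — the corrected test removes most true
signal along with the false positives. The package exposes both variants and
the tests assert the directional consequence (corrected p-values at causal
loci are stochastically larger), not a specific number.

# Bayesian genomic clines

`bgc_fit()` restricts to ancestry-informative loci (parental differential
$\ge 0.6$, `select_informative_loci()`) and runs an independent random-walk
Metropolis chain per locus on $(\alpha_l, \beta_l)$ under
$\mathrm{Normal}(0, 1)$ priors. Defaults follow common practice for this
model: 100,000 iterations, 50,000 burn-in, thinning 24. Proposal scales are
tuned during burn-in toward ~30% acceptance (factor updates every 100
iterations, clipped to [0.5, 2]); chains with post-burn-in acceptance
outside [0.15, 0.6] are flagged. Outliers are loci whose equal-tail
probability interval (ETPI) excludes zero, with the sign of the excess
reported. The ETPI level defaults to 0.95 with 0.99 available — both appear
in the literature this model comes from, and the choice is surfaced rather
than hidden. The hybrid index is held fixed at its point estimate instead of
being co-estimated: with thousands of loci informing $h$, its posterior is
far tighter than any single-locus cline, and fixing it decouples the modules
(a documented deviation from samplers that co-estimate $h$).

The sampler is validated three ways: on null data the flag rate stays at or
below the nominal level; planted $\alpha = +0.8$ loci are recovered with the
correct sign; and on single loci the posterior means match an exact
fine-grid integration of likelihood × prior to within Monte-Carlo error.
Loci with identical parental frequencies carry no cline information and are
excluded; data with no admixed individuals are rejected as unidentifiable.

`logistic_cline_fit()` provides the regression-based companion test: dosage
on $h$, parametric p from the 1-df LRT, permutation p from shuffles of $h$
with the add-one correction. Note the two statistics answer different
questions — the logistic test measures association with $h$, the Bayesian
$\alpha$ measures cline distortion — so their agreement is strongest at
moderate $|\alpha|$ on loci of comparable informativeness; extreme $|\alpha|$
saturates $\phi$ and can weaken the dosage–$h$ association.

`downsample_panels()` reproduces the subset-reanalysis design: subsets
matched on pure-A/pure-B/admixed composition, preferentially removing
individuals flagged as inside exclusion regions.

# Cross-transect comparison

`intersect_scans()` inner-joins two scans on (scaffold, position);
`scan_correlations()` reports Pearson's r and Kendall's tau, with nominal
p-values explicitly flagged as overestimated because linked SNPs are not
independent. Chromosomal "blockiness" is measured by Moran's I on ordinal
SNP positions (sequential rank within scaffold or linkage group,
`ordinal_positions()`) with inverse-distance weights $w_{ij} =
1/|pos_i - pos_j|$; ordinal rather than physical coordinates sidestep
unknown inter-scaffold gaps in fragmented assemblies and the downward bias
physical distances would introduce where SNP density is low.
`compare_blockiness()` computes per-unit I for both datasets on shared SNPs
and a paired t-test across units (two-sided by default, one-sided
switchable).

Candidate genes are SNP-to-gene assignments through intervals extended by
5 kb flanks (`genes_for_snps()`, BED/GFF3 via `rtracklayer`, VCF positions
1-based and BED half-open conversions handled by the import layer). The
k-way overlap test (`overlap_enrichment()`) uses the independence
expectation $N \prod_i (k_i/N)$ and a permutation null that redraws each set
uniformly without replacement from the universe — matching the expectation
formula; gene length is deliberately not part of the null. The universe is
the genes hit by any SNP tested in all analyses, a choice the data cannot
make for you and which is therefore an explicit argument. For $k=2$ the
permutation p converges to the hypergeometric tail; the tests verify this
and, for $k=4$, an exact enumeration computed by chaining hypergeometric
transitions of the running intersection.

# The synthetic generator

`simulate_hybrid_zone()` emulates the study designs end to end:

* **Parental pools** follow the Balding–Nichols model: ancestral frequency
  uniform on [0.05, 0.95], pool frequencies Beta-distributed around it with
  variance parameter `divergence_F` — one parameter controls the expected
  parental FST and, implicitly, the supply of ancestry-informative loci
  (at $F = 0.3$ roughly 11% of loci exceed the 0.6 differential).
* **Transect designs**: the latitudinal model places individuals along a
  smooth logistic ancestry gradient with two trees per population; the
  elevational model emits `n_locations` × {N, S, V} populations with a
  location-level trend plus fixed site-class offsets (±0.18, noise SD 0.06)
  so parent-B ancestry ranks N > S > V within a location. The paper-scale
  data do not pin down the within-location ancestry variance, so the offsets
  are free simulator parameters chosen to give clearly separated but
  overlapping site classes.
* **Genotypes** are drawn through the cline model above with per-locus
  planted $(\alpha, \beta)$ truth; missingness is MCAR at `missing_rate`
  (the simplest model consistent with a 70% call-rate filter).
* **Environment**: one variable is a linear transform of $h$ plus Gaussian
  noise calibrated to correlation `env_effect` (a snow-melt-day analogue),
  plus four noise decoys — this gives RDA1 a recoverable target and the
  pruning step something to reject.
* Two configs sharing a seed share parental pools, coordinates and planted
  truth while differing in sampling design, which is how replicated-transect
  analyses are simulated.

What the generator does **not** emulate: linkage disequilibrium and ancestry
blocks (loci are conditionally independent given $h$; blocky signals must be
planted through the truth vectors), spatially structured environmental
error, genotyping error beyond MCAR missingness, selection acting during the
simulation, and pedigree structure (except for the explicit gamete
construction used in kinship tests). Passing recovery tests therefore show
the estimators are correct under the model's assumptions, not that real
spruce data satisfy those assumptions.

# Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to keep the whole suite
in minutes while leaving Monte-Carlo margins comfortable: 200–240
individuals, 500–1000 loci (1000 informative loci for hybrid-index RMSE),
MCMC at 20,000 iterations / 10,000 burn-in / thinning 5 for calibration
checks (the full-scale defaults remain 100,000 / 50,000 / 24), 10 seeds for
recovery rates, and 4,000–10,000 permutations for enrichment. Frequency
clamps ($10^{-4}$), the ridge penalty ($10^{-6}$), the golden-section
tolerance ($10^{-6}$) and the equal-tail quantile interpolation (type-7
order statistics) are fixed constants, not tuning knobs. Site filters follow
the conventional thresholds (call rate ≥ 0.70, QUAL ≥ 30, GQ ≥ 20, DP ≥ 5
with strict `>` switchable, MAF strictly > 0.05); per-call GQ/DP masking is
applied before the site-level call-rate and MAF evaluation so that masked
calls count as missing, which is the order that makes the call-rate filter
meaningful.

# Known limitations

Per-SNP $d_{xy}$ omits invariant sites; the MCMC has no hierarchical
shrinkage across loci (each locus is flagged on its own interval); Kendall's
tau is quadratic in the number of shared SNPs and is meant for scans up to a
few tens of thousands of loci; and the enrichment null ignores gene length,
matching the expectation formula but not correcting for longer genes
capturing more SNPs.
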