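# hybzone

Analysis of replicated hybrid zones from SNP genotype matrices: hybrid-index
estimation, divergence scans, genotype–environment association (GEA) with a
redundancy-analysis composite predictor, Bayesian genomic clines, and
cross-transect repeatability statistics — plus a synthetic hybrid-zone
generator with known truth so that every stage has a parameter-recovery test.

## The problem

Where two species hybridise repeatedly — the motivating case is the western
Canadian interior spruce zone between white spruce (*Picea glauca*) and
Engelmann spruce (*P. engelmannii*) — comparing genomic patterns across
replicate contact zones helps separate natural selection from drift. But
replicate zones formed from the same parental pools are not independent:
repeated genotype–environment associations alone are weak evidence. Patterns
of *directional introgression* in the middle of each zone are closer to
independent and therefore more informative. This package implements that
analysis programme as tested, reusable functions.

## The core model

Each individual carries a hybrid index `h` in [0, 1], the proportion of its
genome from the parent-A pool, estimated by maximum likelihood from parental
allele-frequency panels. At a locus with cline parameters α (directional
introgression) and β (cline steepness), an allele descends from pool A with
probability

    φ(h) = h + 2h(1−h)[α + β(2h−1)],   truncated to [0, 1]

and is then drawn at the originating pool's allele frequency; φ(0)=0 and
φ(1)=1 for all α, β. Per-locus (α, β) posteriors come from random-walk
Metropolis chains with Normal(0, 1) priors; a locus is an outlier when the
equal-tail probability interval (ETPI) of α or β excludes zero. Around this
sit per-SNP Weir–Cockerham F_ST (variance components a, b, c), missing-aware
π and d_xy, a binomial-logit likelihood-ratio GEA driven by the leading
redundancy-analysis axis of the environment (RDA1), ordinal-position Moran's
I for chromosomal "blockiness", and a permutation test for multi-set
candidate-gene overlap. The methods vignette
(`vignettes/hybrid-zone-analysis.Rmd`) documents each model and the
numerical choices.

## Worked example

```r
library(hybzone)

# simulate an elevational hybrid zone: 7 locations x {N, S, V} sites
cfg <- sim_config(n_individuals = 315, n_scaffolds = 25, loci_per_scaffold = 20,
                  divergence_F = 0.3, transect_model = "elevational",
                  n_locations = 7, env_effect = 0.85, seed = 42)
sim <- simulate_hybrid_zone(cfg)
sim$geno
#> geno_matrix: 315 individuals x 500 loci on 25 scaffolds
#>   missing calls: 2.0%

# hybrid index and ancestry categories
hi <- estimate_hybrid_index(sim$geno, sim$truth$parental)
round(sqrt(mean((hi$h - sim$truth$h)^2)), 4)        # recovery RMSE
#> [1] 0.039
table(classify_ancestry(hi$h))
#>     parentA_pure parentA_dominant         balanced parentB_dominant
#>               21              102               81               85
#>     parentB_pure
#>               26

# species-level divergence between the pure panels
pan <- define_parental_panels(hi, sim$geno)
round(species_fst(sim$geno, pan$panel)$summary, 3)
#>      mean    median        sd n_defined    global
#>     0.188     0.104     0.216   478.000     0.273

# environmental predictor and GEA scan
rda <- fit_rda1(hi$h, prune_env(sim$env[-1]))
round(rda$r_squared, 3)       # hybrid-index variance explained by RDA1
#> [1] 0.717
gea <- gea_lrt(sim$geno, rda$scores)
sum(gea_outliers(gea$p))      # bottom-1% GEA outliers
#> [1] 5

# Bayesian genomic clines on the ancestry-informative loci
sel <- which(select_informative_loci(sim$truth$parental))
adm <- which(hi$h > 0.05 & hi$h < 0.95)
cl <- bgc_fit(geno_matrix(sim$geno$dosage[adm, sel], sim$geno$loci[sel, ]),
              hi$h[adm], sim$truth$parental[sel, ],
              mcmc_config(20000, 10000, 5, seed = 1))
table(cl$alpha_excess)
#>  -  +  0
#>  2  1 39
```

Reading the output: the hybrid index is recovered to RMSE 0.039 from 500
loci; the five ancestry categories span both pure species and the hybrid
swarm; the multi-locus (`global`) F_ST between the estimated pure panels is
0.273, close to the generating divergence of 0.3, while the per-SNP mean
(0.188) sits lower, as per-site ratio averages do; RDA1 explains 72% of
hybrid-index variation, driven by the simulated snow-melt variable; and with
no planted cline distortions the α-outlier flags stay at the few-percent
level expected of a 95% interval (3 of 42 informative loci).

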