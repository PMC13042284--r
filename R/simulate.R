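#' Simulation configuration for a synthetic hybrid zone
#'
#' Bundles and validates the parameters of the hybrid-zone generator. The
#' defaults describe a desk-scale zone: two parental pools at moderate
#' divergence, a smooth ancestry gradient along the transect, one
#' environmental variable tracking the hybrid index plus noise decoys, and
#' missing genotypes at random.
#'
#' @param n_individuals number of sampled trees.
#' @param n_scaffolds,loci_per_scaffold genome layout; the total locus count
#'   is their product.
#' @param divergence_F Balding-Nichols divergence parameter in (0, 1)
#'   controlling the expected allele-frequency differentiation (FST) between
#'   the two parental pools.
#' @param transect_model \code{"latitudinal"} (a long gradient, two trees per
#'   population) or \code{"elevational"} (\code{n_locations} locations, each
#'   with a north-facing, south-facing and valley population).
#' @param n_locations number of locations for the elevational design.
#' @param cline_alpha_truth,cline_beta_truth per-locus true cline parameters
#'   (scalar recycled, or length \code{n_loci}).
#' @param env_effect target correlation between the "true" environmental
#'   variable and the hybrid index.
#' @param missing_rate fraction of genotype calls masked missing (MCAR).
#' @param seed integer RNG seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 240,
                       n_scaffolds = 25,
                       loci_per_scaffold = 20,
                       divergence_F = 0.3,
                       transect_model = c("latitudinal", "elevational"),
                       n_locations = 7,
                       cline_alpha_truth = 0,
                       cline_beta_truth = 0,
                       env_effect = 0.8,
                       missing_rate = 0.02,
                       seed = 1L) {
  transect_model <- match.arg(transect_model)
  n_loci <- n_scaffolds * loci_per_scaffold
  if (!is.finite(divergence_F) || divergence_F <= 0 || divergence_F >= 1) {
    stop("divergence_F must be in (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_individuals < 2 || n_loci < 1) stop("need >= 2 individuals and >= 1 locus")
  recycle <- function(x, what) {
    if (length(x) == 1) x <- rep(x, n_loci)
    if (length(x) != n_loci) stop(what, " must have length 1 or n_loci")
    if (any(!is.finite(x))) stop(what, " must be finite")
    x
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_loci = n_loci,
    n_scaffolds = as.integer(n_scaffolds),
    loci_per_scaffold = as.integer(loci_per_scaffold),
    divergence_F = divergence_F,
    transect_model = transect_model,
    n_locations = as.integer(n_locations),
    cline_alpha_truth = recycle(cline_alpha_truth, "cline_alpha_truth"),
    cline_beta_truth = recycle(cline_beta_truth, "cline_beta_truth"),
    env_effect = env_effect,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate diverged parental allele frequencies (Balding-Nichols)
#'
#' Draws an ancestral frequency per locus uniformly on \[0.05, 0.95\] and
#' then, independently for each parental pool, a frequency from a Beta
#' distribution with that mean and variance parameter \code{divergence_F}
#' (shape parameters \eqn{p(1-F)/F} and \eqn{(1-p)(1-F)/F}), the standard
#' single-parameter model whose expected Weir-Cockerham FST between the two
#' pools equals \code{divergence_F}.
#'
#' @param n_loci number of loci.
#' @param divergence_F divergence parameter in (0, 1).
#' @param seed optional integer seed; \code{NULL} continues the current
#'   RNG stream.
#' @return a \code{parental_freqs} data frame with columns \code{p_anc},
#'   \code{p_a}, \code{p_b} and the per-locus differential
#'   \code{abs(p_a - p_b)}.
#' @export
simulate_parental_freqs <- function(n_loci, divergence_F, seed = NULL) {
  if (!is.numeric(divergence_F) || !is.finite(divergence_F) ||
      divergence_F <= 0 || divergence_F >= 1) {
    stop("divergence_F must be finite and in (0, 1)")
  }
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p_anc <- stats::runif(n_loci, 0.05, 0.95)
  k <- (1 - divergence_F) / divergence_F
  p_a <- stats::rbeta(n_loci, p_anc * k, (1 - p_anc) * k)
  p_b <- stats::rbeta(n_loci, p_anc * k, (1 - p_anc) * k)
  out <- data.frame(
    locus = seq_len(n_loci),
    p_anc = p_anc,
    p_a = p_a,
    p_b = p_b,
    differential = abs(p_a - p_b)
  )
  class(out) <- c("parental_freqs", "data.frame")
  out
}

# location/site design for the sample frame; h is parent-A (white spruce
# analogue) ancestry, so the Engelmann-like pool is most prevalent on
# north-facing slopes: h(N) < h(S) < h(V) within a location.
sim_true_h <- function(config) {
  n <- config$n_individuals
  if (config$transect_model == "latitudinal") {
    t <- seq(0, 1, length.out = n)
    h <- stats::plogis(8 * (t - 0.5)) + stats::rnorm(n, 0, 0.04)
    pop <- sprintf("L%03d", ceiling(seq_len(n) / 2))
    frame <- data.frame(
      sample_id = sprintf("lat_%03d", seq_len(n)),
      population = pop,
      location = pop,
      site_class = NA_character_,
      lat = 49 + 8 * t,
      lon = -125 + 10 * t,
      elevation = 800 + stats::rnorm(n, 0, 50)
    )
  } else {
    n_pop <- config$n_locations * 3L
    per <- ceiling(n / n_pop)
    design <- expand.grid(site_class = c("N", "S", "V"),
                          location = seq_len(config$n_locations),
                          stringsAsFactors = FALSE)
    idx <- rep(seq_len(n_pop), each = per)[seq_len(n)]
    loc <- design$location[idx]
    site <- design$site_class[idx]
    loc_mean <- seq(0.12, 0.88, length.out = config$n_locations)[loc]
    offset <- c(N = -0.18, S = 0, V = 0.18)[site]
    h <- loc_mean + offset + stats::rnorm(n, 0, 0.06)
    frame <- data.frame(
      sample_id = sprintf("ele_%03d", seq_len(n)),
      population = sprintf("loc%02d_%s", loc, site),
      location = sprintf("loc%02d", loc),
      site_class = site,
      lat = 51 + 0.1 * loc + stats::rnorm(n, 0, 0.01),
      lon = -116 - 0.15 * loc + stats::rnorm(n, 0, 0.01),
      elevation = ifelse(site == "V", 1400, 2100) + stats::rnorm(n, 0, 40)
    )
  }
  frame$h_true <- pmin(pmax(h, 0), 1)
  frame
}

#' Simulate a hybrid-zone dataset with known truth
#'
#' Generates parental pools at the configured divergence, assigns each
#' individual a true hybrid index along the transect (elevational design:
#' a location-level trend plus site-class offsets so that parent-B ancestry
#' ranks N > S > V), and draws genotypes through the genomic-cline model:
#' each allele descends from pool A with probability
#' \code{cline_phi(h, alpha_l, beta_l)} and is then sampled at the
#' originating pool's allele frequency. Genotype calls are masked missing
#' completely at random, and an environment table is emitted with one
#' variable correlated with the hybrid index at \code{env_effect} plus
#' noise decoys.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with components \code{geno} (a \code{\link{geno_matrix}}),
#'   \code{samples} (the sample frame with true \code{h_true}), \code{env}
#'   (per-sample environment table) and \code{truth} (true per-individual h,
#'   per-locus alpha/beta, planted-outlier flags and parental frequencies).
#' @export
simulate_hybrid_zone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  parental <- simulate_parental_freqs(config$n_loci, config$divergence_F)
  n <- config$n_individuals
  L <- config$n_loci

  # locus map drawn before any transect-dependent randomness so that two
  # transect designs simulated from the same seed (replicated zones sampling
  # the same species pair) share coordinates and parental pools
  scaffold <- rep(sprintf("SC%04d", seq_len(config$n_scaffolds)),
                  each = config$loci_per_scaffold)
  pos <- as.vector(vapply(seq_len(config$n_scaffolds), function(s) {
    sort(sample.int(2e6L, config$loci_per_scaffold))
  }, integer(config$loci_per_scaffold)))
  lg <- rep(((seq_len(config$n_scaffolds) - 1L) %% 12L) + 1L,
            each = config$loci_per_scaffold)
  loci <- data.frame(
    scaffold = scaffold, pos = pos,
    id = sprintf("snp%05d", seq_len(L)),
    ref = "A", alt = "C", qual = 100,
    lg = lg, stringsAsFactors = FALSE
  )

  frame <- sim_true_h(config)
  h <- frame$h_true
  a <- config$cline_alpha_truth
  b <- config$cline_beta_truth

  dosage <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    phi <- cline_phi(h, a[l], b[l])
    q <- phi * parental$p_a[l] + (1 - phi) * parental$p_b[l]
    dosage[, l] <- stats::rbinom(n, 2L, q)
  }
  if (config$missing_rate > 0) {
    dosage[stats::runif(n * L) < config$missing_rate] <- NA_integer_
  }

  gq <- matrix(sample(60:99, n * L, replace = TRUE), n, L)
  dp <- matrix(stats::rpois(n * L, 20) + 6L, n, L)
  geno <- geno_matrix(dosage, loci, samples = frame$sample_id, gq = gq, dp = dp)

  # one informative environmental variable plus noise decoys
  r <- config$env_effect
  hs <- as.numeric(scale(h))
  signal <- r * hs + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  env <- data.frame(
    sample_id = frame$sample_id,
    snow_melt_day = round(170 - 25 * signal, 1),
    slope = round(stats::runif(n, 0, 40), 1),
    aspect = round(stats::runif(n, 0, 360), 1),
    dif = round(stats::rnorm(n, 700, 60), 1),
    pvout = round(stats::rnorm(n, 1100, 90), 1)
  )

  truth <- list(
    h = h,
    alpha = a,
    beta = b,
    planted = abs(a) > 0 | abs(b) > 0,
    parental = parental
  )
  list(geno = geno, samples = frame, env = env, truth = truth)
}

#' Simulate a daily binary snow-cover series
#'
#' Snow-covered (1) before the true melt day, snow-free (0) from it onward,
#' with isolated flips at rate \code{noise}.
#'
#' @param n_days series length (one snow year).
#' @param melt_day_truth first snow-free day index.
#' @param noise per-day flip probability.
#' @param seed optional integer seed.
#' @return integer vector of 0/1 snow flags of length \code{n_days}.
#' @export
simulate_snow_series <- function(n_days, melt_day_truth, noise = 0, seed = NULL) {
  if (melt_day_truth < 1 || melt_day_truth > n_days) {
    stop("melt_day_truth must be within 1..n_days")
  }
  if (!is.null(seed)) set.seed(seed)
  snow <- as.integer(seq_len(n_days) < melt_day_truth)
  if (noise > 0) {
    flip <- stats::runif(n_days) < noise
    snow[flip] <- 1L - snow[flip]
  }
  snow
}

#' Simulate a cDNA-to-scaffold alignment summary plus linkage map
#'
#' Emits the three tables consumed by \code{\link{anchor_scaffolds}}: an
#' alignment summary (possibly several rows per cDNA), a centimorgan linkage
#' map covering \code{map_fraction} of the cDNAs across 12 linkage groups,
#' and scaffold lengths. Four failure cases are planted in the first four
#' cDNAs: low coverage, low identity, an exact-identity multimapping tie,
#' and an unmapped cDNA, so the anchoring filters can be exercised.
#'
#' @param n_cdna number of cDNAs (at least 6).
#' @param map_fraction fraction of cDNAs present in the linkage map, in (0, 1\].
#' @param seed optional integer seed.
#' @return list with data frames \code{alignments} (cdna_id, scaffold,
#'   coverage, identity), \code{linkage_map} (cdna_id, lg, cm) and
#'   \code{scaffold_lengths} (scaffold, length), plus the planted case ids.
#' @export
simulate_cdna_alignments <- function(n_cdna, map_fraction = 0.8, seed = NULL) {
  if (map_fraction <= 0 || map_fraction > 1) stop("map_fraction must be in (0, 1]")
  if (n_cdna < 6) stop("n_cdna must be >= 6")
  if (!is.null(seed)) set.seed(seed)
  cdna <- sprintf("cdna%04d", seq_len(n_cdna))
  scaffold <- sprintf("SC%04d", seq_len(n_cdna))

  al <- data.frame(
    cdna_id = cdna,
    scaffold = scaffold,
    coverage = round(stats::runif(n_cdna, 0.6, 1), 3),
    identity = round(stats::runif(n_cdna, 0.92, 0.999), 3),
    stringsAsFactors = FALSE
  )
  al$coverage[1] <- 0.30                     # fails the coverage filter
  al$identity[2] <- 0.80                     # fails the identity filter
  tie <- al[3, ]; tie$scaffold <- sprintf("SC%04d", n_cdna + 1L)
  al <- rbind(al, tie)                       # exact-identity multimapping tie
  al <- al[al$cdna_id != cdna[4], ]          # unmapped cDNA: no row at all

  in_map <- sort(sample.int(n_cdna, max(1, round(map_fraction * n_cdna))))
  linkage_map <- data.frame(
    cdna_id = cdna[in_map],
    lg = ((in_map - 1L) %% 12L) + 1L,
    cm = round(stats::runif(length(in_map), 0, 150), 2),
    stringsAsFactors = FALSE
  )
  scaffold_lengths <- data.frame(
    scaffold = c(scaffold, sprintf("SC%04d", n_cdna + 1L)),
    length = sample.int(5e5L, n_cdna + 1L) + 5e4L,
    stringsAsFactors = FALSE
  )
  list(alignments = al, linkage_map = linkage_map,
       scaffold_lengths = scaffold_lengths,
       planted = list(low_coverage = cdna[1], low_identity = cdna[2],
                      tie = cdna[3], unmapped = cdna[4]))
}
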