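#' Per-SNP Weir-Cockerham FST
#'
#' Method-of-moments estimator built from the among-population (a),
#' among-individual (b) and within-individual (c) variance components of
#' Weir & Cockerham (1984), computed per site from observed allele
#' frequencies and heterozygote counts. \code{mode = "multipop"} evaluates
#' the r-population estimator directly; \code{mode = "mean_pairwise"}
#' averages the 2-population estimator over all population pairs (the two
#' agree exactly when r = 2). Populations with no called genotypes at a site
#' are excluded from that site; sites where the estimator is undefined
#' (a + b + c = 0, or fewer than two populations with calls) are reported
#' \code{NA} rather than zero.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param pop_labels population assignment, one per individual.
#' @param mode \code{"multipop"} or \code{"mean_pairwise"}.
#' @return data frame per locus: \code{fst}, components \code{a}, \code{b},
#'   \code{c} (multipop mode), and \code{n_pops} used.
#' @export
wc_fst <- function(geno, pop_labels, mode = c("multipop", "mean_pairwise")) {
  stopifnot(inherits(geno, "geno_matrix"))
  mode <- match.arg(mode)
  if (length(pop_labels) != nrow(geno$dosage)) {
    stop("pop_labels must have one entry per individual")
  }
  pops <- split(seq_along(pop_labels), pop_labels)
  L <- ncol(geno$dosage)
  out <- data.frame(fst = rep(NA_real_, L), a = NA_real_, b = NA_real_,
                    c = NA_real_, n_pops = NA_integer_)
  for (l in seq_len(L)) {
    g <- geno$dosage[, l]
    stats_by_pop <- lapply(pops, function(idx) {
      gi <- g[idx]; gi <- gi[!is.na(gi)]
      if (length(gi) == 0) return(NULL)
      c(n = length(gi), p = mean(gi) / 2, het = mean(gi == 1))
    })
    stats_by_pop <- stats_by_pop[!vapply(stats_by_pop, is.null, TRUE)]
    r <- length(stats_by_pop)
    out$n_pops[l] <- r
    if (r < 2) next
    m <- do.call(rbind, stats_by_pop)
    if (mode == "multipop") {
      comp <- wc_components(m[, "n"], m[, "p"], m[, "het"])
      out$a[l] <- comp["a"]; out$b[l] <- comp["b"]; out$c[l] <- comp["c"]
      denom <- sum(comp)
      if (is.finite(denom) && denom != 0) out$fst[l] <- comp["a"] / denom
    } else {
      prs <- utils::combn(r, 2)
      theta <- apply(prs, 2, function(ij) {
        comp <- wc_components(m[ij, "n"], m[ij, "p"], m[ij, "het"])
        denom <- sum(comp)
        if (is.finite(denom) && denom != 0) comp["a"] / denom else NA_real_
      })
      if (any(is.finite(theta))) out$fst[l] <- mean(theta, na.rm = TRUE)
    }
  }
  out
}

# Weir & Cockerham (1984) variance components for one biallelic site:
# n, p, het are per-population sample sizes (diploid individuals), reference
# allele frequencies and observed heterozygote frequencies.
wc_components <- function(n, p, het) {
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * het) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Between-species FST from pure parental panels
#'
#' Two-population Weir-Cockerham FST per site between the pure parent-A and
#' pure parent-B panels, with a summary over defined sites.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param panel character vector (\code{pureA}/\code{pureB}/\code{admixed})
#'   as produced by \code{\link{define_parental_panels}}.
#' @return list with per-site \code{sites} (as \code{\link{wc_fst}}) and
#'   \code{summary} (mean, median, sd over defined sites).
#' @export
species_fst <- function(geno, panel) {
  keep <- !is.na(panel) & panel %in% c("pureA", "pureB")
  if (!any(panel == "pureA", na.rm = TRUE) || !any(panel == "pureB", na.rm = TRUE)) {
    stop("both pure panels must be non-empty")
  }
  sub <- geno_subset(geno, rows = which(keep))
  sites <- wc_fst(sub, panel[keep])
  ok <- is.finite(sites$fst)
  okc <- is.finite(sites$a)
  list(sites = sites,
       summary = c(mean = mean(sites$fst[ok]), median = stats::median(sites$fst[ok]),
                   sd = stats::sd(sites$fst[ok]), n_defined = sum(ok),
                   global = sum(sites$a[okc]) /
                     sum(sites$a[okc] + sites$b[okc] + sites$c[okc])))
}

# row/column subset preserving the container
geno_subset <- function(geno, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(geno$dosage))
  if (is.null(cols)) cols <- seq_len(ncol(geno$dosage))
  geno_matrix(geno$dosage[rows, cols, drop = FALSE],
              geno$loci[cols, , drop = FALSE],
              samples = geno$samples[rows],
              gq = if (is.null(geno$gq)) NULL else geno$gq[rows, cols, drop = FALSE],
              dp = if (is.null(geno$dp)) NULL else geno$dp[rows, cols, drop = FALSE])
}

#' Nucleotide diversity within and divergence between groups
#'
#' Missing-data-aware per-site estimators on called alleles only (each
#' diploid contributes up to two alleles, no imputation): within a group,
#' pi is the fraction of differing pairs among all pairs of called alleles;
#' between groups, dxy is the probability that one allele drawn from each
#' group differs, \eqn{p_A(1-p_B) + p_B(1-p_A)}. A group with fewer than two
#' called alleles at a site has undefined pi there; dxy needs at least one
#' called allele per group.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param group_a,group_b disjoint row index vectors (or logical masks).
#' @return data frame per locus: \code{pi_a}, \code{pi_b}, \code{dxy}, and
#'   called-allele counts \code{n_a}, \code{n_b}.
#' @export
pi_dxy <- function(geno, group_a, group_b) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (is.logical(group_a)) group_a <- which(group_a)
  if (is.logical(group_b)) group_b <- which(group_b)
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  tally <- function(rows) {
    g <- geno$dosage[rows, , drop = FALSE]
    n <- 2 * colSums(!is.na(g))        # called alleles
    n1 <- colSums(g, na.rm = TRUE)     # counted-allele copies
    list(n = n, n1 = n1)
  }
  ta <- tally(group_a); tb <- tally(group_b)
  pi_of <- function(t) {
    out <- rep(NA_real_, length(t$n))
    ok <- t$n >= 2
    out[ok] <- 2 * t$n1[ok] * (t$n[ok] - t$n1[ok]) / (t$n[ok] * (t$n[ok] - 1))
    out
  }
  ok <- ta$n >= 1 & tb$n >= 1
  pa <- ifelse(ta$n > 0, ta$n1 / ta$n, NA_real_)
  pb <- ifelse(tb$n > 0, tb$n1 / tb$n, NA_real_)
  dxy <- rep(NA_real_, length(ok))
  dxy[ok] <- pa[ok] * (1 - pb[ok]) + pb[ok] * (1 - pa[ok])
  data.frame(pi_a = pi_of(ta), pi_b = pi_of(tb), dxy = dxy,
             n_a = ta$n, n_b = tb$n)
}

#' Summaries of a divergence scan
#'
#' Mean, median and SD of FST over sites where it is defined, plus the
#' fraction of sites segregating (both alleles present) within each panel.
#' When the per-site variance components are available, the multi-locus
#' ratio-of-sums estimator \eqn{\sum a / \sum (a+b+c)} is also reported: the
#' mean of per-site ratios is biased downward at high divergence (the ratio
#' is a concave function of its noisy numerator), whereas the ratio of sums
#' is the standard genome-wide Weir-Cockerham estimator and recovers the
#' generating divergence parameter.
#'
#' @param sites per-site data frame with an \code{fst} column.
#' @param geno optional \code{\link{geno_matrix}} for polymorphism fractions.
#' @param panel optional panel labels (\code{pureA}/\code{pureB}).
#' @return named list of summaries.
#' @export
summarize_divergence <- function(sites, geno = NULL, panel = NULL) {
  if (nrow(sites) == 0) stop("no sites to summarise")
  f <- sites$fst[is.finite(sites$fst)]
  out <- list(fst_mean = mean(f), fst_median = stats::median(f),
              fst_sd = if (length(f) > 1) stats::sd(f) else 0,
              n_defined = length(f), n_sites = nrow(sites))
  if (all(c("a", "b", "c") %in% names(sites))) {
    okc <- is.finite(sites$a)
    out$fst_global <- sum(sites$a[okc]) /
      sum(sites$a[okc] + sites$b[okc] + sites$c[okc])
  }
  if (!is.null(geno) && !is.null(panel)) {
    poly_frac <- function(p) {
      rows <- which(!is.na(panel) & panel == p)
      g <- geno$dosage[rows, , drop = FALSE]
      n1 <- colSums(g, na.rm = TRUE)
      n <- 2 * colSums(!is.na(g))
      mean(n1 > 0 & n1 < n)
    }
    out$polymorphic_pureA <- poly_frac("pureA")
    out$polymorphic_pureB <- poly_frac("pureB")
  }
  out
}
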