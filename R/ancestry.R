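#' Maximum-likelihood hybrid index
#'
#' Estimates each individual's hybrid index h (the proportion of its genome
#' derived from the parent-A pool) by maximising the binomial likelihood of
#' its allele dosages given per-locus mixture frequencies
#' \eqn{q_l(h) = h\,p_{A,l} + (1-h)\,p_{B,l}}. The likelihood is unimodal in
#' h, so a bounded golden-section search on \[0, 1\] (tolerance 1e-6) finds
#' the optimum; parental frequencies are clamped to \[1e-4, 1-1e-4\] to
#' avoid log(0) at fixed loci. Individuals with fewer than \code{min_loci}
#' usable calls are flagged and reported missing.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param parental a \code{parental_freqs} data frame (columns \code{p_a},
#'   \code{p_b}) with one row per locus of \code{geno}.
#' @param min_loci minimum usable loci per individual.
#' @return data frame with \code{sample_id}, \code{h}, \code{loglik},
#'   \code{n_loci}.
#' @export
estimate_hybrid_index <- function(geno, parental, min_loci = 50) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (nrow(parental) != ncol(geno$dosage)) {
    stop("parental must have one row per locus")
  }
  eps <- 1e-4
  p_a <- pmin(pmax(parental$p_a, eps), 1 - eps)
  p_b <- pmin(pmax(parental$p_b, eps), 1 - eps)
  usable_l <- is.finite(p_a) & is.finite(p_b)

  fit_one <- function(g) {
    ok <- !is.na(g) & usable_l
    n_ok <- sum(ok)
    if (n_ok < min_loci) {
      return(c(h = NA_real_, loglik = NA_real_, n_loci = n_ok))
    }
    gg <- g[ok]; pa <- p_a[ok]; pb <- p_b[ok]
    nll <- function(h) {
      q <- h * pa + (1 - h) * pb
      -sum(gg * log(q) + (2 - gg) * log1p(-q))
    }
    opt <- stats::optimize(nll, c(0, 1), tol = 1e-6)
    c(h = opt$minimum, loglik = -opt$objective + sum(lchoose(2, gg)),
      n_loci = n_ok)
  }
  res <- t(apply(geno$dosage, 1, fit_one))
  out <- data.frame(sample_id = geno$samples, h = res[, "h"],
                    loglik = res[, "loglik"],
                    n_loci = as.integer(res[, "n_loci"]),
                    stringsAsFactors = FALSE)
  low <- !is.na(out$n_loci) & out$n_loci < min_loci
  if (any(is.na(out$h))) {
    warning(sum(is.na(out$h)), " individual(s) with < ", min_loci,
            " usable loci; hybrid index reported missing")
  }
  out
}

#' Classify ancestry category from the hybrid index
#'
#' Five categories partitioning \[0, 1\] (h = parent-A proportion):
#' parent-A pure (h >= 0.95), parent-A-dominant hybrid (0.60 <= h < 0.95),
#' balanced hybrid (0.40 < h < 0.60), parent-B-dominant hybrid
#' (0.05 <= h <= 0.40), and parent-B pure (h < 0.05).
#'
#' @param h hybrid index values in \[0, 1\].
#' @return factor with levels \code{parentA_pure}, \code{parentA_dominant},
#'   \code{balanced}, \code{parentB_dominant}, \code{parentB_pure}.
#' @export
classify_ancestry <- function(h) {
  if (any(!is.na(h) & (h < 0 | h > 1))) stop("h must be in [0, 1]")
  lev <- c("parentA_pure", "parentA_dominant", "balanced",
           "parentB_dominant", "parentB_pure")
  out <- rep(NA_character_, length(h))
  out[h >= 0.95] <- "parentA_pure"
  out[h >= 0.60 & h < 0.95] <- "parentA_dominant"
  out[h > 0.40 & h < 0.60] <- "balanced"
  out[h >= 0.05 & h <= 0.40] <- "parentB_dominant"
  out[h < 0.05] <- "parentB_pure"
  factor(out, levels = lev)
}

#' Partition individuals into pure parental panels and admixed set
#'
#' Individuals with h at or above \code{threshold} form the pure parent-A
#' panel, those at or below \code{1 - threshold} the pure parent-B panel,
#' and the remainder are admixed. Panel allele frequencies are recomputed
#' from the pure sets.
#'
#' @param hybrid data frame from \code{\link{estimate_hybrid_index}} (or any
#'   frame with \code{sample_id} and \code{h}).
#' @param geno optional \code{\link{geno_matrix}} for recomputing panel
#'   allele frequencies.
#' @param threshold purity cutoff (default 0.95).
#' @return list with \code{panel} (character vector \code{pureA},
#'   \code{pureB}, \code{admixed} aligned with \code{hybrid}) and, when
#'   \code{geno} is given, \code{freqs} (a \code{parental_freqs}-style frame
#'   recomputed from the pure panels).
#' @export
define_parental_panels <- function(hybrid, geno = NULL, threshold = 0.95) {
  h <- hybrid$h
  panel <- ifelse(is.na(h), NA_character_,
           ifelse(h >= threshold, "pureA",
           ifelse(h <= 1 - threshold, "pureB", "admixed")))
  for (p in c("pureA", "pureB")) {
    if (sum(panel == p, na.rm = TRUE) < 10) {
      warning("pure panel ", p, " has fewer than 10 individuals; ",
              "cline estimates may be underpowered")
    }
  }
  out <- list(panel = panel)
  if (!is.null(geno)) {
    stopifnot(nrow(geno$dosage) == length(panel))
    freq_of <- function(p) {
      rows <- which(!is.na(panel) & panel == p)
      colMeans(geno$dosage[rows, , drop = FALSE], na.rm = TRUE) / 2
    }
    p_a <- freq_of("pureA"); p_b <- freq_of("pureB")
    fr <- data.frame(locus = seq_along(p_a), p_a = p_a, p_b = p_b,
                     differential = abs(p_a - p_b))
    class(fr) <- c("parental_freqs", "data.frame")
    out$freqs <- fr
  }
  out
}

#' Principal component analysis of the dosage matrix
#'
#' Missing dosages are mean-imputed per locus; loci are centred (and
#' optionally scaled) before the decomposition, the standard treatment for
#' genotype PCA.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param n_components number of axes to return.
#' @param scale. scale loci to unit variance (default \code{FALSE}).
#' @return list with \code{scores} (individuals x components) and
#'   \code{var_explained} (fractions, non-increasing).
#' @export
geno_pca <- function(geno, n_components = 2, scale. = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$dosage
  if (n_components > nrow(x)) stop("more components requested than individuals")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  keep <- apply(x, 2, stats::sd) > 0 | !scale.
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE], var_explained = ve[seq_len(k)])
}

#' VanRaden genomic relatedness matrix
#'
#' \eqn{G = ZZ^T / (2\sum_l p_l(1-p_l))} with \eqn{Z = dosage - 2p_l},
#' allele frequencies taken from the sample; monomorphic loci are excluded
#' and missing dosages are imputed at their expectation \eqn{2p_l} (zero
#' after centring). Diagonal entries average about 1 + f for inbreeding
#' level f; unrelated outbred pairs are near 0, half-sibs near 0.25.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @return symmetric individuals x individuals matrix.
#' @export
vanraden_kinship <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$dosage
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("all loci are monomorphic")
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(x, 2, 2 * p)
  z[is.na(z)] <- 0
  g <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(g) <- list(geno$samples, geno$samples)
  (g + t(g)) / 2
}
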