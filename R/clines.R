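#' Select ancestry-informative loci
#'
#' Loci whose parental allele-frequency differential \code{|p_a - p_b|}
#' reaches \code{min_differential} are informative for cline inference and
#' are retained.
#'
#' @param parental a \code{parental_freqs}-style frame with \code{p_a},
#'   \code{p_b}.
#' @param min_differential threshold (default 0.6, inclusive).
#' @return logical vector over loci.
#' @export
select_informative_loci <- function(parental, min_differential = 0.6) {
  d <- abs(parental$p_a - parental$p_b)
  !is.na(d) & d >= min_differential
}

#' MCMC configuration for Bayesian genomic clines
#'
#' @param n_iterations total Metropolis iterations (default 100000).
#' @param burn_in discarded initial iterations (default 50000).
#' @param thin retain every \code{thin}-th post-burn-in iteration
#'   (default 24).
#' @param prior_sd standard deviation of the Normal(0, sd^2) priors on
#'   alpha and beta.
#' @param init_scale initial random-walk proposal scale (tuned during
#'   burn-in toward ~30\% acceptance).
#' @param etpi_level equal-tail probability interval level, 0.95 or 0.99.
#' @param seed integer RNG seed.
#' @return an object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iterations = 100000, burn_in = 50000, thin = 24,
                        prior_sd = 1, init_scale = 0.3,
                        etpi_level = 0.95, seed = 1L) {
  if (burn_in >= n_iterations) stop("burn_in must be below n_iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (!etpi_level %in% c(0.95, 0.99)) stop("etpi_level must be 0.95 or 0.99")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_sd = prior_sd, init_scale = init_scale,
                 etpi_level = etpi_level, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Bayesian genomic clines by per-locus MCMC
#'
#' Fits the genomic-cline model (see \code{\link{cline_phi}}) at each locus
#' by independent random-walk Metropolis on (alpha, beta) with
#' Normal(0, \code{prior_sd}^2) priors, the hybrid index held fixed at its
#' point estimate. Outlier flags mark loci whose equal-tail probability
#' interval (ETPI) at the configured level excludes zero: positive
#' alpha-excess means excess parent-A ancestry relative to the genome-wide
#' expectation, negative alpha-excess the reverse; beta-excess marks
#' unusually steep (+) or shallow (-) ancestry transitions. Chains whose
#' post-burn-in acceptance rate falls outside \[0.15, 0.6\] are flagged for
#' convergence review.
#'
#' @param geno a \code{\link{geno_matrix}} restricted to the selected
#'   ancestry-informative loci.
#' @param h hybrid indexes of the admixed individuals (rows of \code{geno});
#'   must not be all 0 or all 1.
#' @param parental parental frequencies, one row per locus of \code{geno};
#'   loci monomorphic at the same frequency in both parents carry no cline
#'   information and are excluded.
#' @param config an \code{\link{mcmc_config}}.
#' @return data frame per locus: posterior means and ETPI bounds for alpha
#'   and beta, excess flags (\code{"+"}, \code{"-"}, \code{"0"}),
#'   \code{accept} rate, \code{flagged} convergence indicator,
#'   \code{differential}, and \code{excluded} for uninformative loci.
#' @export
bgc_fit <- function(geno, h, parental, config = mcmc_config()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "mcmc_config"))
  if (length(h) != nrow(geno$dosage)) stop("h must match individuals")
  if (any(is.na(h))) stop("h must be fully observed for the cline MCMC")
  if (all(h <= 0) || all(h >= 1)) {
    stop("no admixed individuals: clines are unidentifiable when h is all 0 or all 1")
  }
  if (nrow(parental) != ncol(geno$dosage)) stop("parental must match loci")
  L <- ncol(geno$dosage)
  # loci with identical parental frequencies carry no cline information
  excluded <- parental$p_a == parental$p_b
  run <- which(!excluded)
  out <- data.frame(
    alpha_mean = rep(NA_real_, L), alpha_lo = NA_real_, alpha_hi = NA_real_,
    beta_mean = NA_real_, beta_lo = NA_real_, beta_hi = NA_real_,
    alpha_excess = "0", beta_excess = "0", accept = NA_real_,
    flagged = FALSE, differential = abs(parental$p_a - parental$p_b),
    excluded = excluded, stringsAsFactors = FALSE
  )
  if (length(run) == 0) return(out)
  set.seed(config$seed)
  res <- cline_mcmc_cpp(t(geno$dosage[, run, drop = FALSE]), h,
                        parental$p_a[run], parental$p_b[run],
                        config$n_iterations, config$burn_in, config$thin,
                        config$prior_sd, config$init_scale, config$etpi_level)
  out$alpha_mean[run] <- res$alpha_mean
  out$alpha_lo[run] <- res$alpha_lo
  out$alpha_hi[run] <- res$alpha_hi
  out$beta_mean[run] <- res$beta_mean
  out$beta_lo[run] <- res$beta_lo
  out$beta_hi[run] <- res$beta_hi
  out$accept[run] <- res$accept
  out$alpha_excess[run] <- ifelse(res$alpha_lo > 0, "+",
                           ifelse(res$alpha_hi < 0, "-", "0"))
  out$beta_excess[run] <- ifelse(res$beta_lo > 0, "+",
                          ifelse(res$beta_hi < 0, "-", "0"))
  out$flagged[run] <- res$accept < 0.15 | res$accept > 0.6
  out
}

#' Logistic-regression genomic-cline test
#'
#' Per locus, allele dosage (binomial, two trials) is regressed on the
#' hybrid index with a logit link. The parametric p-value comes from the
#' 1-df likelihood-ratio test against the intercept-only model; the
#' permutation p-value is the add-one-corrected fraction of hybrid-index
#' shuffles whose statistic reaches the observed one.
#'
#' @param geno a \code{\link{geno_matrix}} on the selected loci.
#' @param h hybrid indexes.
#' @param n_permutations number of shuffles (0 skips the permutation test).
#' @param seed optional seed for the shuffles.
#' @return data frame per locus: \code{lrt}, \code{p_parametric},
#'   \code{p_permutation}, \code{converged}.
#' @export
logistic_cline_fit <- function(geno, h, n_permutations = 199, seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(h) != nrow(geno$dosage)) stop("h must match individuals")
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(geno$dosage)
  perms <- if (n_permutations > 0) {
    lapply(seq_len(n_permutations), function(i) sample(length(h)))
  } else list()
  lrt_of <- function(gg, hh) {
    f0 <- ridge_logit(matrix(1, length(gg), 1), gg)
    f1 <- ridge_logit(cbind(1, hh), gg)
    c(stat = max(0, 2 * (f1$loglik - f0$loglik)),
      conv = f0$converged && f1$converged)
  }
  out <- data.frame(lrt = rep(NA_real_, L), p_parametric = NA_real_,
                    p_permutation = NA_real_, converged = NA)
  for (l in seq_len(L)) {
    g <- geno$dosage[, l]
    ok <- !is.na(g) & !is.na(h)
    if (sum(ok) < 3) next
    gg <- g[ok]; hh <- h[ok]
    obs <- lrt_of(gg, hh)
    out$lrt[l] <- obs["stat"]
    out$converged[l] <- as.logical(obs["conv"])
    out$p_parametric[l] <- stats::pchisq(obs["stat"], 1, lower.tail = FALSE)
    if (n_permutations > 0) {
      idx <- which(ok)
      # permute h over all individuals, then restrict to called genotypes
      ge <- sum(vapply(perms, function(pm) {
        lrt_of(gg, h[pm][idx])["stat"] >= obs["stat"]
      }, TRUE))
      out$p_permutation[l] <- (1 + ge) / (n_permutations + 1)
    }
  }
  out
}

#' Downsample to target panel composition
#'
#' Draws a random subset matching target pure-A / pure-B / admixed counts,
#' preferentially removing individuals flagged as lying inside exclusion
#' regions before touching the rest.
#'
#' @param frame sample frame with a \code{panel} column (\code{pureA},
#'   \code{pureB}, \code{admixed}).
#' @param target_counts named vector or list with elements \code{pureA},
#'   \code{pureB}, \code{admixed}.
#' @param exclude logical vector marking individuals in exclusion regions
#'   (dropped first); default none.
#' @param seed optional seed.
#' @return the subset of \code{frame} (row order preserved).
#' @export
downsample_panels <- function(frame, target_counts, exclude = NULL, seed = NULL) {
  if (!"panel" %in% names(frame)) stop("frame needs a 'panel' column")
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(frame))
  if (!is.null(seed)) set.seed(seed)
  keep <- logical(nrow(frame))
  for (cls in c("pureA", "pureB", "admixed")) {
    k <- target_counts[[cls]]
    rows <- which(frame$panel == cls)
    if (is.null(k)) { keep[rows] <- TRUE; next }
    if (k > length(rows)) {
      stop("target for ", cls, " (", k, ") exceeds available (", length(rows), ")")
    }
    pref <- rows[!exclude[rows]]   # kept preferentially
    rest <- rows[exclude[rows]]
    chosen <- if (length(pref) >= k) {
      if (length(pref) == k) pref else sample(pref, k)
    } else {
      c(pref, if (k - length(pref) == length(rest)) rest
        else sample(rest, k - length(pref)))
    }
    keep[chosen] <- TRUE
  }
  frame[keep, , drop = FALSE]
}
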