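#' Genomic-cline ancestry probability
#'
#' Probability that an allele sampled from an individual with hybrid index
#' \code{h} descends from the parent-A gene pool at a locus with cline
#' parameters \code{alpha} (directional introgression) and \code{beta}
#' (cline steepness):
#' \deqn{\phi(h) = h + 2h(1-h)\,[\alpha + \beta(2h - 1)]}
#' truncated to \[0, 1\]. The boundary values are fixed points for all
#' finite parameters: \eqn{\phi(0) = 0} and \eqn{\phi(1) = 1}, so pure
#' parental individuals are unaffected by locus-specific distortions.
#'
#' @param h hybrid index in \[0, 1\] (proportion of parent-A ancestry);
#'   vectorised.
#' @param alpha cline centre parameter; positive values give excess parent-A
#'   ancestry relative to the genome-wide expectation.
#' @param beta cline rate parameter; positive values give a steeper-than-
#'   genome-wide ancestry transition.
#' @return numeric vector of ancestry probabilities in \[0, 1\].
#' @export
cline_phi <- function(h, alpha = 0, beta = 0) {
  stopifnot(is.numeric(h), is.numeric(alpha), is.numeric(beta))
  if (any(!is.finite(h)) || any(h < 0 | h > 1)) {
    stop("h must be finite and in [0, 1]")
  }
  phi <- h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1))
  pmin(pmax(phi, 0), 1)
}

#' Log-likelihood of allele dosages under the genomic-cline model
#'
#' At a locus with parental allele frequencies \code{p_a} and \code{p_b},
#' each of an individual's two alleles descends from pool A with probability
#' \code{cline_phi(h, alpha, beta)} and is then the counted allele with the
#' frequency of its pool of origin; the two alleles are treated as
#' independent ancestry draws, so the dosage is binomial with success
#' probability \eqn{q = \phi p_A + (1-\phi) p_B}.
#'
#' @param g integer dosages in \{0, 1, 2\}; \code{NA} entries are skipped.
#' @param h hybrid indexes, one per individual.
#' @param p_a,p_b parental allele frequencies at the locus.
#' @param alpha,beta cline parameters.
#' @param eps frequency clamp bound guarding \code{log(0)}.
#' @return scalar log-likelihood.
#' @export
cline_loglik <- function(g, h, p_a, p_b, alpha = 0, beta = 0, eps = 1e-4) {
  keep <- !is.na(g)
  g <- g[keep]
  h <- h[keep]
  phi <- cline_phi(h, alpha, beta)
  q <- phi * p_a + (1 - phi) * p_b
  q <- pmin(pmax(q, eps), 1 - eps)
  sum(stats::dbinom(g, 2, q, log = TRUE))
}
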