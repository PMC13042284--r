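# shared fixture builders: everything is generated in code at test time

# minimal geno_matrix from a dosage matrix
make_geno <- function(dosage, scaffold = NULL, pos = NULL, qual = 100,
                      gq = NULL, dp = NULL) {
  L <- ncol(dosage)
  if (is.null(scaffold)) scaffold <- rep("SC0001", L)
  if (is.null(pos)) pos <- seq_len(L)
  geno_matrix(dosage,
              data.frame(scaffold = scaffold, pos = pos,
                         ref = "A", alt = "C", qual = qual,
                         stringsAsFactors = FALSE),
              gq = gq, dp = dp)
}

# draw genotypes for n individuals at the given allele frequencies (HWE)
draw_pool <- function(n, freqs) {
  sapply(freqs, function(p) stats::rbinom(n, 2, p))
}

# genotypes under the genomic-cline model at fixed h and per-locus (alpha, beta)
draw_cline_geno <- function(h, parental, alpha = 0, beta = 0) {
  L <- nrow(parental)
  if (length(alpha) == 1) alpha <- rep(alpha, L)
  if (length(beta) == 1) beta <- rep(beta, L)
  dos <- sapply(seq_len(L), function(l) {
    phi <- cline_phi(h, alpha[l], beta[l])
    q <- phi * parental$p_a[l] + (1 - phi) * parental$p_b[l]
    stats::rbinom(length(h), 2, q)
  })
  make_geno(dos)
}
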