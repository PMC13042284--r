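# independent transcription of the 1984 variance-component formulas used as
# the brute-force oracle for small cases (counts in, components out)
oracle_wc <- function(n, p, het) {
  r <- length(n); nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * het) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

test_that("theta equals the hand-evaluated variance components on toy counts", {
  # pop1: 6 AA, 4 Aa (p = 0.8, het = 0.4); pop2: 4 Aa, 6 aa (p = 0.2, het = 0.4)
  dos <- c(rep(2L, 6), rep(1L, 4), rep(1L, 4), rep(0L, 6))
  g <- make_geno(matrix(dos, 20, 1))
  f <- wc_fst(g, rep(c("p1", "p2"), each = 10))
  # frozen hand evaluation: a = 26/150, b = -1/30, c = 1/5, theta = 26/51
  expect_equal(f$a, 26 / 150, tolerance = 1e-12)
  expect_equal(f$b, -1 / 30, tolerance = 1e-12)
  expect_equal(f$c, 0.2, tolerance = 1e-12)
  expect_equal(f$fst, 26 / 51, tolerance = 1e-12)
  expect_equal(unname(oracle_wc(c(10, 10), c(0.8, 0.2), c(0.4, 0.4))["theta"]),
               f$fst, tolerance = 1e-12)
})

test_that("theta is 1 at fixed alternative alleles and near 0 under identity", {
  g <- make_geno(matrix(c(rep(2L, 20), rep(0L, 20)), 40, 1))
  expect_equal(wc_fst(g, rep(c("A", "B"), each = 20))$fst, 1)
  set.seed(61)
  g2 <- make_geno(sapply(1:200, function(i) rbinom(400, 2, 0.5)),
                  pos = 1:200)
  f2 <- wc_fst(g2, rep(c("A", "B"), each = 200))
  expect_lt(abs(mean(f2$fst, na.rm = TRUE)), 0.01)
})

test_that("multipop estimator matches the oracle for 3 small populations", {
  set.seed(62)
  for (rep_i in 1:5) {
    dos <- matrix(sample(0:2, 18, replace = TRUE), 18, 1)
    labels <- rep(c("x", "y", "z"), each = 6)
    g <- make_geno(dos)
    f <- wc_fst(g, labels)
    n <- tapply(dos[, 1], labels, length)
    p <- tapply(dos[, 1], labels, function(v) mean(v) / 2)
    het <- tapply(dos[, 1], labels, function(v) mean(v == 1))
    ref <- oracle_wc(as.numeric(n), as.numeric(p), as.numeric(het))
    if (is.finite(ref["theta"])) {
      expect_equal(f$fst, unname(ref["theta"]), tolerance = 1e-12)
    }
  }
})

test_that("mean-pairwise mode equals multipop mode with two populations", {
  set.seed(63)
  g <- make_geno(sapply(1:50, function(i) rbinom(24, 2, runif(1, 0.2, 0.8))),
                 pos = 1:50)
  lab <- rep(c("A", "B"), each = 12)
  m1 <- wc_fst(g, lab, mode = "multipop")
  m2 <- wc_fst(g, lab, mode = "mean_pairwise")
  expect_equal(m1$fst, m2$fst, tolerance = 1e-12)
})

test_that("theta is invariant to swapping allele labels at a site", {
  set.seed(64)
  dos <- matrix(sample(0:2, 30, replace = TRUE), 30, 1)
  lab <- rep(c("A", "B", "C"), each = 10)
  f1 <- wc_fst(make_geno(dos), lab)$fst
  f2 <- wc_fst(make_geno(2L - dos), lab)$fst
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("sites without data in enough populations are undefined, not zero", {
  dos <- matrix(c(1L, 1L, NA, NA), 4, 1)
  f <- wc_fst(make_geno(dos), c("A", "A", "B", "B"))
  expect_true(is.na(f$fst))
  expect_equal(f$n_pops, 1L)
})

test_that("species-level FST recovers the simulated divergence parameter", {
  # ratio-of-sums multi-locus estimator: the per-site ratio mean is Jensen-
  # biased downward at high divergence, the genome-wide form is not
  for (F in c(0.07, 0.14, 0.3)) {
    par <- simulate_parental_freqs(4000, F, seed = round(1000 * F))
    set.seed(round(1000 * F) + 1)
    g <- make_geno(rbind(draw_pool(60, par$p_a), draw_pool(60, par$p_b)),
                   pos = seq_len(4000))
    panel <- rep(c("pureA", "pureB"), each = 60)
    res <- species_fst(g, panel)
    expect_lt(abs(res$summary[["global"]] - F), 0.03)
  }
})

test_that("identical panels give near-zero species FST and empty panels error", {
  set.seed(65)
  g <- make_geno(sapply(1:100, function(i) rbinom(40, 2, 0.5)), pos = 1:100)
  dup <- make_geno(rbind(g$dosage, g$dosage), pos = g$loci$pos)
  res <- species_fst(dup, rep(c("pureA", "pureB"), each = 40))
  expect_lt(abs(res$summary[["mean"]]), 0.02)
  expect_error(species_fst(g, rep("pureA", 40)), "non-empty")
})

test_that("pi and dxy match brute-force pair enumeration", {
  # brute-force oracle: enumerate all allele pairs explicitly
  brute <- function(ga, gb) {
    alleles <- function(g) unlist(lapply(g[!is.na(g)], function(d) c(rep(1, d), rep(0, 2 - d))))
    aa <- alleles(ga); ab <- alleles(gb)
    pi_of <- function(al) {
      prs <- utils::combn(length(al), 2)
      mean(al[prs[1, ]] != al[prs[2, ]])
    }
    dxy <- mean(outer(aa, ab, "!="))
    c(pi_a = pi_of(aa), pi_b = pi_of(ab), dxy = dxy)
  }
  set.seed(66)
  for (i in 1:5) {
    ga <- sample(c(0:2, NA), 6, replace = TRUE)
    gb <- sample(0:2, 6, replace = TRUE)
    if (sum(!is.na(ga)) < 2) next
    g <- make_geno(matrix(c(ga, gb), ncol = 1))
    res <- pi_dxy(g, 1:6, 7:12)
    ref <- brute(ga, gb)
    expect_equal(res$pi_a, unname(ref["pi_a"]), tolerance = 1e-12)
    expect_equal(res$pi_b, unname(ref["pi_b"]), tolerance = 1e-12)
    expect_equal(res$dxy, unname(ref["dxy"]), tolerance = 1e-12)
  }
})

test_that("pi/dxy boundary cases and symmetry hold", {
  g <- make_geno(matrix(0L, 8, 1))
  res <- pi_dxy(g, 1:4, 5:8)
  expect_equal(unlist(res[c("pi_a", "pi_b", "dxy")], use.names = FALSE), c(0, 0, 0))
  g2 <- make_geno(matrix(c(rep(2L, 4), rep(0L, 4)), 8, 1))
  res2 <- pi_dxy(g2, 1:4, 5:8)
  expect_equal(res2$dxy, 1)
  expect_equal(res2$pi_a, 0)
  # symmetry in the two groups
  set.seed(67)
  g3 <- make_geno(matrix(sample(0:2, 12, TRUE), 12, 1))
  expect_equal(pi_dxy(g3, 1:6, 7:12)$dxy, pi_dxy(g3, 7:12, 1:6)$dxy)
  expect_error(pi_dxy(g3, 1:6, 5:8), "disjoint")
})

test_that("divergence summaries report central tendency and polymorphism fractions", {
  s <- summarize_divergence(data.frame(fst = 0.5))
  expect_equal(s$fst_mean, 0.5)
  expect_equal(s$fst_median, 0.5)
  expect_equal(s$fst_sd, 0)
  par <- simulate_parental_freqs(3000, 0.07, seed = 68)
  set.seed(69)
  g <- make_geno(rbind(draw_pool(80, par$p_a), draw_pool(80, par$p_b)),
                 pos = seq_len(3000))
  panel <- rep(c("pureA", "pureB"), each = 80)
  res <- species_fst(g, panel)
  s2 <- summarize_divergence(res$sites, g, panel)
  expect_lt(abs(s2$fst_global - 0.07), 0.02)
  expect_gt(s2$polymorphic_pureA, 0.8)
  g_fixed <- make_geno(matrix(rep(c(2L, 0L), each = 4), 8, 1))
  s3 <- summarize_divergence(data.frame(fst = 1), g_fixed,
                             rep(c("pureA", "pureB"), each = 4))
  expect_equal(s3$polymorphic_pureA, 0)
})
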