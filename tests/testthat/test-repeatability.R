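test_that("scan intersection is an inner join with duplicate detection", {
  a <- data.frame(scaffold = "S1", pos = 1:8, stat = rnorm(8))
  b <- data.frame(scaffold = "S1", pos = 4:10, stat = rnorm(7))
  sh <- intersect_scans(a, b)
  expect_equal(sort(sh$pos), 4:8)
  expect_true(all(c("stat_a", "stat_b") %in% names(sh)))
  expect_equal(nrow(intersect_scans(a, data.frame(scaffold = "S2", pos = 1:3, stat = 1:3))), 0)
  expect_equal(nrow(intersect_scans(a, a)), nrow(a))
  expect_error(intersect_scans(rbind(a, a[1, ]), b), "duplicate")
  # planted 5-of-8/7 fixture: exactly the planted keys survive
  a2 <- data.frame(scaffold = rep(c("S1", "S2"), c(5, 3)), pos = c(1:5, 1:3), stat = 1)
  b2 <- data.frame(scaffold = rep(c("S1", "S3"), c(5, 2)), pos = c(1:5, 1:2), stat = 2)
  sh2 <- intersect_scans(a2, b2)
  expect_equal(nrow(sh2), 5)
  expect_setequal(sh2$pos[sh2$scaffold == "S1"], 1:5)
})

test_that("scan correlations report both coefficients and flag non-independence", {
  x <- seq(-2, 2, length.out = 50)
  r <- scan_correlations(x, x)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$kendall_tau, 1)
  expect_true(r$p_values_overestimated)
  set.seed(101)
  r0 <- scan_correlations(rnorm(3000), rnorm(3000))
  expect_lt(abs(r0$pearson_r), 0.05)
  expect_warning(scan_correlations(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(scan_correlations(1:2, 1:2), "3 defined")
})

test_that("Moran's I matches a brute-force double loop with inverse-distance weights", {
  brute_moran <- function(x, pos) {
    n <- length(x); z <- x - mean(x)
    num <- 0; wsum <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      w <- 1 / abs(pos[i] - pos[j])
      num <- num + w * z[i] * z[j]
      wsum <- wsum + w
    }
    (n / wsum) * num / sum(z^2)
  }
  x <- c(1, 1, 1, -1, -1, -1)
  expect_equal(morans_i(x, 1:6), brute_moran(x, 1:6), tolerance = 1e-12)
  set.seed(102)
  for (i in 1:5) {
    v <- rnorm(12); p <- sample(100, 12)
    expect_equal(morans_i(v, p), brute_moran(v, p), tolerance = 1e-12)
  }
})

test_that("Moran's I has the known null expectation and detects blockiness", {
  set.seed(103)
  blocky <- rep(c(2, -2), each = 25) + rnorm(50, 0, 0.3)
  i_obs <- morans_i(blocky, 1:50)
  shuffled <- replicate(200, morans_i(sample(blocky), 1:50))
  expect_lt(abs(mean(shuffled) - (-1 / 49)), 0.02)
  expect_gt(mean(i_obs > shuffled), 0.95)
})

test_that("Moran's I is invariant to location and positive scale changes", {
  set.seed(104)
  x <- rnorm(30); p <- 1:30
  i0 <- morans_i(x, p)
  expect_equal(morans_i(x + 100, p), i0, tolerance = 1e-12)
  expect_equal(morans_i(3 * x, p), i0, tolerance = 1e-12)
  expect_warning(expect_true(is.na(morans_i(rep(1, 10), 1:10))), "zero variance")
})

test_that("blockiness comparison reproduces a textbook paired t-test", {
  set.seed(105)
  units <- sprintf("U%02d", 1:12)
  shared <- do.call(rbind, lapply(units, function(u) {
    data.frame(scaffold = u, ordinal = 1:20,
               stat_a = rep(c(1, -1), each = 10) + rnorm(20, 0, 0.8),
               stat_b = rnorm(20))
  }))
  cb <- compare_blockiness(shared, "stat_a", "stat_b", unit = "scaffold",
                           ordinal = "ordinal")
  ref <- t.test(cb$per_unit$i_a, cb$per_unit$i_b, paired = TRUE)
  expect_equal(cb$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cb$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(cb$mean_diff, mean(cb$per_unit$i_a - cb$per_unit$i_b))
  # identical scans: zero differences, undefined t-test
  same <- shared; same$stat_b <- same$stat_a
  cb2 <- compare_blockiness(same, "stat_a", "stat_b", unit = "scaffold",
                            ordinal = "ordinal")
  expect_equal(cb2$mean_diff, 0)
  expect_true(is.na(cb2$p_value))
  expect_error(compare_blockiness(shared[shared$scaffold %in% units[1:2], ],
                                  "stat_a", "stat_b", unit = "scaffold",
                                  ordinal = "ordinal"), "3 paired")
})

test_that("SNPs map to genes through 5 kb flanks with boundary precision", {
  genes <- data.frame(scaffold = "S1", start = 10000, end = 12000,
                      gene_id = "g1")
  snps <- data.frame(scaffold = "S1",
                     pos = c(10000 - 4999, 10000 - 5000, 10000 - 5001,
                             11000, 12000 + 5000, 12000 + 5001))
  hits <- genes_for_snps(snps, genes, flank = 5000)
  expect_setequal(hits$pos, c(5001, 5000, 11000, 17000))
  # overlapping flanked genes: SNP assigned to both
  genes2 <- rbind(genes, data.frame(scaffold = "S1", start = 13000, end = 14000,
                                    gene_id = "g2"))
  both <- genes_for_snps(data.frame(scaffold = "S1", pos = 12500), genes2)
  expect_setequal(both$gene_id, c("g1", "g2"))
  expect_error(genes_for_snps(snps, data.frame(scaffold = "S1", start = 10,
                                               end = 5, gene_id = "bad")),
               "malformed")
})

test_that("gene mapping reads BED intervals (0-based half-open)", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("S1\t999\t2000\tgeneX", bed)   # 1-based 1000..2000
  hits <- genes_for_snps(data.frame(scaffold = "S1",
                                    pos = c(1000, 2000, 7000, 7001)),
                         bed, flank = 5000)
  expect_setequal(hits$pos[hits$gene_id == "geneX"], c(1000, 2000, 7000))
  expect_false(7001 %in% hits$pos)
})

test_that("overlap enrichment: exact expectation and hypergeometric agreement", {
  uni <- sprintf("g%03d", 1:100)
  sets <- list(uni, uni)
  full <- overlap_enrichment(sets, uni, n_permutations = 50)
  expect_equal(full$observed, 100)
  expect_equal(full$expected, 100)
  expect_equal(full$p_value, 1)

  a <- uni[1:10]
  res <- overlap_enrichment(list(a, a), uni, n_permutations = 2000, seed = 106)
  expect_equal(res$expected, 1.0)
  expect_equal(res$observed, 10)
  # hypergeometric tail P(X >= 10) is ~6e-14: no permutation can reach it
  expect_equal(res$p_value, 1 / 2001)

  # moderate-overlap case against the closed form
  set.seed(107)
  b <- uni[6:15]
  obs <- length(intersect(a, b))          # 5
  res2 <- overlap_enrichment(list(a, b), uni, n_permutations = 4000, seed = 108)
  p_exact <- phyper(obs - 1, 10, 90, 10, lower.tail = FALSE)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res2$p_value - p_exact), mc_err + 1e-3)
})

test_that("k=4 enrichment matches an exact Markov-chain enumeration oracle", {
  # exact distribution of the running-intersection size: each new uniform
  # k-subset intersects the current intersection hypergeometrically
  exact_tail <- function(N, sizes, t) {
    v <- numeric(sizes[1] + 1)
    v[sizes[1] + 1] <- 1       # start: |I| = k1 with probability 1
    for (k in sizes[-1]) {
      nv <- numeric(length(v))
      for (m in which(v > 0) - 1) {
        mm <- 0:min(m, k)
        nv[mm + 1] <- nv[mm + 1] + v[m + 1] * dhyper(mm, m, N - m, k)
      }
      v <- nv
    }
    sum(v[(t + 1):length(v)])
  }
  uni <- sprintf("g%02d", 1:20)
  sets <- list(uni[1:5], uni[c(1, 2, 6, 7, 8)], uni[c(1, 2, 9, 10, 11)],
               uni[c(1, 12, 13, 14, 15)])
  res <- overlap_enrichment(sets, uni, n_permutations = 4000, seed = 109)
  expect_equal(res$observed, 1)
  expect_equal(res$expected, 20 * (5 / 20)^4)
  p_exact <- exact_tail(20, rep(5, 4), 1)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), mc_err + 1e-3)
  expect_error(overlap_enrichment(list(uni[1:5], "zzz"), uni), "subsets")
})
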