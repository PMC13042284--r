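#' Intersect two per-SNP scans
#'
#' Inner join of two scan tables keyed by (scaffold, position). Duplicate
#' keys in either input are an error; statistic columns get \code{_a} /
#' \code{_b} suffixes.
#'
#' @param a,b data frames with \code{scaffold} and \code{pos} columns plus
#'   statistic columns.
#' @return the joined data frame (possibly empty).
#' @export
intersect_scans <- function(a, b) {
  key_a <- paste(a$scaffold, a$pos)
  key_b <- paste(b$scaffold, b$pos)
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("duplicate (scaffold, pos) keys in input")
  }
  merge(a, b, by = c("scaffold", "pos"), suffixes = c("_a", "_b"))
}

#' Correlation of a scan statistic across datasets
#'
#' Pearson's r and Kendall's tau over loci where the statistic is defined in
#' both datasets. The p-values are reported but flagged: linked SNPs are not
#' independent observations, so their nominal significance is overestimated.
#'
#' @param x,y paired statistic vectors.
#' @return list with \code{pearson_r}, \code{kendall_tau}, their nominal
#'   p-values, \code{n}, and \code{p_values_overestimated = TRUE}.
#' @export
scan_correlations <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 defined pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(pearson_r = NA_real_, kendall_tau = NA_real_,
                p_pearson = NA_real_, p_kendall = NA_real_, n = sum(ok),
                p_values_overestimated = TRUE))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  ke <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(pearson_r = unname(pe$estimate), kendall_tau = unname(ke$estimate),
       p_pearson = pe$p.value, p_kendall = ke$p.value, n = length(x),
       p_values_overestimated = TRUE)
}

#' Moran's I on ordinal positions
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2}}
#' with inverse-distance weights \eqn{w_{ij} = 1/|pos_i - pos_j|}
#' (\eqn{w_{ii} = 0}). Applied to statistics at ordinal SNP positions it
#' measures the "blockiness" of a genome scan: how long similar values
#' persist along a scaffold or linkage group. Under random arrangement its
#' expectation is \eqn{-1/(n-1)}.
#'
#' @param x statistic values.
#' @param pos positions (ordinal indices); ties in \code{pos} are not
#'   allowed.
#' @return Moran's I, or \code{NA} with a warning if the values have zero
#'   variance.
#' @export
morans_i <- function(x, pos) {
  ok <- is.finite(x) & is.finite(pos)
  x <- x[ok]; pos <- pos[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  if (anyDuplicated(pos)) stop("positions must be distinct")
  if (stats::var(x) == 0) {
    warning("zero variance; Moran's I undefined")
    return(NA_real_)
  }
  d <- abs(outer(pos, pos, "-"))
  w <- ifelse(d > 0, 1 / d, 0)
  z <- x - mean(x)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}

#' Paired comparison of chromosomal autocorrelation between datasets
#'
#' Computes per-unit (scaffold or linkage group) Moran's I of a scan
#' statistic in each of two datasets on their shared SNPs, then a paired
#' t-test across units, reporting the mean and median difference (dataset A
#' minus dataset B).
#'
#' @param shared joined scan from \code{\link{intersect_scans}} with
#'   statistic columns \code{stat_a} and \code{stat_b}, a unit column, and
#'   an ordinal position column.
#' @param stat_a,stat_b names of the two statistic columns.
#' @param unit name of the grouping column (e.g. \code{"scaffold"} or
#'   \code{"lg"}).
#' @param ordinal name of the ordinal position column.
#' @param min_loci_per_unit units with fewer shared loci are excluded.
#' @param alternative t-test sidedness (default two-sided).
#' @return list with the per-unit table, \code{mean_diff},
#'   \code{median_diff}, \code{t_statistic}, \code{p_value}, \code{n_units}.
#' @export
compare_blockiness <- function(shared, stat_a, stat_b, unit = "scaffold",
                               ordinal = "ordinal", min_loci_per_unit = 10,
                               alternative = "two.sided") {
  units <- split(shared, shared[[unit]])
  rows <- lapply(units, function(d) {
    if (nrow(d) < min_loci_per_unit) return(NULL)
    ia <- tryCatch(morans_i(d[[stat_a]], d[[ordinal]]), warning = function(w) NA_real_)
    ib <- tryCatch(morans_i(d[[stat_b]], d[[ordinal]]), warning = function(w) NA_real_)
    data.frame(unit = d[[unit]][1], n_loci = nrow(d), i_a = ia, i_b = ib)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || sum(stats::complete.cases(tab)) < 3) {
    stop("need at least 3 paired units with defined Moran's I")
  }
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  diff <- tab$i_a - tab$i_b
  tt <- if (stats::sd(diff) == 0) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    stats::t.test(tab$i_a, tab$i_b, paired = TRUE, alternative = alternative)
  }
  list(per_unit = tab, mean_diff = mean(diff), median_diff = stats::median(diff),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_units = nrow(tab))
}

#' Map SNPs to flanked gene intervals
#'
#' Assigns each SNP to every gene whose interval, extended by \code{flank}
#' bp on either side, contains it. Gene intervals come from a BED file
#' (0-based half-open) or GFF3 (1-based closed), read with
#' \pkg{rtracklayer}, or from a data frame with 1-based closed
#' \code{start}/\code{end} columns.
#'
#' @param snps data frame with \code{scaffold} and \code{pos} (1-based).
#' @param genes a path to a BED/GFF3 file, a \code{GRanges}, or a data frame
#'   with \code{scaffold}, \code{start}, \code{end}, \code{gene_id}.
#' @param flank flank size in bp (default 5000).
#' @return data frame with one row per (SNP, gene) assignment:
#'   \code{scaffold}, \code{pos}, \code{gene_id}.
#' @export
genes_for_snps <- function(snps, genes, flank = 5000) {
  if (is.character(genes)) {
    gr <- rtracklayer::import(genes)
    ids <- if (!is.null(gr$name)) gr$name
           else if (!is.null(gr$ID)) gr$ID
           else paste0("gene", seq_along(gr))
  } else if (inherits(genes, "GRanges")) {
    gr <- genes
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  } else {
    if (any(genes$end < genes$start)) {
      stop("malformed interval at line ",
           paste(which(genes$end < genes$start), collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(genes$scaffold,
                                 IRanges::IRanges(genes$start, genes$end))
    ids <- genes$gene_id
  }
  flanked <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2 * flank,
                                   fix = "center")
  flanked <- GenomicRanges::trim(flanked)
  snp_gr <- GenomicRanges::GRanges(snps$scaffold,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, flanked, ignore.strand = TRUE)
  data.frame(scaffold = snps$scaffold[S4Vectors::queryHits(hits)],
             pos = snps$pos[S4Vectors::queryHits(hits)],
             gene_id = ids[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Multi-set overlap enrichment by permutation
#'
#' For k gene sets drawn from a universe of size N, the expected size of
#' the k-way intersection under independence is \eqn{N \prod_i (k_i / N)}.
#' The permutation p-value redraws each set uniformly without replacement
#' from the universe and applies the add-one correction; for k = 2 it
#' converges to the hypergeometric upper tail.
#'
#' @param sets list of character vectors (gene ids), each a subset of the
#'   universe.
#' @param universe character vector of all eligible genes.
#' @param n_permutations number of permutations.
#' @param seed optional seed.
#' @return list: \code{observed}, \code{expected}, \code{p_value},
#'   \code{set_sizes}, \code{universe_size}.
#' @export
overlap_enrichment <- function(sets, universe, n_permutations = 10000,
                               seed = NULL) {
  if (length(sets) < 2) stop("need at least 2 sets")
  N <- length(unique(universe))
  sizes <- vapply(sets, function(s) length(unique(s)), 0L)
  if (any(sizes > N)) stop("a set is larger than the universe")
  bad <- vapply(sets, function(s) !all(s %in% universe), TRUE)
  if (any(bad)) stop("all sets must be subsets of the universe")
  observed <- length(Reduce(intersect, sets))
  expected <- N * prod(sizes / N)
  if (!is.null(seed)) set.seed(seed)
  uni <- unique(universe)
  ge <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- lapply(sizes, function(k) sample(uni, k))
    if (length(Reduce(intersect, perm)) >= observed) ge <- ge + 1L
  }
  list(observed = observed, expected = expected,
       p_value = (1 + ge) / (n_permutations + 1),
       set_sizes = sizes, universe_size = N)
}
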