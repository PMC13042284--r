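#' Genotype matrix container
#'
#' Holds an individuals x loci allele-dosage matrix (0/1/2, \code{NA} for
#' missing) together with the locus map and optional per-call genotype
#' quality (GQ) and read depth (DP) matrices. Loci are kept sorted by
#' (scaffold, position).
#'
#' @param dosage integer matrix, individuals in rows, loci in columns.
#' @param loci data frame with at least \code{scaffold}, \code{pos} (1-based,
#'   as in VCF), \code{ref}, \code{alt}; optional \code{id}, \code{qual},
#'   \code{lg}.
#' @param samples character vector of sample ids (defaults to row names).
#' @param gq,dp optional matrices of the same dimension as \code{dosage}.
#' @return an object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(dosage, loci, samples = rownames(dosage),
                        gq = NULL, dp = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(loci) != ncol(dosage)) stop("loci rows must match dosage columns")
  if (!all(c("scaffold", "pos", "ref", "alt") %in% names(loci))) {
    stop("loci needs columns scaffold, pos, ref, alt")
  }
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(samples)) samples <- sprintf("ind%04d", seq_len(nrow(dosage)))
  if (is.null(loci$id)) loci$id <- sprintf("snp%05d", seq_len(nrow(loci)))
  if (is.null(loci$qual)) loci$qual <- NA_real_
  ord <- order(loci$scaffold, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- NULL
  if (!is.null(gq)) {
    gq <- as.matrix(gq)[, ord, drop = FALSE]
    dimnames(gq) <- NULL
  }
  if (!is.null(dp)) {
    dp <- as.matrix(dp)[, ord, drop = FALSE]
    dimnames(dp) <- NULL
  }
  structure(list(dosage = dosage, loci = loci, samples = as.character(samples),
                 gq = gq, dp = dp),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d loci on %d scaffolds\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$loci$scaffold))))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Write a genotype matrix as VCF v4.2
#'
#' Emits biallelic records with GT:GQ:DP sample fields (GQ/DP omitted when
#' absent from the object). Missing dosages are written as \code{./.}.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param path output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  loci <- geno$loci
  n <- nrow(geno$dosage)
  has_fmt <- !is.null(geno$gq) && !is.null(geno$dp)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybzone",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_fmt) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    if (has_fmt) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- vapply(seq_len(nrow(loci)), function(l) {
    g <- geno$dosage[, l]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    field <- if (has_fmt) {
      paste(gt, geno$gq[, l], geno$dp[, l], sep = ":")
    } else gt
    qual <- if (is.na(loci$qual[l])) "." else format(loci$qual[l])
    paste(c(loci$scaffold[l], loci$pos[l], loci$id[l], loci$ref[l],
            loci$alt[l], qual, "PASS", ".",
            if (has_fmt) "GT:GQ:DP" else "GT", field), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) into a \code{\link{geno_matrix}}.
#' Only biallelic SNP records are accepted; multiallelic records raise an
#' error naming the offending positions. Genotypes \code{./.} become missing
#' dosages; per-call GQ and DP are carried along when present.
#'
#' @param path VCF file path.
#' @return a \code{\link{geno_matrix}}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("multiallelic records at: ",
         paste(paste0(fix$CHROM[multi], ":", fix$POS[multi]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_count <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    out[ok] <- vapply(strsplit(x[ok], "[/|]"), function(a) sum(a == "1"), 0L)
    out
  }
  dosage <- t(matrix(allele_count(as.vector(gt)), nrow = nrow(gt),
                     dimnames = dimnames(gt)))
  fmt <- if (is.null(v@gt)) character() else strsplit(v@gt[1, "FORMAT"], ":")[[1]]
  get_num <- function(el) {
    if (!el %in% fmt) return(NULL)
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    t(m)
  }
  loci <- data.frame(
    scaffold = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    stringsAsFactors = FALSE
  )
  geno_matrix(dosage, loci, samples = colnames(gt),
              gq = get_num("GQ"), dp = get_num("DP"))
}

#' Apply the standard site filters
#'
#' Per-call GQ/DP masking is applied first (a call with GQ below
#' \code{min_gq} or DP below \code{min_dp} becomes missing), then sites are
#' dropped unless they are genotyped in at least \code{min_call_rate} of the
#' individuals, have QUAL of at least \code{min_qual}, and minor allele
#' frequency strictly above \code{min_maf}. With \code{anchored_only}, sites
#' on scaffolds absent from the super-scaffold assembly are also dropped.
#' Filtering is idempotent: a second pass with the same thresholds is a
#' no-op.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param min_call_rate minimum fraction of called genotypes per site.
#' @param min_qual minimum site QUAL (sites with missing QUAL are kept).
#' @param min_gq,min_dp per-call thresholds; calls below them are masked.
#'   DP uses minimum-depth semantics (calls with DP >= \code{min_dp} kept);
#'   set \code{dp_strict = TRUE} for strictly-greater semantics.
#' @param min_maf minor-allele-frequency threshold (strict: a site at
#'   exactly \code{min_maf} is dropped).
#' @param anchored_only restrict to anchored scaffolds.
#' @param anchors a \code{super_scaffold} (required if \code{anchored_only}).
#' @param dp_strict see \code{min_dp}.
#' @return the filtered \code{\link{geno_matrix}} (possibly with zero loci,
#'   with a warning).
#' @export
filter_sites <- function(geno, min_call_rate = 0.7, min_qual = 30,
                         min_gq = 20, min_dp = 5, min_maf = 0.05,
                         anchored_only = FALSE, anchors = NULL,
                         dp_strict = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  dosage <- geno$dosage
  if (!is.null(geno$gq)) dosage[geno$gq < min_gq] <- NA_integer_
  if (!is.null(geno$dp)) {
    mask <- if (dp_strict) geno$dp <= min_dp else geno$dp < min_dp
    dosage[mask] <- NA_integer_
  }
  call_rate <- colMeans(!is.na(dosage))
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  qual_ok <- is.na(geno$loci$qual) | geno$loci$qual >= min_qual
  keep <- call_rate >= min_call_rate & qual_ok & maf > min_maf
  if (anchored_only) {
    if (is.null(anchors)) stop("anchored_only requires anchors")
    keep <- keep & geno$loci$scaffold %in% anchors$scaffolds$scaffold
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no sites pass the filters")
  geno_matrix(dosage[, keep, drop = FALSE],
              geno$loci[keep, , drop = FALSE],
              samples = geno$samples,
              gq = if (is.null(geno$gq)) NULL else geno$gq[, keep, drop = FALSE],
              dp = if (is.null(geno$dp)) NULL else geno$dp[, keep, drop = FALSE])
}
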