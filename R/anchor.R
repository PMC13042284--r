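#' Anchor genome scaffolds onto a linkage map
#'
#' Builds a super-scaffold assembly from a cDNA-to-scaffold alignment
#' summary and a centimorgan linkage map. Per cDNA: alignment rows with
#' coverage at or below \code{min_coverage} or identity at or below
#' \code{min_identity} are dropped; among the survivors the single best
#' scaffold by highest identity is kept, and a cDNA whose best identity is
#' tied across different scaffolds is discarded as unresolvable
#' multimapping. Retained cDNAs are restricted to those present in the
#' linkage map; each scaffold is anchored at the linkage group of its
#' cDNA(s) and at the median of their centimorgan positions (a scaffold
#' whose cDNAs disagree on the linkage group is discarded with a warning).
#' Scaffolds are ordered within each linkage group by anchor cM, ties broken
#' by scaffold id.
#'
#' Coverage/identity units are auto-detected: values above 1 are read as
#' percentages.
#'
#' @param alignments data frame with \code{cdna_id}, \code{scaffold},
#'   \code{coverage}, \code{identity} (fractions or percent).
#' @param linkage_map data frame with \code{cdna_id}, \code{lg}, \code{cm}.
#' @param scaffold_lengths data frame with \code{scaffold}, \code{length}.
#' @param min_coverage,min_identity retention thresholds (strictly above).
#' @return an object of class \code{super_scaffold}: a list with
#'   \code{scaffolds} (scaffold, lg, cm, length, order within LG, global
#'   order), the total \code{span_bp}, and a \code{report} of counts at each
#'   anchoring step.
#' @export
anchor_scaffolds <- function(alignments, linkage_map, scaffold_lengths,
                             min_coverage = 0.50, min_identity = 0.90) {
  need <- c("cdna_id", "scaffold", "coverage", "identity")
  if (!all(need %in% names(alignments))) {
    stop("alignments needs columns: ", paste(need, collapse = ", "))
  }
  al <- alignments
  # unit auto-detection: percent dialect if anything exceeds 1
  if (any(al$coverage > 1, na.rm = TRUE)) al$coverage <- al$coverage / 100
  if (any(al$identity > 1, na.rm = TRUE)) al$identity <- al$identity / 100

  al <- al[al$coverage > min_coverage & al$identity > min_identity, , drop = FALSE]
  n_pass <- length(unique(al$cdna_id))

  # best scaffold per cDNA by highest identity; exact ties across scaffolds
  # are unresolvable multimapping and the cDNA is discarded
  best <- do.call(rbind, lapply(split(al, al$cdna_id), function(d) {
    top <- d[d$identity == max(d$identity), , drop = FALSE]
    if (length(unique(top$scaffold)) > 1) return(NULL)
    top[1, , drop = FALSE]
  }))
  n_tied <- n_pass - if (is.null(best)) 0L else nrow(best)
  if (is.null(best) || nrow(best) == 0) stop("no cDNA passed the anchoring filters")

  mapped <- merge(best, linkage_map, by = "cdna_id")
  n_unmapped <- nrow(best) - nrow(mapped)

  anchors <- do.call(rbind, lapply(split(mapped, mapped$scaffold), function(d) {
    if (length(unique(d$lg)) > 1) {
      warning("scaffold ", d$scaffold[1],
              " has conflicting linkage-group assignments; discarded")
      return(NULL)
    }
    data.frame(scaffold = d$scaffold[1], lg = d$lg[1],
               cm = stats::median(d$cm), n_cdna = nrow(d),
               stringsAsFactors = FALSE)
  }))
  if (is.null(anchors) || nrow(anchors) == 0) stop("no scaffold could be anchored")
  anchors <- merge(anchors, scaffold_lengths, by = "scaffold")
  anchors <- anchors[order(anchors$lg, anchors$cm, anchors$scaffold), , drop = FALSE]
  anchors$order_in_lg <- stats::ave(seq_len(nrow(anchors)), anchors$lg,
                                    FUN = seq_along)
  anchors$order <- seq_len(nrow(anchors))
  rownames(anchors) <- NULL

  structure(list(
    scaffolds = anchors,
    span_bp = sum(as.numeric(anchors$length)),
    report = c(cdna_pass_filters = n_pass, cdna_tied = n_tied,
               cdna_not_in_map = n_unmapped, scaffolds_anchored = nrow(anchors))
  ), class = "super_scaffold")
}

#' @export
print.super_scaffold <- function(x, ...) {
  cat(sprintf("super_scaffold: %d scaffolds on %d linkage groups, span %.0f bp\n",
              nrow(x$scaffolds), length(unique(x$scaffolds$lg)), x$span_bp))
  invisible(x)
}

#' Write a super-scaffold assembly as TSV
#'
#' @param anchors a \code{super_scaffold}.
#' @param path output path.
#' @export
write_super_scaffold <- function(anchors, path) {
  utils::write.table(anchors$scaffolds[, c("scaffold", "lg", "order_in_lg",
                                           "cm", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ordinal SNP positions along scaffolds and linkage groups
#'
#' Assigns each locus a sequential index (1, 2, 3, ...) within its scaffold
#' by position, and within its linkage group by (anchored scaffold order,
#' position). These ordinal positions treat SNPs as equally spaced and are
#' the coordinates used for chromosomal autocorrelation, which sidesteps
#' unknown inter-scaffold gap sizes in fragmented assemblies.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param anchors a \code{super_scaffold}.
#' @return data frame aligned with \code{geno$loci}: scaffold, pos, lg,
#'   \code{ordinal_scaffold}, \code{ordinal_lg}.
#' @export
ordinal_positions <- function(geno, anchors) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(anchors, "super_scaffold"))
  loci <- geno$loci
  sc <- anchors$scaffolds
  idx <- match(loci$scaffold, sc$scaffold)
  if (anyNA(idx)) {
    stop("loci on unanchored scaffolds: ",
         paste(unique(loci$scaffold[is.na(idx)]), collapse = ", "))
  }
  lg <- sc$lg[idx]
  sc_order <- sc$order[idx]
  ord_scaffold <- stats::ave(loci$pos, loci$scaffold,
                             FUN = function(p) rank(p, ties.method = "first"))
  key <- order(lg, sc_order, loci$pos)
  ord_lg <- integer(nrow(loci))
  ord_lg[key] <- stats::ave(seq_along(key), lg[key], FUN = seq_along)
  data.frame(scaffold = loci$scaffold, pos = loci$pos, lg = lg,
             ordinal_scaffold = as.integer(ord_scaffold),
             ordinal_lg = as.integer(ord_lg),
             stringsAsFactors = FALSE)
}
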