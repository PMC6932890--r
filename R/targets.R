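#' @include network.R
NULL

#' Strongest intra-chromosomal interactor of a bin
#'
#' Returns the intra-chromosomal partner bin with the maximal contact
#' frequency, excluding the bin itself.  Ties are broken toward the
#' smaller bin distance, then the smaller bin ID.  In a pure
#' distance-decay matrix this is always an adjacent bin; planted or
#' genuine long-range peaks override that.
#'
#' @param bin global bin ID.
#' @param cm a [ContactMatrix-class] (typically 10-kb intra contacts).
#' @return list with `target` (bin ID or NA if the bin has no positive
#'   intra-chromosomal contact), `frequency`, and `distance` (in bins).
#' @export
strongestInteractor <- function(bin, cm) {
  layout <- cm@layout
  .checkBins(layout, bin)
  row <- cm@mat[bin, ]
  idx <- which(row > 0)
  idx <- idx[idx != bin]
  idx <- idx[binChrom(layout, idx) == binChrom(layout, bin)]
  if (!length(idx))
    return(list(target = NA_integer_, frequency = NA_real_,
                distance = NA_integer_))
  f <- row[idx]
  d <- abs(idx - bin)
  ord <- order(-f, d, idx)
  best <- ord[1L]
  list(target = as.integer(idx[best]), frequency = unname(f[best]),
       distance = as.integer(d[best]))
}

#' Rank long-range SNP-target bin pairs
#'
#' For every SNP-harboring bin whose strongest intra-chromosomal
#' interactor lies at a distance of at least `minDistance` bins
#' (default 2, i.e. non-adjacent), emits one pair; pairs are sorted by
#' contact frequency (descending) and the top `topK` are returned.  Genes
#' intersecting the target bin are listed; gene-less target bins yield an
#' empty gene list.
#'
#' @param snpBins integer vector of bins harboring (non-coding) SNPs.
#' @param cm a [ContactMatrix-class] at the matching resolution.
#' @param minDistance minimum bin distance to call a pair long-range.
#' @param topK maximum number of pairs returned (all, if fewer).
#' @param genes optional gene table for target-gene annotation.
#' @return data.table `snp_bin`, `target_bin`, `frequency`,
#'   `distance_bins`, `distance_bp`, `genes_in_target` (comma-joined,
#'   possibly empty).
#' @export
rankLongRangePairs <- function(snpBins, cm, minDistance = 2L, topK = 30L,
                               genes = NULL) {
  snpBins <- sort(unique(as.integer(snpBins)))
  layout <- cm@layout
  tr <- contactEntries(cm, diagonal = FALSE)
  tr <- tr[tr$f > 0 &
           binChrom(layout, tr$i) == binChrom(layout, tr$j), , drop = FALSE]
  # both directions, restricted to seed bins, then per-bin argmax with the
  # tie-break order (frequency desc, distance asc, partner ID asc)
  long <- data.table::data.table(
    bin = c(tr$i, tr$j), partner = c(tr$j, tr$i), f = c(tr$f, tr$f))
  long <- long[long$bin %in% snpBins]
  out <- data.table::data.table(snp_bin = integer(0),
                                target_bin = integer(0),
                                frequency = numeric(0),
                                distance_bins = integer(0))
  if (nrow(long)) {
    long$d <- abs(long$partner - long$bin)
    data.table::setorder(long, bin, -f, d, partner)
    best <- long[!duplicated(long$bin)]
    best <- best[best$d >= minDistance]
    out <- data.table::data.table(snp_bin = best$bin,
                                  target_bin = best$partner,
                                  frequency = best$f,
                                  distance_bins = best$d)
  }
  if (nrow(out) == 0L)
    return(data.table::data.table(snp_bin = integer(0),
                                  target_bin = integer(0),
                                  frequency = numeric(0),
                                  distance_bins = integer(0),
                                  distance_bp = numeric(0),
                                  genes_in_target = character(0)))
  data.table::setorder(out, -frequency, snp_bin)
  out <- head(out, topK)
  out$distance_bp <- out$distance_bins * binSize(cm@layout)
  out$genes_in_target <- if (is.null(genes)) "" else
    vapply(out$target_bin, function(b)
      paste(genesInBin(b, genes, cm@layout), collapse = ","), "")
  out
}

#' Genes intersecting a genomic bin
#'
#' @param bin global bin ID.
#' @param genes gene table (BED-style `chrom`, `start`, `end`, `name`).
#' @param layout the [GenomeLayout-class] defining the bin.
#' @return character vector of gene names (possibly empty: "gene-less"
#'   bins occur).
#' @export
genesInBin <- function(bin, genes, layout) {
  bc <- binCoords(layout, bin)
  gr <- GenomicRanges::GRanges(bc$chrom,
          IRanges::IRanges(start = bc$start + 1, end = bc$end))
  hits <- .findOverlaps(.bedGRanges(genes), gr)
  sort(unique(genes$name[S4Vectors::queryHits(hits)]))
}
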