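#' @include gwas.R
NULL

#' Build flanked TAD border regions
#'
#' Extends each border core by a flank (default 100 bp) on both sides,
#' clamped to the chromosome, producing the "TAD boundary regions" in which
#' SNPs are counted.
#'
#' @param borders border table (BED-style `chrom`, `start`, `end`,
#'   optional `name`).
#' @param flank flank width in bp.
#' @param layout a [GenomeLayout-class] providing chromosome bounds.
#' @return data.table with the core columns plus `flank_start`,
#'   `flank_end`, forming the flanked region (0-based half-open).
#' @export
makeBorderRegions <- function(borders, flank = 100, layout) {
  borders <- data.table::as.data.table(borders)
  len <- chromLengths(layout)
  m <- match(borders$chrom, names(len))
  if (anyNA(m)) stop("border chromosome absent from layout")
  if (any(borders$start < 0 | borders$end > len[m] |
          borders$start >= borders$end))
    stop("border interval outside chromosome bounds")
  borders$flank_start <- pmax(borders$start - flank, 0)
  borders$flank_end <- pmin(borders$end + flank, len[m])
  if (is.null(borders$name))
    borders$name <- sprintf("border%04d", seq_len(nrow(borders)))
  borders
}

#' Count SNPs inside regions
#'
#' Counts each SNP in every region containing its position (flanked
#' interval when present).  For disjoint regions the total equals the
#' number of SNPs falling in any region.
#'
#' @param snps SNP table (`chrom`, `pos`); typically pre-filtered to
#'   non-coding SNPs.
#' @param regions region table; `flank_start`/`flank_end` are used when
#'   present, otherwise `start`/`end` (0-based half-open either way).
#' @return list with `perRegion` (integer vector, one count per region
#'   row) and `total` (sum of per-region counts).
#' @export
countSnpsInRegions <- function(snps, regions) {
  gr <- .snpGRanges(snps)
  st <- if (!is.null(regions$flank_start)) regions$flank_start else regions$start
  en <- if (!is.null(regions$flank_end)) regions$flank_end else regions$end
  rr <- GenomicRanges::GRanges(regions$chrom,
          IRanges::IRanges(start = st + 1, end = en))
  cnt <- .countOverlaps(rr, gr)
  list(perRegion = as.integer(cnt), total = sum(cnt))
}

#' Sample matched random control borders
#'
#' For each replicate, places one random border per real border on the same
#' chromosome, preserving the real border's core width, flanks it, and
#' rejects placements whose flanked region overlaps any real flanked border
#' region.  Replicates use per-replicate RNG substreams, so a fixed seed
#' reproduces the full control set.
#'
#' @param borders flanked border table from [makeBorderRegions()].
#' @param layout a [GenomeLayout-class].
#' @param reps number of control replicates (default 100).
#' @param seed RNG seed.
#' @param flank flank width (must match the real borders').
#' @param pointBorders logical; if TRUE control cores are single points
#'   (the literal point-plus-flanks reading) instead of width-preserving.
#' @param maxRetry maximum placement rounds per replicate before erroring.
#' @return list of `reps` data.tables, each a control border set with
#'   `chrom`, `start`, `end`, `flank_start`, `flank_end`.
#' @export
sampleControlBorders <- function(borders, layout, reps = 100, seed = 1L,
                                 flank = 100, pointBorders = FALSE,
                                 maxRetry = 10000L) {
  borders <- data.table::as.data.table(borders)
  len <- chromLengths(layout)
  realGr <- GenomicRanges::GRanges(borders$chrom,
              IRanges::IRanges(start = borders$flank_start + 1,
                               end = borders$flank_end))
  width <- if (pointBorders) rep(1L, nrow(borders))
           else borders$end - borders$start
  lapply(seq_len(reps), function(r) {
    .withStream(seed, paste0("controls:", r), {
      need <- seq_len(nrow(borders))
      st <- numeric(nrow(borders))
      for (round in seq_len(maxRetry)) {
        if (!length(need)) break
        maxStart <- len[borders$chrom[need]] - width[need] - flank
        cand <- floor(runif(length(need)) * (maxStart - flank)) + flank
        gr <- GenomicRanges::GRanges(borders$chrom[need],
                IRanges::IRanges(start = cand - flank + 1,
                                 end = cand + width[need] + flank))
        bad <- .overlapsAny(gr, realGr)
        st[need[!bad]] <- cand[!bad]
        need <- need[bad]
      }
      if (length(need))
        stop("could not place control borders after ", maxRetry,
             " rounds (chromosome saturated?)")
      data.table::data.table(
        chrom = borders$chrom, start = st, end = st + width,
        flank_start = pmax(st - flank, 0),
        flank_end = pmin(st + width + flank, len[borders$chrom]))
    })
  })
}

#' Fisher's exact enrichment test on observed vs control counts
#'
#' Builds the 2x2 table `[[obsIn, obsTotal-obsIn], [ctrlIn,
#' ctrlTotal-ctrlIn]]` and runs Fisher's exact test.  The control count may
#' be fractional (an average over control replicates); it is rounded
#' half-up to an integer first.  The default sidedness is one-sided
#' greater (overrepresentation); `"two.sided"` is available and matches
#' published two-sided usage.
#'
#' @param obsIn SNPs observed inside the real regions.
#' @param obsTotal total SNPs considered.
#' @param ctrlIn (possibly fractional, averaged) SNPs inside control
#'   regions.
#' @param ctrlTotal total SNPs in the control comparison (usually
#'   `obsTotal`).
#' @param sided `"greater"` (default) or `"two.sided"`.
#' @return list with `table` (2x2 matrix), `oddsRatio` (sample OR),
#'   `p` and `log10p`.
#' @export
fisherEnrichment <- function(obsIn, obsTotal, ctrlIn, ctrlTotal,
                             sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  ctrlIn <- floor(ctrlIn + 0.5)
  counts <- c(obsIn, obsTotal - obsIn, ctrlIn, ctrlTotal - ctrlIn)
  if (any(counts < 0)) stop("negative or inconsistent counts")
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "control"),
                                c("in", "out")))
  ft <- fisher.test(tab, alternative = sided)
  orHat <- (tab[1, 1] / tab[1, 2]) / (tab[2, 1] / tab[2, 2])
  list(table = tab, oddsRatio = unname(orHat), p = ft$p.value,
       log10p = log10(ft$p.value))
}

#' Full TAD-border SNP enrichment analysis
#'
#' Counts non-coding SNPs in flanked border regions, generates matched
#' random control border sets, averages the control counts, and tests
#' overrepresentation with Fisher's exact test.
#'
#' @param snps non-coding SNP table (`chrom`, `pos`).
#' @param borders flanked border table from [makeBorderRegions()].
#' @param layout a [GenomeLayout-class].
#' @param reps control replicates (default 100).
#' @param seed RNG seed for control placement.
#' @param sided test sidedness, see [fisherEnrichment()].
#' @return list with the enrichment result plus `obsIn`, `ctrlInMean`,
#'   `nMutatedBorders` (borders containing at least one SNP) and
#'   `perBorder` counts.
#' @export
tadEnrichment <- function(snps, borders, layout, reps = 100, seed = 1L,
                          sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  obs <- countSnpsInRegions(snps, borders)
  ctrl <- sampleControlBorders(borders, layout, reps = reps, seed = seed)
  # one overlap query against the union of all replicates
  allCtrl <- data.table::rbindlist(ctrl)
  ctrlGr <- GenomicRanges::GRanges(allCtrl$chrom,
              IRanges::IRanges(start = allCtrl$flank_start + 1,
                               end = allCtrl$flank_end))
  perRegion <- .countOverlaps(ctrlGr, .snpGRanges(snps))
  repIdx <- rep(seq_len(reps), each = nrow(borders))
  ctrlCounts <- as.numeric(rowsum(perRegion, repIdx))
  n <- nrow(snps)
  enr <- fisherEnrichment(obs$total, n, mean(ctrlCounts), n, sided = sided)
  c(enr, list(obsIn = obs$total, ctrlInMean = mean(ctrlCounts),
              nMutatedBorders = sum(obs$perRegion > 0),
              perBorder = obs$perRegion))
}

#' Classify phenotype genes by proximity to mutated borders
#'
#' A border's proximity window is the 10-kb bin containing it plus one
#' adjacent bin on each side (30 kb in total).  A gene is "near" a border
#' iff its interval intersects that window.  Each gene is classified by
#' the mutation status (snp_count > 0) of all nearby borders:
#' `mutated-only`, `nonmutated-only`, `both`, or `none`.
#'
#' @param genes gene table (`chrom`, `start`, `end`, `name`).
#' @param borders flanked border table carrying a `snp_count` column.
#' @param layout10kb a 10-kb [GenomeLayout-class].
#' @return data.table `name`, `class`, `nMutatedNear`, `nNonmutatedNear`.
#' @export
geneBorderProximity <- function(genes, borders, layout10kb) {
  if (is.null(borders$snp_count))
    stop("borders must carry a snp_count column")
  bs <- binSize(layout10kb)
  mid <- floor((borders$start + borders$end) / 2)
  len <- chromLengths(layout10kb)
  binStart <- floor(mid / bs) * bs
  winStart <- pmax(binStart - bs, 0)
  winEnd <- pmin(binStart + 2 * bs, len[borders$chrom])
  winGr <- GenomicRanges::GRanges(borders$chrom,
             IRanges::IRanges(start = winStart + 1, end = winEnd))
  geneGr <- .bedGRanges(genes)
  hits <- .findOverlaps(geneGr, winGr)
  mut <- borders$snp_count > 0
  nMut <- nNon <- integer(nrow(genes))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    nMut <- as.integer(tapply(mut[s], factor(q, seq_len(nrow(genes))),
                              sum, default = 0L))
    nNon <- as.integer(tapply(!mut[s], factor(q, seq_len(nrow(genes))),
                              sum, default = 0L))
  }
  cls <- ifelse(nMut > 0 & nNon > 0, "both",
         ifelse(nMut > 0, "mutated-only",
         ifelse(nNon > 0, "nonmutated-only", "none")))
  data.table::data.table(name = genes$name, class = cls,
                         nMutatedNear = nMut, nNonmutatedNear = nNon)
}
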