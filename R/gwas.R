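#' @include utils.R
NULL

#' Haplotype-frequency divergence statistic D
#'
#' For a SNP with per-founder haplotype frequencies in the old group
#' (`hO`) and the young control group (`hY`), the divergence is
#' \deqn{D = 100 \sqrt{\sum_{j=1}^{n} (h_{O,j} - h_{Y,j})^2 / n},}
#' i.e. 100 times the root-mean-square frequency difference over the n
#' founder haplotypes present at that position.  D lies in `[0, 100]`;
#' D > 7.9 is the conventional genome-wide significance cut for
#' evolve-and-resequence data of this design.
#'
#' @param hO,hY numeric frequency vectors of equal length n >= 1, entries
#'   in `[0, 1]`.
#' @return single nonnegative numeric D.
#' @export
#' @examples
#' computeD(rep(0.2, 5), rep(0.2, 5))      # 0
#' computeD(rep(0.2, 8), rep(0.2, 8) + 0.1) # 10
computeD <- function(hO, hY) {
  if (length(hO) == 0L) stop("empty frequency vectors")
  if (length(hO) != length(hY)) stop("frequency vectors differ in length")
  if (any(hO < 0 | hO > 1) || any(hY < 0 | hY > 1))
    stop("frequencies must lie in [0, 1]")
  100 * sqrt(sum((hO - hY)^2) / length(hO))
}

#' Add a D column to a haplotype-frequency SNP table
#'
#' Vectorised [computeD()] over the `hO_*`/`hY_*` columns of a SNP table.
#' Rows may have trailing `NA` founder columns (as produced by
#' [combineDuplicateSnps()] when tables with different n are mixed); the
#' per-row n is the number of non-missing founder frequencies.
#'
#' @param snps data.frame/data.table with `hO_1..` and `hY_1..` columns.
#' @return the table with a `D` column appended.
#' @export
addDStatistic <- function(snps) {
  oc <- grep("^hO_", names(snps), value = TRUE)
  yc <- grep("^hY_", names(snps), value = TRUE)
  if (length(oc) == 0L || length(oc) != length(yc))
    stop("table must carry matching hO_*/hY_* columns")
  hO <- as.matrix(snps[, oc, with = FALSE])
  hY <- as.matrix(snps[, yc, with = FALSE])
  d2 <- (hO - hY)^2
  n <- rowSums(!is.na(d2))
  snps$D <- 100 * sqrt(rowSums(d2, na.rm = TRUE) / n)
  snps
}

#' Combine duplicated SNP records
#'
#' SNPs recorded at the same (chrom, pos) across populations are collapsed
#' to a single record: the populations' haplotype-frequency vectors are
#' concatenated per group and renormalised to sum 1, and n (the number of
#' haplotypes at the position) becomes the sum of the duplicates' n.
#' Records whose IDs conflict are logged and the first is kept as the
#' record ID.
#'
#' Because combined records have more founder columns than singletons, the
#' output table is widened with `NA` padding; [addDStatistic()] handles the
#' per-row n.
#'
#' @param snps haplotype-frequency SNP table (columns `chrom`, `pos`, `id`,
#'   `hO_*`, `hY_*`).
#' @return table with one row per (chrom, pos).
#' @export
combineDuplicateSnps <- function(snps) {
  snps <- data.table::as.data.table(snps)
  key <- paste(snps$chrom, snps$pos)
  if (!anyDuplicated(key)) return(snps[order(chrom, pos)])
  oc <- grep("^hO_", names(snps), value = TRUE)
  yc <- grep("^hY_", names(snps), value = TRUE)
  isDup <- key %in% key[duplicated(key)]
  uniq <- snps[!isDup]
  dup <- snps[isDup]
  grp <- split(seq_len(nrow(dup)), key[isDup])
  maxN <- max(vapply(grp, function(ix)
    sum(!is.na(as.matrix(dup[ix, oc, with = FALSE]))), 0))
  rows <- lapply(grp, function(ix) {
    snps <- dup
    hO <- as.vector(t(as.matrix(snps[ix, oc, with = FALSE])))
    hY <- as.vector(t(as.matrix(snps[ix, yc, with = FALSE])))
    hO <- hO[!is.na(hO)]; hY <- hY[!is.na(hY)]
    hO <- hO / sum(hO); hY <- hY / sum(hY)
    ids <- unique(snps$id[ix])
    pad <- function(v) c(v, rep(NA_real_, maxN - length(v)))
    c(list(chrom = snps$chrom[ix[1]], pos = snps$pos[ix[1]], id = ids[1]),
      setNames(as.list(pad(hO)), paste0("hO_", seq_len(maxN))),
      setNames(as.list(pad(hY)), paste0("hY_", seq_len(maxN))))
  })
  combined <- data.table::rbindlist(rows)
  nConf <- sum(vapply(grp, function(ix)
    length(unique(dup$id[ix])) > 1L, NA))
  message("combineDuplicateSnps: combined ", length(grp),
          " duplicated positions",
          if (nConf) paste0(" (", nConf,
                            " with conflicting record IDs; first kept)"))
  # pad untouched singleton records to the combined founder-column width
  if (maxN > length(oc)) {
    for (q in seq(length(oc) + 1L, maxN)) {
      data.table::set(uniq, j = paste0("hO_", q),
                      value = rep(NA_real_, nrow(uniq)))
      data.table::set(uniq, j = paste0("hY_", q),
                      value = rep(NA_real_, nrow(uniq)))
    }
  }
  out <- data.table::rbindlist(
    list(uniq[, c("chrom", "pos", "id",
                  paste0("hO_", seq_len(maxN)),
                  paste0("hY_", seq_len(maxN))), with = FALSE],
         combined), use.names = TRUE)
  data.table::setorder(out, chrom, pos)
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (here, the number of genomic bins: 1,503 at
#'   80 kb, 11,839 at 10 kb for the reference fly contact data).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroniThreshold(0.05, 1503)   # 3.33e-05
#' bonferroniThreshold(0.05, 11839)  # 4.22e-06
bonferroniThreshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Significance policy for SNP selection
#'
#' Either a fixed divergence cut (`mode = "d"`, significant iff
#' `D > dCut`) or a Bonferroni p-value policy (`mode = "bonferroni"`,
#' significant iff `pvalue < alpha/m`).  Both inequalities are strict.
#'
#' @param mode `"d"` or `"bonferroni"`.
#' @param dCut divergence cut (default 7.9).
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests.
#' @return a `SignificancePolicy` list.
#' @export
significancePolicy <- function(mode = c("d", "bonferroni"), dCut = 7.9,
                               alpha = 0.05, m = NULL) {
  mode <- match.arg(mode)
  if (mode == "bonferroni" && is.null(m))
    stop("bonferroni mode requires the number of tests 'm'")
  structure(list(mode = mode, dCut = dCut, alpha = alpha, m = m,
                 threshold = if (mode == "bonferroni")
                   bonferroniThreshold(alpha, m) else dCut),
            class = "SignificancePolicy")
}

#' Select significant SNPs under a policy
#'
#' @param snps SNP table carrying a `D` column (d mode) or `pvalue`
#'   column (bonferroni mode).
#' @param policy a [significancePolicy()].
#' @return the subset of rows passing the strict cut, input order
#'   preserved.
#' @export
selectSignificant <- function(snps, policy) {
  if (policy$mode == "d") {
    if (is.null(snps$D))
      stop("policy mode 'd' needs a D column (see addDStatistic)")
    snps[snps$D > policy$dCut, , drop = FALSE]
  } else {
    if (is.null(snps$pvalue))
      stop("policy mode 'bonferroni' needs a pvalue column")
    snps[snps$pvalue < policy$threshold, , drop = FALSE]
  }
}

#' Classify SNPs as coding or non-coding
#'
#' A SNP is coding iff its position falls between the start and end of at
#' least one gene (gene intervals treated as closed; a SNP exactly at a
#' gene start or end is coding).  `gene_ids` lists every overlapping gene.
#' SNPs on chromosomes absent from the gene table are logged and flagged
#' non-coding.
#'
#' @param snps SNP table (`chrom`, `pos`, ...).
#' @param genes gene table (BED-style `chrom`, `start`, `end`, `name`).
#' @return the SNP table with logical `coding` and character `gene_ids`
#'   (comma-joined) columns appended.
#' @export
classifyCoding <- function(snps, genes) {
  snps <- data.table::as.data.table(snps)
  gr <- .snpGRanges(snps)
  gg <- .bedGRanges(genes)
  unknown <- !(as.character(GenomicRanges::seqnames(gr)) %in%
               unique(genes$chrom))
  if (any(unknown))
    message("classifyCoding: ", sum(unknown),
            " SNPs on chromosomes absent from the gene table; ",
            "flagged non-coding")
  hits <- .findOverlaps(gr, gg)
  snps$coding <- FALSE
  snps$coding[unique(S4Vectors::queryHits(hits))] <- TRUE
  ids <- rep(NA_character_, nrow(snps))
  if (length(hits)) {
    byq <- split(genes$name[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    ids[as.integer(names(byq))] <-
      vapply(byq, function(v) paste(sort(unique(v)), collapse = ","), "")
  }
  snps$gene_ids <- ids
  snps
}

# global bin arithmetic shared by assignBins and the generators
.globalBin <- function(layout, chrom, pos) {
  m <- match(chrom, chromNames(layout))
  if (anyNA(m))
    stop("SNP chromosome(s) absent from layout: ",
         paste(unique(chrom[is.na(m)]), collapse = ", "))
  bad <- pos < 1 | pos > chromLengths(layout)[m]
  if (any(bad))
    stop("SNP position(s) beyond chromosome end: ",
         paste(head(paste0(chrom[bad], ":", pos[bad]), 5), collapse = ", "))
  local <- floor((pos - 1) / binSize(layout)) + 1
  as.integer(layout@offsets[m] + local - 1)
}

#' Assign SNPs to genomic bins
#'
#' Maps each SNP position to the global bin index of the layout: local bin
#' `floor((pos-1)/binSize)+1`, offset by the chromosome's first global
#' index.  Position 1 of the first chromosome maps to bin 1; position
#' 80,000 stays in bin 1 and 80,001 starts bin 2 (at 80-kb resolution).
#'
#' @param snps SNP table (`chrom`, `pos`, ...).
#' @param layout a [GenomeLayout-class].
#' @return the table with an integer `bin` column appended.
#' @export
assignBins <- function(snps, layout) {
  snps <- data.table::as.data.table(snps)
  snps$bin <- .globalBin(layout, snps$chrom, snps$pos)
  snps
}
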