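#' @include AllGenerics.R
NULL

#' Default fly-like chromosome arm lengths
#'
#' Arm lengths (bp) chosen so that binning at 80 kb yields exactly 1,503
#' global bins with the canonical arm boundaries: 2L bins 1-287, 2R 288-551,
#' 3L 552-858, 3R 859-1207, chromosome 4 1208-1223 and X 1224-1503.
#'
#' @return named numeric vector of arm lengths in bp.
#' @export
#' @examples
#' layout <- makeGenomeLayout(flyChromosomes(), 80000)
#' nBins(layout)  # 1503
flyChromosomes <- function() {
  c("2L" = 22960000, "2R" = 21120000, "3L" = 24560000,
    "3R" = 27920000, "4" = 1280000, "X" = 22400000)
}

#' Construct a genome bin layout
#'
#' Partitions each chromosome into fixed-width windows (the last window of a
#' chromosome may be short) and assigns contiguous 1-based global bin
#' indices across chromosomes in the given order.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), in the desired order.
#' @param binSize bin width in bp (e.g. 80000 or 10000).
#' @return a [GenomeLayout-class] object.
#' @export
#' @examples
#' makeGenomeLayout(c(chrA = 160001), 80000)  # 3 bins
makeGenomeLayout <- function(chromosomes, binSize) {
  if (length(chromosomes) == 0L)
    stop("'chromosomes' must name at least one chromosome")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("'chromosomes' must be a named vector of lengths")
  if (length(binSize) != 1L || !is.finite(binSize) || binSize <= 0)
    stop("'binSize' must be a single positive number")
  if (any(!is.finite(chromosomes) | chromosomes <= 0))
    stop("chromosome lengths must be positive")
  nb <- as.integer(ceiling(chromosomes / binSize))
  offs <- as.integer(cumsum(c(1L, nb[-length(nb)])))
  new("GenomeLayout",
      chromosomes = names(chromosomes),
      lengths = unname(as.numeric(chromosomes)),
      binSize = as.numeric(binSize),
      nBinsPerChrom = setNames(nb, names(chromosomes)),
      offsets = setNames(offs, names(chromosomes)))
}

#' GenomeLayout accessors
#'
#' @param x a [GenomeLayout-class] (or an object carrying one).
#' @return `nBins`: total bin count; `binSize`: bin width in bp;
#'   `chromNames`: chromosome names; `chromLengths`: named lengths in bp;
#'   `genomeLayout`: the embedded layout.
#' @name GenomeLayout-accessors
NULL

#' @rdname GenomeLayout-accessors
#' @export
setMethod("nBins", "GenomeLayout", function(x) sum(x@nBinsPerChrom))

#' @rdname GenomeLayout-accessors
#' @export
setMethod("binSize", "GenomeLayout", function(x) x@binSize)

#' @rdname GenomeLayout-accessors
#' @export
setMethod("chromNames", "GenomeLayout", function(x) x@chromosomes)

#' @rdname GenomeLayout-accessors
#' @export
setMethod("chromLengths", "GenomeLayout",
          function(x) setNames(x@lengths, x@chromosomes))

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", length(object@chromosomes), "chromosomes,",
      sum(object@nBinsPerChrom), "bins of", format(object@binSize, big.mark = ","),
      "bp\n")
  rng <- binRangeOfChrom(object)
  for (ch in object@chromosomes)
    cat(sprintf("  %-4s %12s bp  bins %d-%d\n", ch,
                format(chromLengths(object)[[ch]], big.mark = ","),
                rng[ch, "first"], rng[ch, "last"]))
})

# per-chromosome global index ranges, as a matrix with rownames
binRangeOfChrom <- function(layout) {
  first <- layout@offsets
  last <- first + layout@nBinsPerChrom - 1L
  m <- cbind(first = first, last = last)
  rownames(m) <- layout@chromosomes
  m
}

#' Map global bin IDs to chromosomes and coordinates
#'
#' `binChrom` returns the chromosome of each global bin; `binCoords` the
#' 0-based half-open genomic window each bin covers (clamped to the
#' chromosome end for the final, possibly short, bin).
#'
#' @param layout a [GenomeLayout-class].
#' @param bins integer vector of global bin IDs.
#' @return `binChrom`: character vector; `binCoords`: data.frame with
#'   columns `bin`, `chrom`, `start`, `end`.
#' @export
binChrom <- function(layout, bins) {
  .checkBins(layout, bins)
  idx <- findInterval(bins, layout@offsets)
  layout@chromosomes[idx]
}

#' @rdname binChrom
#' @export
binCoords <- function(layout, bins) {
  .checkBins(layout, bins)
  idx <- findInterval(bins, layout@offsets)
  local <- bins - layout@offsets[idx]   # 0-based local bin
  start <- local * layout@binSize
  end <- pmin(start + layout@binSize, layout@lengths[idx])
  data.frame(bin = bins, chrom = layout@chromosomes[idx],
             start = start, end = end, row.names = NULL)
}

.checkBins <- function(layout, bins) {
  nb <- sum(layout@nBinsPerChrom)
  bad <- bins < 1L | bins > nb | is.na(bins)
  if (any(bad))
    stop("global bin IDs out of range [1, ", nb, "]: ",
         paste(head(bins[bad], 5L), collapse = ", "))
  invisible(TRUE)
}

#' Chromosome grouping for threshold pooling
#'
#' Chromosome arms that share a numeric prefix (e.g. 2L and 2R) are pooled
#' into one group ("2") when computing intra-chromosomal interaction
#' thresholds, mirroring per-chromosome (not per-arm) threshold reporting.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of group labels.
#' @export
#' @examples
#' chromGroup(c("2L", "2R", "3L", "4", "X"))  # "2" "2" "3" "4" "X"
chromGroup <- function(chrom) {
  sub("^(chr)?([0-9]+)[LR]$", "\\1\\2", chrom)
}

#' Bins as a GRanges object
#'
#' @param layout a [GenomeLayout-class].
#' @return `GRanges` with one range per global bin (1-based closed
#'   coordinates), metadata column `bin`.
#' @export
binGRanges <- function(layout) {
  bc <- binCoords(layout, seq_len(nBins(layout)))
  gr <- GenomicRanges::GRanges(bc$chrom,
          IRanges::IRanges(start = bc$start + 1L, end = bc$end))
  S4Vectors::mcols(gr)$bin <- bc$bin
  gr
}
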