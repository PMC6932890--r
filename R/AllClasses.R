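#' @import methods
#' @importFrom stats setNames rgamma rlnorm rnorm runif rbinom rpois
#'   fisher.test phyper pchisq p.adjust quantile median
#' @importFrom utils head tail packageVersion
#' @importClassesFrom Matrix Matrix
NULL

#' GenomeLayout: fixed-width binning of a chromosome set
#'
#' A `GenomeLayout` records an ordered set of chromosomes, their lengths and
#' a fixed bin width, and assigns every bin a 1-based global index that is
#' contiguous across chromosomes in the stated order.  All network nodes,
#' contact-matrix indices and SNP bin assignments refer to these global
#' indices.  For the default fly-like arm set at 80 kb the layout has exactly
#' 1,503 bins with chromosome 2L occupying bins 1-287.
#'
#' @slot chromosomes character vector of chromosome names, in order.
#' @slot lengths numeric vector of chromosome lengths (bp), parallel to
#'   `chromosomes`.
#' @slot binSize single numeric, bin width in bp.
#' @slot nBinsPerChrom integer vector of per-chromosome bin counts
#'   (`ceiling(length / binSize)`).
#' @slot offsets integer vector; global index of each chromosome's first bin.
#'
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(
    chromosomes = "character",
    lengths = "numeric",
    binSize = "numeric",
    nBinsPerChrom = "integer",
    offsets = "integer"
  )
)

setValidity("GenomeLayout", function(object) {
  msg <- character()
  n <- length(object@chromosomes)
  if (n == 0L) msg <- c(msg, "layout must contain at least one chromosome")
  if (length(object@lengths) != n || length(object@nBinsPerChrom) != n ||
      length(object@offsets) != n)
    msg <- c(msg, "per-chromosome slots must be parallel to 'chromosomes'")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (any(object@lengths <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  if (anyDuplicated(object@chromosomes))
    msg <- c(msg, "duplicated chromosome names")
  if (n > 0 && length(msg) == 0L) {
    expected <- as.integer(ceiling(object@lengths / object@binSize))
    if (!identical(expected, unname(object@nBinsPerChrom)))
      msg <- c(msg, "nBinsPerChrom must equal ceiling(length / binSize)")
    # contiguity of global indices
    if (object@offsets[1L] != 1L ||
        (n > 1L && !identical(unname(object@offsets[-1L]),
                              unname(object@offsets[-n] +
                                     object@nBinsPerChrom[-n]))))
      msg <- c(msg, "global bin indices must be contiguous in chromosome order")
  }
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: symmetric normalized Hi-C interaction frequencies
#'
#' Wraps a symmetric sparse matrix of normalized contact frequencies between
#' the global bins of a [GenomeLayout].  Frequencies are nonnegative;
#' the diagonal (self-contacts) may be populated but is excluded from all
#' threshold computations.
#'
#' @slot layout the [GenomeLayout] the indices refer to.
#' @slot mat symmetric sparse `Matrix` (bins x bins) of frequencies.
#'
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(layout = "GenomeLayout", mat = "Matrix")
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  nb <- sum(object@layout@nBinsPerChrom)
  if (!identical(dim(object@mat), c(as.integer(nb), as.integer(nb))))
    msg <- c(msg, "matrix dimension must equal the layout's bin count")
  if (!Matrix::isSymmetric(object@mat))
    msg <- c(msg, "contact matrix must be symmetric")
  if (length(object@mat@x) && min(object@mat@x) < 0)
    msg <- c(msg, "contact frequencies must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ThresholdSet: top-percentile "strong interaction" cutoffs
#'
#' Per-chromosome intra-chromosomal thresholds and a single
#' inter-chromosomal threshold, each defined as the smallest observed
#' positive frequency v such that the fraction of entries strictly greater
#' than v is at most 1 - q.  Chromosome arms sharing a numeric prefix
#' (2L/2R, 3L/3R) are pooled into one group ("2", "3"), so the default fly
#' layout yields four intra thresholds: chromosomes 2, 3, 4 and X.
#'
#' @slot q quantile (default 0.99, i.e. top 1 percent).
#' @slot intra named numeric vector of thresholds per chromosome group.
#' @slot inter single numeric inter-chromosomal threshold (NA if the matrix
#'   holds no inter-chromosomal entries).
#' @slot crossArm how contacts between arms of the same numbered chromosome
#'   were classed when thresholding: "intra" (default) or "inter".
#'
#' @exportClass ThresholdSet
setClass("ThresholdSet",
  representation(q = "numeric", intra = "numeric", inter = "numeric",
                 crossArm = "character")
)

setValidity("ThresholdSet", function(object) {
  msg <- character()
  if (length(object@q) != 1L || object@q <= 0 || object@q >= 1)
    msg <- c(msg, "q must be a single value in (0,1)")
  if (any(object@intra < 0, na.rm = TRUE)) msg <- c(msg, "thresholds must be >= 0")
  if (!object@crossArm %in% c("intra", "inter"))
    msg <- c(msg, "crossArm must be 'intra' or 'inter'")
  if (length(msg)) msg else TRUE
})

#' ColocationNetwork: weighted co-location graph over genomic bins
#'
#' Nodes are global bin indices of a [GenomeLayout]; an edge joins two bins
#' whose contact frequency exceeds the applicable top-percentile threshold.
#' Nodes are tagged by provenance: `original` nodes harbor significant GWAS
#' SNPs, `added` nodes were pulled in during network extension through a
#' strong interaction with an original node.
#'
#' @slot layout the [GenomeLayout].
#' @slot nodes integer vector of global bin IDs (sorted, unique).
#' @slot origin character vector parallel to `nodes`; "original" or "added".
#' @slot edges data.frame with columns `i`, `j` (global bin IDs, i < j) and
#'   `weight` (contact frequency).
#' @slot dataset free-text tag of the GWAS dataset the network derives from.
#'
#' @exportClass ColocationNetwork
setClass("ColocationNetwork",
  representation(layout = "GenomeLayout", nodes = "integer",
                 origin = "character", edges = "data.frame",
                 dataset = "character")
)

setValidity("ColocationNetwork", function(object) {
  msg <- character()
  if (length(object@origin) != length(object@nodes))
    msg <- c(msg, "origin must be parallel to nodes")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated node IDs")
  if (!all(object@origin %in% c("original", "added")))
    msg <- c(msg, "origin tags must be 'original' or 'added'")
  e <- object@edges
  if (!all(c("i", "j", "weight") %in% names(e)))
    msg <- c(msg, "edges must have columns i, j, weight")
  else if (nrow(e)) {
    if (any(e$i == e$j)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$i, e$j) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be network nodes")
  }
  if (length(msg)) msg else TRUE
})

#' CommunityPartition: Louvain communities of a co-location network
#'
#' @slot membership named integer vector: community ID per node (names are
#'   global bin IDs).
#' @slot resolution resolution parameter of the modularity optimisation.
#' @slot seed RNG seed used for the Louvain run.
#' @slot modularity modularity of the returned partition.
#'
#' @exportClass CommunityPartition
setClass("CommunityPartition",
  representation(membership = "integer", resolution = "numeric",
                 seed = "integer", modularity = "numeric")
)

setValidity("CommunityPartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node ID")
  if (length(object@membership) && any(tabulate(object@membership) == 0) &&
      max(object@membership) > length(unique(object@membership)))
    msg <- c(msg, "community IDs must be dense (no empty communities)")
  if (length(msg)) msg else TRUE
})
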