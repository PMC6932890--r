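#' @include gwas.R
NULL

#' Extract contact-matrix entries as triplets
#'
#' @param cm a [ContactMatrix-class].
#' @param diagonal include self-contacts f(i,i)?
#' @return data.frame with columns `i`, `j` (i <= j) and `f`.
#' @export
contactEntries <- function(cm, diagonal = FALSE) {
  tr <- Matrix::summary(cm@mat)
  i <- pmin(tr$i, tr$j); j <- pmax(tr$i, tr$j)
  out <- data.frame(i = i, j = j, f = tr$x)
  if (!diagonal) out <- out[out$i != out$j, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}

# classify bin pairs as intra (same chromosome group) or inter, with the
# cross-arm switch: contacts between arms of the same numbered chromosome
# are intra by default but can be classed as inter
.pairClass <- function(layout, i, j, crossArm = "intra") {
  ci <- binChrom(layout, i); cj <- binChrom(layout, j)
  gi <- chromGroup(ci); gj <- chromGroup(cj)
  sameGroup <- gi == gj
  isIntra <- if (crossArm == "intra") sameGroup else ci == cj
  list(isIntra = isIntra, group = ifelse(isIntra, gi, NA_character_))
}

# order-statistic threshold: smallest observed value v such that the
# fraction of entries strictly greater than v is <= 1 - q
.tailThreshold <- function(vals, q) {
  s <- sort(vals, decreasing = TRUE)
  m <- floor(length(s) * (1 - q))
  s[min(m + 1L, length(s))]
}

#' Top-percentile interaction-frequency thresholds
#'
#' Computes, per chromosome group (arms pooled: 2L+2R as "2", 3L+3R as
#' "3"), the cutoff above which only the strongest `1-q` fraction of
#' positive intra-chromosomal contact frequencies lie, plus one analogous
#' inter-chromosomal threshold.  The cutoff is the smallest observed value
#' v with `mean(f > v) <= 1-q` over positive upper-triangle entries;
#' "strong" means strictly `f > tau`.  Self-contacts are always excluded.
#'
#' @param cm a [ContactMatrix-class].
#' @param q quantile, default 0.99 (top 1 percent).
#' @param crossArm class contacts between arms of the same numbered
#'   chromosome as `"intra"` (default) or `"inter"` when thresholding.
#' @return a [ThresholdSet-class].
#' @export
computeThresholds <- function(cm, q = 0.99, crossArm = c("intra", "inter")) {
  crossArm <- match.arg(crossArm)
  layout <- cm@layout
  tr <- contactEntries(cm, diagonal = FALSE)
  tr <- tr[tr$f > 0, , drop = FALSE]
  if (nrow(tr) == 0L) stop("contact matrix has no positive entries")
  cls <- .pairClass(layout, tr$i, tr$j, crossArm)
  groups <- unique(chromGroup(chromNames(layout)))
  intra <- setNames(numeric(length(groups)), groups)
  for (g in groups) {
    vals <- tr$f[cls$isIntra & !is.na(cls$group) & cls$group == g]
    if (length(vals) == 0L)
      stop("no positive intra-chromosomal entries for chromosome group ", g)
    intra[g] <- .tailThreshold(vals, q)
  }
  interVals <- tr$f[!cls$isIntra]
  inter <- if (length(interVals)) .tailThreshold(interVals, q) else NA_real_
  new("ThresholdSet", q = q, intra = intra, inter = inter,
      crossArm = crossArm)
}

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet (q =", object@q, ", crossArm =", object@crossArm, ")\n")
  cat("  intra:", paste(names(object@intra), round(object@intra, 3),
                        sep = "=", collapse = "  "), "\n")
  cat("  inter:", round(object@inter, 3), "\n")
})

# applicable threshold per bin pair
.applicableTau <- function(thr, layout, i, j) {
  cls <- .pairClass(layout, i, j, thr@crossArm)
  tau <- rep(thr@inter, length(i))
  hit <- cls$isIntra
  tau[hit] <- thr@intra[cls$group[hit]]
  tau
}

# strong entries of a matrix under a threshold set (no diagonal)
.strongEntries <- function(cm, thr) {
  tr <- contactEntries(cm, diagonal = FALSE)
  tau <- .applicableTau(thr, cm@layout, tr$i, tr$j)
  tr[!is.na(tau) & tr$f > tau, , drop = FALSE]
}

#' Build the original co-location network
#'
#' Nodes are the bins harboring at least one significant GWAS SNP (isolated
#' nodes are retained); an edge joins two nodes whose contact frequency
#' strictly exceeds the applicable intra- or inter-chromosomal threshold.
#'
#' @param sigBins integer vector of global bin IDs with significant SNPs.
#' @param cm a [ContactMatrix-class].
#' @param thresholds a [ThresholdSet-class] computed from the same matrix.
#' @param dataset free-text dataset tag.
#' @return a [ColocationNetwork-class]; all nodes tagged `"original"`.
#' @export
buildOriginalNetwork <- function(sigBins, cm, thresholds, dataset = "") {
  nodes <- sort(unique(as.integer(sigBins)))
  if (length(nodes)) .checkBins(cm@layout, nodes)
  strong <- .strongEntries(cm, thresholds)
  keep <- strong$i %in% nodes & strong$j %in% nodes
  edges <- data.frame(i = strong$i[keep], j = strong$j[keep],
                      weight = strong$f[keep])
  new("ColocationNetwork", layout = cm@layout, nodes = nodes,
      origin = rep("original", length(nodes)), edges = edges,
      dataset = dataset)
}

#' Extend a co-location network
#'
#' Adds every bin outside the network that interacts with at least one
#' original node above the applicable threshold, tagged `"added"`.  By
#' default the extended edge set contains every above-threshold pair among
#' the final node set, including added-added pairs; with
#' `starExtension = TRUE` only edges touching an original node are kept
#' (the strict added-to-original reading).  Extension is a single round.
#'
#' @param net a [ColocationNetwork-class] of original nodes.
#' @param cm the [ContactMatrix-class] the network was built from.
#' @param thresholds the matching [ThresholdSet-class].
#' @param starExtension restrict edges to those incident to an original
#'   node.
#' @return the extended [ColocationNetwork-class].
#' @export
extendNetwork <- function(net, cm, thresholds, starExtension = FALSE) {
  strong <- .strongEntries(cm, thresholds)
  inNet <- strong$i %in% net@nodes
  jnNet <- strong$j %in% net@nodes
  added <- sort(unique(c(strong$j[inNet & !jnNet], strong$i[jnNet & !inNet])))
  nodes <- sort(unique(c(net@nodes, added)))
  origin <- ifelse(nodes %in% net@nodes, "original", "added")
  keep <- strong$i %in% nodes & strong$j %in% nodes
  if (starExtension)
    keep <- keep & (inNet | jnNet)
  edges <- data.frame(i = strong$i[keep], j = strong$j[keep],
                      weight = strong$f[keep])
  new("ColocationNetwork", layout = net@layout, nodes = nodes,
      origin = origin, edges = edges, dataset = net@dataset)
}

#' Network accessors
#'
#' @param x a [ColocationNetwork-class].
#' @return `networkNodes`: integer bin IDs; `networkEdges`: data.frame
#'   `i`, `j`, `weight`; `nodeOrigin`: named character vector
#'   ("original"/"added"); `datasetTag`: dataset label.
#' @name networkAccessors
NULL

#' @rdname networkAccessors
#' @export
setMethod("networkNodes", "ColocationNetwork", function(x) x@nodes)

#' @rdname networkAccessors
#' @export
setMethod("networkEdges", "ColocationNetwork", function(x) x@edges)

#' @rdname networkAccessors
#' @export
setMethod("nodeOrigin", "ColocationNetwork",
          function(x) setNames(x@origin, x@nodes))

#' @rdname networkAccessors
#' @export
setMethod("datasetTag", "ColocationNetwork", function(x) x@dataset)

#' @rdname networkAccessors
#' @export
setMethod("genomeLayout", "ColocationNetwork", function(x) x@layout)

setMethod("show", "ColocationNetwork", function(object) {
  cat("ColocationNetwork", if (nzchar(object@dataset))
        paste0("[", object@dataset, "]"), ":",
      length(object@nodes), "nodes (",
      sum(object@origin == "original"), "original /",
      sum(object@origin == "added"), "added ),",
      nrow(object@edges), "edges\n")
})

#' Convert a co-location network to an igraph graph
#'
#' Vertex names are global bin IDs (as character); edge attribute `weight`
#' carries the contact frequency; vertex attribute `origin` the provenance
#' tag.
#'
#' @param net a [ColocationNetwork-class].
#' @return an `igraph` graph including isolated nodes.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(net@edges$i),
                   to = as.character(net@edges$j),
                   weight = net@edges$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(net@nodes),
                          origin = net@origin))
}

#' Node degree and connected components
#'
#' `nodeDegree` returns the unweighted degree (number of connections) of
#' every node; `connectedComponents` the node sets of the connected
#' components (singletons included), largest first.
#'
#' @param net a [ColocationNetwork-class].
#' @return `nodeDegree`: named integer vector; `connectedComponents`:
#'   list of integer vectors of bin IDs.
#' @export
nodeDegree <- function(net) {
  deg <- setNames(rep(0L, length(net@nodes)), net@nodes)
  if (nrow(net@edges)) {
    t1 <- table(factor(as.character(net@edges$i), levels = names(deg)))
    t2 <- table(factor(as.character(net@edges$j), levels = names(deg)))
    deg <- deg + as.integer(t1) + as.integer(t2)
    names(deg) <- as.character(net@nodes)
  }
  deg
}

#' @rdname nodeDegree
#' @export
connectedComponents <- function(net) {
  if (length(net@nodes) == 0L) return(list())
  comp <- igraph::components(asIgraph(net))
  out <- split(net@nodes, comp$membership)
  out[order(-vapply(out, length, 0L))]
}

#' Louvain community detection
#'
#' Runs weighted Louvain modularity optimisation with a resolution
#' parameter (default 0.1, favouring a finer community structure than the
#' resolution-1 default) on the network.  The run is seeded and therefore
#' reproducible.
#'
#' @param net a non-empty [ColocationNetwork-class].
#' @param resolution resolution parameter of the modularity function.
#' @param seed RNG seed for the Louvain run.
#' @return a [CommunityPartition-class].
#' @export
detectCommunities <- function(net, resolution = 0.1, seed = 1L) {
  if (length(net@nodes) == 0L) stop("network is empty")
  g <- asIgraph(net)
  cl <- .withStream(seed, "louvain", {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution)
  })
  memb <- igraph::membership(cl)
  new("CommunityPartition",
      membership = setNames(as.integer(memb), names(memb)),
      resolution = resolution, seed = as.integer(seed),
      modularity = max(igraph::modularity(cl)))
}

#' @rdname communityAccessors
#' @param x a [CommunityPartition-class].
#' @return named integer vector: community ID per node (names are bin IDs).
#' @export
setMethod("communityMembership", "CommunityPartition",
          function(x) x@membership)

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", length(unique(object@membership)),
      "communities over", length(object@membership),
      "nodes (resolution", object@resolution,
      ", modularity", round(object@modularity, 4), ")\n")
})

#' Ego subnetwork of a node
#'
#' The node, its neighbors, and all network edges among them.
#'
#' @param net a [ColocationNetwork-class].
#' @param node a global bin ID present in the network.
#' @return a [ColocationNetwork-class].
#' @export
egoSubnetwork <- function(net, node) {
  node <- as.integer(node)
  if (!node %in% net@nodes) stop("node ", node, " is not in the network")
  nb <- c(net@edges$j[net@edges$i == node], net@edges$i[net@edges$j == node])
  keepNodes <- sort(unique(c(node, nb)))
  keep <- net@edges$i %in% keepNodes & net@edges$j %in% keepNodes
  new("ColocationNetwork", layout = net@layout, nodes = keepNodes,
      origin = net@origin[match(keepNodes, net@nodes)],
      edges = net@edges[keep, , drop = FALSE], dataset = net@dataset)
}

#' Shared nodes of two networks
#'
#' Intersection of the node sets of two networks over the same layout and
#' resolution, and the genomic span the shared bins cover.
#'
#' @param netA,netB [ColocationNetwork-class] objects at the same
#'   resolution.
#' @return list with `bins` (integer vector) and `spanMb` (numeric,
#'   `length(bins) * binSize / 1e6`).
#' @export
#' @examples
#' # 14 shared 80-kb bins cover 1.12 Mb; 527 cover 42.16 Mb
sharedNodes <- function(netA, netB) {
  if (binSize(netA@layout) != binSize(netB@layout))
    stop("networks have different resolutions")
  bins <- sort(intersect(netA@nodes, netB@nodes))
  list(bins = bins, spanMb = length(bins) * binSize(netA@layout) / 1e6)
}
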