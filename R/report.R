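#' @include targets.R
NULL

#' Genes residing within a set of network nodes
#'
#' Union over the node bins of interval-intersecting genes; a gene
#' spanning two member bins is counted once.
#'
#' @param nodes integer vector of global bin IDs.
#' @param genes gene table (BED-style).
#' @param layout the [GenomeLayout-class] matching the nodes' resolution.
#' @return character vector of unique gene names (sorted).
#' @export
genesInNodes <- function(nodes, genes, layout) {
  if (length(nodes) == 0L) return(character(0))
  bc <- binCoords(layout, as.integer(nodes))
  gr <- GenomicRanges::GRanges(bc$chrom,
          IRanges::IRanges(start = bc$start + 1, end = bc$end))
  hits <- .findOverlaps(.bedGRanges(genes), gr)
  sort(unique(genes$name[S4Vectors::queryHits(hits)]))
}

#' Hypergeometric GO term enrichment
#'
#' One-sided hypergeometric test per GO term: with N universe genes of
#' which K carry the term, and a query of n genes with k carrying it,
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n).  Terms are returned
#' sorted by ascending p.  No multiple-testing correction is applied by
#' default (raw p-values are reported); an optional Benjamini-Hochberg
#' column is available.
#'
#' @param query character vector of query gene names (must be a subset of
#'   the universe).
#' @param universe character vector of background gene names.
#' @param annotations gene table carrying `name` and semicolon-joined
#'   `go_terms` columns.
#' @param bh add a BH-adjusted p column?
#' @return data.table `term`, `k`, `K`, `n`, `N`, `p` (and `p_bh`),
#'   sorted by `p`; `overlap` lists the query genes carrying the term.
#' @export
goEnrichment <- function(query, universe, annotations, bh = FALSE) {
  if (length(universe) == 0L) stop("empty gene universe")
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  ann <- annotations[annotations$name %in% universe, ]
  terms <- strsplit(ann$go_terms, ";", fixed = TRUE)
  long <- data.table::data.table(
    name = rep(ann$name, lengths(terms)), term = unlist(terms))
  long <- long[nzchar(long$term)]
  if (nrow(long) == 0L)
    return(data.table::data.table(term = character(0), k = integer(0),
                                  K = integer(0), n = integer(0),
                                  N = integer(0), p = numeric(0),
                                  overlap = character(0)))
  N <- length(universe); n <- length(query)
  Ktab <- table(long$term)
  inq <- long[long$name %in% query]
  out <- data.table::data.table(term = names(Ktab),
                                K = as.integer(Ktab))
  ktab <- table(factor(inq$term, levels = names(Ktab)))
  out$k <- as.integer(ktab)
  out$n <- n; out$N <- N
  out$p <- phyper(out$k - 1, out$K, N - out$K, n, lower.tail = FALSE)
  out$overlap <- vapply(out$term, function(tm)
    paste(sort(unique(inq$name[inq$term == tm])), collapse = ","), "")
  if (bh) out$p_bh <- p.adjust(out$p, method = "BH")
  data.table::setorder(out, p, term)
  out[, c("term", "k", "K", "n", "N", "p",
          if (bh) "p_bh", "overlap"), with = FALSE]
}

#' Per-cluster report of a partitioned co-location network
#'
#' For every community of the partition: its nodes, the genes residing in
#' them, phenotype-flag tallies, per-gene SNP counts, GO enrichment
#' against the network-wide gene universe, and for the top term the count
#' of nodes harboring enriched genes out of the cluster's total nodes.
#'
#' @param partition a [CommunityPartition-class].
#' @param net the [ColocationNetwork-class] that was partitioned.
#' @param genes gene table with `phenotype` and `go_terms` columns.
#' @param snps optional SNP table (`chrom`, `pos`) for per-gene SNP
#'   counts.
#' @param universe GO background: `"network"` (genes in the network's
#'   nodes; default) or `"genome"` (all genes in the table).
#' @param maxTerms GO terms retained per cluster.
#' @return list with `summary` (one row per cluster) and `clusters`
#'   (named list of per-cluster details: `nodes`, `genes`, `phenotypes`,
#'   `enrichment`, `snpCountsPerGene`).
#' @export
clusterReport <- function(partition, net, genes, snps = NULL,
                          universe = c("network", "genome"),
                          maxTerms = 5L) {
  universe <- match.arg(universe)
  memb <- communityMembership(partition)
  if (!setequal(names(memb), as.character(networkNodes(net))))
    stop("partition does not match the network's node set")
  layout <- genomeLayout(net)
  uniGenes <- if (universe == "network")
    genesInNodes(networkNodes(net), genes, layout) else sort(genes$name)
  snpPerGene <- NULL
  if (!is.null(snps)) {
    hits <- .findOverlaps(.snpGRanges(snps), .bedGRanges(genes))
    cnt <- table(factor(S4Vectors::subjectHits(hits),
                        levels = seq_len(nrow(genes))))
    snpPerGene <- setNames(as.integer(cnt), genes$name)
  }
  ids <- sort(unique(memb))
  clusters <- lapply(ids, function(cid) {
    nodes <- as.integer(names(memb)[memb == cid])
    gset <- genesInNodes(nodes, genes, layout)
    phen <- table(factor(genes$phenotype[genes$name %in% gset],
                         levels = c("none", "long-lived", "short-lived",
                                    "increased-mortality", "lethal")))
    enr <- if (length(gset))
      head(goEnrichment(gset, uniGenes, genes), maxTerms)
    else data.table::data.table()
    nodesWithEnriched <- NA_integer_
    if (nrow(enr) > 0 && nzchar(enr$overlap[1])) {
      eg <- strsplit(enr$overlap[1], ",", fixed = TRUE)[[1]]
      gsub <- genes[genes$name %in% eg, ]
      nodesWithEnriched <- sum(vapply(nodes, function(b)
        length(genesInBin(b, gsub, layout)) > 0, NA))
    }
    list(id = cid, nodes = nodes, genes = gset,
         phenotypes = phen, enrichment = enr,
         nodesWithEnrichedGenes = nodesWithEnriched,
         snpCountsPerGene = if (is.null(snpPerGene)) NULL
                            else snpPerGene[gset])
  })
  names(clusters) <- paste0("cluster", ids)
  summary <- data.table::data.table(
    cluster = ids,
    n_nodes = vapply(clusters, function(cl) length(cl$nodes), 0L),
    n_genes = vapply(clusters, function(cl) length(cl$genes), 0L),
    n_long_lived = vapply(clusters, function(cl)
      as.integer(cl$phenotypes[["long-lived"]]), 0L),
    top_term = vapply(clusters, function(cl)
      if (nrow(cl$enrichment)) cl$enrichment$term[1] else NA_character_, ""),
    top_term_p = vapply(clusters, function(cl)
      if (nrow(cl$enrichment)) cl$enrichment$p[1] else NA_real_, 0),
    nodes_with_enriched = vapply(clusters, function(cl)
      cl$nodesWithEnrichedGenes, NA_integer_))
  list(summary = summary, clusters = clusters)
}
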