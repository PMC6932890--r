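#' @include report.R tad.R simulate.R io.R
NULL

#' Write a network as node and edge TSV files
#'
#' @param net a [ColocationNetwork-class].
#' @param prefix file path prefix; writes `<prefix>_nodes.tsv`
#'   (`bin`, `origin`, `degree`) and `<prefix>_edges.tsv`
#'   (`bin_i`, `bin_j`, `weight`, `origin_i`, `origin_j`).
#' @return invisibly, the two paths.
#' @export
writeNetwork <- function(net, prefix) {
  deg <- nodeDegree(net)
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  data.table::fwrite(data.table::data.table(
    bin = net@nodes, origin = net@origin, degree = as.integer(deg)),
    np, sep = "\t")
  org <- setNames(net@origin, net@nodes)
  data.table::fwrite(data.table::data.table(
    bin_i = net@edges$i, bin_j = net@edges$j, weight = net@edges$weight,
    origin_i = org[as.character(net@edges$i)],
    origin_j = org[as.character(net@edges$j)]), ep, sep = "\t")
  invisible(c(np, ep))
}

#' @rdname writeNetwork
#' @param partition a [CommunityPartition-class].
#' @param path output TSV path (`bin`, `community`).
#' @export
writePartition <- function(partition, path) {
  memb <- communityMembership(partition)
  data.table::fwrite(data.table::data.table(
    bin = as.integer(names(memb)), community = as.integer(memb)),
    path, sep = "\t")
  invisible(path)
}

# best per-bin GWAS score at a given resolution: max D or -log10 min p
.bestScorePerBin <- function(snps, layout) {
  b <- .globalBin(layout, snps$chrom, snps$pos)
  if (!is.null(snps$D)) {
    v <- tapply(snps$D, b, max)
  } else {
    v <- tapply(-log10(snps$pvalue), b, max)
  }
  setNames(as.numeric(v), names(v))
}

#' Run the full co-location analysis pipeline on synthetic inputs
#'
#' Generates all inputs under the config's seed, then runs every analysis
#' stage: D statistic and significance filtering for the
#' haplotype-frequency dataset, Bonferroni filtering for the p-value
#' dataset, coding/non-coding classification, 80-kb bin assignment,
#' top-percentile contact thresholding, original and extended network
#' construction, degrees/components, Louvain communities (resolution 0.1),
#' shared-node accounting, TAD-border SNP enrichment with matched random
#' controls, phenotype-gene border proximity, 10-kb long-range target-gene
#' mapping, and per-cluster GO enrichment reports.  All outputs are plain
#' TSV plus a run manifest; two runs with the same config are
#' byte-identical.
#'
#' @param config a [simConfig()] object (the seed lives here).
#' @param outDir output directory.
#' @param reps TAD control replicates (default 100).
#' @param resolution Louvain resolution (default 0.1).
#' @param topK long-range target pairs retained (default 30).
#' @param chromosomes named chromosome lengths (default [flyChromosomes()]).
#' @return invisibly, a list with every intermediate and final object.
#' @export
runPipeline <- function(config = simConfig(), outDir, reps = 100,
                        resolution = 0.1, topK = 30L,
                        chromosomes = flyChromosomes()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inDir <- file.path(outDir, "inputs")
  sim <- simulateAll(config, inDir, chromosomes = chromosomes)
  layout <- sim$layout; layout10 <- sim$layout10

  ## GWAS preprocessing
  synth <- combineDuplicateSnps(sim$snps$synthetic)
  synth <- addDStatistic(synth)
  synth <- classifyCoding(synth, sim$genes)
  synth <- assignBins(synth, layout)
  dgrp <- classifyCoding(sim$snps$dgrp, sim$genes)
  dgrp <- assignBins(dgrp, layout)

  polD <- significancePolicy("d", dCut = 7.9)
  polP <- significancePolicy("bonferroni", alpha = 0.05, m = nBins(layout))
  sigSynth <- selectSignificant(synth, polD)
  sigDgrp <- selectSignificant(dgrp, polP)

  ## networks
  thr <- computeThresholds(sim$contacts, q = 0.99)
  origS <- buildOriginalNetwork(unique(sigSynth$bin), sim$contacts, thr,
                                dataset = "synthetic")
  origD <- buildOriginalNetwork(unique(sigDgrp$bin), sim$contacts, thr,
                                dataset = "dgrp")
  extS <- extendNetwork(origS, sim$contacts, thr)
  extD <- extendNetwork(origD, sim$contacts, thr)
  commS <- detectCommunities(extS, resolution = resolution,
                             seed = config$seed)
  commD <- detectCommunities(extD, resolution = resolution,
                             seed = config$seed)
  sharedOrig <- sharedNodes(origS, origD)
  sharedExt <- sharedNodes(extS, extD)

  ## TAD border enrichment (p-value dataset, as the larger SNP panel)
  borders <- makeBorderRegions(sim$borders, flank = 100, layout)
  ncDgrp <- dgrp[!dgrp$coding]
  ncSynth <- synth[!synth$coding]
  tad <- tadEnrichment(ncDgrp, borders, layout, reps = reps,
                       seed = config$seed)
  borders$snp_count <- tad$perBorder
  proximity <- geneBorderProximity(
    sim$genes[sim$genes$phenotype %in% c("long-lived", "short-lived")],
    borders, layout10)

  ## 10-kb long-range target mapping
  binsS <- unique(.globalBin(layout10, ncSynth$chrom, ncSynth$pos))
  binsD <- unique(.globalBin(layout10, ncDgrp$chrom, ncDgrp$pos))
  pairsS <- rankLongRangePairs(binsS, sim$contacts10, topK = topK,
                               genes = sim$genes)
  pairsD <- rankLongRangePairs(binsD, sim$contacts10, topK = topK,
                               genes = sim$genes)
  scoreS <- .bestScorePerBin(ncSynth, layout10)
  scoreD <- .bestScorePerBin(ncDgrp, layout10)
  pairsS$best_score <- unname(scoreS[as.character(pairsS$snp_bin)])
  pairsD$best_score <- unname(scoreD[as.character(pairsD$snp_bin)])

  ## cluster reports
  repS <- clusterReport(commS, extS, sim$genes, snps = synth)
  repD <- clusterReport(commD, extD, sim$genes, snps = dgrp)

  ## outputs
  writeNetwork(origS, file.path(outDir, "network_synthetic_original"))
  writeNetwork(origD, file.path(outDir, "network_dgrp_original"))
  writeNetwork(extS, file.path(outDir, "network_synthetic_extended"))
  writeNetwork(extD, file.path(outDir, "network_dgrp_extended"))
  writePartition(commS, file.path(outDir, "communities_synthetic.tsv"))
  writePartition(commD, file.path(outDir, "communities_dgrp.tsv"))
  data.table::fwrite(pairsS, file.path(outDir, "targets_synthetic.tsv"),
                     sep = "\t")
  data.table::fwrite(pairsD, file.path(outDir, "targets_dgrp.tsv"),
                     sep = "\t")
  data.table::fwrite(repS$summary,
                     file.path(outDir, "clusters_synthetic.tsv"), sep = "\t")
  data.table::fwrite(repD$summary,
                     file.path(outDir, "clusters_dgrp.tsv"), sep = "\t")
  data.table::fwrite(proximity,
                     file.path(outDir, "border_proximity.tsv"), sep = "\t")
  enrTab <- data.table::data.table(
    dataset = "dgrp", obs_in = tad$obsIn, obs_total = nrow(ncDgrp),
    ctrl_in_mean = tad$ctrlInMean, odds_ratio = tad$oddsRatio,
    p = tad$p, log10p = tad$log10p,
    n_mutated_borders = tad$nMutatedBorders,
    synth_obs_in = countSnpsInRegions(ncSynth, borders)$total,
    synth_obs_total = nrow(ncSynth))
  data.table::fwrite(enrTab, file.path(outDir, "tad_enrichment.tsv"),
                     sep = "\t")

  ## run manifest (no timestamps: outputs must be byte-identical)
  cfgPath <- file.path(outDir, "config.txt")
  writeLines(paste(names(unlist(config)), unlist(config), sep = "\t"),
             cfgPath)
  manifest <- c(
    paste0("package: ColocNet ",
           as.character(utils::packageVersion("ColocNet"))),
    paste0("config_md5: ", unname(tools::md5sum(cfgPath))),
    paste0("seed: ", config$seed),
    paste0("bins_80kb: ", nBins(layout)),
    paste0("bins_10kb: ", nBins(layout10)))
  writeLines(manifest, file.path(outDir, "run_manifest.txt"))

  invisible(list(
    config = config, layout = layout, layout10 = layout10,
    snps = list(synthetic = synth, dgrp = dgrp),
    significant = list(synthetic = sigSynth, dgrp = sigDgrp),
    thresholds = thr,
    networks = list(originalSynthetic = origS, originalDgrp = origD,
                    extendedSynthetic = extS, extendedDgrp = extD),
    communities = list(synthetic = commS, dgrp = commD),
    shared = list(original = sharedOrig, extended = sharedExt),
    tad = tad, borders = borders, proximity = proximity,
    targets = list(synthetic = pairsS, dgrp = pairsD),
    reports = list(synthetic = repS, dgrp = repD)))
}
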