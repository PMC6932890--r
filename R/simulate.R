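#' @include utils.R
NULL

#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator with defaults that mirror the
#' study conditions the pipeline targets: a 1,503-bin 80-kb fly-like layout,
#' eight founder haplotypes, roughly one and two million SNPs in the
#' haplotype-frequency ("synthetic"-population) and p-value ("DGRP") tables
#' respectively, 2,847 TAD borders, and distance-decaying Hi-C contacts with
#' planted high-frequency modules.
#'
#' The haplotype-frequency noise model is: per SNP a founder-frequency base
#' vector b ~ Dirichlet(`dirichletAlpha`); old and young group vectors are
#' b plus independent sum-zero Gaussian noise (sd `noiseSd`), clipped to
#' `[0,1]` and renormalised (clipping is rare and logged).  Under this null
#' the divergence statistic D is `100*sqrt(2*noiseSd^2*X/n)` with
#' X ~ chi-squared(n-1), which provides an analytic tail rate.  In planted
#' bins the old-group vector is pulled toward one founder by `effectSize`,
#' so that the expected D comfortably exceeds the 7.9 significance cut.
#'
#' @param seed master seed; every generator derives its own RNG stream.
#' @param nFounders founder haplotype count n.
#' @param nSnps named vector: SNP counts for the `synthetic` and `dgrp`
#'   tables.
#' @param dirichletAlpha Dirichlet concentration of founder base
#'   frequencies.
#' @param noiseSd per-group Gaussian frequency noise sd.
#' @param effectSize planted pull toward one founder (0-1 scale).
#' @param plantedSignalBins global 80-kb bin IDs carrying planted GWAS
#'   signal (default: two bins in each planted module).
#' @param plantedFracSig fraction of planted-bin SNPs in the p-value table
#'   pushed below the Bonferroni cut.
#' @param plantedModules list of integer vectors: bin sets whose mutual
#'   contacts are boosted.
#' @param moduleBoost multiplicative contact boost within planted modules.
#' @param decayExponent power of the `(1+d)^-decay` intra-chromosomal
#'   distance decay.
#' @param intraScale expected contact frequency scale at distance 0.
#' @param interBase expected inter-chromosomal contact frequency.
#' @param sdLogContacts sdlog of multiplicative log-normal contact noise at
#'   80 kb resolution.
#' @param sdLogContacts10kb same, for the 10-kb intra-chromosomal matrix.
#' @param bandBins10kb maximum bin distance simulated in the 10-kb matrix.
#' @param plantedPairBoost contact boost of planted long-range 10-kb pairs.
#' @param nBorders TAD border count.
#' @param borderWidthRange range (bp) of border core widths.
#' @param borderMultiplier named vector: SNP-rate multiplier inside flanked
#'   borders for each dataset (1 = no enrichment).
#' @param nGenes gene count.
#' @param nPlantedGoGenes genes carrying the planted longevity GO term.
#' @return an object of class `SimConfig` (a validated list).
#' @export
simConfig <- function(seed = 1L,
                      nFounders = 8L,
                      nSnps = c(synthetic = 1e6, dgrp = 2e6),
                      dirichletAlpha = 50,
                      noiseSd = 0.03,
                      effectSize = 0.5,
                      plantedSignalBins = c(40L, 45L, 400L, 405L,
                                            700L, 705L, 1000L, 1005L),
                      plantedFracSig = 0.3,
                      plantedModules = list(40:49, 400:409, 700:709,
                                            1000:1009),
                      moduleBoost = 20,
                      decayExponent = 1,
                      intraScale = 600,
                      interBase = 2,
                      sdLogContacts = 1,
                      sdLogContacts10kb = 0.5,
                      bandBins10kb = 100L,
                      plantedPairBoost = 80,
                      nBorders = 2847L,
                      borderWidthRange = c(100L, 500L),
                      borderMultiplier = c(synthetic = 1, dgrp = 1.3),
                      nGenes = 15000L,
                      nPlantedGoGenes = 40L) {
  stopifnot(nFounders >= 2L, all(nSnps > 0),
            dirichletAlpha > 0, noiseSd >= 0,
            effectSize >= 0, effectSize <= 1,
            all(c("synthetic", "dgrp") %in% names(nSnps)),
            all(c("synthetic", "dgrp") %in% names(borderMultiplier)),
            decayExponent > 0, intraScale > 0, interBase >= 0,
            nBorders >= 1L, nGenes >= 1L,
            borderWidthRange[1] <= borderWidthRange[2])
  structure(list(
    seed = as.integer(seed), nFounders = as.integer(nFounders),
    nSnps = nSnps, dirichletAlpha = dirichletAlpha, noiseSd = noiseSd,
    effectSize = effectSize,
    plantedSignalBins = as.integer(plantedSignalBins),
    plantedFracSig = plantedFracSig,
    plantedModules = lapply(plantedModules, as.integer),
    moduleBoost = moduleBoost, decayExponent = decayExponent,
    intraScale = intraScale, interBase = interBase,
    sdLogContacts = sdLogContacts, sdLogContacts10kb = sdLogContacts10kb,
    bandBins10kb = as.integer(bandBins10kb),
    plantedPairBoost = plantedPairBoost,
    nBorders = as.integer(nBorders),
    borderWidthRange = as.integer(borderWidthRange),
    borderMultiplier = borderMultiplier,
    nGenes = as.integer(nGenes),
    nPlantedGoGenes = as.integer(nPlantedGoGenes)
  ), class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: seed", x$seed, "|", x$nFounders, "founders |",
      format(x$nSnps["synthetic"], big.mark = ","), "+",
      format(x$nSnps["dgrp"], big.mark = ","), "SNPs |",
      length(x$plantedModules), "planted modules |",
      x$nBorders, "borders |", x$nGenes, "genes\n")
  invisible(x)
}

#' Simulate a normalized Hi-C contact matrix
#'
#' Intra-chromosomal expected frequency follows a power-law distance decay
#' `intraScale * (1+d)^-decayExponent` (d = bin distance); inter-chromosomal
#' pairs sit at a low constant baseline.  All entries receive multiplicative
#' log-normal noise, producing the heavy upper tail that top-percentile
#' thresholding assumes.  Bin pairs inside a planted module (and explicitly
#' planted long-range pairs) have their expected frequency boosted
#' multiplicatively.  Self-contacts are generated but are excluded from all
#' downstream threshold computations.
#'
#' @param layout a [GenomeLayout-class].
#' @param config a [simConfig()] object.
#' @param intraOnly generate intra-chromosomal contacts only (used for the
#'   10-kb matrix, which ships intra contacts only).
#' @param bandBins maximum intra-chromosomal bin distance generated
#'   (`Inf` = all pairs).
#' @param plantedPairs optional data.frame (`bin_a`, `bin_b`, `boost`) of
#'   long-range pairs to boost; both bins must be intra-chromosomal
#'   partners within `bandBins`.
#' @param sdLog sdlog of the multiplicative noise; defaults to the config
#'   value appropriate for the resolution.
#' @return a [ContactMatrix-class].
#' @export
simulateContactMatrix <- function(layout, config, intraOnly = FALSE,
                                  bandBins = Inf, plantedPairs = NULL,
                                  sdLog = config$sdLogContacts) {
  nb <- nBins(layout)
  modules <- config$plantedModules
  if (length(modules) && !intraOnly) {
    allm <- unlist(modules)
    if (any(allm < 1L | allm > nb))
      stop("planted module references bin outside the layout")
  }
  rng <- binRangeOfChrom(layout)
  moduleId <- rep(NA_integer_, nb)
  if (!intraOnly)
    for (k in seq_along(modules)) moduleId[modules[[k]]] <- k

  .withStream(config$seed, paste0("contacts:", binSize(layout)), {
    ii <- jj <- integer(0); mu <- numeric(0)
    # intra pairs, chromosome by chromosome, distance band-limited
    for (ch in chromNames(layout)) {
      lo <- rng[ch, "first"]; hi <- rng[ch, "last"]
      n <- hi - lo + 1L
      dmax <- if (n < 2L) 0L else min(n - 1L, bandBins)
      for (d in seq_len(dmax)) {
        i <- lo:(hi - d)
        ii <- c(ii, i); jj <- c(jj, i + d)
        mu <- c(mu, rep(config$intraScale * (1 + d)^(-config$decayExponent),
                        length(i)))
      }
    }
    # planted-module boost (both endpoints in the same module)
    if (any(!is.na(moduleId))) {
      same <- !is.na(moduleId[ii]) & !is.na(moduleId[jj]) &
              moduleId[ii] == moduleId[jj]
      mu[same] <- mu[same] * config$moduleBoost
    }
    # explicit planted long-range pairs
    if (!is.null(plantedPairs) && nrow(plantedPairs)) {
      a <- pmin(plantedPairs$bin_a, plantedPairs$bin_b)
      b <- pmax(plantedPairs$bin_a, plantedPairs$bin_b)
      if (any(a < 1L | b > nb))
        stop("planted pair references bin outside the layout")
      key <- paste(ii, jj)
      hit <- match(paste(a, b), key)
      if (anyNA(hit))
        stop("planted pair outside the simulated contact band")
      mu[hit] <- mu[hit] * plantedPairs$boost
    }
    # inter-chromosomal baseline
    if (!intraOnly) {
      chs <- chromNames(layout)
      for (a in seq_along(chs)) for (b in seq_along(chs)) {
        if (b <= a) next
        ia <- rng[chs[a], "first"]:rng[chs[a], "last"]
        ib <- rng[chs[b], "first"]:rng[chs[b], "last"]
        ii <- c(ii, rep(ia, times = length(ib)))
        jj <- c(jj, rep(ib, each = length(ia)))
        mu <- c(mu, rep(config$interBase, length(ia) * length(ib)))
      }
    }
    # self-contacts (strongest; excluded from thresholding downstream)
    ii <- c(ii, seq_len(nb)); jj <- c(jj, seq_len(nb))
    mu <- c(mu, rep(2 * config$intraScale, nb))
    x <- mu * rlnorm(length(mu), meanlog = 0, sdlog = sdLog)
    mat <- Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = c(nb, nb),
                                symmetric = TRUE)
    new("ContactMatrix", layout = layout, mat = mat)
  })
}

# clip negative frequencies to zero and renormalise rows to sum 1;
# returns the matrix, reporting the number of clipped rows via attribute
.clipRenorm <- function(h) {
  neg <- h < 0
  nClipped <- sum(rowSums(neg) > 0)
  if (nClipped) h[neg] <- 0
  h <- h / rowSums(h)
  attr(h, "nClipped") <- nClipped
  h
}

# uniform 1-based positions across the genome, length-weighted
.uniformPositions <- function(layout, n) {
  len <- chromLengths(layout)
  chromIdx <- sample.int(length(len), n, replace = TRUE,
                         prob = len / sum(len))
  pos <- ceiling(runif(n) * len[chromIdx])
  pos[pos < 1] <- 1
  data.table::data.table(chrom = names(len)[chromIdx], pos = as.numeric(pos))
}

# extra positions placed uniformly inside flanked border regions
.borderPositions <- function(bordersFlanked, n) {
  w <- bordersFlanked$end - bordersFlanked$start
  idx <- sample.int(nrow(bordersFlanked), n, replace = TRUE,
                    prob = w / sum(w))
  pos <- bordersFlanked$start[idx] + ceiling(runif(n) * w[idx])
  data.table::data.table(chrom = bordersFlanked$chrom[idx],
                         pos = as.numeric(pos))
}

#' Simulate GWAS SNP summary tables
#'
#' Produces the two SNP tables the pipeline consumes: a
#' haplotype-frequency table (per-founder frequencies for the old and young
#' groups, each row's group vectors summing to 1) and a p-value table.
#' SNP positions are uniform across the genome; SNPs falling in planted
#' signal bins carry a frequency shift (respectively depressed p-values) so
#' the planted bins are recoverable downstream.  When a border table is
#' supplied, extra SNPs are placed inside flanked border regions at the
#' configured rate multiplier, emulating border SNP enrichment.
#'
#' @param layout a [GenomeLayout-class] (80-kb resolution).
#' @param config a [simConfig()] object.
#' @param borders optional border table (as from [simulateAnnotations()]);
#'   needed only when a `borderMultiplier` exceeds 1.
#' @return list with `synthetic` and `dgrp` data.tables.  The synthetic
#'   table has columns `chrom`, `pos`, `id`, `hO_1..hO_n`, `hY_1..hY_n`;
#'   the dgrp table `chrom`, `pos`, `id`, `pvalue`.
#' @export
simulateGwasTables <- function(layout, config, borders = NULL) {
  k <- config$nFounders
  planted <- config$plantedSignalBins
  if (length(planted) && any(planted < 1L | planted > nBins(layout)))
    stop("planted signal bin outside the layout")
  flanked <- if (!is.null(borders))
    data.table::data.table(chrom = borders$chrom,
                           start = pmax(borders$start - 100, 0),
                           end = borders$end + 100)

  synth <- .withStream(config$seed, "gwas:synthetic", {
    n0 <- as.integer(config$nSnps[["synthetic"]])
    tab <- .uniformPositions(layout, n0)
    mult <- config$borderMultiplier[["synthetic"]]
    if (!is.null(flanked) && mult > 1) {
      frac <- sum(flanked$end - flanked$start) / sum(chromLengths(layout))
      nx <- round(n0 * frac * (mult - 1))
      if (nx > 0) tab <- rbind(tab, .borderPositions(flanked, nx))
    }
    data.table::setorder(tab, chrom, pos)
    n <- nrow(tab)
    b <- .rdirichlet(n, config$dirichletAlpha, k)
    noise <- function() {
      e <- matrix(rnorm(n * k, sd = config$noiseSd), n, k)
      e - rowMeans(e)
    }
    hY <- .clipRenorm(b + noise())
    hO <- b + noise()
    bin <- .globalBin(layout, tab$chrom, tab$pos)
    inPlant <- bin %in% planted
    if (any(inPlant)) {
      # per planted bin, pull the old group toward one founder
      founderOfBin <- setNames(sample.int(k, length(planted), replace = TRUE),
                               planted)
      jstar <- founderOfBin[as.character(bin[inPlant])]
      d <- config$effectSize
      hOp <- hO[inPlant, , drop = FALSE] * (1 - d)
      hOp[cbind(seq_len(nrow(hOp)), jstar)] <-
        hOp[cbind(seq_len(nrow(hOp)), jstar)] + d
      hO[inPlant, ] <- hOp
    }
    hO <- .clipRenorm(hO)
    nc <- attr(hY, "nClipped") + attr(hO, "nClipped")
    if (nc > 0)
      message("simulateGwasTables: clipped-and-renormalised ", nc,
              " haplotype frequency vectors")
    colnames(hO) <- paste0("hO_", seq_len(k))
    colnames(hY) <- paste0("hY_", seq_len(k))
    cbind(data.table::data.table(chrom = tab$chrom, pos = tab$pos,
                                 id = sprintf("snpS%07d", seq_len(n))),
          data.table::as.data.table(hO), data.table::as.data.table(hY))
  })

  dgrp <- .withStream(config$seed, "gwas:dgrp", {
    n0 <- as.integer(config$nSnps[["dgrp"]])
    tab <- .uniformPositions(layout, n0)
    mult <- config$borderMultiplier[["dgrp"]]
    if (!is.null(flanked) && mult > 1) {
      frac <- sum(flanked$end - flanked$start) / sum(chromLengths(layout))
      nx <- round(n0 * frac * (mult - 1))
      if (nx > 0) tab <- rbind(tab, .borderPositions(flanked, nx))
    }
    data.table::setorder(tab, chrom, pos)
    n <- nrow(tab)
    p <- runif(n)
    bin <- .globalBin(layout, tab$chrom, tab$pos)
    inPlant <- which(bin %in% planted)
    if (length(inPlant)) {
      hit <- inPlant[runif(length(inPlant)) < config$plantedFracSig]
      cut <- 0.05 / nBins(layout)
      p[hit] <- runif(length(hit)) * 0.1 * cut
    }
    data.table::data.table(chrom = tab$chrom, pos = tab$pos,
                           id = sprintf("snpD%07d", seq_len(n)),
                           pvalue = p)
  })

  list(synthetic = synth, dgrp = dgrp)
}

#' Simulate TAD borders and gene annotations
#'
#' Borders are pairwise-disjoint intervals (disjoint even after ±100 bp
#' flanking), allocated to chromosomes proportionally to length.  Genes are
#' intervals carrying a phenotype flag and a GO term set drawn from a fixed
#' vocabulary; genes annotated with the planted longevity term
#' (`"determination of adult lifespan"`) are concentrated inside the planted
#' contact modules so that cluster-level GO enrichment has a recoverable
#' truth.
#'
#' @param layout a [GenomeLayout-class].
#' @param config a [simConfig()] object.
#' @return list with data.tables `borders` (`chrom`, `start`, `end`,
#'   `name`; BED-style 0-based half-open) and `genes` (`chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `phenotype`, `go_terms`).
#' @export
simulateAnnotations <- function(layout, config) {
  .withStream(config$seed, "annotations", {
    len <- chromLengths(layout)
    nb <- config$nBorders
    perChrom <- floor(nb * len / sum(len))
    rem <- nb - sum(perChrom)
    if (rem > 0) {
      extra <- order(nb * len / sum(len) - perChrom, decreasing = TRUE)
      perChrom[extra[seq_len(rem)]] <- perChrom[extra[seq_len(rem)]] + 1L
    }
    bs <- lapply(names(len), function(ch) {
      need <- perChrom[[ch]]
      if (need == 0L) return(NULL)
      kept <- data.table::data.table(start = numeric(0), end = numeric(0))
      for (round in 1:100) {
        if (nrow(kept) >= need) break
        w <- sample(config$borderWidthRange[1]:config$borderWidthRange[2],
                    need * 2L, replace = TRUE)
        st <- floor(runif(need * 2L) * (len[[ch]] - w - 200)) + 100
        cand <- rbind(kept, data.table::data.table(start = st, end = st + w))
        data.table::setorder(cand, start)
        # greedy keep with a >=200 bp gap so flanked (+/-100 bp) regions
        # stay disjoint too
        keep <- logical(nrow(cand)); lastEnd <- -Inf
        for (r in seq_len(nrow(cand))) {
          if (cand$start[r] >= lastEnd + 201) {
            keep[r] <- TRUE; lastEnd <- cand$end[r]
          }
        }
        kept <- cand[keep]
      }
      if (nrow(kept) < need)
        stop("could not place ", need, " disjoint borders on ", ch)
      out <- kept[seq_len(need)]
      out$chrom <- ch
      out
    })
    borders <- data.table::rbindlist(bs)[, c("chrom", "start", "end")]
    data.table::setorder(borders, chrom, start)
    borders$name <- sprintf("border%04d", seq_len(nrow(borders)))

    ng <- config$nGenes
    glen <- pmin(pmax(round(rlnorm(ng, log(2000), 0.8)), 200), 50000)
    chromIdx <- sample.int(length(len), ng, replace = TRUE,
                           prob = len / sum(len))
    gst <- floor(runif(ng) * (len[chromIdx] - glen))
    genes <- data.table::data.table(chrom = names(len)[chromIdx],
                                    start = gst, end = gst + glen)
    # GO vocabulary; the first term is the planted longevity term
    vocab <- c("determination of adult lifespan", "apoptotic process",
               "DNA repair", "immune system process",
               "nervous system development", "cellular response to stress",
               "localization", "cell communication",
               "macromolecule modification", "cellular catabolic process",
               "developmental process", "gene expression",
               "response to stimulus", "organelle assembly",
               "open tracheal system development", "nervous system process",
               "regulation of immune system process", "development growth",
               "positive regulation of gene expression",
               "negative regulation of transcription")
    nTerms <- pmin(rpois(ng, 2), length(vocab) - 1L)
    goSets <- lapply(nTerms, function(m)
      if (m == 0L) character(0) else sample(vocab[-1L], m))
    # planted longevity genes: concentrated inside planted module bins
    npg <- min(config$nPlantedGoGenes, ng)
    if (npg > 0) {
      pick <- sample.int(ng, npg)
      moduleBins <- unlist(config$plantedModules)
      moduleBins <- moduleBins[moduleBins <= nBins(layout)]
      nIn <- ceiling(0.85 * npg)
      if (length(moduleBins)) {
        binPick <- sample(moduleBins, nIn, replace = TRUE)
        bc <- binCoords(layout, binPick)
        glenIn <- pmin(glen[pick[seq_len(nIn)]], bc$end - bc$start - 1)
        st <- bc$start + floor(runif(nIn) * (bc$end - bc$start - glenIn))
        genes$chrom[pick[seq_len(nIn)]] <- bc$chrom
        genes$start[pick[seq_len(nIn)]] <- st
        genes$end[pick[seq_len(nIn)]] <- st + glenIn
      }
      for (g in pick) goSets[[g]] <- c(vocab[1L], goSets[[g]])
    }
    genes$name <- sprintf("gene%05d", seq_len(ng))
    genes$score <- 0L
    genes$strand <- "."
    genes$phenotype <- sample(c("none", "long-lived", "short-lived",
                                "increased-mortality", "lethal"),
                              ng, replace = TRUE,
                              prob = c(0.90, 0.03, 0.03, 0.03, 0.01))
    genes$go_terms <- vapply(goSets, paste, "", collapse = ";")
    data.table::setorder(genes, chrom, start)
    list(borders = borders, genes = genes)
  })
}

#' Default planted long-range 10-kb target pairs
#'
#' Picks deterministic SNP-harboring bins and partner bins at 50 kb
#' (distance 5 bins) and 100 kb (10 bins) on several chromosomes, matching
#' the long-range distances the target-mapping stage is designed to
#' recover.
#'
#' @param layout10kb a 10-kb [GenomeLayout-class].
#' @param boost contact boost factor for the planted pairs.
#' @return data.frame with columns `bin_a`, `bin_b`, `boost`.
#' @export
defaultPlantedPairs <- function(layout10kb, boost = 80) {
  rng <- binRangeOfChrom(layout10kb)
  chs <- chromNames(layout10kb)
  dist <- c(5L, 5L, 5L, 10L, 10L, 10L)
  pick <- rep(chs, length.out = length(dist))
  a <- integer(0); b <- integer(0)
  for (q in seq_along(dist)) {
    lo <- rng[pick[q], "first"]; hi <- rng[pick[q], "last"]
    base <- lo + min(500L + 137L * q, hi - lo - dist[q] - 1L)
    a <- c(a, base); b <- c(b, base + dist[q])
  }
  data.frame(bin_a = a, bin_b = b, boost = boost)
}

#' Generate and write the full synthetic input set
#'
#' Runs every generator under its own seeded stream and writes the pipeline
#' input files to `outDir`: 80-kb and 10-kb layout sidecars, contact
#' triplets at both resolutions, the two SNP tables, and the border and
#' gene BED-style tables.  Byte-identical across runs with the same config.
#'
#' @param config a [simConfig()] object.
#' @param outDir output directory (created if needed).
#' @param chromosomes named chromosome lengths (default [flyChromosomes()]).
#' @return invisibly, a list of the generated in-memory objects and file
#'   paths.
#' @export
simulateAll <- function(config = simConfig(), outDir,
                        chromosomes = flyChromosomes()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  layout <- makeGenomeLayout(chromosomes, 80000)
  layout10 <- makeGenomeLayout(chromosomes, 10000)
  ann <- simulateAnnotations(layout, config)
  gwas <- simulateGwasTables(layout, config, borders = ann$borders)
  cm <- simulateContactMatrix(layout, config)
  pairs10 <- defaultPlantedPairs(layout10, boost = config$plantedPairBoost)
  cm10 <- simulateContactMatrix(layout10, config, intraOnly = TRUE,
                                bandBins = config$bandBins10kb,
                                plantedPairs = pairs10,
                                sdLog = config$sdLogContacts10kb)
  paths <- list(
    layout = writeLayout(layout, file.path(outDir, "layout_80kb.tsv")),
    layout10 = writeLayout(layout10, file.path(outDir, "layout_10kb.tsv")),
    contacts = writeContacts(cm, file.path(outDir, "contacts_80kb.tsv")),
    contacts10 = writeContacts(cm10, file.path(outDir, "contacts_10kb.tsv")),
    synthetic = writeSnpTable(gwas$synthetic,
                              file.path(outDir, "snps_synthetic.tsv")),
    dgrp = writeSnpTable(gwas$dgrp, file.path(outDir, "snps_dgrp.tsv")),
    borders = writeBedTable(ann$borders, file.path(outDir, "borders.tsv")),
    genes = writeBedTable(ann$genes, file.path(outDir, "genes.tsv")))
  invisible(list(layout = layout, layout10 = layout10,
                 contacts = cm, contacts10 = cm10,
                 snps = gwas, borders = ann$borders, genes = ann$genes,
                 plantedPairs = pairs10, paths = paths))
}
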