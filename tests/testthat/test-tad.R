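test_that("border regions gain 100-bp flanks clamped to the chromosome", {
  lay <- toyLayout(4e6, 4e6)
  b <- data.table::data.table(chrom = c("A", "A", "B"),
                              start = c(1000, 50, 3999500),
                              end = c(1100, 150, 3999990))
  out <- makeBorderRegions(b, flank = 100, lay)
  expect_equal(out$flank_start, c(900, 0, 3999400))
  expect_equal(out$flank_end, c(1200, 250, 4e6))
  # unclamped widths are core + 200
  set.seed(8)
  st <- sort(sample(1000:3e6, 50)) * 1.0
  bb <- data.table::data.table(chrom = "A", start = st, end = st + 120)
  ob <- makeBorderRegions(bb, flank = 100, lay)
  expect_true(all(ob$flank_end - ob$flank_start ==
                  (ob$end - ob$start) + 200))
  expect_error(makeBorderRegions(
    data.table::data.table(chrom = "A", start = -5, end = 10), 100, lay),
    "outside chromosome")
})

test_that("SNP counting in regions is exact on hand-placed fixtures", {
  regions <- data.table::data.table(chrom = "A",
                                    start = c(100, 500), end = c(200, 600))
  none <- data.table::data.table(chrom = character(0), pos = numeric(0))
  expect_equal(countSnpsInRegions(none, regions)$total, 0L)
  snps <- data.table::data.table(chrom = "A",
                                 pos = c(150, 550, 300, 700, 90))
  out <- countSnpsInRegions(snps, regions)
  expect_equal(out$perRegion, c(1L, 1L))
  expect_equal(out$total, 2L)
  # half-open convention: position end is outside, start+1 is the first in
  edge <- data.table::data.table(chrom = "A", pos = c(100, 101, 200, 201))
  oe <- countSnpsInRegions(edge, regions[1])
  expect_equal(oe$total, 2L)  # 1-based positions 101..200 fall in [100,200)
})

test_that("control borders preserve structure and avoid real borders", {
  lay <- toyLayout(2e6, 1e6)
  set.seed(3)
  stA <- sort(sample(seq(1000, 1.9e6, by = 4000), 30))
  stB <- sort(sample(seq(1000, 0.9e6, by = 4000), 15))
  b <- data.table::data.table(chrom = rep(c("A", "B"), c(30, 15)),
                              start = c(stA, stB) * 1.0,
                              end = c(stA + 300, stB + 300) * 1.0)
  borders <- makeBorderRegions(b, 100, lay)
  ctrl <- sampleControlBorders(borders, lay, reps = 5, seed = 11)
  ctrl2 <- sampleControlBorders(borders, lay, reps = 5, seed = 11)
  expect_identical(ctrl, ctrl2)
  realGr <- GenomicRanges::GRanges(borders$chrom,
              IRanges::IRanges(borders$flank_start + 1, borders$flank_end))
  for (cb in ctrl) {
    expect_equal(table(cb$chrom), table(borders$chrom))
    expect_equal(cb$end - cb$start, borders$end - borders$start)
    cg <- GenomicRanges::GRanges(cb$chrom,
            IRanges::IRanges(cb$flank_start + 1, cb$flank_end))
    expect_equal(sum(IRanges::overlapsAny(cg, realGr)), 0L)
  }
})

test_that("mean control count matches the analytic uniform expectation", {
  lay <- toyLayout(2e6, 2e6)
  set.seed(5)
  st <- sort(sample(seq(2000, 1.9e6, by = 10000), 60))
  b <- data.table::data.table(chrom = rep(c("A", "B"), each = 30),
                              start = rep(st[1:30], 2) * 1.0,
                              end = rep(st[1:30] + 200, 2) * 1.0)
  borders <- makeBorderRegions(b, 100, lay)
  nsnp <- 40000
  snps <- data.table::data.table(
    chrom = sample(c("A", "B"), nsnp, replace = TRUE),
    pos = ceiling(runif(nsnp) * 2e6))
  ctrl <- sampleControlBorders(borders, lay, reps = 100, seed = 4)
  counts <- vapply(ctrl, function(cb) countSnpsInRegions(snps, cb)$total, 0)
  footprint <- sum(borders$flank_end - borders$flank_start)
  expected <- nsnp * footprint / sum(chromLengths(lay))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("Fisher enrichment matches exhaustive enumeration and edge cases", {
  # no observed SNPs in regions, one-sided greater -> p = 1
  expect_equal(fisherEnrichment(0, 10, 3, 10)$p, 1)
  # 3/10 vs 0/10 equals the brute-force hypergeometric enumeration
  fe <- fisherEnrichment(3, 10, 0, 10)
  expect_equal(fe$p, oracleFisherGreater(3, 10, 0, 10), tolerance = 1e-12)
  expect_error(fisherEnrichment(5, 3, 1, 10), "negative")
  # fractional averaged control counts are rounded half-up
  expect_equal(fisherEnrichment(5, 20, 2.5, 20)$table[2, 1], 3)
  expect_equal(fisherEnrichment(5, 20, 2.49, 20)$table[2, 1], 2)
})

test_that("gene classes reflect mutation status of nearby borders", {
  lay10 <- makeGenomeLayout(c(A = 1e6), 10000)
  borders <- data.table::data.table(
    chrom = "A", start = c(105000, 505000), end = c(105200, 505200),
    flank_start = c(104900, 504900), flank_end = c(105300, 505300),
    snp_count = c(3L, 0L))
  # windows: bins around 100-110 kb (mutated) and 500-510 kb (clean),
  # each widened by one 10-kb bin on each side
  genes <- data.table::data.table(
    chrom = "A",
    start = c(95000, 515000, 100000, 700000),
    end = c(97000, 518000, 515500, 710000),
    name = c("nearMut", "nearClean", "spansBoth", "far"))
  out <- geneBorderProximity(genes, borders, lay10)
  expect_equal(out$class[out$name == "nearMut"], "mutated-only")
  expect_equal(out$class[out$name == "nearClean"], "nonmutated-only")
  expect_equal(out$class[out$name == "spansBoth"], "both")
  expect_equal(out$class[out$name == "far"], "none")
  expect_error(geneBorderProximity(genes, borders[, -"snp_count"], lay10),
               "snp_count")
})

test_that("tadEnrichment detects planted border enrichment end to end", {
  lay <- toyLayout(4e6, 4e6)
  cfg <- toyConfig(seed = 21, nBorders = 60L,
                   borderMultiplier = c(synthetic = 1, dgrp = 3),
                   nSnps = c(synthetic = 100, dgrp = 30000))
  ann <- simulateAnnotations(lay, cfg)
  gw <- simulateGwasTables(lay, cfg, borders = ann$borders)
  borders <- makeBorderRegions(ann$borders, 100, lay)
  res <- tadEnrichment(gw$dgrp, borders, lay, reps = 20, seed = 2)
  expect_gt(res$obsIn, res$ctrlInMean)
  expect_lt(res$p, 1e-6)
  expect_gt(res$nMutatedBorders, 0)
})
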