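test_that("computeD matches closed forms and handles errors", {
  expect_equal(computeD(rep(0.3, 5), rep(0.3, 5)), 0)
  # n = 8, every |difference| = 0.1 -> 100*sqrt(8*0.01/8) = 10
  expect_equal(computeD(rep(0.15, 8), rep(0.25, 8)), 10)
  expect_error(computeD(numeric(0), numeric(0)), "empty")
  expect_error(computeD(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(computeD(c(1.5, -0.5), c(0.5, 0.5)), "\\[0, 1\\]")
})

test_that("computeD agrees with the brute-force oracle and is invariant", {
  set.seed(42)
  for (r in 1:200) {
    n <- sample(2:10, 1)
    hO <- runif(n); hO <- hO / sum(hO)
    hY <- runif(n); hY <- hY / sum(hY)
    expect_equal(computeD(hO, hY), oracleD(hO, hY), tolerance = 1e-12)
    # permutation of founder indices leaves D unchanged
    p <- sample(n)
    expect_equal(computeD(hO[p], hY[p]), computeD(hO, hY))
    # scaling all differences by c in [0,1] scales D by c
    cc <- runif(1)
    mid <- (hO + hY) / 2
    expect_equal(computeD(mid + cc * (hO - mid), mid + cc * (hY - mid)),
                 cc * computeD(hO, hY), tolerance = 1e-12)
  }
})

test_that("addDStatistic reproduces per-row computeD including NA padding", {
  tab <- data.table::data.table(chrom = "A", pos = c(10, 20), id = c("a", "b"),
    hO_1 = c(0.5, 0.2), hO_2 = c(0.5, 0.3), hO_3 = c(NA, 0.5),
    hY_1 = c(0.4, 0.2), hY_2 = c(0.6, 0.5), hY_3 = c(NA, 0.3))
  out <- addDStatistic(tab)
  expect_equal(out$D[1], computeD(c(0.5, 0.5), c(0.4, 0.6)))
  expect_equal(out$D[2], computeD(c(0.2, 0.3, 0.5), c(0.2, 0.5, 0.3)))
})

test_that("duplicate SNPs combine into a single renormalised record", {
  mk <- function(pos, hO, hY, id) {
    row <- data.table::data.table(chrom = "A", pos = pos, id = id)
    for (q in seq_along(hO)) row[[paste0("hO_", q)]] <- hO[q]
    for (q in seq_along(hO)) row[[paste0("hY_", q)]] <- hY[q]
    row
  }
  # no duplicates: output = input
  tab <- rbind(mk(10, c(0.5, 0.5), c(0.4, 0.6), "x"),
               mk(20, c(0.1, 0.9), c(0.2, 0.8), "y"))
  expect_equal(as.data.frame(combineDuplicateSnps(tab)), as.data.frame(tab))

  # duplicate with n=7 and n=8 vectors -> combined n=15, groups sum to 1
  h7 <- runif(7); h7 <- h7 / sum(h7)
  h8 <- runif(8); h8 <- h8 / sum(h8)
  y7 <- runif(7); y7 <- y7 / sum(y7)
  y8 <- runif(8); y8 <- y8 / sum(y8)
  tab <- rbind(mk(10, c(h7, NA), c(y7, NA), "x"),
               mk(10, h8, y8, "x2"))
  out <- suppressMessages(combineDuplicateSnps(tab))
  expect_equal(nrow(out), 1L)
  oc <- grep("^hO_", names(out), value = TRUE)
  expect_equal(length(oc), 15L)
  expect_equal(sum(unlist(out[, oc, with = FALSE]), na.rm = TRUE), 1,
               tolerance = 1e-9)
  yc <- grep("^hY_", names(out), value = TRUE)
  expect_equal(sum(unlist(out[, yc, with = FALSE]), na.rm = TRUE), 1,
               tolerance = 1e-9)

  # three-way duplicate -> single record, n = 6
  tab <- rbind(mk(10, c(0.5, 0.5), c(0.4, 0.6), "a"),
               mk(10, c(0.2, 0.8), c(0.3, 0.7), "b"),
               mk(10, c(0.9, 0.1), c(0.8, 0.2), "c"),
               mk(30, c(0.5, 0.5), c(0.5, 0.5), "d"))
  out <- suppressMessages(combineDuplicateSnps(tab))
  expect_equal(nrow(out), 2L)
  first <- out[out$pos == 10]
  expect_equal(sum(!is.na(unlist(first[, grep("^hO_", names(first)),
                                       with = FALSE]))), 6L)
})

test_that("bonferroni thresholds are alpha/m with input validation", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.01, 4), 0.0025)
  expect_error(bonferroniThreshold(0, 10))
  expect_error(bonferroniThreshold(0.05, 0))
})

test_that("significance selection uses strict cuts and is idempotent", {
  tab <- data.table::data.table(id = letters[1:5],
                                D = c(12.009, 7.9, 3.2, 8.0, 7.8999))
  pol <- significancePolicy("d", dCut = 7.9)
  out <- selectSignificant(tab, pol)
  # strict ">": 7.9 itself is excluded; the printed D = 12.009 example passes
  expect_equal(out$id, c("a", "d"))
  expect_equal(selectSignificant(out, pol), out)
  expect_equal(nrow(selectSignificant(tab[0], pol)), 0L)

  ptab <- data.table::data.table(id = letters[1:4],
    pvalue = c(1e-6, 0.05 / 1503, 3.3e-5, 0.5))
  polp <- significancePolicy("bonferroni", alpha = 0.05, m = 1503)
  outp <- selectSignificant(ptab, polp)
  expect_equal(outp$id, c("a", "c"))   # boundary p = alpha/m excluded
  expect_error(selectSignificant(tab[, .(id)], pol), "D column")
  expect_error(significancePolicy("bonferroni"), "requires")
})

test_that("coding classification uses closed gene intervals", {
  genes <- data.table::data.table(chrom = c("A", "A", "A"),
                                  start = c(100, 150, 1000),
                                  end = c(200, 250, 2000),
                                  name = c("g1", "g2", "g3"))
  snps <- data.table::data.table(chrom = c("A", "A", "A", "A", "B"),
                                 pos = c(50, 180, 101, 2000, 10),
                                 id = paste0("s", 1:5))
  out <- suppressMessages(classifyCoding(snps, genes))
  expect_equal(out$coding, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$gene_ids[2], "g1,g2")   # two overlapping genes
  expect_equal(out$gene_ids[3], "g1")      # exactly at a gene start
  expect_equal(out$gene_ids[4], "g3")      # exactly at a gene end
  # coding + non-coding partition the SNP set
  expect_equal(sum(out$coding) + sum(!out$coding), nrow(snps))
})

test_that("bin assignment follows the half-open window convention", {
  lay <- makeGenomeLayout(flyChromosomes(), 80000)
  snps <- data.table::data.table(
    chrom = c("2L", "2R", "2L", "2L"),
    pos = c(1, 1, 80000, 80001))
  out <- assignBins(snps, lay)
  expect_equal(out$bin, c(1L, 288L, 1L, 2L))
  expect_error(assignBins(data.table::data.table(chrom = "2L", pos = 3e7),
                          lay), "beyond chromosome end")
  expect_error(assignBins(data.table::data.table(chrom = "nope", pos = 1),
                          lay), "absent from layout")
  # every SNP maps to exactly one bin; occupancy sums to the SNP count
  set.seed(1)
  rnd <- data.table::data.table(chrom = "2L", pos = sample.int(2e7, 500))
  outr <- assignBins(rnd, lay)
  expect_equal(sum(table(outr$bin)), 500L)
})
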