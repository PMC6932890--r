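test_that("tail thresholds follow the strictly-greater order statistic", {
  lay <- makeGenomeLayout(c(A = 8e5), 8e4)   # 10 bins
  # all entries equal 5 -> tau = 5, nothing is "strong"
  pairs <- t(combn(1:10, 2))
  cm <- makeCM(lay, pairs[, 1], pairs[, 2], rep(5, nrow(pairs)))
  thr <- computeThresholds(cm, q = 0.99)
  expect_equal(unname(thr@intra["A"]), 5)
  expect_equal(nrow(ColocNet:::.strongEntries(cm, thr)), 0L)

  # 1000 distinct values 1..1000 at q = 0.99 -> tau = 990, 10 exceed it
  lay2 <- makeGenomeLayout(c(A = 50 * 8e4), 8e4)
  pr <- t(combn(1:50, 2))[1:1000, ]
  cm2 <- makeCM(lay2, pr[, 1], pr[, 2], sample(1:1000))
  thr2 <- computeThresholds(cm2, q = 0.99)
  expect_equal(unname(thr2@intra["A"]), 990)
  expect_equal(sum(contactEntries(cm2)$f > 990), 10L)

  # a chromosome with no positive entries is an error
  lay3 <- toyLayout()
  cm3 <- makeCM(lay3, 1, 2, 7)   # only chromosome A has entries
  expect_error(computeThresholds(cm3), "no positive intra")
})

test_that("thresholds match the sort-and-count oracle on random matrices", {
  set.seed(99)
  for (r in 1:30) {
    nb <- sample(6:12, 1)
    lay <- makeGenomeLayout(c(A = nb * 8e4, B = 10 * 8e4), 8e4)
    total <- nBins(lay)
    pairs <- t(combn(seq_len(total), 2))
    keep <- runif(nrow(pairs)) < 0.8
    pairs <- pairs[keep, , drop = FALSE]
    vals <- round(rlnorm(nrow(pairs), 3, 1), 3)
    cm <- makeCM(lay, pairs[, 1], pairs[, 2], vals)
    q <- sample(c(0.9, 0.95, 0.99), 1)
    thr <- computeThresholds(cm, q = q)
    tr <- contactEntries(cm)
    tr <- tr[tr$f > 0, ]
    chi <- binChrom(lay, tr$i); chj <- binChrom(lay, tr$j)
    for (g in c("A", "B")) {
      vg <- tr$f[chi == g & chj == g]
      expect_equal(unname(thr@intra[g]), oracleTailThreshold(vg, q))
    }
    expect_equal(thr@inter, oracleTailThreshold(tr$f[chi != chj], q))
  }
})

test_that("arm pooling yields one threshold per numbered chromosome", {
  lay <- makeGenomeLayout(c("2L" = 4e5, "2R" = 4e5, "X" = 4e5), 8e4)
  pairs <- t(combn(1:15, 2))
  set.seed(1)
  cm <- makeCM(lay, pairs[, 1], pairs[, 2], runif(nrow(pairs), 1, 100))
  thr <- computeThresholds(cm, q = 0.9)
  expect_setequal(names(thr@intra), c("2", "X"))
  # cross-arm 2L-2R entries are intra under the default pooling
  cls <- ColocNet:::.pairClass(lay, 3, 8, "intra")
  expect_true(cls$isIntra)
  cls2 <- ColocNet:::.pairClass(lay, 3, 8, "inter")
  expect_false(cls2$isIntra)
})

test_that("original network keeps isolated significant bins and strong edges", {
  lay <- makeGenomeLayout(c(A = 8e5), 8e4)
  thr <- makeThr(c(A = 10), NA_real_)
  cm <- makeCM(lay, c(1, 1), c(2, 3), c(20, 5))  # f(1,2)=2*tau, f(1,3)=tau/2
  net <- buildOriginalNetwork(c(1, 2, 3), cm, thr)
  expect_equal(networkNodes(net), c(1L, 2L, 3L))
  expect_equal(nrow(networkEdges(net)), 1L)
  expect_equal(unname(nodeDegree(net)[c("1", "2", "3")]), c(1L, 1L, 0L))
  # empty significant set -> empty network
  empty <- buildOriginalNetwork(integer(0), cm, thr)
  expect_equal(length(networkNodes(empty)), 0L)
  expect_error(buildOriginalNetwork(99, cm, thr), "out of range")
})

test_that("network extension adds strongly linked bins one round deep", {
  lay <- makeGenomeLayout(c(A = 10 * 8e4), 8e4)
  thr <- makeThr(c(A = 10), NA_real_)
  # originals {1,2}; bin 5 strongly linked to both; bin 6 strongly linked
  # only to 5 (outside the original set: must NOT be added - one round)
  cm <- makeCM(lay, c(1, 1, 2, 5, 7), c(2, 5, 5, 6, 8),
               c(50, 30, 40, 99, 99))
  net <- buildOriginalNetwork(c(1, 2), cm, thr)
  ext <- extendNetwork(net, cm, thr)
  expect_equal(networkNodes(ext), c(1L, 2L, 5L))
  expect_equal(unname(nodeOrigin(ext)["5"]), "added")
  expect_equal(nrow(networkEdges(ext)), 3L)
  # no qualifying external bin -> extension is the identity
  net2 <- buildOriginalNetwork(c(7, 8), cm, thr)
  ext2 <- extendNetwork(net2, cm, thr)
  expect_equal(networkNodes(ext2), networkNodes(net2))

  # added-added edges kept by default, dropped under star extension
  cm3 <- makeCM(lay, c(1, 1, 5, 7), c(5, 6, 6, 8), c(30, 30, 99, 1))
  net3 <- buildOriginalNetwork(1, cm3, thr)
  ext3 <- extendNetwork(net3, cm3, thr)
  expect_true(any(ext3@edges$i == 5 & ext3@edges$j == 6))
  ext3s <- extendNetwork(net3, cm3, thr, starExtension = TRUE)
  expect_false(any(ext3s@edges$i == 5 & ext3s@edges$j == 6))
  # restriction of the extended network to original nodes recovers the
  # original node set exactly
  expect_setequal(networkNodes(ext3)[nodeOrigin(ext3) == "original"],
                  networkNodes(net3))
})

test_that("degrees and components behave on hand-built graphs", {
  lay <- makeGenomeLayout(c(A = 10 * 8e4), 8e4)
  thr <- makeThr(c(A = 1), NA_real_)
  cm <- makeCM(lay, c(1, 2, 1), c(2, 3, 3), c(5, 5, 5))  # triangle
  net <- buildOriginalNetwork(c(1, 2, 3, 9), cm, thr)
  deg <- nodeDegree(net)
  expect_equal(unname(deg[c("1", "2", "3")]), c(2L, 2L, 2L))
  expect_equal(unname(deg["9"]), 0L)
  expect_equal(sum(deg), 2L * nrow(networkEdges(net)))
  comps <- connectedComponents(net)
  expect_equal(length(comps), 2L)
  expect_setequal(comps[[1]], c(1L, 2L, 3L))
  expect_equal(comps[[2]], 9L)
})

test_that("Louvain separates cliques, is seeded, and beats singletons", {
  lay <- makeGenomeLayout(c(A = 15 * 8e4), 8e4)
  thr <- makeThr(c(A = 1), NA_real_)
  # one 5-clique -> a single community
  p5 <- t(combn(1:5, 2))
  cmc <- makeCM(lay, p5[, 1], p5[, 2], rep(10, nrow(p5)))
  net1 <- buildOriginalNetwork(1:5, cmc, thr)
  cl1 <- detectCommunities(net1, resolution = 0.1, seed = 1)
  expect_equal(length(unique(communityMembership(cl1))), 1L)

  # two 6-cliques joined by a single light edge -> the two cliques
  c1 <- t(combn(1:6, 2)); c2 <- t(combn(7:12, 2))
  ii <- c(c1[, 1], c2[, 1], 6); jj <- c(c1[, 2], c2[, 2], 7)
  ww <- c(rep(10, nrow(c1) + nrow(c2)), 2)
  cm2 <- makeCM(lay, ii, jj, ww)
  net2 <- buildOriginalNetwork(1:12, cm2, thr)
  cl2 <- detectCommunities(net2, resolution = 0.1, seed = 3)
  memb <- communityMembership(cl2)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[as.character(1:6)])), 1L)
  expect_equal(length(unique(memb[as.character(7:12)])), 1L)
  expect_false(memb[["1"]] == memb[["12"]])

  # seeded determinism
  cl2b <- detectCommunities(net2, resolution = 0.1, seed = 3)
  expect_identical(communityMembership(cl2), communityMembership(cl2b))

  # returned partition beats the all-singletons partition on modularity
  g <- asIgraph(net2)
  singletons <- seq_along(networkNodes(net2))
  expect_gt(igraph::modularity(g, memb[igraph::V(g)$name],
                               weights = igraph::E(g)$weight),
            igraph::modularity(g, singletons,
                               weights = igraph::E(g)$weight))
  expect_error(detectCommunities(buildOriginalNetwork(integer(0), cmc, thr)),
               "empty")
})

test_that("ego subnetworks carry the node, its neighbors and their edges", {
  lay <- makeGenomeLayout(c(A = 10 * 8e4), 8e4)
  thr <- makeThr(c(A = 1), NA_real_)
  # hub 1 with leaves 2,3,4 plus a detached edge 5-6
  cm <- makeCM(lay, c(1, 1, 1, 5), c(2, 3, 4, 6), c(9, 9, 9, 9))
  net <- buildOriginalNetwork(1:6, cm, thr)
  ego <- egoSubnetwork(net, 1)
  expect_setequal(networkNodes(ego), 1:4)
  expect_equal(nrow(networkEdges(ego)), 3L)
  # triangle: any node's ego is the whole triangle
  cmt <- makeCM(lay, c(1, 2, 1), c(2, 3, 3), c(5, 5, 5))
  nett <- buildOriginalNetwork(1:3, cmt, thr)
  expect_setequal(networkNodes(egoSubnetwork(nett, 2)), 1:3)
  # isolated node -> single-node subnetwork
  neti <- buildOriginalNetwork(c(1, 9), makeCM(lay, 1, 2, 0.5), thr)
  expect_equal(networkNodes(egoSubnetwork(neti, 9)), 9L)
  expect_error(egoSubnetwork(net, 8), "not in the network")
})

test_that("shared nodes intersect symmetrically with exact span accounting", {
  lay <- makeGenomeLayout(flyChromosomes(), 80000)
  thr <- makeThr(c("2" = 1, "3" = 1, "4" = 1, "X" = 1), 1)
  cm <- makeCM(lay, 1, 2, 0.5)
  a <- buildOriginalNetwork(1:20, cm, thr)
  b <- buildOriginalNetwork(15:30, cm, thr)
  ab <- sharedNodes(a, b); ba <- sharedNodes(b, a)
  expect_equal(ab$bins, 15:20)
  expect_identical(ab, ba)
  expect_equal(ab$spanMb, 6 * 0.08)
  disj <- sharedNodes(buildOriginalNetwork(1:3, cm, thr),
                      buildOriginalNetwork(8:9, cm, thr))
  expect_equal(length(disj$bins), 0L)
  expect_equal(disj$spanMb, 0)
  lay10 <- makeGenomeLayout(flyChromosomes(), 10000)
  cm10 <- makeCM(lay10, 1, 2, 0.5)
  expect_error(sharedNodes(a, buildOriginalNetwork(1:3, cm10,
    makeThr(c("2" = 1, "3" = 1, "4" = 1, "X" = 1), 1))),
    "different resolutions")
})
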