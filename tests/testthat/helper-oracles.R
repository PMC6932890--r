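# Independent oracles and small fixture builders used across the suite.

# term-by-term brute-force divergence statistic
oracleD <- function(hO, hY) {
  n <- length(hO)
  acc <- 0
  for (j in seq_len(n)) acc <- acc + (hO[j] - hY[j])^2
  100 * sqrt(acc / n)
}

# sort-and-count tail threshold: smallest observed value v such that the
# fraction of entries strictly greater than v is <= 1 - q
oracleTailThreshold <- function(vals, q) {
  for (v in sort(unique(vals))) {
    if (mean(vals > v) <= 1 - q) return(v)
  }
  stop("no threshold found")
}

# exhaustive hypergeometric enumeration: P(X >= a) for the 2x2 table
# [[a, r1-a], [c, r2-c]] with fixed margins (one-sided greater)
oracleFisherGreater <- function(a, r1, c, r2) {
  col1 <- a + c
  N <- r1 + r2
  xs <- max(0, col1 - r2):min(r1, col1)
  probs <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, col1 - x) / choose(N, col1), 0)
  sum(probs[xs >= a])
}

# exhaustive hypergeometric enumeration of the upper tail P(X >= k) for
# GO-style draws: N universe, K carriers, n drawn
oracleHyperTail <- function(k, K, n, N) {
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), 0)
  sum(probs[xs >= k])
}

# a ContactMatrix from explicit triplets
makeCM <- function(layout, i, j, x) {
  nb <- nBins(layout)
  lo <- pmin(i, j); hi <- pmax(i, j)
  mat <- Matrix::sparseMatrix(i = lo, j = hi, x = x, dims = c(nb, nb),
                              symmetric = TRUE)
  methods::new("ContactMatrix", layout = layout, mat = mat)
}

# a ThresholdSet with fixed cutoffs
makeThr <- function(intra, inter, q = 0.99, crossArm = "intra") {
  methods::new("ThresholdSet", q = q, intra = intra, inter = inter,
               crossArm = crossArm)
}

# two-chromosome toy layout
toyLayout <- function(lenA = 8e5, lenB = 8e5, binSize = 8e4) {
  makeGenomeLayout(c(A = lenA, B = lenB), binSize)
}

# small-genome simulation config (planted structure sized for toy layouts)
toyConfig <- function(seed = 1L, ...) {
  defaults <- list(seed = seed,
                   nSnps = c(synthetic = 3000, dgrp = 3000),
                   plantedSignalBins = c(3L, 5L),
                   plantedModules = list(3:7),
                   nBorders = 40L, nGenes = 300L, nPlantedGoGenes = 20L)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(simConfig, defaults)
}
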