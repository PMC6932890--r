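#' @include layout.R
#' @importFrom data.table data.table as.data.table setorder fread fwrite
#'   rbindlist
NULL

# data.table semantics inside this package
.datatable.aware <- TRUE

# Derive a deterministic sub-seed for a named generator stream, so each
# generator draws from its own stream and adding a generator does not
# perturb the others.  Kept strictly below 2^31.
.streamSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1e9
  as.integer(((as.double(seed) %% 2147483647) * 2147 + h) %% 2147483647)
}

# Evaluate expr under a generator-specific RNG stream, restoring the
# caller's RNG state afterwards.
.withStream <- function(seed, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.streamSeed(seed, label))
  expr
}

# points (1-based positions) as GRanges
.snpGRanges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom,
    IRanges::IRanges(start = snps$pos, width = 1L))
}

# BED-style 0-based half-open intervals as 1-based closed GRanges
.bedGRanges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# overlap wrappers with harmonized seqlevels (avoids the mismatched-
# seqlevels warning when one table lacks a chromosome)
.harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

.findOverlaps <- function(q, s) {
  h <- .harmonize(q, s)
  GenomicRanges::findOverlaps(h[[1]], h[[2]], ignore.strand = TRUE)
}

.countOverlaps <- function(q, s) {
  h <- .harmonize(q, s)
  GenomicRanges::countOverlaps(h[[1]], h[[2]], ignore.strand = TRUE)
}

.overlapsAny <- function(q, s) {
  h <- .harmonize(q, s)
  IRanges::overlapsAny(h[[1]], h[[2]], ignore.strand = TRUE)
}

# Dirichlet draws: n x k matrix, rows sum to 1
.rdirichlet <- function(n, alpha, k) {
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, ncol = k)
  g / rowSums(g)
}
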