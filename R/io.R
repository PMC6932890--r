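#' @include layout.R
NULL

#' Read and write pipeline files
#'
#' All pipeline inputs and outputs are plain TSV.  Layout sidecars carry
#' one row per chromosome (`chrom`, `length`, `first_bin`, `n_bins`,
#' `bin_size`); contact matrices are upper-triangle triplets
#' (`bin_i`, `bin_j`, `frequency`, including the diagonal); SNP tables carry
#' `chrom`, `pos`, `id` plus either per-founder `hO_*`/`hY_*` frequency
#' columns or a `pvalue` column; borders and genes are BED-style
#' (0-based half-open `chrom`, `start`, `end`, `name`, plus extra columns
#' for genes).
#'
#' @param layout,cm,snps,df object to write.
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeLayout <- function(layout, path) {
  rng <- binRangeOfChrom(layout)
  data.table::fwrite(data.table::data.table(
    chrom = chromNames(layout),
    length = unname(chromLengths(layout)),
    first_bin = rng[, "first"],
    n_bins = rng[, "last"] - rng[, "first"] + 1L,
    bin_size = binSize(layout)), path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readLayout <- function(path) {
  df <- data.table::fread(path)
  makeGenomeLayout(setNames(df$length, df$chrom), df$bin_size[1])
}

#' @rdname pipeline-io
#' @export
writeContacts <- function(cm, path) {
  tr <- contactEntries(cm, diagonal = TRUE)
  data.table::fwrite(data.table::data.table(
    bin_i = tr$i, bin_j = tr$j, frequency = tr$f), path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline-io
#' @param layout the [GenomeLayout-class] the triplet indices refer to.
#' @export
readContacts <- function(path, layout) {
  df <- data.table::fread(path)
  nb <- nBins(layout)
  i <- pmin(df$bin_i, df$bin_j); j <- pmax(df$bin_i, df$bin_j)
  mat <- Matrix::sparseMatrix(i = i, j = j, x = df$frequency,
                              dims = c(nb, nb), symmetric = TRUE)
  new("ContactMatrix", layout = layout, mat = mat)
}

#' @rdname pipeline-io
#' @export
writeSnpTable <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readSnpTable <- function(path) {
  data.table::fread(path)
}

#' @rdname pipeline-io
#' @export
writeBedTable <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readBedTable <- function(path) {
  data.table::fread(path)
}
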