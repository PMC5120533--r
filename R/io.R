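#' Tab-separated I/O helpers
#'
#' TSV is the canonical interchange format: header row, UTF-8, '.' decimal.
#' GFF3 is accepted at the edge for gene lengths (exon-union per gene).
#'
#' @name io
NULL

#' Read a genes-by-samples count matrix from TSV
#'
#' First column is the gene id, remaining columns are integer sample counts
#' with sample ids in the header row.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("count TSV needs a gene column plus >=1 sample")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("sample columns must be numeric")
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read a two-column gene-length TSV
#'
#' @param path TSV with columns gene id and length in bp (header required).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("gene-length TSV needs two columns")
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Derive gene lengths from a GFF3 file
#'
#' Length is the union of the exon intervals of each gene (or of each
#' feature of `feature_type` grouped by `group_attr`). Requires rtracklayer
#' and GenomicRanges.
#'
#' @param path GFF3 file.
#' @param feature_type Feature rows to use (default `"exon"`).
#' @param group_attr Attribute naming the gene (default `"gene_id"`; falls
#'   back to `"Parent"` when absent).
#' @return Named numeric vector of exon-union lengths per gene.
#' @export
gene_lengths_from_gff <- function(path, feature_type = "exon",
                                  group_attr = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("gene_lengths_from_gff() needs rtracklayer and GenomicRanges")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  if (length(gr) == 0L) stop("no '", feature_type, "' features in ", path)
  meta <- S4Vectors::mcols(gr)
  ids <- if (group_attr %in% names(meta)) meta[[group_attr]] else meta[["Parent"]]
  if (is.null(ids)) stop("no '", group_attr, "' or 'Parent' attribute found")
  ids <- vapply(as.list(ids), function(x) as.character(x)[1L], character(1))
  red <- GenomicRanges::reduce(S4Vectors::split(gr, ids))
  lens <- sum(GenomicRanges::width(red))  # per-gene exon-union bp
  stats::setNames(as.numeric(lens), names(lens))
}

#' Read a design table (sample, genotype, stage, replicate)
#'
#' @param path TSV path with at least columns `sample` and `genotype`.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample", "genotype") %in% names(df)))
    stop("design TSV needs columns 'sample' and 'genotype'")
  df
}

#' Read a per-SNP allele-count table
#'
#' Expected columns: snp_id, chrom, pos, gene_id, maternal_hyb, paternal_hyb,
#' maternal_parent_depth, paternal_parent_depth, base_quality_ok,
#' parental_consistent. Coordinates are 1-based (VCF convention).
#'
#' @param path TSV path.
#' @return Data frame with logical quality flags.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("snp_id", "gene_id", "maternal_hyb", "paternal_hyb")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele-count TSV missing: ", paste(miss, collapse = ", "))
  for (col in c("base_quality_ok", "parental_consistent"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]]) else df[[col]] <- TRUE
  df
}

#' Write a table as TSV with a provenance header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param provenance Optional named character vector written as `# key: value`
#'   comment lines before the header.
#' @export
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (skipping provenance comments)
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
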