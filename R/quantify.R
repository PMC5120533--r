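#' RPKM quantification and expression binning
#'
#' Raw gene counts are converted to RPKM (reads per kilobase of gene model
#' per million mapped reads), genes are flagged as expressed when any
#' genotype reaches RPKM >= 1, and expressed genes are binned into
#' high / medium / low expression levels.
#'
#' @name quantify
NULL

#' Compute RPKM
#'
#' `rpkm = 1e9 * count / (length_bp * library_size)`. `library_size` is the
#' total number of reads assigned to genes in that sample (column sum of the
#' count matrix), not the total sequenced.
#'
#' @param count Integer count (vector or genes-by-samples matrix).
#' @param length_bp Gene length in base pairs (> 0); recycled along rows for
#'   a matrix `count`.
#' @param library_size Per-sample total assigned reads (> 0); recycled along
#'   columns for a matrix `count`.
#' @return RPKM values with the shape of `count`.
#' @examples
#' compute_rpkm(100, 2000, 1e6)   # 50
#' @export
compute_rpkm <- function(count, length_bp, library_size) {
  if (any(is.na(length_bp)) || any(length_bp <= 0))
    stop("'length_bp' must be positive")
  if (any(is.na(library_size)) || any(library_size <= 0))
    stop("'library_size' must be positive")
  if (any(count < 0, na.rm = TRUE)) stop("'count' must be non-negative")
  if (is.matrix(count)) {
    1e9 * count / (length_bp * rep(library_size, each = nrow(count)))
  } else {
    1e9 * count / (length_bp * library_size)
  }
}

#' Flag a gene as expressed
#'
#' A gene is expressed if its RPKM reaches 1 in at least one genotype.
#' Genotype-level RPKM is the mean over that genotype's replicates.
#'
#' @param rpkm Numeric vector of per-genotype RPKM values (already averaged
#'   over replicates), or a genes-by-genotypes matrix.
#' @return Logical: `TRUE` when `max(rpkm) >= 1`. Vectorised by row for a
#'   matrix input.
#' @export
flag_expressed <- function(rpkm) {
  if (length(rpkm) == 0L) stop("'rpkm' must be non-empty")
  if (is.matrix(rpkm)) {
    apply(rpkm, 1L, function(x) max(x) >= 1)
  } else {
    max(rpkm) >= 1
  }
}

#' Bin an RPKM value into an expression level
#'
#' high: RPKM >= 50; medium: 20 <= RPKM < 50; low: 1 <= RPKM < 20;
#' not_expressed: RPKM < 1. The boundary RPKM = 20 belongs to medium
#' (half-open bins).
#'
#' @param rpkm Non-negative numeric vector.
#' @return Factor with levels `not_expressed`, `low`, `medium`, `high`.
#' @export
bin_expression_level <- function(rpkm) {
  if (any(is.na(rpkm)) || any(rpkm < 0)) stop("'rpkm' must be non-negative")
  cut(rpkm, breaks = c(-Inf, 1, 20, 50, Inf), right = FALSE,
      labels = c("not_expressed", "low", "medium", "high"))
}

#' Quantify a count matrix
#'
#' Computes per-sample RPKM, per-genotype mean RPKM, the expression flag and
#' the expression bin (from the maximum genotype RPKM) for every gene.
#'
#' @param counts Integer genes-by-samples matrix with rownames = gene ids.
#' @param lengths_bp Named numeric vector of gene lengths (bp); must cover
#'   every gene in `counts`.
#' @param design Data frame with columns `sample`, `genotype` (and
#'   optionally `stage`, `replicate`); `sample` must match `colnames(counts)`.
#' @param library_sizes Optional per-sample totals; default `colSums(counts)`.
#' @return A list of class `hybridexpr_quant` with elements `rpkm`
#'   (genes-by-samples), `genotype_rpkm` (genes-by-genotypes mean RPKM),
#'   `table` (per-gene data frame: gene_id, length_bp, expressed, level_bin,
#'   max_rpkm), and `library_sizes`.
#' @export
quantify_counts <- function(counts, lengths_bp, design,
                            library_sizes = colSums(counts)) {
  .check_counts_design(counts, design)
  missing <- setdiff(rownames(counts), names(lengths_bp))
  if (length(missing))
    stop("gene lengths missing for: ", paste(utils::head(missing, 5), collapse = ", "))
  len <- lengths_bp[rownames(counts)]
  rpkm <- compute_rpkm(counts, len, library_sizes)
  genotypes <- unique(design$genotype)
  geno_rpkm <- vapply(genotypes, function(g) {
    smp <- design$sample[design$genotype == g]
    rowMeans(rpkm[, smp, drop = FALSE])
  }, numeric(nrow(counts)))
  if (is.null(dim(geno_rpkm))) geno_rpkm <- matrix(geno_rpkm, nrow = nrow(counts))
  colnames(geno_rpkm) <- genotypes
  max_rpkm <- apply(geno_rpkm, 1L, max)
  tab <- data.frame(
    gene_id = rownames(counts),
    length_bp = unname(len),
    expressed = max_rpkm >= 1,
    level_bin = bin_expression_level(max_rpkm),
    max_rpkm = max_rpkm,
    row.names = NULL
  )
  structure(list(rpkm = rpkm, genotype_rpkm = geno_rpkm, table = tab,
                 library_sizes = library_sizes),
            class = "hybridexpr_quant")
}

.check_counts_design <- function(counts, design) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must be a matrix with gene rownames and sample colnames")
  if (!all(c("sample", "genotype") %in% names(design)))
    stop("'design' needs columns 'sample' and 'genotype'")
  bad <- setdiff(design$sample, colnames(counts))
  if (length(bad))
    stop("design samples absent from counts: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
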