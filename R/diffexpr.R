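#' Pairwise differential expression by exact count tests
#'
#' Replicates of each group are pooled (the exact tests have no replicate
#' term) and the two groups are compared with Fisher's exact test on the
#' 2x2 table (gene count, rest of library) after library-size equalization:
#' the group with the larger pooled library is scaled down by the library
#' ratio and rounded half-to-even so the table stays integer. Note the
#' exact test models sampling (Poisson-level) noise only; biological
#' overdispersion between replicates makes it anticonservative (see the
#' methods vignette).
#'
#' @name diffexpr
NULL

#' Equalize two pooled counts to a common library size
#'
#' @param k1,k2 Pooled gene counts of the two groups.
#' @param l1,l2 Pooled library sizes.
#' @return List with integer `k1`, `k2` on the common scale and `lib` (the
#'   smaller library total).
#' @keywords internal
equalize_libraries <- function(k1, k2, l1, l2) {
  if (any(l1 <= 0) || any(l2 <= 0)) stop("library sizes must be positive")
  lib <- pmin(l1, l2)
  n <- max(length(k1), length(k2))
  s1 <- rep_len(lib / l1, n); s2 <- rep_len(lib / l2, n)
  # round() is round-half-to-even in R
  k1 <- ifelse(s1 < 1, round(rep_len(k1, n) * s1), rep_len(k1, n))
  k2 <- ifelse(s2 < 1, round(rep_len(k2, n) * s2), rep_len(k2, n))
  list(k1 = as.integer(k1), k2 = as.integer(k2), lib = lib)
}

#' Test one comparison for all genes
#'
#' @param counts_a,counts_b Genes-by-replicates integer matrices (or vectors
#'   of pooled counts) for the two groups, same genes in the same order.
#' @param libsize_a,libsize_b Library sizes; either per-replicate vectors
#'   (summed when counts are matrices) or pooled scalars.
#' @return Data frame with `gene_id`, `count_a`, `count_b` (equalized),
#'   `log2_fold_change` (pseudocount 1), `p_value`, `untestable`.
#' @export
de_test_genes <- function(counts_a, counts_b, libsize_a, libsize_b) {
  ka <- if (is.matrix(counts_a)) rowSums(counts_a) else counts_a
  kb <- if (is.matrix(counts_b)) rowSums(counts_b) else counts_b
  if (length(ka) != length(kb)) stop("count vectors must align gene-by-gene")
  la <- sum(libsize_a); lb <- sum(libsize_b)
  eq <- equalize_libraries(ka, kb, la, lb)
  untestable <- eq$k1 == 0L & eq$k2 == 0L
  p <- rep(1, length(ka))
  idx <- which(!untestable)
  if (length(idx))
    p[idx] <- fisher_exact_2x2(eq$k1[idx], eq$lib - eq$k1[idx],
                               eq$k2[idx], eq$lib - eq$k2[idx])
  lfc <- ifelse(untestable, 0, log2((eq$k1 + 1) / (eq$k2 + 1)))
  ids <- if (is.matrix(counts_a) && !is.null(rownames(counts_a)))
    rownames(counts_a) else as.character(seq_along(ka))
  data.frame(gene_id = ids, count_a = eq$k1, count_b = eq$k2,
             log2_fold_change = lfc, p_value = p, untestable = untestable,
             row.names = NULL)
}

#' Call differentially expressed genes
#'
#' Genes failing the expression filter (RPKM >= 1 in at least one genotype
#' of the comparison) are removed before FDR adjustment; the remaining
#' p-values are BH-adjusted and direction is assigned.
#'
#' @param de Data frame from [de_test_genes()].
#' @param expressed Logical vector aligned with `de` (`TRUE` = passes the
#'   RPKM filter), or `NULL` to keep all genes.
#' @param alpha Q-value threshold (default 0.05).
#' @return Data frame of the analyzed genes with `q_value`, `significant`
#'   and `direction` (up / down / ns); the summary (up, down, total counts
#'   and percentages of analyzed genes) is attached as
#'   `attr(, "summary")`.
#' @export
call_degs <- function(de, expressed = NULL, alpha = 0.05) {
  .check_alpha(alpha)
  if (!is.null(expressed)) {
    if (length(expressed) != nrow(de))
      stop("'expressed' must align with 'de'")
    de <- de[expressed, , drop = FALSE]
  }
  p <- ifelse(de$untestable, NA_real_, de$p_value)
  de$q_value <- bh_adjust(p)
  de$significant <- !is.na(de$q_value) & de$q_value < alpha
  de$direction <- ifelse(!de$significant, "ns",
                         ifelse(de$log2_fold_change > 0, "up", "down"))
  n <- nrow(de)
  up <- sum(de$direction == "up"); down <- sum(de$direction == "down")
  attr(de, "summary") <- data.frame(
    up = up, down = down, total = up + down, analyzed = n,
    up_pct = pct_of(up, n), down_pct = pct_of(down, n),
    total_pct = pct_of(up + down, n))
  de
}

#' Percentage of a count over a denominator
#'
#' The worked-ratio primitive used by every summary table:
#' `100 * count / total` (NaN-safe for `total = 0`).
#'
#' @param count Numerator count(s).
#' @param total Denominator.
#' @return Percentage value(s).
#' @export
pct_of <- function(count, total) {
  n <- max(length(count), length(total))
  ifelse(rep_len(total, n) > 0, 100 * rep_len(count, n) / rep_len(total, n),
         NA_real_)
}

#' Venn region cardinalities for up to three DEG sets
#'
#' @param sets Named list of 2 or 3 character vectors of gene ids.
#' @return Named integer vector: one entry per non-empty region combination
#'   (names like `"A"`, `"A&B"`, `"A&B&C"`), counting genes exclusive to
#'   that region.
#' @export
overlap_sets <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L)
    stop("overlap_sets() supports 2 or 3 sets; report pairwise for k > 3")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1L,
                                           dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- table(key)
  out <- as.integer(regions)
  names(out) <- names(regions)
  out
}
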