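#' Cis/trans decomposition of regulatory divergence
#'
#' Per gene, parental expression divergence at SNP sites is quantified as
#' A = log2(P1/P2) and tested with the exact binomial test; the cis
#' component is the allelic imbalance inside the hybrid, B = log2 of the
#' maternal/paternal allele ratio, tested the same way; the trans component
#' is A - B, tested by Fisher's exact test on the 2x2 table of parental
#' versus hybrid allele counts. Significance patterns assign each gene to
#' cis-only, trans-only, cis-trans (enhancing or compensating), conserved,
#' or ambiguous.
#'
#' @name cistrans
NULL

.REG_CATEGORIES <- c("cis_only", "trans_only", "cis_trans", "conserved",
                     "ambiguous")

#' Test parental divergence (A)
#'
#' @param p1,p2 Per-gene parental counts summed over retained SNP sites,
#'   already equalized to a common library scale and rounded.
#' @return List of vectors `A` (log2 with pseudocount 1) and `p` (exact
#'   binomial p; NA when both counts are zero).
#' @export
test_parental_divergence <- function(p1, p2) {
  tot <- p1 + p2
  p <- rep(NA_real_, length(p1))
  idx <- which(tot > 0)
  if (length(idx)) p[idx] <- binomial_two_sided(p1[idx], tot[idx], 0.5)
  list(A = log2((p1 + 1) / (p2 + 1)), p = p)
}

#' Test the cis component (B): allelic imbalance in the hybrid
#'
#' @param maternal,paternal Per-gene hybrid allele totals.
#' @return List of vectors `B` and `p`.
#' @export
test_cis <- function(maternal, paternal) {
  res <- test_parental_divergence(maternal, paternal)
  list(B = res$A, p = res$p)
}

#' Test the trans component (A - B)
#'
#' Fisher's exact test of the parental split against the hybrid allelic
#' split; a significant difference in ratios indicates a trans effect.
#'
#' @param p1,p2 Equalized parental site counts.
#' @param maternal,paternal Hybrid allele totals.
#' @return List of vectors `p` (NA when either pair sums to zero).
#' @export
test_trans <- function(p1, p2, maternal, paternal) {
  p <- rep(NA_real_, length(p1))
  idx <- which(p1 + p2 > 0 & maternal + paternal > 0)
  if (length(idx))
    p[idx] <- fisher_exact_2x2(p1[idx], p2[idx], maternal[idx], paternal[idx])
  list(p = p)
}

#' Assign regulatory categories from the three significance calls
#'
#' Truth table: cis_only = sig A, sig B, ns A-B; trans_only = sig A, ns B,
#' sig A-B; cis_trans = all three significant; conserved = none significant;
#' everything else is ambiguous. For cis_trans genes the interaction is
#' enhancing when A and B share a sign, compensating when they oppose
#' (`convention = "parental-vs-hybrid"`, the ratio-direction rule); with
#' `convention = "cis-vs-trans"` the comparison is sign(B) versus
#' sign(A - B) instead.
#'
#' @param sig_A,sig_B,sig_AB Logical vectors of significance for the three
#'   test families.
#' @param A,B Log2 divergence statistics.
#' @param convention Enhancing/compensating convention (see above).
#' @return Data frame with `category` and `interaction`
#'   (enhancing / compensating / none).
#' @export
classify_regulation <- function(sig_A, sig_B, sig_AB, A, B,
                                convention = c("parental-vs-hybrid",
                                               "cis-vs-trans")) {
  convention <- match.arg(convention)
  category <- rep("ambiguous", length(sig_A))
  category[sig_A & sig_B & !sig_AB] <- "cis_only"
  category[sig_A & !sig_B & sig_AB] <- "trans_only"
  category[sig_A & sig_B & sig_AB] <- "cis_trans"
  category[!sig_A & !sig_B & !sig_AB] <- "conserved"
  interaction <- rep("none", length(sig_A))
  ct <- category == "cis_trans"
  same <- if (convention == "parental-vs-hybrid") sign(A) == sign(B)
          else sign(B) == sign(A - B)
  interaction[ct] <- ifelse(same[ct], "enhancing", "compensating")
  data.frame(category = factor(category, levels = .REG_CATEGORIES),
             interaction = interaction)
}

#' Full per-gene regulatory decomposition
#'
#' Runs the three test families over a gene table, FDR-adjusts each across
#' genes, classifies categories and computes percent-cis.
#'
#' @param genes Data frame with columns `gene_id`, `p1_site`, `p2_site`
#'   (parental site counts), `maternal_hyb`, `paternal_hyb` (hybrid allele
#'   totals).
#' @param p1_lib,p2_lib Parental library totals used to equalize the site
#'   counts (defaults: equal, no scaling).
#' @param alpha Q-value threshold (default 0.05).
#' @param min_parental_depth Minimum combined equalized parental site depth
#'   (default 10); genes below it are dropped with reason.
#' @param convention Enhancing/compensating convention, see
#'   [classify_regulation()].
#' @return Data frame per retained gene with A, B, `trans_component`
#'   (A - B), p/q-values of the three families, `category`, `interaction`,
#'   and `percent_cis` = 100 |B| / (|B| + |A - B|). Dropped genes are in
#'   `attr(, "dropped")`.
#' @export
regulatory_calls <- function(genes, p1_lib = 1, p2_lib = 1, alpha = 0.05,
                             min_parental_depth = 10,
                             convention = c("parental-vs-hybrid",
                                            "cis-vs-trans")) {
  .check_alpha(alpha)
  convention <- match.arg(convention)
  eq <- equalize_libraries(genes$p1_site, genes$p2_site, p1_lib, p2_lib)
  p1 <- eq$k1; p2 <- eq$k2
  keep <- (p1 + p2) >= min_parental_depth &
    (genes$maternal_hyb + genes$paternal_hyb) > 0
  dropped <- genes[!keep, , drop = FALSE]
  if (nrow(dropped))
    dropped$reason <- ifelse(p1[!keep] + p2[!keep] < min_parental_depth,
                             "parental_depth", "no_hybrid_coverage")
  g <- genes[keep, , drop = FALSE]
  p1 <- p1[keep]; p2 <- p2[keep]
  tA <- test_parental_divergence(p1, p2)
  tB <- test_cis(g$maternal_hyb, g$paternal_hyb)
  tAB <- test_trans(p1, p2, g$maternal_hyb, g$paternal_hyb)
  qA <- bh_adjust(tA$p); qB <- bh_adjust(tB$p); qAB <- bh_adjust(tAB$p)
  sA <- !is.na(qA) & qA < alpha
  sB <- !is.na(qB) & qB < alpha
  sAB <- !is.na(qAB) & qAB < alpha
  cls <- classify_regulation(sA, sB, sAB, tA$A, tB$B, convention)
  out <- data.frame(
    gene_id = g$gene_id,
    p1_site = p1, p2_site = p2,
    maternal_hyb = g$maternal_hyb, paternal_hyb = g$paternal_hyb,
    A = tA$A, B = tB$B, trans_component = tA$A - tB$B,
    p_A = tA$p, q_A = qA, p_B = tB$p, q_B = qB, p_AB = tAB$p, q_AB = qAB,
    category = cls$category, interaction = cls$interaction,
    percent_cis = percent_cis(tA$A, tB$B),
    row.names = NULL)
  attr(out, "dropped") <- dropped
  out
}

#' Percent of divergence attributable to cis
#'
#' `100 * |B| / (|B| + |A - B|)`; NA when both components are zero.
#'
#' @param A,B Log2 divergence statistics.
#' @return Percent-cis values in `[0, 100]`.
#' @export
percent_cis <- function(A, B) {
  denom <- abs(B) + abs(A - B)
  ifelse(denom > 0, 100 * abs(B) / denom, NA_real_)
}

#' Percent-cis distributions binned by total divergence
#'
#' Bins |A| into [0,1), [1,2), [2,3), [3,4), [4,5) and >= 5 and summarizes
#' percent-cis inside each bin.
#'
#' @param calls Data frame from [regulatory_calls()].
#' @return Data frame per bin: `bin`, `n`, `mean_percent_cis`,
#'   `median_percent_cis`.
#' @export
percent_cis_binned <- function(calls) {
  bin <- cut(abs(calls$A), breaks = c(0, 1, 2, 3, 4, 5, Inf), right = FALSE,
             labels = c("0-1", "1-2", "2-3", "3-4", "4-5", ">=5"))
  ok <- !is.na(calls$percent_cis)
  agg <- function(f) tapply(calls$percent_cis[ok], bin[ok], f)
  n <- table(bin[ok])
  data.frame(bin = names(n), n = as.integer(n),
             mean_percent_cis = as.numeric(agg(mean))[match(names(n), names(agg(mean)))],
             median_percent_cis = as.numeric(agg(stats::median))[match(names(n), names(agg(stats::median)))],
             row.names = NULL)
}

#' Cross-tabulate regulatory category with inheritance mode
#'
#' @param reg_calls Data frame from [regulatory_calls()].
#' @param inh_calls Data frame from [classify_inheritance()].
#' @return List with `table` (category by mode counts over the shared gene
#'   universe), `by_bin` (same split by |A| bin), and `n_shared`.
#' @export
crosstab_regulation_inheritance <- function(reg_calls, inh_calls) {
  shared <- intersect(reg_calls$gene_id, inh_calls$gene_id)
  if (length(shared) == 0L) {
    warning("regulatory and inheritance calls share no genes")
    return(list(table = table(factor(), factor()), by_bin = NULL,
                n_shared = 0L))
  }
  r <- reg_calls[match(shared, reg_calls$gene_id), ]
  m <- inh_calls$mode[match(shared, inh_calls$gene_id)]
  bin <- cut(abs(r$A), breaks = c(0, 1, 2, 3, 4, 5, Inf), right = FALSE,
             labels = c("0-1", "1-2", "2-3", "3-4", "4-5", ">=5"))
  list(table = table(category = r$category, mode = m),
       by_bin = table(bin = bin, category = r$category, mode = m),
       n_shared = length(shared))
}
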