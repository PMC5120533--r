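#' Allele-specific expression analysis
#'
#' SNPs distinguishing the two parental alleles are filtered (read quality,
#' parental consistency, minimum hybrid coverage of 10 reads), the allelic
#' ratio at each SNP is tested against the balanced 1:1 null with the exact
#' binomial test, allele counts are summed per gene, and significant genes
#' are classed as monoallelic, preferential (> 2-fold) or biallelic
#' (<= 2-fold).
#'
#' @name ase
NULL

#' Filter SNPs for ASE analysis
#'
#' Retains SNPs with `base_quality_ok`, `parental_consistent` and hybrid
#' coverage (maternal + paternal reads) at or above `min_coverage`.
#'
#' @param snps Allele-count data frame (see [read_allele_counts()]).
#' @param min_coverage Minimum hybrid reads covering the SNP (default 10).
#' @return The retained rows; the dropped rows with a `reason` column
#'   (first rule that fired: quality, consistency, coverage) are attached as
#'   `attr(, "rejected")`.
#' @export
filter_snps <- function(snps, min_coverage = 10) {
  coverage <- snps$maternal_hyb + snps$paternal_hyb
  reason <- rep(NA_character_, nrow(snps))
  reason[coverage < min_coverage] <- "coverage"
  reason[!snps$parental_consistent] <- "consistency"
  reason[!snps$base_quality_ok] <- "quality"
  keep <- is.na(reason)
  rejected <- snps[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  out <- snps[keep, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Test allelic bias at single SNPs
#'
#' Exact binomial test of the maternal read count against coverage at
#' p0 = 0.5, BH-adjusted across all retained SNPs.
#'
#' @param snps Retained allele-count data frame.
#' @param alpha Q-value threshold (default 0.05).
#' @return `snps` with `coverage`, `p_value`, `q_value`, `significant`.
#' @export
test_snp_bias <- function(snps, alpha = 0.05) {
  .check_alpha(alpha)
  snps$coverage <- snps$maternal_hyb + snps$paternal_hyb
  p <- rep(NA_real_, nrow(snps))
  idx <- which(snps$coverage > 0)
  if (length(idx))
    p[idx] <- binomial_two_sided(snps$maternal_hyb[idx], snps$coverage[idx], 0.5)
  snps$p_value <- p
  snps$q_value <- bh_adjust(p)
  snps$significant <- !is.na(snps$q_value) & snps$q_value < alpha
  snps
}

#' Aggregate SNP allele counts to gene-level ASE calls
#'
#' Allele counts are summed over each gene's retained SNPs (discordant SNPs
#' cancel), the summed counts are tested with the exact binomial test, and
#' q-values are computed across genes.
#'
#' @param snps Retained allele-count data frame.
#' @param alpha Q-value threshold (default 0.05).
#' @return Data frame per gene: `maternal_total`, `paternal_total`,
#'   `n_snps`, `allelic_ratio` (pseudocount 1), `log2_ratio`, `p_value`,
#'   `q_value`, `significant`, `bias` (maternal / paternal / none).
#' @export
aggregate_gene_ase <- function(snps, alpha = 0.05) {
  .check_alpha(alpha)
  if (nrow(snps) == 0L)
    return(data.frame(gene_id = character(), maternal_total = integer(),
                      paternal_total = integer(), n_snps = integer(),
                      allelic_ratio = numeric(), log2_ratio = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), bias = character()))
  mat <- tapply(snps$maternal_hyb, snps$gene_id, sum)
  pat <- tapply(snps$paternal_hyb, snps$gene_id, sum)
  nsnp <- tapply(snps$snp_id, snps$gene_id, length)
  genes <- names(mat)
  m <- as.integer(mat); p_ <- as.integer(pat[genes])
  cov <- m + p_
  pv <- rep(NA_real_, length(genes))
  idx <- which(cov > 0)
  pv[idx] <- binomial_two_sided(m[idx], cov[idx], 0.5)
  qv <- bh_adjust(pv)
  sig <- !is.na(qv) & qv < alpha
  bias <- ifelse(!sig, "none", ifelse(m > p_, "maternal", "paternal"))
  data.frame(gene_id = genes,
             maternal_total = m, paternal_total = p_,
             n_snps = as.integer(nsnp[genes]),
             allelic_ratio = (m + 1) / (p_ + 1),
             log2_ratio = log2((m + 1) / (p_ + 1)),
             p_value = pv, q_value = qv, significant = sig, bias = bias,
             row.names = NULL)
}

#' Assign the ASE class of each gene
#'
#' Non-significant genes are `unbiased`. Significant genes are `monoallelic`
#' when the minor allele total is at (or below a configurable tolerance of)
#' zero, `preferential` when the major/minor ratio exceeds `fold_boundary`
#' (default 2; a ratio of exactly 2 is biallelic), else `biallelic`.
#'
#' @param gene_ase Data frame from [aggregate_gene_ase()].
#' @param fold_boundary Fold-change boundary between preferential and
#'   biallelic (default 2).
#' @param mono_minor_fraction Maximum minor-allele fraction still counted as
#'   monoallelic (default 0 = strict).
#' @return `gene_ase` with an `ase_class` factor column
#'   (unbiased / biallelic / preferential / monoallelic).
#' @export
classify_ase <- function(gene_ase, fold_boundary = 2, mono_minor_fraction = 0) {
  major <- pmax(gene_ase$maternal_total, gene_ase$paternal_total)
  minor <- pmin(gene_ase$maternal_total, gene_ase$paternal_total)
  total <- major + minor
  cls <- rep("unbiased", nrow(gene_ase))
  sig <- gene_ase$significant
  mono <- sig & (minor <= mono_minor_fraction * total)
  pref <- sig & !mono & (major > fold_boundary * minor)
  biall <- sig & !mono & !pref
  cls[biall] <- "biallelic"; cls[pref] <- "preferential"; cls[mono] <- "monoallelic"
  gene_ase$ase_class <- factor(cls, levels = c("unbiased", "biallelic",
                                               "preferential", "monoallelic"))
  gene_ase
}

#' Compare gene-level allelic bias between two stages
#'
#' @param ase1,ase2 Classified gene ASE data frames from two stages.
#' @return List with `table` (stage-1 bias by stage-2 bias), `n_shared`,
#'   `conserved` (same bias label in both stages), `conserved_pct`, and
#'   per-gene transitions (`transitions` data frame with labels conserved /
#'   switched / gained / lost).
#' @export
compare_stage_ase <- function(ase1, ase2) {
  shared <- intersect(ase1$gene_id, ase2$gene_id)
  if (length(shared) == 0L) {
    warning("no shared genes between stages")
    return(list(table = table(factor(), factor()), n_shared = 0L,
                conserved = 0L, conserved_pct = NA_real_,
                transitions = data.frame()))
  }
  b1 <- ase1$bias[match(shared, ase1$gene_id)]
  b2 <- ase2$bias[match(shared, ase2$gene_id)]
  lab <- ifelse(b1 == b2, "conserved",
         ifelse(b1 == "none", "gained",
         ifelse(b2 == "none", "lost", "switched")))
  cons <- sum(lab == "conserved")
  list(table = table(stage1 = b1, stage2 = b2),
       n_shared = length(shared), conserved = cons,
       conserved_pct = pct_of(cons, length(shared)),
       transitions = data.frame(gene_id = shared, stage1 = b1, stage2 = b2,
                                transition = lab, row.names = NULL))
}

#' SNP-table summary statistics
#'
#' The descriptive summary reported for an ASE SNP set: SNP count, total
#' reads covering SNPs, mean reads per SNP, gene count, mean SNPs per gene,
#' and the share of the protein-coding gene universe tagged.
#'
#' @param snps Retained allele-count data frame.
#' @param gene_universe Number of protein-coding genes in the annotation
#'   (default 39469).
#' @return One-row data frame.
#' @export
summarize_snp_table <- function(snps, gene_universe = 39469) {
  n_snps <- nrow(snps)
  reads <- sum(snps$maternal_hyb + snps$paternal_hyb)
  genes <- length(unique(snps$gene_id))
  data.frame(n_snps = n_snps, reads_covering = reads,
             reads_per_snp = if (n_snps > 0) reads / n_snps else NA_real_,
             n_genes = genes,
             snps_per_gene = if (genes > 0) n_snps / genes else NA_real_,
             pct_of_protein_coding = pct_of(genes, gene_universe))
}
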