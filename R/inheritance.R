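#' Inheritance-mode classification against the mid-parent value
#'
#' Each gene's hybrid expression is compared with the mid-parent value (MPV)
#' and with each parent by Fisher's exact test on pooled, library-equalized
#' counts. Genes indistinguishable from the MPV are additive; non-additive
#' genes split into over-dominance (above both parents), under-dominance
#' (below both), high-/low-parent dominance (matching exactly one parent)
#' and conserved (different from both parents yet inside the parental
#' range). Each of the four test families (hybrid-MPV, hybrid-P1, hybrid-P2,
#' P1-P2) is FDR-adjusted separately across genes.
#'
#' @name inheritance
NULL

.MODES <- c("additive", "over_dominance", "high_parent_dominance",
            "low_parent_dominance", "under_dominance", "conserved",
            "unclassifiable")

#' Mid-parent pseudo-sample count
#'
#' The MPV is materialized as a count on the common library scale so the
#' hybrid-vs-MPV comparison can reuse the same exact-test machinery:
#' `round((c1 + c2) / 2)` with round-half-to-even.
#'
#' @param c1,c2 Pooled normalized parental counts (common library scale).
#' @return Integer MPV counts.
#' @export
midparent_counts <- function(c1, c2) {
  as.integer(round((c1 + c2) / 2))
}

#' Classify inheritance modes for a set of genes
#'
#' @param hybrid,p1,p2 Pooled normalized integer counts per gene on a common
#'   library scale (p1 = maternal parent, p2 = paternal parent).
#' @param library_size Common library total (single number).
#' @param alpha Q-value threshold (default 0.05).
#' @param gene_id Optional gene ids (default 1..n).
#' @return Data frame with one row per gene: `mode`,
#'   `dominant_parent` (maternal / paternal / none), the MPV count, and the
#'   p/q-values of the four test families (`p_mpv`, `q_mpv`, `p_p1`, ...).
#' @export
classify_inheritance <- function(hybrid, p1, p2, library_size, alpha = 0.05,
                                 gene_id = NULL) {
  .check_alpha(alpha)
  n <- length(hybrid)
  if (length(p1) != n || length(p2) != n)
    stop("'hybrid', 'p1' and 'p2' must have equal length")
  if (length(library_size) != 1L || library_size <= max(hybrid, p1, p2))
    stop("'library_size' must be a single total exceeding every count")
  if (is.null(gene_id)) gene_id <- as.character(seq_len(n))
  mpv <- midparent_counts(p1, p2)

  fam <- function(ka, kb) {
    untest <- ka == 0L & kb == 0L
    p <- rep(NA_real_, n)
    idx <- which(!untest)
    if (length(idx))
      p[idx] <- fisher_exact_2x2(ka[idx], library_size - ka[idx],
                                 kb[idx], library_size - kb[idx])
    q <- bh_adjust(p)
    list(p = p, q = q, sig = !is.na(q) & q < alpha)
  }
  t_mpv <- fam(hybrid, mpv)
  t_p1 <- fam(hybrid, p1)
  t_p2 <- fam(hybrid, p2)
  t_pp <- fam(p1, p2)

  mode <- character(n)
  dominant <- rep("none", n)
  for (i in seq_len(n)) {
    if (hybrid[i] == 0L && p1[i] == 0L && p2[i] == 0L) {
      mode[i] <- "unclassifiable"; next
    }
    if (!t_mpv$sig[i]) { mode[i] <- "additive"; next }
    s1 <- t_p1$sig[i]; s2 <- t_p2$sig[i]
    if (s1 && s2) {
      mode[i] <- if (hybrid[i] > p1[i] && hybrid[i] > p2[i]) "over_dominance"
        else if (hybrid[i] < p1[i] && hybrid[i] < p2[i]) "under_dominance"
        else "conserved"
    } else if (xor(s1, s2)) {
      matched_is_p1 <- !s1           # the parent the hybrid matches
      if (p1[i] == p2[i]) { mode[i] <- "unclassifiable"; next }
      matched_is_high <- if (matched_is_p1) p1[i] > p2[i] else p2[i] > p1[i]
      mode[i] <- if (matched_is_high) "high_parent_dominance"
                 else "low_parent_dominance"
      dominant[i] <- if (matched_is_p1) "maternal" else "paternal"
    } else {
      # indistinguishable from both parents yet different from the MPV
      mode[i] <- "unclassifiable"
    }
  }
  data.frame(gene_id = gene_id,
             mode = factor(mode, levels = .MODES),
             dominant_parent = dominant,
             hybrid = hybrid, p1 = p1, p2 = p2, mpv = mpv,
             p_mpv = t_mpv$p, q_mpv = t_mpv$q,
             p_p1 = t_p1$p, q_p1 = t_p1$q,
             p_p2 = t_p2$p, q_p2 = t_p2$q,
             p_parents = t_pp$p, q_parents = t_pp$q,
             row.names = NULL)
}

#' Summarize inheritance calls
#'
#' Mirrors the classical additive/non-additive classification table: counts
#' and percentages per mode over testable genes, dominance classes split by
#' dominant parent.
#'
#' @param calls Data frame from [classify_inheritance()].
#' @return Data frame with columns `class`, `count`, `pct` (percentage of
#'   testable genes, i.e. excluding unclassifiable).
#' @export
summarize_modes <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(class = character(), count = integer(), pct = numeric()))
  testable <- calls[calls$mode != "unclassifiable", , drop = FALSE]
  n <- nrow(testable)
  cnt <- function(sel) sum(sel)
  rows <- list(
    additive = cnt(testable$mode == "additive"),
    non_additive = cnt(testable$mode != "additive"),
    over_dominance = cnt(testable$mode == "over_dominance"),
    high_parent_dominance_maternal = cnt(testable$mode == "high_parent_dominance" &
                                           testable$dominant_parent == "maternal"),
    high_parent_dominance_paternal = cnt(testable$mode == "high_parent_dominance" &
                                           testable$dominant_parent == "paternal"),
    low_parent_dominance_maternal = cnt(testable$mode == "low_parent_dominance" &
                                          testable$dominant_parent == "maternal"),
    low_parent_dominance_paternal = cnt(testable$mode == "low_parent_dominance" &
                                          testable$dominant_parent == "paternal"),
    under_dominance = cnt(testable$mode == "under_dominance"),
    conserved = cnt(testable$mode == "conserved"))
  data.frame(class = names(rows),
             count = unlist(rows, use.names = FALSE),
             pct = pct_of(unlist(rows, use.names = FALSE), n),
             row.names = NULL)
}

#' Cross-stage persistence of inheritance modes
#'
#' @param calls1,calls2 Call data frames from two stages (matched on
#'   `gene_id`).
#' @return List with `table` (stage-1 mode by stage-2 mode contingency),
#'   `n_shared`, `kept` (genes with identical mode) and `persistence_pct`.
#' @export
compare_stage_modes <- function(calls1, calls2) {
  shared <- intersect(calls1$gene_id, calls2$gene_id)
  if (length(shared) == 0L) {
    warning("no shared genes between stages")
    return(list(table = table(factor(), factor()), n_shared = 0L,
                kept = 0L, persistence_pct = NA_real_))
  }
  m1 <- calls1$mode[match(shared, calls1$gene_id)]
  m2 <- calls2$mode[match(shared, calls2$gene_id)]
  tab <- table(stage1 = m1, stage2 = m2)
  kept <- sum(as.character(m1) == as.character(m2))
  list(table = tab, n_shared = length(shared), kept = kept,
       persistence_pct = pct_of(kept, length(shared)))
}
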