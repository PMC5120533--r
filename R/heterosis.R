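#' Mid-parent and best-parent heterosis
#'
#' Trait-level heterosis statistics: MPH is the percent excess of the F1
#' trait mean over the parental average, BPH the percent excess over the
#' better parent.
#'
#' @name heterosis
NULL

#' Mid-parent heterosis (percent)
#'
#' `100 * (f1 - MP) / MP` with `MP = (p1 + p2) / 2`.
#'
#' @param p1_mean,p2_mean,f1_mean Trait means (vectorised).
#' @return MPH percentages.
#' @examples
#' mph(8.25, 6.4, 15.58)   # 112.7
#' @export
mph <- function(p1_mean, p2_mean, f1_mean) {
  mp <- (p1_mean + p2_mean) / 2
  if (any(mp == 0)) stop("mid-parent mean is zero; MPH undefined")
  100 * (f1_mean - mp) / mp
}

#' Best-parent heterosis (percent)
#'
#' `100 * (f1 - BP) / BP` where BP is the better parent: the larger mean
#' when `higher_is_better`, the smaller otherwise.
#'
#' @param p1_mean,p2_mean,f1_mean Trait means (vectorised).
#' @param higher_is_better Whether larger trait values are superior
#'   (default TRUE).
#' @return BPH percentages.
#' @examples
#' bph(8.25, 6.4, 15.58)   # 88.85
#' @export
bph <- function(p1_mean, p2_mean, f1_mean, higher_is_better = TRUE) {
  bp <- ifelse(rep_len(higher_is_better, length(p1_mean)),
               pmax(p1_mean, p2_mean), pmin(p1_mean, p2_mean))
  if (any(bp == 0)) stop("best-parent mean is zero; BPH undefined")
  100 * (f1_mean - bp) / bp
}

#' Heterosis table from trait means
#'
#' @param traits Data frame with columns `trait`, `stage`, `p1_mean`,
#'   `p2_mean`, `f1_mean` (optional `p1_sd`, `p2_sd`, `f1_sd`,
#'   `higher_is_better`).
#' @param n Optional per-group sample size; when supplied (and SDs are
#'   present) a Welch t-test of F1 against the better parent is added.
#' @return `traits` with `mph` and `bph` columns (and `bph_p_value` when
#'   `n` is given).
#' @export
heterosis_table <- function(traits, n = NULL) {
  need <- c("trait", "p1_mean", "p2_mean", "f1_mean")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits table missing: ", paste(miss, collapse = ", "))
  hib <- if ("higher_is_better" %in% names(traits))
    as.logical(traits$higher_is_better) else rep(TRUE, nrow(traits))
  traits$mph <- mph(traits$p1_mean, traits$p2_mean, traits$f1_mean)
  traits$bph <- bph(traits$p1_mean, traits$p2_mean, traits$f1_mean, hib)
  if (!is.null(n) && all(c("p1_sd", "p2_sd", "f1_sd") %in% names(traits))) {
    traits$bph_p_value <- vapply(seq_len(nrow(traits)), function(i) {
      best_is_p1 <- xor(traits$p1_mean[i] < traits$p2_mean[i], hib[i])
      bp_mean <- if (best_is_p1) traits$p1_mean[i] else traits$p2_mean[i]
      bp_sd <- if (best_is_p1) traits$p1_sd[i] else traits$p2_sd[i]
      welch_t_pvalue(traits$f1_mean[i], traits$f1_sd[i], n,
                     bp_mean, bp_sd, n)
    }, numeric(1))
  }
  traits
}

#' Welch t-test p-value from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and sample size of group 1.
#' @param m2,s2,n2 Mean, SD and sample size of group 2.
#' @return Two-sided p-value.
#' @export
welch_t_pvalue <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) return(if (m1 == m2) 1 else 0)
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}
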