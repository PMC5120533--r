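#' Synthetic data with known truth
#'
#' Generates what the pipeline consumes: a parental/hybrid count matrix
#' (two inbred parents plus F1, two replicates each, negative-binomial
#' counts) with a known inheritance mode per gene, and a per-SNP allele
#' count table whose allelic ratios encode configurable cis and trans
#' effects. Every random draw flows through the configured seed; global RNG
#' state is restored on exit.
#'
#' @name synthetic_data
NULL

.SIM_MODES <- c("additive", "over", "under", "hp_dom_p1", "hp_dom_p2",
                "lp_dom_p1", "lp_dom_p2", "conserved", "null")
.SIM_CATEGORIES <- c("cis_only", "trans_only", "cis_trans_enh",
                     "cis_trans_comp", "conserved")

#' Simulation configuration
#'
#' Defaults state the simulated world: 2,000 genes, two replicates per
#' genotype, log-normal base expression with median 200 counts,
#' negative-binomial dispersion 0.05, parental divergence effects uniform
#' on 1-4 log2 units, 3.5 SNPs per gene (zero-truncated Poisson) and
#' negative-binomial per-SNP hybrid coverage with mean 70 reads (echoing
#' typical deep RNA-seq ASE designs).
#'
#' @param n_genes Number of genes (default 2000).
#' @param replicates Replicates per genotype (default 2).
#' @param mode_proportions Named fractions over the inheritance modes
#'   `additive, over, under, hp_dom_p1, hp_dom_p2, lp_dom_p1, lp_dom_p2,
#'   conserved, null`; must sum to 1.
#' @param reg_proportions Named fractions over regulatory categories
#'   `cis_only, trans_only, cis_trans_enh, cis_trans_comp, conserved`.
#' @param effect_range Range of |A| (log2) effects, default `c(1, 4)`.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal base-mean parameters
#'   (default median 200, sdlog 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts. Default 0.05.
#' @param snps_per_gene_mean Mean of the zero-truncated Poisson SNP count
#'   per gene (default 3.5).
#' @param site_coverage_mean,site_coverage_size NB parameters of per-SNP
#'   hybrid coverage (default mean 70, size 10).
#' @param library_size Optional target expected per-sample total; scales
#'   base means. Default NULL (totals emerge from the base means).
#' @param ase_hybrid_additive When TRUE, per-SNP hybrid coverage is drawn
#'   Poisson around the mean of the realized parental depths, so hybrid
#'   gene totals are additive by construction (used to link cis-regulation
#'   with additive inheritance). Default FALSE.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       replicates = 2,
                       mode_proportions = c(additive = 0.40, over = 0.05,
                                            under = 0.05, hp_dom_p1 = 0.075,
                                            hp_dom_p2 = 0.075, lp_dom_p1 = 0.075,
                                            lp_dom_p2 = 0.075, conserved = 0.05,
                                            null = 0.15),
                       reg_proportions = c(cis_only = 0.45, trans_only = 0.10,
                                           cis_trans_enh = 0.07,
                                           cis_trans_comp = 0.13,
                                           conserved = 0.25),
                       effect_range = c(1, 4),
                       base_mean_meanlog = log(200), base_mean_sdlog = 1,
                       dispersion = 0.05,
                       snps_per_gene_mean = 3.5,
                       site_coverage_mean = 70, site_coverage_size = 10,
                       library_size = NULL,
                       ase_hybrid_additive = FALSE,
                       seed = 1L) {
  stopifnot(n_genes >= 1, replicates >= 1, dispersion >= 0,
            snps_per_gene_mean > 0, site_coverage_mean > 0,
            site_coverage_size > 0, effect_range[1] > 0,
            effect_range[2] >= effect_range[1])
  .check_props(mode_proportions, .SIM_MODES, "mode_proportions")
  .check_props(reg_proportions, .SIM_CATEGORIES, "reg_proportions")
  structure(as.list(environment()), class = "sim_config")
}

.check_props <- function(p, universe, what) {
  if (is.null(names(p)) || !all(names(p) %in% universe))
    stop("'", what, "' must be named with names among: ",
         paste(universe, collapse = ", "))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("'", what, "' must be non-negative and sum to 1")
  invisible(p)
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Zero-truncated Poisson via rejection of zeros (exact and fast for the
# lambdas used here).
.rtpois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0L)) x[x == 0L] <- stats::rpois(sum(x == 0L), lambda)
  x
}

#' Simulate parental/hybrid gene counts with known inheritance modes
#'
#' Per gene: the parental means are set `effect` log2 units apart around a
#' log-normal base mean; the F1 mean follows the true mode (additive:
#' arithmetic mid-parent; high/low-parent dominance: the respective
#' parent's mean; over: twice the high parent; under: half the low parent;
#' conserved: the geometric mean of the parents, i.e. mid-way on the log
#' scale but below the arithmetic mid-parent; null: parents and F1 all at
#' the base mean). Counts are NB draws per replicate.
#'
#' @param config A [sim_config()].
#' @return List of class `hybridexpr_sim`: `counts` (genes x samples
#'   integer matrix, samples P1_r*, P2_r*, F1_r*), `design` data frame,
#'   `truth` data frame (`gene_id`, `true_mode`, `true_A` signed
#'   log2(mu1/mu2), `effect`, `mu1`, `mu2`, `muF`), and `config`.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_genes
    modes <- sample(names(config$mode_proportions), n, replace = TRUE,
                    prob = config$mode_proportions)
    eff <- stats::runif(n, config$effect_range[1], config$effect_range[2])
    base <- stats::rlnorm(n, config$base_mean_meanlog, config$base_mean_sdlog)
    flip <- stats::runif(n) < 0.5      # random parent orientation
    hi <- base * 2^(eff / 2); lo <- base * 2^(-eff / 2)

    mu1 <- ifelse(flip, hi, lo)
    mu2 <- ifelse(flip, lo, hi)
    # dominance modes pin the orientation
    mu1[modes == "hp_dom_p1"] <- hi[modes == "hp_dom_p1"]
    mu2[modes == "hp_dom_p1"] <- lo[modes == "hp_dom_p1"]
    mu1[modes == "hp_dom_p2"] <- lo[modes == "hp_dom_p2"]
    mu2[modes == "hp_dom_p2"] <- hi[modes == "hp_dom_p2"]
    mu1[modes == "lp_dom_p1"] <- lo[modes == "lp_dom_p1"]
    mu2[modes == "lp_dom_p1"] <- hi[modes == "lp_dom_p1"]
    mu1[modes == "lp_dom_p2"] <- hi[modes == "lp_dom_p2"]
    mu2[modes == "lp_dom_p2"] <- lo[modes == "lp_dom_p2"]
    mu1[modes == "null"] <- base[modes == "null"]
    mu2[modes == "null"] <- base[modes == "null"]
    eff[modes == "null"] <- 0

    muF <- rep(NA_real_, n)
    muF[modes == "additive"] <- ((mu1 + mu2) / 2)[modes == "additive"]
    muF[modes == "hp_dom_p1"] <- mu1[modes == "hp_dom_p1"]
    muF[modes == "hp_dom_p2"] <- mu2[modes == "hp_dom_p2"]
    muF[modes == "lp_dom_p1"] <- mu1[modes == "lp_dom_p1"]
    muF[modes == "lp_dom_p2"] <- mu2[modes == "lp_dom_p2"]
    muF[modes == "over"] <- 2 * pmax(mu1, mu2)[modes == "over"]
    muF[modes == "under"] <- 0.5 * pmin(mu1, mu2)[modes == "under"]
    muF[modes == "conserved"] <- sqrt(mu1 * mu2)[modes == "conserved"]
    muF[modes == "null"] <- base[modes == "null"]

    if (!is.null(config$library_size)) {
      scale <- config$library_size / mean(c(sum(mu1), sum(mu2), sum(muF)))
      mu1 <- mu1 * scale; mu2 <- mu2 * scale; muF <- muF * scale
    }

    reps <- config$replicates
    draw <- function(mu) vapply(seq_len(reps), function(r)
      .rnb(n, mu, config$dispersion), numeric(n))
    counts <- cbind(draw(mu1), draw(mu2), draw(muF))
    storage.mode(counts) <- "integer"
    samples <- c(paste0("P1_r", seq_len(reps)), paste0("P2_r", seq_len(reps)),
                 paste0("F1_r", seq_len(reps)))
    dimnames(counts) <- list(sprintf("g%05d", seq_len(n)), samples)
    design <- data.frame(sample = samples,
                         genotype = rep(c("P1", "P2", "F1"), each = reps),
                         replicate = rep(seq_len(reps), 3L))
    truth <- data.frame(gene_id = rownames(counts), true_mode = modes,
                        true_A = log2(mu1 / mu2), effect = eff,
                        mu1 = mu1, mu2 = mu2, muF = muF, row.names = NULL)
    structure(list(counts = counts, design = design, truth = truth,
                   config = config), class = "hybridexpr_sim")
  })
}

#' Simulate SNP allele counts with known cis/trans regulatory categories
#'
#' Per gene a signed parental divergence `A` is drawn; the hybrid allelic
#' divergence `B` follows the category (cis-only: B = A; trans-only: B = 0;
#' cis-trans: B = +/- A*u with u ~ U(0.25, 0.75), sign by interaction;
#' conserved: A = B = 0). Each SNP's parental depths split a NB total
#' binomially at `2^A / (1 + 2^A)`; the hybrid maternal read fraction is
#' `2^B / (1 + 2^B)` at NB coverage (or, when `ase_hybrid_additive`,
#' Poisson coverage centred on the realized parental mean so hybrid totals
#' are additive).
#'
#' @param config A [sim_config()].
#' @return List of class `hybridexpr_ase_sim`: `snps` (allele-count data
#'   frame), `truth` (`gene_id`, `true_category`, `true_A`, `true_B`,
#'   `true_interaction`), and `config`.
#' @export
simulate_ase <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    n <- config$n_genes
    cat_ <- sample(names(config$reg_proportions), n, replace = TRUE,
                   prob = config$reg_proportions)
    A <- stats::runif(n, config$effect_range[1], config$effect_range[2]) *
      sample(c(-1, 1), n, replace = TRUE)
    B <- rep(0, n)
    B[cat_ == "cis_only"] <- A[cat_ == "cis_only"]
    u <- stats::runif(n, 0.25, 0.75)
    B[cat_ == "cis_trans_enh"] <- (A * u)[cat_ == "cis_trans_enh"]
    B[cat_ == "cis_trans_comp"] <- (-A * u)[cat_ == "cis_trans_comp"]
    A[cat_ == "conserved"] <- 0
    interaction <- rep("none", n)
    interaction[cat_ == "cis_trans_enh"] <- "enhancing"
    interaction[cat_ == "cis_trans_comp"] <- "compensating"

    nsnp <- .rtpois(n, config$snps_per_gene_mean)
    gene_of <- rep(seq_len(n), nsnp)
    ns <- length(gene_of)
    wA <- (2^A / (1 + 2^A))[gene_of]
    wB <- (2^B / (1 + 2^B))[gene_of]

    parent_total <- .rnb_size(ns, 2 * config$site_coverage_mean,
                              config$site_coverage_size)
    p1_depth <- stats::rbinom(ns, parent_total, wA)
    p2_depth <- parent_total - p1_depth
    coverage <- if (isTRUE(config$ase_hybrid_additive)) {
      stats::rpois(ns, pmax((p1_depth + p2_depth) / 2, 1e-9))
    } else {
      .rnb_size(ns, config$site_coverage_mean, config$site_coverage_size)
    }
    mat_hyb <- stats::rbinom(ns, coverage, wB)
    pat_hyb <- coverage - mat_hyb

    gene_ids <- sprintf("g%05d", seq_len(n))
    snps <- data.frame(
      snp_id = sprintf("s%06d", seq_len(ns)),
      chrom = "chr1",
      pos = seq_len(ns) * 100L,
      gene_id = gene_ids[gene_of],
      maternal_hyb = mat_hyb, paternal_hyb = pat_hyb,
      maternal_parent_depth = p1_depth, paternal_parent_depth = p2_depth,
      base_quality_ok = TRUE, parental_consistent = TRUE,
      row.names = NULL)
    truth <- data.frame(gene_id = gene_ids, true_category = cat_,
                        true_A = A, true_B = B,
                        true_interaction = interaction, row.names = NULL)
    structure(list(snps = snps, truth = truth, config = config),
              class = "hybridexpr_ase_sim")
  })
}

.rnb_size <- function(n, mu, size) stats::rnbinom(n, mu = mu, size = size)

#' Pool simulated replicate counts per genotype
#'
#' Convenience accessor used by the classification stages: sums replicates
#' per genotype and reports pooled library sizes.
#'
#' @param sim A `hybridexpr_sim` from [simulate_counts()].
#' @return List with vectors `p1`, `p2`, `f1` and `lib` (named pooled
#'   library totals).
#' @export
pooled_counts <- function(sim) {
  pool <- function(g) {
    smp <- sim$design$sample[sim$design$genotype == g]
    rowSums(sim$counts[, smp, drop = FALSE])
  }
  p1 <- pool("P1"); p2 <- pool("P2"); f1 <- pool("F1")
  list(p1 = p1, p2 = p2, f1 = f1,
       lib = c(P1 = sum(p1), P2 = sum(p2), F1 = sum(f1)))
}

#' Per-gene sums of a simulated allele-count table
#'
#' @param snps Allele-count data frame (e.g. `simulate_ase()$snps`, after
#'   [filter_snps()]).
#' @return Data frame with `gene_id`, `p1_site`, `p2_site`, `maternal_hyb`,
#'   `paternal_hyb`, ready for [regulatory_calls()].
#' @export
gene_site_sums <- function(snps) {
  genes <- sort(unique(snps$gene_id))
  ord <- function(col) {
    v <- tapply(snps[[col]], snps$gene_id, sum)
    as.integer(v[genes])
  }
  data.frame(gene_id = genes,
             p1_site = ord("maternal_parent_depth"),
             p2_site = ord("paternal_parent_depth"),
             maternal_hyb = ord("maternal_hyb"),
             paternal_hyb = ord("paternal_hyb"),
             row.names = NULL)
}
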