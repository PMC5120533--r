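#' End-to-end pipeline orchestration
#'
#' Runs the enabled stages in dependency order (quantify -> de -> inherit;
#' ase -> cistrans; heterosis independent), writes every stage table as TSV
#' with a provenance header, and produces a summary report whose
#' percentages are recomputed from the per-gene tables.
#'
#' @name pipeline_cli
NULL

#' Build a run configuration
#'
#' @param counts Count matrix (genes x samples) or TSV path.
#' @param lengths Named gene-length vector or TSV path.
#' @param design Design data frame or TSV path (`sample`, `genotype`,
#'   optional `stage`, `replicate`).
#' @param allele_counts Allele-count data frame or TSV path.
#' @param traits Trait-mean data frame or TSV path.
#' @param stages Character vector of stages to run, among
#'   `quantify`, `de`, `inherit`, `ase`, `cistrans`, `heterosis`.
#' @param genotypes Named vector mapping roles to genotype labels
#'   (default `c(maternal = "P1", paternal = "P2", hybrid = "F1")`).
#' @param alpha Q-value threshold (default 0.05).
#' @param rpkm_expressed Expression threshold (default 1).
#' @param snp_min_coverage Minimum SNP coverage (default 10).
#' @param fold_boundary Preferential/biallelic boundary (default 2).
#' @param gene_universe Protein-coding gene universe size (default 39469).
#' @param seed Integer seed recorded in provenance.
#' @param out_dir Output directory (created if needed); NULL writes nothing.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts = NULL, lengths = NULL, design = NULL,
                       allele_counts = NULL, traits = NULL,
                       stages = c("quantify", "de", "inherit"),
                       genotypes = c(maternal = "P1", paternal = "P2",
                                     hybrid = "F1"),
                       alpha = 0.05, rpkm_expressed = 1,
                       snp_min_coverage = 10, fold_boundary = 2,
                       gene_universe = 39469, seed = 1L, out_dir = NULL) {
  known <- c("quantify", "de", "inherit", "ase", "cistrans", "heterosis")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (length(stages) == 0L) stop("nothing to do: no stages enabled")
  .check_alpha(alpha)
  stopifnot(rpkm_expressed > 0, snp_min_coverage > 0, fold_boundary > 0,
            gene_universe > 0)
  structure(as.list(environment()), class = "run_config")
}

.load_input <- function(x, reader, what) {
  if (is.null(x)) stop("missing required input: ", what, call. = FALSE)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing required input file: ", x, call. = FALSE)
    reader(x)
  } else x
}

#' Run the pipeline
#'
#' @param config A [run_config()].
#' @return List of class `hybridexpr_run` with one element per executed
#'   stage (`quant`, `de`, `inherit`, `ase`, `cistrans`, `heterosis`) plus
#'   `config`. Stage tables are also written under `config$out_dir` when
#'   set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  # fail on missing inputs before any computation
  needs_counts <- any(c("quantify", "de", "inherit") %in% st)
  if (needs_counts) {
    counts <- .load_input(config$counts, read_count_matrix, "counts")
    design <- .load_input(config$design, read_design, "design")
    .check_counts_design(counts, design)
  }
  if (any(c("ase", "cistrans") %in% st))
    snps <- .load_input(config$allele_counts, read_allele_counts, "allele_counts")
  if ("heterosis" %in% st)
    traits <- .load_input(config$traits, utils::read.delim, "traits")

  out <- list(config = config)
  prov <- c(package = "hybridexpr",
            version = as.character(utils::packageVersion("hybridexpr")),
            seed = as.character(config$seed), alpha = as.character(config$alpha))
  emit <- function(df, name) {
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir))
        dir.create(config$out_dir, recursive = TRUE)
      write_tsv(df, file.path(config$out_dir, paste0(name, ".tsv")), prov)
    }
  }

  if ("quantify" %in% st) {
    lengths <- .load_input(config$lengths, read_gene_lengths, "lengths")
    out$quant <- quantify_counts(counts, lengths, design)
    emit(out$quant$table, "quantify")
  }
  if (any(c("de", "inherit") %in% st)) {
    g <- config$genotypes
    pool <- function(label) {
      smp <- design$sample[design$genotype == label]
      if (length(smp) == 0L) stop("genotype '", label, "' absent from design")
      rowSums(counts[, smp, drop = FALSE])
    }
    p1 <- pool(g[["maternal"]]); p2 <- pool(g[["paternal"]])
    f1 <- pool(g[["hybrid"]])
    expressed <- if (!is.null(out$quant)) out$quant$table$expressed else NULL
  }
  if ("de" %in% st) {
    pairs <- list(P1_vs_P2 = list(p1, p2), F1_vs_P1 = list(f1, p1),
                  F1_vs_P2 = list(f1, p2))
    out$de <- lapply(pairs, function(pr) {
      de <- de_test_genes(pr[[1]], pr[[2]], sum(pr[[1]]), sum(pr[[2]]))
      de$gene_id <- rownames(counts)
      call_degs(de, expressed, config$alpha)
    })
    for (nm in names(out$de)) emit(out$de[[nm]], paste0("de_", nm))
    de_summary <- do.call(rbind, lapply(names(out$de), function(nm)
      cbind(comparison = nm, attr(out$de[[nm]], "summary"))))
    emit(de_summary, "de_summary")
    out$de_summary <- de_summary
  }
  if ("inherit" %in% st) {
    lib <- min(sum(p1), sum(p2), sum(f1))
    f1n <- if (sum(f1) > lib) as.integer(round(f1 * lib / sum(f1))) else f1
    p1n <- if (sum(p1) > lib) as.integer(round(p1 * lib / sum(p1))) else p1
    p2n <- if (sum(p2) > lib) as.integer(round(p2 * lib / sum(p2))) else p2
    keep <- if (!is.null(expressed)) expressed else rep(TRUE, nrow(counts))
    out$inherit <- classify_inheritance(f1n[keep], p1n[keep], p2n[keep],
                                        library_size = lib,
                                        alpha = config$alpha,
                                        gene_id = rownames(counts)[keep])
    emit(out$inherit, "inheritance")
    out$inherit_summary <- summarize_modes(out$inherit)
    emit(out$inherit_summary, "inheritance_summary")
  }
  if ("ase" %in% st || "cistrans" %in% st) {
    retained <- filter_snps(snps, config$snp_min_coverage)
    out$snps <- test_snp_bias(retained, config$alpha)
    gene_ase <- classify_ase(aggregate_gene_ase(retained, config$alpha),
                             config$fold_boundary)
    out$ase <- gene_ase
    out$ase_summary <- summarize_snp_table(retained, config$gene_universe)
    if ("ase" %in% st) {
      emit(out$snps, "snp_bias")
      emit(gene_ase, "gene_ase")
      emit(out$ase_summary, "ase_summary")
    }
  }
  if ("cistrans" %in% st) {
    sums <- gene_site_sums(retained)
    out$cistrans <- regulatory_calls(sums, alpha = config$alpha)
    emit(out$cistrans, "cistrans")
  }
  if ("heterosis" %in% st) {
    out$heterosis <- heterosis_table(traits)
    emit(out$heterosis, "heterosis")
  }
  structure(out, class = "hybridexpr_run")
}

#' Summarize a pipeline run
#'
#' Collects the stage summaries into one report; every percentage is
#' recomputed from the per-gene tables of the run itself.
#'
#' @param run A `hybridexpr_run` from [run_pipeline()].
#' @return List with whichever of `de`, `inheritance`, `ase`, `cistrans`,
#'   `heterosis` summaries the run produced.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "hybridexpr_run"))
  rep_ <- list()
  if (!is.null(run$de_summary)) rep_$de <- run$de_summary
  if (!is.null(run$inherit)) rep_$inheritance <- summarize_modes(run$inherit)
  if (!is.null(run$ase)) {
    cls <- table(run$ase$ase_class)
    biased <- run$ase[run$ase$bias != "none", , drop = FALSE]
    rep_$ase <- list(
      snp_table = run$ase_summary,
      class_counts = cls,
      bias_counts = table(run$ase$bias),
      bias_pct = data.frame(
        maternal = pct_of(sum(biased$bias == "maternal"), nrow(biased)),
        paternal = pct_of(sum(biased$bias == "paternal"), nrow(biased))))
  }
  if (!is.null(run$cistrans)) {
    ct <- run$cistrans
    rep_$cistrans <- list(
      category_counts = table(ct$category),
      interaction_counts = table(ct$interaction[ct$category == "cis_trans"]),
      percent_cis_bins = percent_cis_binned(ct))
  }
  if (!is.null(run$heterosis)) rep_$heterosis <- run$heterosis
  rep_
}
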