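test_that("midparent_counts is the rounded arithmetic mean", {
  expect_equal(midparent_counts(1000, 1000), 1000L)
  expect_equal(midparent_counts(2000, 200), 1100L)
  expect_equal(midparent_counts(0, 0), 0L)
  expect_equal(midparent_counts(3, 2), 2L)   # 2.5 rounds half-to-even
})

test_that("classification follows the mode decision sequence", {
  L <- 1e6
  # hybrid at the MPV of divergent parents -> additive
  call <- classify_inheritance(1100, 2000, 200, L)
  expect_equal(as.character(call$mode), "additive")
  expect_equal(call$dominant_parent, "none")
  # hybrid at the high parent -> high-parent dominance, maternal
  call <- classify_inheritance(2000, 2000, 200, L)
  expect_equal(as.character(call$mode), "high_parent_dominance")
  expect_equal(call$dominant_parent, "maternal")
  # hybrid at the low parent (paternal) -> low-parent dominance, paternal
  call <- classify_inheritance(200, 2000, 200, L)
  expect_equal(as.character(call$mode), "low_parent_dominance")
  expect_equal(call$dominant_parent, "paternal")
  # hybrid above both parents -> over-dominance
  call <- classify_inheritance(5000, 1000, 1000, L)
  expect_equal(as.character(call$mode), "over_dominance")
  # hybrid below both parents -> under-dominance
  call <- classify_inheritance(200, 1000, 1000, L)
  expect_equal(as.character(call$mode), "under_dominance")
  # hybrid inside the range, different from both parents and the MPV
  call <- classify_inheritance(1000, 2500, 500, L)
  expect_equal(as.character(call$mode), "conserved")
  # all-zero gene is unclassifiable
  call <- classify_inheritance(0, 0, 0, L)
  expect_equal(as.character(call$mode), "unclassifiable")
})

test_that("the four test families are each FDR-adjusted across genes", {
  L <- 1e6
  h <- c(1100, 2000, 5000); p1 <- c(2000, 2000, 1000); p2 <- c(200, 200, 1000)
  calls <- classify_inheritance(h, p1, p2, L)
  expect_equal(calls$q_mpv, bh_adjust(calls$p_mpv))
  expect_equal(calls$q_p1, bh_adjust(calls$p_p1))
  expect_equal(calls$p_mpv[1], fisher_exact_2x2(1100, L - 1100, 1100, L - 1100))
  expect_equal(calls$p_parents[1:2],
               rep(fisher_exact_2x2(2000, L - 2000, 200, L - 200), 2))
})

test_that("summarize_modes computes percentages over testable genes", {
  calls <- data.frame(
    gene_id = paste0("g", 1:4),
    mode = factor(c("additive", "additive", "additive", "over_dominance"),
                  levels = hybridexpr:::.MODES),
    dominant_parent = "none")
  s <- summarize_modes(calls)
  expect_equal(s$pct[s$class == "additive"], 75)
  expect_equal(s$pct[s$class == "over_dominance"], 25)
  expect_equal(s$count[s$class == "non_additive"], 1L)
  expect_equal(nrow(summarize_modes(calls[0, ])), 0L)
})

test_that("parent-label swap flips dominance labels and nothing else", {
  set.seed(31)
  n <- 300
  p1 <- rpois(n, exp(runif(n, 4, 8)))
  p2 <- rpois(n, exp(runif(n, 4, 8)))
  h <- rpois(n, (p1 + p2) / 2 + sample(0:500, n, TRUE))
  L <- 1e6
  a <- classify_inheritance(h, p1, p2, L)
  b <- classify_inheritance(h, p2, p1, L)
  expect_equal(a$p_mpv, b$p_mpv)
  expect_equal(a$p_p1, b$p_p2)
  expect_equal(as.character(a$mode), as.character(b$mode))
  swap <- c(maternal = "paternal", paternal = "maternal", none = "none")
  expect_equal(unname(swap[a$dominant_parent]), b$dominant_parent)
})

test_that("classification is deterministic", {
  set.seed(32)
  h <- rpois(50, 800); p1 <- rpois(50, 600); p2 <- rpois(50, 1000)
  expect_identical(classify_inheritance(h, p1, p2, 1e6),
                   classify_inheritance(h, p1, p2, 1e6))
})

test_that("known mode proportions are recovered at depth 2000 (seed 7)", {
  cfg <- sim_config(n_genes = 2000, dispersion = 0,
                    base_mean_meanlog = log(2000), base_mean_sdlog = 0.5,
                    mode_proportions = c(additive = 0.6, hp_dom_p1 = 0.05,
                                         hp_dom_p2 = 0.05, lp_dom_p1 = 0.05,
                                         lp_dom_p2 = 0.05, over = 0.1,
                                         under = 0.05, conserved = 0.05),
                    seed = 7)
  sim <- simulate_counts(cfg)
  pc <- pooled_counts(sim)
  # simulated genotypes share one implicit sequencing depth: counts are
  # already on a common scale, so only a nominal library total is needed
  calls <- classify_inheritance(pc$f1, pc$p1, pc$p2, round(mean(pc$lib)) * 2)
  map <- c(additive = "additive", hp_dom_p1 = "high_parent_dominance",
           hp_dom_p2 = "high_parent_dominance",
           lp_dom_p1 = "low_parent_dominance",
           lp_dom_p2 = "low_parent_dominance", over = "over_dominance",
           under = "under_dominance", conserved = "conserved")
  lv <- unique(unname(map))
  recovered <- table(factor(as.character(calls$mode), levels = lv)) / nrow(calls)
  truth_prop <- table(factor(unname(map[sim$truth$true_mode]),
                             levels = lv)) / nrow(calls)
  expect_true(all(abs(100 * (recovered - truth_prop)) <= 3))
})

test_that("cross-stage mode persistence is tallied correctly", {
  mk <- function(modes) data.frame(gene_id = paste0("g", seq_along(modes)),
                                   mode = modes)
  same <- mk(c("additive", "over_dominance", "conserved"))
  expect_equal(compare_stage_modes(same, same)$persistence_pct, 100)
  a <- mk(c("additive", "additive", "over_dominance", "conserved"))
  b <- mk(c("additive", "conserved", "additive", "conserved"))
  cmp <- compare_stage_modes(a, b)
  expect_equal(cmp$persistence_pct, 50)
  expect_equal(cmp$n_shared, 4L)
  expect_warning(compare_stage_modes(mk("additive"),
                                     data.frame(gene_id = "zz", mode = "additive")),
                 "no shared genes")
})

test_that("resampling 30% of stage-2 modes gives ~70% persistence (seed 11)", {
  set.seed(11)
  n <- 2000
  modes <- sample(hybridexpr:::.MODES[1:6], n, replace = TRUE)
  stage1 <- data.frame(gene_id = paste0("g", 1:n), mode = modes)
  flip <- runif(n) < 0.30
  modes2 <- modes
  modes2[flip] <- vapply(modes[flip], function(m)
    sample(setdiff(hybridexpr:::.MODES[1:6], m), 1), character(1))
  stage2 <- data.frame(gene_id = stage1$gene_id, mode = modes2)
  cmp <- compare_stage_modes(stage1, stage2)
  expect_true(abs(cmp$persistence_pct - 70) <= 3)
  expect_equal(cmp$kept + sum(flip), n)
})
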