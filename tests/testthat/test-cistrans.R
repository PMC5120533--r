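test_that("A, B and trans statistics follow the exact-test primitives", {
  tA <- test_parental_divergence(c(500, 800, 0), c(500, 200, 100))
  expect_equal(tA$A, log2(c(501 / 501, 801 / 201, 1 / 101)))
  expect_equal(tA$p[1], 1)
  expect_equal(tA$p[2], binomial_two_sided(800, 1000))
  expect_equal(tA$p[3], oracle_binom_p(0, 100))
  expect_lt(tA$A[3], -6.6)

  tB <- test_cis(c(500, 800, 51), c(500, 200, 49))
  expect_equal(tB$B[3], log2(52 / 50))
  expect_gt(tB$p[3], 0.8)           # 51:49 is far from significant
  expect_lt(tB$p[2], 1e-10)

  tAB <- test_trans(c(800, 80, 10), c(200, 20, 10), c(800, 50, 10), c(200, 50, 10))
  expect_equal(tAB$p[1], 1)          # identical ratios
  expect_equal(tAB$p[2], fisher_exact_2x2(80, 20, 50, 50))
  expect_lt(tAB$p[2], 0.05)
  expect_equal(tAB$p[3], 1)
})

test_that("regulatory categories follow the significance truth table", {
  grid <- expand.grid(sA = c(TRUE, FALSE), sB = c(TRUE, FALSE),
                      sAB = c(TRUE, FALSE))
  out <- classify_regulation(grid$sA, grid$sB, grid$sAB,
                             A = rep(2, 8), B = rep(1, 8))
  expected <- ifelse(grid$sA & grid$sB & !grid$sAB, "cis_only",
              ifelse(grid$sA & !grid$sB & grid$sAB, "trans_only",
              ifelse(grid$sA & grid$sB & grid$sAB, "cis_trans",
              ifelse(!grid$sA & !grid$sB & !grid$sAB, "conserved",
                     "ambiguous"))))
  expect_equal(as.character(out$category), expected)
  expect_true(all(out$interaction[out$category != "cis_trans"] == "none"))
})

test_that("enhancing/compensating follows the configured convention", {
  # opposite signs of A and B -> compensating under the ratio-direction rule
  out <- classify_regulation(TRUE, TRUE, TRUE, A = 3, B = -1)
  expect_equal(out$interaction, "compensating")
  out <- classify_regulation(TRUE, TRUE, TRUE, A = 3, B = 1)
  expect_equal(out$interaction, "enhancing")
  # A = 1, B = 3: same sign (enhancing) but cis and trans components oppose
  expect_equal(classify_regulation(TRUE, TRUE, TRUE, 1, 3)$interaction,
               "enhancing")
  expect_equal(classify_regulation(TRUE, TRUE, TRUE, 1, 3,
                                   convention = "cis-vs-trans")$interaction,
               "compensating")
})

test_that("percent_cis follows |B| / (|B| + |A-B|)", {
  expect_equal(percent_cis(2, 2), 100)   # pure cis
  expect_equal(percent_cis(2, 0), 0)     # pure trans
  expect_equal(percent_cis(3, 1), 100 / 3)
  expect_true(is.na(percent_cis(0, 0)))
})

test_that("regulatory_calls integrates tests, FDR and filters", {
  genes <- data.frame(
    gene_id = c("cis", "trans", "null", "shallow"),
    p1_site = c(800L, 800L, 500L, 4L),
    p2_site = c(200L, 200L, 500L, 3L),
    maternal_hyb = c(800L, 500L, 500L, 5L),
    paternal_hyb = c(200L, 500L, 500L, 5L))
  out <- regulatory_calls(genes)
  expect_equal(nrow(out), 3L)           # shallow gene dropped
  expect_equal(attr(out, "dropped")$reason, "parental_depth")
  expect_equal(as.character(out$category),
               c("cis_only", "trans_only", "conserved"))
  expect_equal(out$q_A, bh_adjust(out$p_A))
  expect_equal(out$percent_cis[1], 100)
  expect_equal(out$percent_cis[2], 0)
})

test_that("percent_cis_binned partitions |A| as stated", {
  calls <- data.frame(A = c(0.5, 1.5, 2.5, 5.5, 7),
                      percent_cis = c(10, 20, 30, 40, 60))
  b <- percent_cis_binned(calls)
  expect_equal(b$n[b$bin == "0-1"], 1L)
  expect_equal(b$mean_percent_cis[b$bin == ">=5"], 50)
  expect_equal(sum(b$n), 5L)
})

test_that("parent-label swap negates A and B and preserves categories", {
  cfg <- sim_config(n_genes = 400, site_coverage_mean = 120, seed = 19)
  sim <- simulate_ase(cfg)
  sums <- gene_site_sums(filter_snps(sim$snps))
  fwd <- regulatory_calls(sums)
  rsums <- sums
  rsums$p1_site <- sums$p2_site; rsums$p2_site <- sums$p1_site
  rsums$maternal_hyb <- sums$paternal_hyb
  rsums$paternal_hyb <- sums$maternal_hyb
  bwd <- regulatory_calls(rsums)
  expect_equal(fwd$A, -bwd$A)
  expect_equal(fwd$B, -bwd$B)
  expect_equal(fwd$p_A, bwd$p_A)
  expect_equal(as.character(fwd$category), as.character(bwd$category))
  expect_equal(fwd$interaction, bwd$interaction)
  expect_equal(fwd$percent_cis, bwd$percent_cis)
})

test_that("pure-cis, pure-trans and null constructions are recovered", {
  run_recovery <- function(category, seed) {
    props <- stats::setNames(rep(0, 5), hybridexpr:::.SIM_CATEGORIES)
    props[category] <- 1
    cfg <- sim_config(n_genes = 1000, reg_proportions = props,
                      site_coverage_mean = 200, seed = seed)
    sim <- simulate_ase(cfg)
    sums <- gene_site_sums(filter_snps(sim$snps))
    calls <- regulatory_calls(sums)
    calls <- merge(calls, sim$truth, by = "gene_id")
    deep <- calls$maternal_hyb + calls$paternal_hyb >= 500 &
      abs(calls$true_A) >= 2
    if (category == "conserved") deep <- rep(TRUE, nrow(calls))
    table(calls$category[deep]) / sum(deep)
  }
  cis <- run_recovery("cis_only", 101)
  expect_gte(cis[["cis_only"]], 0.95)
  trans <- run_recovery("trans_only", 102)
  expect_gte(trans[["trans_only"]], 0.90)
  null <- run_recovery("conserved", 103)
  expect_gte(null[["conserved"]], 0.95)
})

test_that("crosstab against inheritance matches a manual tally", {
  reg <- data.frame(gene_id = paste0("g", 1:6),
                    A = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
                    category = factor(rep(c("cis_only", "trans_only"), 3),
                                      levels = hybridexpr:::.REG_CATEGORIES))
  inh <- data.frame(gene_id = paste0("g", 1:6),
                    mode = factor(rep(c("additive", "conserved", "additive"), 2),
                                  levels = hybridexpr:::.MODES))
  ct <- crosstab_regulation_inheritance(reg, inh)
  expect_equal(ct$n_shared, 6L)
  expect_equal(unname(ct$table["cis_only", "additive"]), 2L)
  expect_equal(unname(ct$table["trans_only", "conserved"]), 1L)
  expect_equal(sum(ct$table), 6)
  expect_warning(crosstab_regulation_inheritance(
    reg, data.frame(gene_id = "zz", mode = "additive")), "share no genes")
})
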