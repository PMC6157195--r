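test_that("single-replicate experiments give 0/1 proportions and full accounting", {
  cat <- build_set_catalogue(major = FALSE, n_noncausal_genes = 3,
                             noncausal_sizes = c(4, 6), seed = 71)
  cfg <- experiment_config(cat, n_individuals = 80, n_replicates = 1, B = 60,
                           master_seed = 72)
  pt <- run_experiment(cfg)
  expect_true(all(pt$rejection_proportion %in% c(0, 1)))
  expect_true(all(pt$n_replicates == 1))
  # 3 genes x (6 combiners + single marker)
  expect_equal(nrow(pt), 3L * 7L)
  expect_equal(length(attr(pt, "failures")), 0L)
})

test_that("experiments are deterministic and reports round-trip byte-identically", {
  cat <- build_set_catalogue(major = FALSE, n_noncausal_genes = 2,
                             noncausal_sizes = 5, seed = 73)
  cfg <- experiment_config(cat, n_individuals = 70, n_replicates = 2, B = 50,
                           master_seed = 74)
  pt1 <- run_experiment(cfg)
  pt2 <- run_experiment(cfg)
  expect_identical(as.data.frame(pt1), as.data.frame(pt2))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- report(pt1, d1); p2 <- report(pt2, d2)
  expect_identical(readLines(p1[["power"]]), readLines(p2[["power"]]))
  back <- read_power_table(p1[["power"]])
  expect_equal(back$rejection_proportion, pt1$rejection_proportion)
  expect_equal(back$gene_id, pt1$gene_id)
  expect_true(file.exists(p1[["manifest"]]))
})

test_that("a pure-causal set is rejected by every method in one replicate", {
  cat <- build_set_catalogue(major = TRUE, sets = "CAUSAL5", seed = 75)
  # drop the major genes themselves to keep this fast; keep the CAUSAL5 set
  cat$genes <- cat$genes[0, , drop = FALSE]
  cfg <- experiment_config(cat, n_replicates = 1, B = 200, master_seed = 76)
  pt <- run_experiment(cfg)
  c5 <- pt[pt$gene_id == "CAUSAL5", ]
  expect_equal(nrow(c5), 7L)
  expect_true(all(c5$rejection_proportion == 1))
})

test_that("power rises with heritability for a single causal pair", {
  # n chosen so power is interior at the lowest heritability
  n <- 150
  power_at <- function(h2, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      ped <- build_pedigree(n, sibship_sizes = 2)
      snps <- data.frame(snp_id = "s1", chrom = "1", pos = 100L, maf = 0.3,
                         stringsAsFactors = FALSE)
      cpgs <- data.frame(cpg_id = "c1", chrom = "1", pos = 111L,
                         stringsAsFactors = FALSE)
      sc <- sim_scenario(snps, cpgs,
                         causal = data.frame(snp_id = "s1", cpg_id = "c1", h2 = h2),
                         n_individuals = n, sigma2_g = 0.2)
      cohort <- simulate_cohort(sc, seed = s, pedigree = ped)
      ph <- derive_phenotype(cohort$phenotype)
      covars <- ph[, c("age", "ln_tg_base")]
      fit <- fit_stage1(ph$y, covars, cohort$kinship)
      pm <- pair_snps_to_cpgs(cohort$genotypes, cohort$methylation)
      pm <- assemble_gene_sets(pm, data.frame(gene_id = "g", chrom = "1",
                                              start = 1L, stop = 200L,
                                              category = "major_causal"))
      plan <- make_plan(n, 199, seed = s + 1)
      res <- run_gene_tests(fit$residuals, cohort$genotypes,
                            cohort$methylation, pm, plan)
      any(res$gene_results$significant[res$gene_results$method == "pt_0.05"])
    }, logical(1)))
  }
  seeds <- 300 + 1:40
  p_low <- power_at(0.025, seeds)
  p_mid <- power_at(0.075, seeds)
  p_high <- power_at(0.125, seeds)
  se <- sqrt(0.25 / 40)
  expect_gte(p_mid, p_low - 2 * se)
  expect_gte(p_high, p_mid - 2 * se)
  expect_gt(p_high, p_low)   # strict rise across the full range
})

test_that("failed replicates are logged and excluded from denominators", {
  cat <- build_set_catalogue(major = FALSE, n_noncausal_genes = 1,
                             noncausal_sizes = 4, seed = 77)
  cfg <- experiment_config(cat, n_individuals = 12, n_replicates = 2, B = 20,
                           master_seed = 78)   # too few observations: stage 2 errors
  expect_error(run_experiment(cfg), "all replicates failed")
})
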