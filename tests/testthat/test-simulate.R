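founder_pedigree <- function(n) {
  ped <- data.frame(family_id = paste0("F", seq_len(n)),
                    individual_id = sprintf("I%05d", seq_len(n)),
                    father_id = NA_character_, mother_id = NA_character_,
                    sex = 1L, stringsAsFactors = FALSE)
  class(ped) <- c("methgene_pedigree", "data.frame")
  ped
}

test_that("founder genotypes follow Hardy-Weinberg proportions at the stated MAF", {
  ped <- founder_pedigree(4000)
  g <- simulate_genotypes(ped, mafs = 0.5, positions = 100, seed = 2)
  freq <- tabulate(g$values[, 1] + 1L, 3) / 4000
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 4000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  g0 <- simulate_genotypes(ped, mafs = 1e-8, positions = 100, seed = 2)
  expect_true(all(g0$values == 0))
  expect_error(simulate_genotypes(ped, mafs = 0.6, positions = 100), "0, 0.5")
})

test_that("sib genotype covariance reflects Mendelian transmission", {
  ped <- build_pedigree(3000, sibship_sizes = 2, seed = 4)
  maf <- 0.3
  g <- simulate_genotypes(ped, mafs = maf, positions = 100, seed = 8)
  sib1 <- which(!is.na(ped$father_id))[c(TRUE, FALSE)]
  cv <- stats::cov(g$values[sib1, 1], g$values[sib1 + 1, 1])
  expected <- 2 * 0.25 * 2 * maf * (1 - maf)  # 2*phi*Var(allele dose)/... = 0.5*2pq
  expect_lt(abs(cv - expected), 4 * 2 * maf * (1 - maf) / sqrt(length(sib1)))
})

test_that("methylation draws honour the beta distribution and bounds", {
  m <- simulate_methylation(10000, cpg_positions = c(50, 150), beta_params = c(1, 1), seed = 1)
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_lt(abs(mean(m$values[, 1]) - 0.5), 3 * sqrt(1 / 12 / 10000))

  m2 <- simulate_methylation(10000, cpg_positions = 50, beta_params = c(2, 2), seed = 2)
  expect_lt(abs(mean(m2$values) - 0.5), 0.01)
  expect_lt(abs(stats::var(as.vector(m2$values)) - 0.05), 0.005)

  m0 <- simulate_methylation(100, cpg_positions = 50, constant = 0)
  expect_true(all(m0$values == 0))
})

test_that("effect calibration matches the closed form and Monte Carlo variance shares", {
  expect_equal(calibrate_effect_size(0, 0.3), 0)
  # CPG identically 0: beta = sqrt(h2 / Var(SNP)), Var(SNP) = 2*maf*(1-maf)
  expect_equal(calibrate_effect_size(0.125, 0.11, meth_dist = 0),
               sqrt(0.125 / (2 * 0.11 * 0.89)), tolerance = 1e-12)
  expect_error(calibrate_effect_size(1, 0.3), "0, 1")

  set.seed(11)
  for (case in list(c(0.125, 0.11), c(0.05, 0.41), c(0.025, 0.14))) {
    h2 <- case[1]; maf <- case[2]
    beta <- calibrate_effect_size(h2, maf, meth_dist = c(2, 2))
    s <- rbinom(1e6, 2, maf); w <- 1 - rbeta(1e6, 2, 2)
    share <- stats::var(beta * s * w)
    expect_lt(abs(share - h2), 3 * h2 / sqrt(5e5))
  }
})

test_that("phenotype variance decomposition follows the scenario", {
  snps <- data.frame(snp_id = "s1", chrom = "1", pos = 100L, maf = 0.25,
                     stringsAsFactors = FALSE)
  cpgs <- data.frame(cpg_id = "c1", chrom = "1", pos = 111L,
                     stringsAsFactors = FALSE)
  sc <- sim_scenario(snps, cpgs,
                     causal = data.frame(snp_id = "s1", cpg_id = "c1", h2 = 0.125),
                     n_individuals = 670, sigma2_g = 0.2)
  shares <- replicate(25, {
    cohort <- simulate_cohort(sc, seed = sample.int(1e6, 1))
    lat <- attr(cohort$phenotype, "latent_change")
    ct <- attr(cohort$phenotype, "causal_term")
    stats::cor(ct, lat)^2
  })
  expect_lt(abs(mean(shares) - 0.125), 0.02)

  # sib intraclass covariance of the change score ~ 2 * 0.25 * sigma2_g
  sc0 <- sim_scenario(snps, cpgs, n_individuals = 670, sibship_sizes = 2,
                      sigma2_g = 0.3)
  covs <- replicate(40, {
    cohort <- simulate_cohort(sc0, seed = sample.int(1e6, 1))
    ped <- cohort$pedigree
    lat <- attr(cohort$phenotype, "latent_change")
    sib1 <- which(!is.na(ped$father_id))[c(TRUE, FALSE)]
    stats::cov(lat[sib1], lat[sib1 + 1])
  })
  expect_lt(abs(mean(covs) - 2 * 0.25 * 0.3), 0.03)
})

test_that("identical seeds give bit-identical cohorts", {
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = "1", pos = c(100L, 300L),
                     maf = c(0.2, 0.4), stringsAsFactors = FALSE)
  cpgs <- data.frame(cpg_id = c("c1", "c2"), chrom = "1", pos = c(111L, 311L),
                     stringsAsFactors = FALSE)
  sc <- sim_scenario(snps, cpgs, n_individuals = 50, missing_rate = 0.02)
  expect_identical(simulate_cohort(sc, seed = 99), simulate_cohort(sc, seed = 99))
})

test_that("scenario validation enforces the variance budget", {
  snps <- data.frame(snp_id = "s1", chrom = "1", pos = 100L, maf = 0.25,
                     stringsAsFactors = FALSE)
  cpgs <- data.frame(cpg_id = "c1", chrom = "1", pos = 111L,
                     stringsAsFactors = FALSE)
  expect_error(sim_scenario(snps, cpgs,
                            causal = data.frame(snp_id = "s1", cpg_id = "c1", h2 = 0.9),
                            sigma2_g = 0.2), "< 1")
  expect_error(sim_scenario(transform(snps, maf = 0.7), cpgs), "0, 0.5")
})
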