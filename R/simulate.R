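#' Simulate genotypes by Mendelian gene dropping
#'
#' Founder alleles are drawn independently at the stated minor allele
#' frequency; every non-founder receives one uniformly chosen allele from
#' each parent, independently per SNP (no linkage between SNPs). Entries are
#' minor-allele counts in `{0, 1, 2}`, with optional missingness applied
#' completely at random.
#'
#' @param ped Pedigree (parents precede children).
#' @param mafs Minor allele frequencies, each in (0, 0.5].
#' @param positions 1-based basepair positions, strictly increasing within a
#'   chromosome.
#' @param seed Optional integer seed.
#' @param chrom Chromosome label(s), recycled to `length(mafs)`.
#' @param snp_ids Optional SNP identifiers (default `snp1, snp2, ...`).
#' @param missing_rate Probability that an individual genotype is set
#'   missing (default 0).
#' @return An object of class `snp_matrix`: a list with `values` (n x S
#'   integer matrix, possibly with `NA`) and `info` (data frame with
#'   `snp_id`, `chrom`, `pos`, `maf`).
#' @export
simulate_genotypes <- function(ped, mafs, positions, seed = NULL,
                               chrom = "1", snp_ids = NULL,
                               missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (any(mafs <= 0 | mafs > 0.5)) stop("`mafs` must lie in (0, 0.5].")
  S <- length(mafs)
  if (length(positions) != S) stop("`positions` must match `mafs` in length.")
  chrom <- rep_len(as.character(chrom), S)
  for (ch in unique(chrom)) {
    p <- positions[chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within a chromosome")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1).")
  par <- validate_pedigree(ped)
  n <- nrow(ped)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(S))

  a1 <- matrix(0L, n, S)
  a2 <- matrix(0L, n, S)
  founder <- is.na(par$father) & is.na(par$mother)
  nf <- sum(founder)
  if (nf > 0L) {
    pr <- rep(mafs, each = nf)
    a1[founder, ] <- matrix(rbinom(nf * S, 1L, pr), nf, S)
    a2[founder, ] <- matrix(rbinom(nf * S, 1L, pr), nf, S)
  }
  for (i in which(!founder)) {
    fi <- par$father[i]; mi <- par$mother[i]
    if (is.na(fi) || is.na(mi)) stop("non-founders must have both parents in the pedigree")
    pick <- runif(S) < 0.5
    a1[i, ] <- ifelse(pick, a1[fi, ], a2[fi, ])
    pick <- runif(S) < 0.5
    a2[i, ] <- ifelse(pick, a1[mi, ], a2[mi, ])
  }
  values <- a1 + a2
  if (missing_rate > 0) {
    values[matrix(runif(n * S) < missing_rate, n, S)] <- NA_integer_
  }
  dimnames(values) <- list(ped$individual_id, snp_ids)
  structure(list(values = values,
                 info = data.frame(snp_id = snp_ids, chrom = chrom,
                                   pos = as.integer(positions), maf = mafs,
                                   stringsAsFactors = FALSE)),
            class = "snp_matrix")
}

#' Simulate CpG methylation proportions
#'
#' Each value is an independent draw from a beta distribution (default
#' `Beta(2, 2)`), guaranteeing methylation scores in the closed interval
#' \[0, 1\]. A degenerate point-mass option (`constant`) is provided so the
#' unmoderated single-SNP limit can be exercised downstream.
#'
#' @param n Number of individuals, or a pedigree (its row count is used and
#'   its ids become rownames).
#' @param cpg_positions 1-based positions, strictly increasing within a
#'   chromosome.
#' @param beta_params Length-2 positive vector of beta shape parameters.
#' @param seed Optional integer seed.
#' @param chrom Chromosome label(s), recycled.
#' @param cpg_ids Optional CpG identifiers.
#' @param constant If non-`NULL`, every methylation value is this constant
#'   (must lie in \[0, 1\]).
#' @return An object of class `cpg_matrix`: list with `values` (n x C matrix
#'   in \[0, 1\]) and `info` (`cpg_id`, `chrom`, `pos`).
#' @export
simulate_methylation <- function(n, cpg_positions, beta_params = c(2, 2),
                                 seed = NULL, chrom = "1", cpg_ids = NULL,
                                 constant = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- NULL
  if (inherits(n, "data.frame")) {
    ids <- n$individual_id
    n <- nrow(n)
  }
  C <- length(cpg_positions)
  chrom <- rep_len(as.character(chrom), C)
  for (ch in unique(chrom)) {
    p <- cpg_positions[chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within a chromosome")
  }
  if (is.null(cpg_ids)) cpg_ids <- paste0("cpg", seq_len(C))
  if (is.null(constant)) {
    if (length(beta_params) != 2L || any(beta_params <= 0)) {
      stop("`beta_params` must be two positive shape parameters.")
    }
    values <- matrix(rbeta(n * C, beta_params[1], beta_params[2]), n, C)
  } else {
    if (constant < 0 || constant > 1) stop("`constant` must be in [0, 1].")
    values <- matrix(constant, n, C)
  }
  dimnames(values) <- list(ids, cpg_ids)
  structure(list(values = values,
                 info = data.frame(cpg_id = cpg_ids, chrom = chrom,
                                   pos = as.integer(cpg_positions),
                                   stringsAsFactors = FALSE)),
            class = "cpg_matrix")
}

meth_w_moments <- function(meth_dist, moderation) {
  # first two moments of the moderation weight w(CPG)
  if (length(meth_dist) == 1L) {        # point mass at a constant value
    c0 <- meth_dist
    if (c0 < 0 || c0 > 1) stop("constant methylation value must be in [0, 1]")
    ec <- c0; ec2 <- c0^2
  } else {
    a <- meth_dist[1]; b <- meth_dist[2]
    if (a <= 0 || b <= 0) stop("beta shape parameters must be positive")
    ec <- a / (a + b)
    ec2 <- a * (a + 1) / ((a + b) * (a + b + 1))
  }
  if (moderation == "attenuation") {
    list(ew = 1 - ec, ew2 = 1 - 2 * ec + ec2)   # w = 1 - CPG
  } else {
    list(ew = ec, ew2 = ec2)                    # w = CPG
  }
}

#' Calibrate a SNP-by-CpG effect coefficient to a target heritability
#'
#' Returns the coefficient `beta` such that the causal term
#' `beta * SNP * w(CPG)` has variance `h2_target` in a phenotype of total
#' variance 1, with `SNP ~ Binomial(2, maf)` and `CPG` from the stated
#' methylation distribution, assumed independent. Under the default
#' `"attenuation"` moderation `w(CPG) = 1 - CPG`, so full methylation
#' silences the SNP effect. The variance is evaluated analytically from the
#' first two moments of SNP and CPG.
#'
#' @param h2_target Target variance share in \[0, 1).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param meth_dist Either a length-2 vector of beta shape parameters or a
#'   single constant methylation value in \[0, 1\].
#' @param moderation `"attenuation"` (`w = 1 - CPG`, the default) or
#'   `"direct"` (`w = CPG`).
#' @return The effect coefficient `beta` (non-negative scalar).
#' @examples
#' calibrate_effect_size(0.125, 0.11, meth_dist = 0) # CPG identically 0
#' @export
calibrate_effect_size <- function(h2_target, maf, meth_dist = c(2, 2),
                                  moderation = c("attenuation", "direct")) {
  moderation <- match.arg(moderation)
  if (h2_target < 0 || h2_target >= 1) stop("`h2_target` must lie in [0, 1).")
  if (maf <= 0 || maf > 0.5) stop("`maf` must lie in (0, 0.5].")
  if (h2_target == 0) return(0)
  es <- 2 * maf
  es2 <- 2 * maf * (1 - maf) + (2 * maf)^2
  w <- meth_w_moments(meth_dist, moderation)
  v <- es2 * w$ew2 - (es * w$ew)^2
  if (v <= 0) stop("moderated causal term has zero variance; cannot reach a positive h2")
  sqrt(h2_target / v)
}

#' Define a simulation scenario
#'
#' Bundles and validates the generative parameters for one synthetic
#' cohort: marker maps, causal SNP-CpG pairs with target heritabilities,
#' the methylation distribution, covariate effects, and variance
#' components. The total variance of the (covariate-adjusted) change score
#' is normalized to 1, so each causal pair's heritability is its variance
#' share and the residual variance is
#' `1 - sum(h2) - sigma2_g`.
#'
#' @param snps Data frame with `snp_id`, `chrom`, `pos`, `maf`.
#' @param cpgs Data frame with `cpg_id`, `chrom`, `pos`.
#' @param causal Optional data frame with `snp_id`, `cpg_id`, `h2`: the
#'   causal SNP-CpG pairs and their target variance shares.
#' @param n_individuals Cohort size (default 670).
#' @param sibship_sizes Sibship sizes sampled per family.
#' @param sigma2_g Polygenic variance share (default 0.2).
#' @param meth_beta Beta shape parameters of the methylation distribution
#'   (default `c(2, 2)`), or a single constant in \[0, 1\].
#' @param moderation `"attenuation"` or `"direct"` (how methylation scales
#'   the SNP effect).
#' @param covariate_effects Optional named numeric vector of fixed effects
#'   on the change score; names among `age`, `centerB`, `smokingformer`,
#'   `smokingcurrent`, `msdx`, `fasting`. Default: all zero (covariates are
#'   simulated but carry no signal).
#' @param measurement_sd Standard deviation of ln-scale measurement noise
#'   added to each duplicate visit measurement (default 0.05).
#' @param second_measurement_prob Probability that the second visit
#'   measurement is present (default 0.8).
#' @param missing_rate Genotype missingness rate (default 0).
#' @param ln_tg_baseline,ln_hdl_baseline Mean/sd of the latent ln-scale
#'   baseline triglyceride and HDL levels.
#' @return A validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(snps, cpgs, causal = NULL, n_individuals = 670,
                         sibship_sizes = 2:4, sigma2_g = 0.2,
                         meth_beta = c(2, 2),
                         moderation = c("attenuation", "direct"),
                         covariate_effects = NULL,
                         measurement_sd = 0.05,
                         second_measurement_prob = 0.8,
                         missing_rate = 0,
                         ln_tg_baseline = c(mean = 4.7, sd = 0.45),
                         ln_hdl_baseline = c(mean = 3.9, sd = 0.25)) {
  moderation <- match.arg(moderation)
  stopifnot(all(c("snp_id", "chrom", "pos", "maf") %in% names(snps)),
            all(c("cpg_id", "chrom", "pos") %in% names(cpgs)))
  if (any(snps$maf <= 0 | snps$maf > 0.5)) stop("SNP MAFs must lie in (0, 0.5].")
  h2_total <- 0
  if (!is.null(causal) && nrow(causal) > 0) {
    stopifnot(all(c("snp_id", "cpg_id", "h2") %in% names(causal)))
    if (!all(causal$snp_id %in% snps$snp_id)) stop("causal snp_id not in `snps`")
    if (!all(causal$cpg_id %in% cpgs$cpg_id)) stop("causal cpg_id not in `cpgs`")
    if (any(causal$h2 < 0 | causal$h2 >= 1)) stop("heritabilities must lie in [0, 1).")
    h2_total <- sum(causal$h2)
  }
  if (sigma2_g < 0) stop("`sigma2_g` must be non-negative.")
  # accept named or positional (mean, sd) specifications
  ln_tg_baseline <- c(mean = unname(ln_tg_baseline[1]), sd = unname(ln_tg_baseline[2]))
  ln_hdl_baseline <- c(mean = unname(ln_hdl_baseline[1]), sd = unname(ln_hdl_baseline[2]))
  if (anyNA(ln_tg_baseline) || anyNA(ln_hdl_baseline)) {
    stop("baseline distributions need a mean and an sd")
  }
  sigma2_e <- 1 - h2_total - sigma2_g
  if (sigma2_e <= 0) {
    stop("causal heritabilities plus polygenic variance must be < 1 ",
         "(total phenotypic variance is normalized to 1)")
  }
  structure(list(snps = snps, cpgs = cpgs,
                 causal = causal %||% data.frame(snp_id = character(),
                                                 cpg_id = character(),
                                                 h2 = numeric()),
                 n_individuals = n_individuals,
                 sibship_sizes = sibship_sizes,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 meth_beta = meth_beta, moderation = moderation,
                 covariate_effects = covariate_effects,
                 measurement_sd = measurement_sd,
                 second_measurement_prob = second_measurement_prob,
                 missing_rate = missing_rate,
                 ln_tg_baseline = ln_tg_baseline,
                 ln_hdl_baseline = ln_hdl_baseline),
            class = "sim_scenario")
}

covariate_design <- function(pt) {
  cbind(age = (pt$age - 50) / 10,
        centerB = as.numeric(pt$center == "B"),
        smokingformer = as.numeric(pt$smoking == "former"),
        smokingcurrent = as.numeric(pt$smoking == "current"),
        msdx = pt$msdx_score,
        fasting = (pt$fasting_time - 11) / 2)
}

#' Simulate the phenotype table of a cohort
#'
#' Builds the latent change in ln-triglycerides as covariate fixed effects
#' plus the sum of heritability-calibrated causal terms
#' `beta_j * SNP_j * w(CPG_j)`, a polygenic random effect with covariance
#' `2 * Phi * sigma2_g`, and iid Gaussian noise. Baseline ln-TG is drawn
#' independently and follow-up TG is constructed so the latent ln change is
#' exact; duplicate visit measurements (TG baseline/follow-up, HDL
#' baseline) add ln-scale measurement noise.
#'
#' @param scenario A [sim_scenario()].
#' @param geno,meth `snp_matrix` / `cpg_matrix` for the same individuals.
#' @param ped Pedigree.
#' @param seed Optional integer seed.
#' @param kinship Optional precomputed kinship matrix (computed from `ped`
#'   if missing and `sigma2_g > 0`).
#' @return A data frame (class `phenotype_table`) with covariates and up to
#'   two measurements per visit variable; attributes `latent_change` and
#'   `causal_term` hold the noise-free components for diagnostics.
#' @export
simulate_phenotype <- function(scenario, geno, meth, ped, seed = NULL,
                               kinship = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  if (nrow(geno$values) != n || nrow(meth$values) != n) {
    stop("genotype/methylation row counts do not match the pedigree")
  }
  pt <- data.frame(individual_id = ped$individual_id,
                   age = sample(30:75, n, replace = TRUE),
                   center = sample(c("A", "B"), n, replace = TRUE),
                   smoking = sample(c("never", "former", "current"), n,
                                    replace = TRUE, prob = c(0.5, 0.25, 0.25)),
                   msdx_score = rnorm(n),
                   fasting_time = runif(n, 8, 14),
                   stringsAsFactors = FALSE)
  fixed <- rep(0, n)
  if (!is.null(scenario$covariate_effects)) {
    Xc <- covariate_design(pt)
    eff <- scenario$covariate_effects
    bad <- setdiff(names(eff), colnames(Xc))
    if (length(bad)) stop("unknown covariate effect name(s): ", paste(bad, collapse = ", "))
    fixed <- drop(Xc[, names(eff), drop = FALSE] %*% eff)
  }
  causal_term <- rep(0, n)
  cz <- scenario$causal
  if (nrow(cz) > 0) {
    for (j in seq_len(nrow(cz))) {
      sc <- match(cz$snp_id[j], geno$info$snp_id)
      cc <- match(cz$cpg_id[j], meth$info$cpg_id)
      if (is.na(sc) || is.na(cc)) stop("causal pair not present in supplied matrices")
      maf <- scenario$snps$maf[match(cz$snp_id[j], scenario$snps$snp_id)]
      beta <- calibrate_effect_size(cz$h2[j], maf, scenario$meth_beta,
                                    scenario$moderation)
      s <- geno$values[, sc]
      if (anyNA(s)) s[is.na(s)] <- mean(s, na.rm = TRUE)
      w <- if (scenario$moderation == "attenuation") 1 - meth$values[, cc] else meth$values[, cc]
      causal_term <- causal_term + beta * s * w
    }
  }
  g <- rep(0, n)
  if (scenario$sigma2_g > 0) {
    if (is.null(kinship)) kinship <- kinship_from_pedigree(ped)
    u <- chol(2 * kinship)
    g <- sqrt(scenario$sigma2_g) * drop(crossprod(u, rnorm(n)))
  }
  e <- rnorm(n, 0, sqrt(scenario$sigma2_e))
  latent <- fixed + causal_term + g + e

  msd <- scenario$measurement_sd
  p2 <- scenario$second_measurement_prob
  meas <- function(ln_true) {
    m1 <- exp(ln_true + rnorm(n, 0, msd))
    m2 <- exp(ln_true + rnorm(n, 0, msd))
    m2[runif(n) >= p2] <- NA_real_
    list(m1 = m1, m2 = m2)
  }
  ln_tg0 <- rnorm(n, scenario$ln_tg_baseline["mean"], scenario$ln_tg_baseline["sd"])
  ln_hdl0 <- rnorm(n, scenario$ln_hdl_baseline["mean"], scenario$ln_hdl_baseline["sd"])
  tgb <- meas(ln_tg0); tgf <- meas(ln_tg0 + latent); hdl <- meas(ln_hdl0)
  pt$hdl_base_1 <- hdl$m1; pt$hdl_base_2 <- hdl$m2
  pt$tg_base_1 <- tgb$m1; pt$tg_base_2 <- tgb$m2
  pt$tg_followup_1 <- tgf$m1; pt$tg_followup_2 <- tgf$m2
  attr(pt, "latent_change") <- latent
  attr(pt, "causal_term") <- causal_term
  class(pt) <- c("phenotype_table", "data.frame")
  pt
}

#' Simulate a complete cohort
#'
#' Runs pedigree construction, kinship, gene-dropped genotypes, beta
#' methylation and the phenotype model under a single seed, so identical
#' `(scenario, seed)` give a bit-identical cohort. A fixed pedigree (and
#' its kinship) can be supplied to hold family structure constant across
#' replicate phenotype simulations.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed for the whole cohort.
#' @param pedigree,kinship Optional fixed pedigree/kinship.
#' @return A list of class `cohort` with elements `pedigree`, `kinship`,
#'   `genotypes`, `methylation`, `phenotype`, `scenario`.
#' @export
simulate_cohort <- function(scenario, seed = NULL, pedigree = NULL,
                            kinship = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pedigree %||% build_pedigree(scenario$n_individuals,
                                      scenario$sibship_sizes)
  kin <- kinship %||% kinship_from_pedigree(ped)
  geno <- simulate_genotypes(ped, scenario$snps$maf, scenario$snps$pos,
                             chrom = scenario$snps$chrom,
                             snp_ids = scenario$snps$snp_id,
                             missing_rate = scenario$missing_rate)
  constant <- if (length(scenario$meth_beta) == 1L) scenario$meth_beta else NULL
  meth <- simulate_methylation(ped, scenario$cpgs$pos,
                               beta_params = if (is.null(constant)) scenario$meth_beta else c(2, 2),
                               chrom = scenario$cpgs$chrom,
                               cpg_ids = scenario$cpgs$cpg_id,
                               constant = constant)
  pheno <- simulate_phenotype(scenario, geno, meth, ped, kinship = kin)
  structure(list(pedigree = ped, kinship = kin, genotypes = geno,
                 methylation = meth, phenotype = pheno, scenario = scenario),
            class = "cohort")
}
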