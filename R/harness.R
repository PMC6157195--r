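derive_seed <- function(master, index) {
  # deterministic 31-bit stream: replicate seeds are a pure function of the
  # master seed and the replicate index
  ((master %% 2147483647) * 48271 + index * 104729) %% 2147483647 + 1
}

table3_major_genes <- function() {
  data.frame(gene_id = c("major125", "major100", "major075", "major050", "major025"),
             h2 = c(0.125, 0.100, 0.075, 0.050, 0.025),
             m = c(141L, 23L, 63L, 29L, 32L),
             causal_maf = c(0.11, 0.19, 0.10, 0.41, 0.14),
             stringsAsFactors = FALSE)
}

#' Build a gene/set catalogue for simulation experiments
#'
#' Lays out synthetic marker maps (one CpG adjacent to every SNP, SNPs
#' 200 bp apart, genes in well-separated blocks on one chromosome) for up
#' to three gene categories and five named variant sets:
#'
#' * five major-effect genes with pair counts 141/23/63/29/32, one causal
#'   SNP each with heritabilities 0.125/0.10/0.075/0.05/0.025 and minor
#'   allele frequencies 0.11/0.19/0.10/0.41/0.14;
#' * minor-effect genes with one causal SNP of heritability 0.001 each;
#' * noncausal genes of configurable sizes;
#' * sets `CAUSAL5` (the 5 major causal pairs only), `UNION5` / `UNION2`
#'   (unions of all five / of the 0.075 and 0.05 genes: 288 and 92 pairs),
#'   and `NOISE5` / `NOISE2` (the same 5 / 2 causal pairs spiked into
#'   independent noise pairs, `noise5_size` / `noise2_size` pairs total).
#'
#' Non-causal ("noise") SNP frequencies are drawn once from
#' `noise_maf_range` under `seed`; the catalogue is a fixed design reused
#' across replicates.
#'
#' @param major Include the five major-effect genes.
#' @param n_minor_genes Number of minor-effect genes (h2 = 0.001).
#' @param n_noncausal_genes Number of noncausal genes.
#' @param noncausal_sizes Pair counts of the noncausal genes (recycled;
#'   default cycles 5, 10, 15, 20, 25, 30).
#' @param sets Which named sets to construct (subset of `CAUSAL5`,
#'   `UNION5`, `UNION2`, `NOISE5`, `NOISE2`; all require `major`).
#' @param noise5_size,noise2_size Total pair counts of the spiked sets.
#' @param noise_maf_range Range of noise-SNP minor allele frequencies.
#' @param minor_m_range Range of minor-gene pair counts.
#' @param seed Seed for the catalogue's random design quantities.
#' @return A list of class `catalogue`: `snps`, `cpgs`, `causal`, `genes`,
#'   `sets`, `overrides`, `major_snp_ids`.
#' @export
build_set_catalogue <- function(major = TRUE, n_minor_genes = 0,
                                n_noncausal_genes = 0,
                                noncausal_sizes = NULL,
                                sets = character(0),
                                noise5_size = 288, noise2_size = 92,
                                noise_maf_range = c(0.05, 0.5),
                                minor_m_range = c(5, 20), seed = 1) {
  if (length(sets)) {
    sets <- match.arg(sets, c("CAUSAL5", "UNION5", "UNION2", "NOISE5", "NOISE2"),
                      several.ok = TRUE)
  }
  if (length(sets) && !major) stop("named sets require the major-effect genes")
  set.seed(seed)
  spacing <- 200L; gap <- 120000L
  pos_cursor <- 1000L
  snps <- list(); cpgs <- list(); genes <- list(); causal <- list()

  add_block <- function(block_id, m, causal_idx = NA, causal_maf = NA,
                        h2 = NA, category = "noncausal", as_gene = TRUE) {
    p0 <- pos_cursor
    spos <- p0 + (seq_len(m) - 1L) * spacing
    maf <- runif(m, noise_maf_range[1], noise_maf_range[2])
    ids <- sprintf("%s_snp%03d", block_id, seq_len(m))
    if (!is.na(causal_idx)) {
      maf[causal_idx] <- causal_maf
      ids[causal_idx] <- paste0(block_id, "_causal")
    }
    snps[[block_id]] <<- data.frame(snp_id = ids, chrom = "1", pos = spos,
                                    maf = maf, stringsAsFactors = FALSE)
    cpgs[[block_id]] <<- data.frame(cpg_id = paste0("cg_", ids), chrom = "1",
                                    pos = spos + 11L, stringsAsFactors = FALSE)
    if (as_gene) {
      genes[[block_id]] <<- data.frame(gene_id = block_id, chrom = "1",
                                       start = min(spos) - 50L,
                                       stop = max(spos) + 50L,
                                       category = category,
                                       stringsAsFactors = FALSE)
    }
    if (!is.na(causal_idx)) {
      causal[[block_id]] <<- data.frame(snp_id = ids[causal_idx],
                                        cpg_id = paste0("cg_", ids[causal_idx]),
                                        h2 = h2, stringsAsFactors = FALSE)
    }
    pos_cursor <<- max(spos) + gap
    ids
  }

  major_ids <- character(0)
  if (major) {
    tab <- table3_major_genes()
    for (g in seq_len(nrow(tab))) {
      ids <- add_block(tab$gene_id[g], tab$m[g],
                       causal_idx = ceiling(tab$m[g] / 2),
                       causal_maf = tab$causal_maf[g], h2 = tab$h2[g],
                       category = "major_causal")
      major_ids <- c(major_ids, ids[ceiling(tab$m[g] / 2)])
    }
  }
  if (n_minor_genes > 0) {
    msz <- sample(seq(minor_m_range[1], minor_m_range[2]), n_minor_genes,
                  replace = TRUE)
    for (g in seq_len(n_minor_genes)) {
      add_block(sprintf("minor%02d", g), msz[g],
                causal_idx = ceiling(msz[g] / 2),
                causal_maf = runif(1, noise_maf_range[1], noise_maf_range[2]),
                h2 = 0.001, category = "minor_causal")
    }
  }
  if (n_noncausal_genes > 0) {
    sz <- rep_len(noncausal_sizes %||% c(5L, 10L, 15L, 20L, 25L, 30L),
                  n_noncausal_genes)
    for (g in seq_len(n_noncausal_genes)) {
      add_block(sprintf("null%02d", g), sz[g], category = "noncausal")
    }
  }
  set_list <- list()
  gene_causal_ids <- function(gids) {
    vapply(gids, function(g) paste0(g, "_causal"), character(1))
  }
  if ("CAUSAL5" %in% sets) {
    set_list$CAUSAL5 <- list(snp_ids = unname(gene_causal_ids(table3_major_genes()$gene_id)),
                             category = "synthetic_set")
  }
  if ("UNION5" %in% sets) {
    set_list$UNION5 <- list(genes = table3_major_genes()$gene_id,
                            category = "synthetic_set")
  }
  if ("UNION2" %in% sets) {
    set_list$UNION2 <- list(genes = c("major075", "major050"),
                            category = "synthetic_set")
  }
  if ("NOISE5" %in% sets) {
    extra <- add_block("noise5pool", noise5_size - 5L, as_gene = FALSE)
    set_list$NOISE5 <- list(snp_ids = c(unname(gene_causal_ids(table3_major_genes()$gene_id)), extra),
                            category = "synthetic_set")
  }
  if ("NOISE2" %in% sets) {
    extra <- add_block("noise2pool", noise2_size - 2L, as_gene = FALSE)
    set_list$NOISE2 <- list(snp_ids = c(unname(gene_causal_ids(c("major075", "major050"))), extra),
                            category = "synthetic_set")
  }
  snps <- do.call(rbind, c(snps, list(make.row.names = FALSE)))
  cpgs <- do.call(rbind, c(cpgs, list(make.row.names = FALSE)))
  causal <- if (length(causal)) do.call(rbind, c(causal, list(make.row.names = FALSE)))
            else data.frame(snp_id = character(), cpg_id = character(), h2 = numeric())
  genes <- do.call(rbind, c(genes, list(make.row.names = FALSE)))
  overrides <- causal[, c("snp_id", "cpg_id"), drop = FALSE]
  structure(list(snps = snps, cpgs = cpgs, causal = causal, genes = genes,
                 sets = set_list, overrides = overrides,
                 major_snp_ids = major_ids),
            class = "catalogue")
}

#' Configure a replicate experiment
#'
#' @param catalogue A [build_set_catalogue()] object.
#' @param n_individuals Cohort size (default 670).
#' @param sibship_sizes Family sibship sizes (default 2:4).
#' @param sigma2_g Polygenic variance share (default 0.2).
#' @param n_replicates Number of replicate cohorts (default 200).
#' @param B Permutations per replicate (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param master_seed Master seed; replicate seeds are derived
#'   deterministically from it.
#' @param qc [qc_thresholds()] applied to each replicate's genotypes.
#' @param meth_beta,moderation,covariate_effects,measurement_sd,missing_rate
#'   Passed to [sim_scenario()].
#' @param include_intercept Stage-2 intercept switch.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(catalogue, n_individuals = 670,
                              sibship_sizes = 2:4, sigma2_g = 0.2,
                              n_replicates = 200, B = 1000, alpha = 0.05,
                              master_seed = 1, qc = qc_thresholds(),
                              meth_beta = c(2, 2),
                              moderation = "attenuation",
                              covariate_effects = NULL,
                              measurement_sd = 0.05, missing_rate = 0,
                              include_intercept = TRUE) {
  stopifnot(inherits(catalogue, "catalogue"), n_replicates >= 1, B >= 1)
  structure(list(catalogue = catalogue, n_individuals = n_individuals,
                 sibship_sizes = sibship_sizes, sigma2_g = sigma2_g,
                 n_replicates = n_replicates, B = B, alpha = alpha,
                 master_seed = master_seed, qc = qc, meth_beta = meth_beta,
                 moderation = moderation,
                 covariate_effects = covariate_effects,
                 measurement_sd = measurement_sd,
                 missing_rate = missing_rate,
                 include_intercept = include_intercept),
            class = "experiment_config")
}

scenario_from_config <- function(cfg) {
  cat <- cfg$catalogue
  sim_scenario(snps = cat$snps, cpgs = cat$cpgs, causal = cat$causal,
               n_individuals = cfg$n_individuals,
               sibship_sizes = cfg$sibship_sizes, sigma2_g = cfg$sigma2_g,
               meth_beta = cfg$meth_beta, moderation = cfg$moderation,
               covariate_effects = cfg$covariate_effects,
               measurement_sd = cfg$measurement_sd,
               missing_rate = cfg$missing_rate)
}

run_replicate <- function(cfg, scenario, ped, kin, eig, seed) {
  cat <- cfg$catalogue
  cohort <- simulate_cohort(scenario, seed = seed, pedigree = ped,
                            kinship = kin)
  keep <- qc_filter(cohort$genotypes, cfg$qc)
  geno <- subset_markers(cohort$genotypes, keep)
  ov <- cat$overrides[cat$overrides$snp_id %in% geno$info$snp_id, , drop = FALSE]
  pm <- pair_snps_to_cpgs(geno, cohort$methylation, overrides = ov)
  pm <- assemble_gene_sets(pm, cat$genes, major_snp_ids = cat$major_snp_ids,
                           sets = cat$sets)
  ph <- suppressMessages(derive_phenotype(cohort$phenotype))
  covars <- ph[, c("age", "center", "smoking", "msdx_score", "fasting_time",
                   "ln_hdl_base", "ln_tg_base")]
  idx <- match(ph$individual_id, ped$individual_id)
  full <- length(idx) == nrow(ped) && all(idx == seq_len(nrow(ped)))
  fit <- fit_stage1(ph$y, covars, kin[idx, idx, drop = FALSE],
                    kinship_eigen = if (full) eig else NULL)
  geno$values <- geno$values[idx, , drop = FALSE]
  meth <- cohort$methylation
  meth$values <- meth$values[idx, , drop = FALSE]
  plan <- make_plan(length(fit$residuals), cfg$B,
                    seed = derive_seed(seed, 999983))
  suppressMessages(run_gene_tests(fit$residuals, geno, meth, pm, plan,
                                  alpha = cfg$alpha,
                                  include_intercept = cfg$include_intercept))
}

#' Run a replicate power / type-I-error experiment
#'
#' For each replicate: simulate a cohort, apply QC, pair SNPs to CpGs,
#' assemble genes and sets, residualize the phenotype (stage 1), fit every
#' pair model (stage 2), combine per-gene statistics, assess significance
#' by shared-shuffle permutation, and record the decisions (including the
#' single-marker Bonferroni rule). Family structure is held fixed across
#' replicates; genotypes, methylation and phenotype are regenerated. Failed
#' replicates are logged and excluded from denominators.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Emit a progress message every 10 replicates.
#' @return A data frame of class `power_table` with one row per gene/set
#'   and method (`single_marker` included): `gene_id`, `category`,
#'   `method`, `rejections`, `n_replicates`, `rejection_proportion`.
#'   Attributes: `"pooled"` (category x method proportions) and
#'   `"failures"` (character vector of per-replicate error messages).
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  scenario <- scenario_from_config(cfg)
  ped <- build_pedigree(cfg$n_individuals, cfg$sibship_sizes,
                        seed = derive_seed(cfg$master_seed, 0))
  kin <- kinship_from_pedigree(ped)
  eig <- eigen(2 * kin, symmetric = TRUE)
  decisions <- list()
  failures <- character(0)
  for (i in seq_len(cfg$n_replicates)) {
    res <- tryCatch(
      run_replicate(cfg, scenario, ped, kin, eig,
                    seed = derive_seed(cfg$master_seed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", i, conditionMessage(res)))
      next
    }
    gr <- res$gene_results[, c("gene_id", "category", "method", "significant")]
    sm <- data.frame(gene_id = res$single_marker$gene_id,
                     category = res$single_marker$category,
                     method = "single_marker",
                     significant = res$single_marker$significant,
                     stringsAsFactors = FALSE)
    decisions[[i]] <- rbind(gr, sm)
    if (verbose && i %% 10 == 0) message("completed replicate ", i, "/", cfg$n_replicates)
  }
  if (!length(decisions)) stop("all replicates failed: ", failures[1])
  all_dec <- do.call(rbind, decisions)
  agg <- stats::aggregate(significant ~ gene_id + category + method,
                          data = all_dec,
                          FUN = function(x) c(rej = sum(x), n = length(x)))
  out <- data.frame(gene_id = agg$gene_id, category = agg$category,
                    method = agg$method,
                    rejections = agg$significant[, "rej"],
                    n_replicates = agg$significant[, "n"],
                    stringsAsFactors = FALSE)
  out$rejection_proportion <- out$rejections / out$n_replicates
  out <- out[order(out$gene_id, out$method), , drop = FALSE]
  rownames(out) <- NULL
  pooled_agg <- stats::aggregate(significant ~ category + method,
                                 data = all_dec,
                                 FUN = function(x) c(rej = sum(x), n = length(x)))
  pooled <- data.frame(category = pooled_agg$category,
                       method = pooled_agg$method,
                       rejections = pooled_agg$significant[, "rej"],
                       n = pooled_agg$significant[, "n"],
                       stringsAsFactors = FALSE)
  pooled$rejection_proportion <- pooled$rejections / pooled$n
  class(out) <- c("power_table", "data.frame")
  attr(out, "pooled") <- pooled
  attr(out, "failures") <- failures
  attr(out, "config") <- cfg[setdiff(names(cfg), "catalogue")]
  out
}

#' Write experiment reports
#'
#' Writes the per-gene power table and the category-pooled table as TSV, a
#' short human-readable summary, and a JSON run manifest (seed, replicate
#' counts, failures).
#'
#' @param power_table Result of [run_experiment()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"experiment"`).
#' @return Invisibly, the paths written.
#' @export
report <- function(power_table, dir, prefix = "experiment") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(power = file.path(dir, paste0(prefix, "_power.tsv")),
             pooled = file.path(dir, paste0(prefix, "_pooled.tsv")),
             summary = file.path(dir, paste0(prefix, "_summary.txt")),
             manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  write.table(as.data.frame(power_table), paths["power"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  pooled <- attr(power_table, "pooled")
  write.table(pooled, paths["pooled"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- attr(power_table, "config")
  con <- file(paths["summary"], "w")
  writeLines(c("Gene-based methylation-moderated association experiment",
               sprintf("replicates requested: %s, alpha = %s, B = %s",
                       cfg$n_replicates %||% NA, cfg$alpha %||% NA, cfg$B %||% NA),
               "", "Pooled rejection proportions (category x method):",
               utils::capture.output(print(pooled, row.names = FALSE))), con)
  close(con)
  manifest <- list(master_seed = cfg$master_seed, alpha = cfg$alpha,
                   B = cfg$B, n_replicates = cfg$n_replicates,
                   n_rows = nrow(power_table),
                   failures = attr(power_table, "failures"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a power table written by [report()]
#'
#' @param path Path to the `_power.tsv` file.
#' @return A `power_table` data frame (without pooled/failure attributes).
#' @export
read_power_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(out) <- c("power_table", "data.frame")
  out
}
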