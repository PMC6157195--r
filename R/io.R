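#' Marker-matrix TSV input/output
#'
#' Genotype and methylation matrices are stored as tab-separated text with
#' one marker per row: the id/chrom/pos columns followed by one column per
#' individual.
#'
#' @param x A `snp_matrix` or `cpg_matrix`.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the
#'   reconstructed object.
#' @export
write_genotypes_tsv <- function(x, path) {
  ind <- rownames(x$values) %||% paste0("ind", seq_len(nrow(x$values)))
  out <- cbind(x$info, as.data.frame(t(x$values)))
  colnames(out) <- c(colnames(x$info), ind)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  meta <- intersect(c("snp_id", "chrom", "pos", "maf"), colnames(x))
  vals <- t(as.matrix(x[, setdiff(colnames(x), meta), drop = FALSE]))
  colnames(vals) <- x$snp_id
  info <- x[, meta, drop = FALSE]
  info$chrom <- as.character(info$chrom)
  structure(list(values = vals, info = info), class = "snp_matrix")
}

#' @rdname write_genotypes_tsv
#' @export
write_methylation_tsv <- function(x, path) {
  ind <- rownames(x$values) %||% paste0("ind", seq_len(nrow(x$values)))
  out <- cbind(x$info, as.data.frame(t(x$values)))
  colnames(out) <- c(colnames(x$info), ind)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_methylation_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  meta <- intersect(c("cpg_id", "chrom", "pos"), colnames(x))
  vals <- t(as.matrix(x[, setdiff(colnames(x), meta), drop = FALSE]))
  colnames(vals) <- x$cpg_id
  info <- x[, meta, drop = FALSE]
  info$chrom <- as.character(info$chrom)
  structure(list(values = vals, info = info), class = "cpg_matrix")
}

#' Write genotypes as plain-text VCFv4.2
#'
#' Minor-allele counts are encoded as unphased genotypes (`0/0`, `0/1`,
#' `1/1`, `./.` for missing) with placeholder `A`/`G` alleles. Reading back
#' requires the vcfR package.
#'
#' @param geno A `snp_matrix`.
#' @param path Output `.vcf` path (uncompressed text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  ind <- rownames(geno$values) %||% paste0("ind", seq_len(nrow(geno$values)))
  gt <- apply(geno$values, 2, function(col) {
    c("0/0", "0/1", "1/1")[col + 1L]
  })
  gt[is.na(gt)] <- "./."
  gt <- t(gt)                                  # markers x individuals
  header <- c("##fileformat=VCFv4.2",
              "##source=methgene",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ind), collapse = "\t"))
  body <- paste(geno$info$chrom, geno$info$pos, geno$info$snp_id, "A", "G",
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a snp_matrix (via vcfR)
#'
#' @param path VCF file path.
#' @return A `snp_matrix`; ALT-allele dosages 0/1/2 with `NA` for missing.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    known <- !is.na(x) & !grepl("\\.", x)
    parts <- strsplit(x[known], "[/|]")
    out[known] <- vapply(parts, function(p) sum(as.integer(p) > 0), integer(1))
    out
  }
  vals <- apply(gt, 2, count_alt)              # individuals in columns of gt
  vals <- t(matrix(vals, nrow = nrow(gt),
                   dimnames = list(rownames(gt), colnames(gt))))
  fix <- vcfR::getFIX(v)
  structure(list(values = vals,
                 info = data.frame(snp_id = unname(fix[, "ID"]),
                                   chrom = unname(fix[, "CHROM"]),
                                   pos = as.integer(fix[, "POS"]),
                                   stringsAsFactors = FALSE)),
            class = "snp_matrix")
}

#' Gene-definition BED input/output
#'
#' Genes are held 1-based inclusive internally; BED files are 0-based
#' half-open, so `start` is decremented on write and incremented on read.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `stop` (and
#'   optionally `category`, carried in column 5).
#' @param path File path.
#' @return `write_bed_genes()` returns `path` invisibly; `read_bed_genes()`
#'   the genes data frame.
#' @export
write_bed_genes <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$stop, name = genes$gene_id,
                    score = if ("category" %in% names(genes)) genes$category else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_genes
#' @export
read_bed_genes <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(gene_id = x$V4, chrom = as.character(x$V1),
                    start = x$V2 + 1L, stop = x$V3, stringsAsFactors = FALSE)
  if (ncol(x) >= 5 && !all(x$V5 == ".")) out$category <- x$V5
  out
}

#' Residuals and stage-1 fit-report output
#'
#' @param fit A `stage1_fit`.
#' @param path Output path (TSV for residuals, JSON for the report).
#' @return `path`, invisibly.
#' @export
write_residuals_tsv <- function(fit, path) {
  out <- data.frame(individual_id = names(fit$residuals) %||%
                      seq_along(fit$residuals),
                    residual = unname(fit$residuals))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_residuals_tsv
#' @export
write_stage1_report <- function(fit, path) {
  jsonlite::write_json(list(fixed_effects = as.list(fit$fixed_effects),
                            sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                            lambda = fit$lambda,
                            loglik_reml = fit$loglik_reml, n = fit$n),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pair- and gene-level result tables
#'
#' @param x Result data frame ([fit_all_pairs()] output or the
#'   `gene_results` element of [run_gene_tests()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_results <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_results
#' @export
write_gene_results <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Scenario configuration input/output (JSON or YAML)
#'
#' Serializes the generative parameters of a [sim_scenario()] (marker
#' tables, causal pairs, variance components, distributions) together with
#' an explicit seed. Format is chosen by file extension: `.json` (default)
#' or `.yml`/`.yaml` (requires the yaml package).
#'
#' @param scenario A `sim_scenario`.
#' @param path Output path.
#' @param seed Seed recorded alongside the scenario.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns `list(scenario, seed)`.
#' @export
write_scenario_config <- function(scenario, path, seed = NULL) {
  obj <- unclass(scenario)
  obj$seed <- seed
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML output requires the yaml package")
    }
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML input requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- obj$seed
  scenario <- sim_scenario(snps = as.data.frame(obj$snps),
                           cpgs = as.data.frame(obj$cpgs),
                           causal = if (length(obj$causal$snp_id)) as.data.frame(obj$causal) else NULL,
                           n_individuals = obj$n_individuals,
                           sibship_sizes = obj$sibship_sizes,
                           sigma2_g = obj$sigma2_g,
                           meth_beta = unlist(obj$meth_beta),
                           moderation = obj$moderation,
                           covariate_effects = if (length(obj$covariate_effects)) unlist(obj$covariate_effects) else NULL,
                           measurement_sd = obj$measurement_sd,
                           second_measurement_prob = obj$second_measurement_prob,
                           missing_rate = obj$missing_rate,
                           ln_tg_baseline = unlist(obj$ln_tg_baseline),
                           ln_hdl_baseline = unlist(obj$ln_hdl_baseline))
  list(scenario = scenario, seed = seed)
}
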