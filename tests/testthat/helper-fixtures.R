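# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

make_snp_matrix <- function(values, pos = NULL, chrom = "1", mafs = NULL) {
  S <- ncol(values)
  pos <- pos %||% seq(100L, by = 200L, length.out = S)
  structure(list(values = values,
                 info = data.frame(snp_id = colnames(values) %||% paste0("snp", seq_len(S)),
                                   chrom = rep_len(chrom, S), pos = pos,
                                   maf = mafs %||% rep(NA_real_, S),
                                   stringsAsFactors = FALSE)),
            class = "snp_matrix")
}

make_cpg_matrix <- function(values, pos = NULL, chrom = "1") {
  C <- ncol(values)
  pos <- pos %||% seq(111L, by = 200L, length.out = C)
  structure(list(values = values,
                 info = data.frame(cpg_id = colnames(values) %||% paste0("cpg", seq_len(C)),
                                   chrom = rep_len(chrom, C), pos = pos,
                                   stringsAsFactors = FALSE)),
            class = "cpg_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small cohort with m independent SNP-CpG pairs, no causal effects, one
# single gene containing them all unless gene sizes are given.
make_null_toy <- function(n = 80, m = 5, seed = 1, missing_col = NULL,
                          constant_col = NULL) {
  set.seed(seed)
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m,
                 dimnames = list(NULL, paste0("snp", seq_len(m))))
  if (!is.null(missing_col)) geno[sample(n, 5), missing_col] <- NA
  if (!is.null(constant_col)) geno[, constant_col] <- 1L
  meth <- matrix(rbeta(n * m, 2, 2), n, m,
                 dimnames = list(NULL, paste0("cpg", seq_len(m))))
  r <- rnorm(n)
  gmat <- make_snp_matrix(geno)
  cmat <- make_cpg_matrix(meth)
  pm <- pair_snps_to_cpgs(gmat, cmat)
  genes <- data.frame(gene_id = "geneA", chrom = "1", start = 1L,
                      stop = max(gmat$info$pos) + 100L,
                      category = "noncausal", stringsAsFactors = FALSE)
  pm <- assemble_gene_sets(pm, genes)
  list(r = r, geno = gmat, meth = cmat, pairs = pm)
}
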