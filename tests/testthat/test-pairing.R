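toy_markers <- function(spos, cpos, schrom = "1", cchrom = "1") {
  n <- 4
  g <- make_snp_matrix(matrix(rep(0:2, length.out = n * length(spos)), n),
                       pos = spos, chrom = schrom)
  m <- make_cpg_matrix(matrix(0.5, n, length(cpos)), pos = cpos, chrom = cchrom)
  list(g = g, m = m)
}

test_that("each SNP pairs with its nearest CpG, ties to the lower coordinate", {
  tm <- toy_markers(spos = c(100L, 205L), cpos = c(90L, 120L, 300L))
  pm <- pair_snps_to_cpgs(tm$g, tm$m)
  expect_equal(pm$pairs$cpg_id, c("cpg1", "cpg2"))   # 10 < 20; 85 < 95
  expect_equal(pm$pairs$distance, c(10L, 85L))

  # exact tie: SNP at 105 equidistant from 90 and 120
  tm2 <- toy_markers(spos = 105L, cpos = c(90L, 120L))
  expect_equal(pair_snps_to_cpgs(tm2$g, tm2$m)$pairs$cpg_id, "cpg1")

  # chromosome with SNPs but no CpGs errors
  tm3 <- toy_markers(spos = 100L, cpos = 90L, schrom = "2", cchrom = "1")
  expect_error(pair_snps_to_cpgs(tm3$g, tm3$m), "no CpG")
})

test_that("override table wins over the nearest rule and warns beyond 12.5 kb", {
  tm <- toy_markers(spos = 100L, cpos = c(90L, 5000L))
  ov <- data.frame(snp_id = "snp1", cpg_id = "cpg2", stringsAsFactors = FALSE)
  pm <- pair_snps_to_cpgs(tm$g, tm$m, overrides = ov)
  expect_equal(pm$pairs$cpg_id, "cpg2")
  expect_true(pm$pairs$override)

  tm2 <- toy_markers(spos = 100L, cpos = c(90L, 20000L))
  ov2 <- data.frame(snp_id = "snp1", cpg_id = "cpg2", stringsAsFactors = FALSE)
  expect_warning(pair_snps_to_cpgs(tm2$g, tm2$m, overrides = ov2), "12500")
})

test_that("pairing is total and deterministic over kept SNPs", {
  set.seed(31)
  spos <- sort(sample(1e6, 40))
  cpos <- sort(sample(1e6, 15))
  tm <- toy_markers(spos = spos, cpos = cpos)
  pm <- pair_snps_to_cpgs(tm$g, tm$m)
  expect_equal(nrow(pm$pairs), 40L)
  expect_false(anyNA(pm$pairs$cpg_id))
  expect_identical(pm, pair_snps_to_cpgs(tm$g, tm$m))
  # every SNP appears exactly once
  expect_equal(anyDuplicated(pm$pairs$snp_id), 0L)
})

test_that("gene assembly uses 1-based inclusive bounds and the orphan rules", {
  spos <- c(1000L, 2000L, 31000L, 150000L, 160000L, 500000L)
  cpos <- spos + 11L
  tm <- toy_markers(spos = spos, cpos = cpos)
  pm <- pair_snps_to_cpgs(tm$g, tm$m)
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 1000L, stop = 2000L,
                      category = "noncausal", stringsAsFactors = FALSE)

  # snp2 at exactly stop = 2000 is included (inclusive bounds)
  pm1 <- assemble_gene_sets(pm, genes)
  expect_equal(pm$pairs$snp_id[pm1$genes$G1], c("snp1", "snp2"))

  # orphan major SNP 29 kb from G1 gets appended to it
  pm2 <- assemble_gene_sets(pm, genes, major_snp_ids = "snp3")
  expect_true(match("snp3", pm$pairs$snp_id) %in% pm2$genes$G1)

  # orphan major SNP far from everything spawns a synthetic +-50 kb gene
  pm3 <- assemble_gene_sets(pm, genes, major_snp_ids = "snp4")
  expect_true("SYNTH_snp4" %in% names(pm3$genes))
  expect_equal(pm$pairs$snp_id[pm3$genes$SYNTH_snp4], c("snp4", "snp5"))
  expect_equal(pm3$gene_info$category[pm3$gene_info$gene_id == "SYNTH_snp4"],
               "major_causal")
})

test_that("union and spiked sets resolve members and record m_k", {
  spos <- seq(1000L, by = 1000L, length.out = 8)
  tm <- toy_markers(spos = spos, cpos = spos + 11L)
  pm <- pair_snps_to_cpgs(tm$g, tm$m)
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "1",
                      start = c(1000L, 4000L), stop = c(3000L, 5000L),
                      category = "noncausal", stringsAsFactors = FALSE)
  sets <- list(U = list(genes = c("G1", "G2"), category = "synthetic_set"),
               S = list(snp_ids = c("snp1", "snp7", "snp8"),
                        category = "synthetic_set"))
  pm <- assemble_gene_sets(pm, genes, sets = sets)
  gi <- pm$gene_info
  expect_equal(gi$m[gi$gene_id == "U"], 5L)   # 3 + 2, disjoint union
  expect_equal(gi$m[gi$gene_id == "S"], 3L)
  expect_equal(sum(lengths(pm$genes[["U"]])), 5L)

  # empty gene is excluded with a message
  genes2 <- rbind(genes, data.frame(gene_id = "G3", chrom = "1",
                                    start = 900000L, stop = 900100L,
                                    category = "noncausal"))
  expect_message(pm2 <- assemble_gene_sets(pm, genes2), "empty")
  expect_false("G3" %in% names(pm2$genes))
})

test_that("the study catalogue reproduces the published pair counts", {
  cat <- build_set_catalogue(major = TRUE,
                             sets = c("CAUSAL5", "UNION5", "UNION2",
                                      "NOISE5", "NOISE2"), seed = 1)
  n <- 30
  set.seed(1)
  geno <- structure(list(values = matrix(rbinom(n * nrow(cat$snps), 2, 0.3), n,
                                         dimnames = list(NULL, cat$snps$snp_id)),
                         info = cat$snps), class = "snp_matrix")
  meth <- structure(list(values = matrix(0.5, n, nrow(cat$cpgs),
                                         dimnames = list(NULL, cat$cpgs$cpg_id)),
                         info = cat$cpgs), class = "cpg_matrix")
  pm <- pair_snps_to_cpgs(geno, meth, overrides = cat$overrides)
  pm <- assemble_gene_sets(pm, cat$genes, major_snp_ids = cat$major_snp_ids,
                           sets = cat$sets)
  m <- setNames(pm$gene_info$m, pm$gene_info$gene_id)
  expect_equal(unname(m[c("major125", "major100", "major075", "major050",
                          "major025")]), c(141L, 23L, 63L, 29L, 32L))
  expect_equal(unname(m[c("CAUSAL5", "UNION5", "UNION2", "NOISE5", "NOISE2")]),
               c(5L, 288L, 92L, 288L, 92L))
})
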