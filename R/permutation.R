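#' Build a shared permutation plan
#'
#' Draws `B` uniformly random permutations of `1..n`. The same plan (the
#' same shuffles) is applied to the residual vector for every SNP-CpG pair
#' and every gene, which preserves the correlation structure between and
#' across CpG sites and SNPs within each gene.
#'
#' @param n Number of individuals (>= 2).
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed; identical `(n, B, seed)` give an
#'   identical plan.
#' @return A list of class `perm_plan`: `n`, `B`, `seed`, and `perms`, a
#'   `B x n` integer matrix whose rows are permutations of `1..n`.
#' @export
make_plan <- function(n, B = 1000, seed = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  if (B < 1) stop("`B` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  perms <- t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  structure(list(n = as.integer(n), B = as.integer(B), seed = seed,
                 perms = perms),
            class = "perm_plan")
}

# Per-pair permuted p-values via the precomputed-cross-product path.
# For each pair only the response changes across permutations, so after one
# QR of the pair's design the B overall-model F statistics come from a
# single (4 x n) %*% (n x B) product: SSE_b = |r_b|^2 - |Q' r_b|^2.
perm_pair_pvalues <- function(r, geno, meth, pairs, plan,
                              include_intercept = TRUE, p_floor = 1e-300) {
  n <- length(r)
  if (plan$n != n) stop("permutation plan size does not match residual vector")
  pp <- pairs$pairs
  scol <- match(pp$snp_id, geno$info$snp_id)
  ccol <- match(pp$cpg_id, meth$info$cpg_id)
  if (anyNA(scol) || anyNA(ccol)) stop("pair map references markers absent from the matrices")
  B <- plan$B
  Rp <- matrix(r[t(plan$perms)], n, B)      # column b = r shuffled by row b
  tss_full <- sum(r^2)
  s1_full <- sum(r)
  P <- matrix(1, nrow(pp), B)
  for (j in seq_len(nrow(pp))) {
    s <- geno$values[, scol[j]]
    cg <- meth$values[, ccol[j]]
    keep <- !is.na(s)
    nk <- sum(keep)
    np <- if (include_intercept) 4L else 3L
    if (nk - np < 10L) stop("need at least 10 more observations than parameters")
    X <- if (include_intercept) cbind(1, s, cg, s * cg)[keep, , drop = FALSE]
         else cbind(s, cg, s * cg)[keep, , drop = FALSE]
    qx <- qr(X)
    rank <- qx$rank
    df1 <- rank - as.integer(include_intercept)
    if (df1 <= 0L) next                     # nothing testable: p stays 1
    Q <- qr.Q(qx)[, seq_len(rank), drop = FALSE]
    if (all(keep)) {
      R <- Rp; tss <- tss_full
      ssr0 <- if (include_intercept) tss_full - s1_full^2 / n else tss_full
    } else {
      R <- Rp[keep, , drop = FALSE]
      tss <- colSums(R^2)
      ssr0 <- if (include_intercept) tss - colSums(R)^2 / nk else tss
    }
    qtr <- crossprod(Q, R)
    sse <- pmax(tss - colSums(qtr^2), 0)
    df2 <- nk - rank
    Fb <- ((ssr0 - sse) / df1) / (sse / df2)
    pb <- pf(Fb, df1, df2, lower.tail = FALSE)
    P[j, ] <- pmin(pmax(pb, p_floor), 1)
  }
  P
}

#' Permuted gene statistics under a shared plan
#'
#' For each permutation `b`, the residual vector is shuffled by row `b` of
#' the plan, every pair's stage-2 p-value is recomputed (the same shuffled
#' residuals are used for all pairs), and every gene statistic is
#' recomputed from those p-values. The heavy lifting reuses each pair's
#' design cross-products, so the sweep costs one matrix product per pair
#' rather than `B` full refits; the two routes agree to numerical
#' precision.
#'
#' @param r Observed stage-1 residual vector.
#' @param geno,meth Marker matrices.
#' @param pairs A `pair_map` with gene assignments.
#' @param plan A [make_plan()] object.
#' @param methods Subset of [gene_stat_methods()].
#' @param include_intercept Passed to the pair model.
#' @return A numeric array of dimension `B x n_genes x n_methods` with
#'   dimnames.
#' @export
permuted_statistics <- function(r, geno, meth, pairs, plan,
                                methods = gene_stat_methods(),
                                include_intercept = TRUE) {
  if (is.null(pairs$gene_info)) stop("pair map has no gene assignments; run assemble_gene_sets()")
  methods <- match.arg(methods, gene_stat_methods(), several.ok = TRUE)
  P <- perm_pair_pvalues(r, geno, meth, pairs, plan, include_intercept)
  stats_from_pmatrix(P, pairs, methods)
}

# Combine an (n_pairs x B) p-value matrix into a (B x genes x methods) array.
stats_from_pmatrix <- function(P, pairs, methods) {
  logP <- log(P)
  gene_ids <- pairs$gene_info$gene_id
  B <- ncol(P)
  arr <- array(NA_real_, dim = c(B, length(gene_ids), length(methods)),
               dimnames = list(NULL, gene_ids, methods))
  thr <- c("pt_0.01" = 0.01, "pt_0.05" = 0.05, "pt_0.10" = 0.10)
  for (g in seq_along(gene_ids)) {
    ix <- pairs$genes[[gene_ids[g]]]
    Lg <- logP[ix, , drop = FALSE]
    Pg <- P[ix, , drop = FALSE]
    for (m in methods) {
      arr[, g, m] <- switch(m,
        sum_ln_p = colSums(Lg),
        sum_neg_sq_ln_p = -colSums(Lg^2),
        min_p = apply(Pg, 2, min),
        {
          Tm <- thr[[m]]
          dd <- Lg - log(Tm)
          -colSums(dd^2 * (Pg <= Tm))
        })
    }
  }
  arr
}

#' Permutation empirical p-value
#'
#' Add-one rank estimator: `(1 + #\{b : G_perm_b <= G_obs\}) / (B + 1)`
#' under the smaller-is-more-extreme orientation, with ties counted as
#' extreme. The add-one rule avoids zero p-values (the raw proportion of a
#' finite permutation sample can be zero, which is not a valid p-value).
#'
#' @param G_obs Observed statistic.
#' @param G_perm Vector of permuted statistics (length `B >= 1`).
#' @return Empirical p-value in `(0, 1]`.
#' @examples
#' empirical_p(-3, c(-5, -3, -1, 0))  # (1 + 2) / 5
#' @export
empirical_p <- function(G_obs, G_perm) {
  if (length(G_perm) < 1L) stop("permutation vector must be non-empty")
  (1 + sum(G_perm <= G_obs)) / (length(G_perm) + 1)
}

#' Gene-level significance decisions
#'
#' Marks a result significant iff its empirical p-value is strictly below
#' `alpha` (so `empirical_p == alpha` is NOT significant).
#'
#' @param results Data frame with an `empirical_p` column.
#' @param alpha Significance level (default 0.05).
#' @return `results` with a logical `significant` column (re)computed.
#' @export
gene_decisions <- function(results, alpha = 0.05) {
  results$significant <- results$empirical_p < alpha
  results
}

#' Run the full gene-based testing stage on one cohort
#'
#' Computes the observed per-pair p-values, the observed gene statistics,
#' the shared-shuffle permutation distribution, empirical p-values and
#' significance calls for the six combiners, plus the single-marker
#' Bonferroni comparator.
#'
#' @param r Stage-1 residual vector.
#' @param geno,meth Marker matrices.
#' @param pairs A `pair_map` with gene assignments.
#' @param plan A [make_plan()] object.
#' @param alpha Significance level (default 0.05).
#' @param methods Subset of [gene_stat_methods()].
#' @param include_intercept Passed to the pair model.
#' @return A list with `pair_results` (from [fit_all_pairs()]),
#'   `gene_results` (data frame: `gene_id`, `category`, `method`, `m`,
#'   `G_obs`, `empirical_p`, `significant`, `B_used`) and `single_marker`
#'   (data frame: `gene_id`, `category`, `m`, `min_p`, `threshold`,
#'   `significant`).
#' @export
run_gene_tests <- function(r, geno, meth, pairs, plan, alpha = 0.05,
                           methods = gene_stat_methods(),
                           include_intercept = TRUE) {
  pair_results <- fit_all_pairs(r, geno, meth, pairs,
                                include_intercept = include_intercept)
  perm <- permuted_statistics(r, geno, meth, pairs, plan, methods,
                              include_intercept = include_intercept)
  gi <- pairs$gene_info
  rows <- vector("list", nrow(gi))
  sm <- data.frame(gene_id = gi$gene_id, category = gi$category, m = gi$m,
                   min_p = NA_real_, threshold = NA_real_, significant = NA,
                   stringsAsFactors = FALSE)
  for (g in seq_len(nrow(gi))) {
    ix <- pairs$genes[[gi$gene_id[g]]]
    p <- pair_results$p[ix]
    G_obs <- gene_statistics(p, methods)
    ep <- vapply(methods, function(m) empirical_p(G_obs[[m]], perm[, g, m]),
                 numeric(1))
    rows[[g]] <- data.frame(gene_id = gi$gene_id[g], category = gi$category[g],
                            method = methods, m = gi$m[g],
                            G_obs = unname(G_obs), empirical_p = unname(ep),
                            B_used = plan$B, stringsAsFactors = FALSE)
    sm$min_p[g] <- min(p)
    sm$threshold[g] <- alpha / length(p)
    sm$significant[g] <- single_marker_decision(p, alpha)
  }
  gene_results <- gene_decisions(do.call(rbind, rows), alpha)
  list(pair_results = pair_results, gene_results = gene_results,
       single_marker = sm, alpha = alpha)
}
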