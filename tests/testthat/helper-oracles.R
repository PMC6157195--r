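# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: explicit normal equations, dense REML algebra and
# naive gene dropping.

# Pair-model oracle: explicit normal-equations fit plus nested-model SSR
# comparison. Requires a full-rank design.
oracle_pair_fit <- function(r, snp, cpg, include_intercept = TRUE) {
  keep <- !is.na(snp)
  r0 <- r[keep]; s <- snp[keep]; cg <- cpg[keep]
  X <- if (include_intercept) cbind(1, s, cg, s * cg) else cbind(s, cg, s * cg)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% r0)
  res <- r0 - X %*% beta
  sse <- sum(res^2)
  ssr0 <- if (include_intercept) sum((r0 - mean(r0))^2) else sum(r0^2)
  df1 <- 3
  df2 <- length(r0) - ncol(X)
  Fstat <- ((ssr0 - sse) / df1) / (sse / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, p = min(max(p, 1e-300), 1), beta = drop(beta))
}

# Oracle for the nested F-test of a SNP-only model against the intercept.
oracle_snp_only_F <- function(r, snp) {
  X <- cbind(1, snp)
  beta <- solve(t(X) %*% X, t(X) %*% r)
  sse <- sum((r - X %*% beta)^2)
  ssr0 <- sum((r - mean(r))^2)
  Fstat <- (ssr0 - sse) / (sse / (length(r) - 2))
  list(F = Fstat,
       p = stats::pf(Fstat, 1, length(r) - 2, lower.tail = FALSE))
}

# Dense REML profile log-likelihood: generic matrix algebra, no
# eigendecomposition shortcut. K2 = 2 * Phi.
oracle_reml_ll <- function(lambda, y, X, K2) {
  n <- length(y); p <- ncol(X)
  V <- diag(n) + lambda * K2
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  beta <- solve(M, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  rss <- drop(t(res) %*% Vi %*% res)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
          as.numeric(determinant(V, logarithm = TRUE)$modulus) +
          as.numeric(determinant(M, logarithm = TRUE)$modulus) - p * log(s2))
}

# Gene-dropping Monte Carlo kinship: vectorized over `drops` independent
# gene drops of unique founder allele labels.
gene_drop_kinship <- function(ped, drops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$individual_id
  fi <- unname(idx[ped$father_id]); mi <- unname(idx[ped$mother_id])
  L1 <- matrix(0L, n, drops); L2 <- matrix(0L, n, drops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      L1[i, ] <- lab + 1L; L2[i, ] <- lab + 2L; lab <- lab + 2L
    } else {
      pick <- stats::runif(drops) < 0.5
      L1[i, ] <- ifelse(pick, L1[fi[i], ], L2[fi[i], ])
      pick <- stats::runif(drops) < 0.5
      L2[i, ] <- ifelse(pick, L1[mi[i], ], L2[mi[i], ])
    }
  }
  phi <- function(i, j) {
    mean((L1[i, ] == L1[j, ]) + (L1[i, ] == L2[j, ]) +
         (L2[i, ] == L1[j, ]) + (L2[i, ] == L2[j, ])) / 4
  }
  list(phi = phi, drops = drops)
}

# Three-generation toy pedigree: grandparents, their two children married
# to unrelated spouses, and grandchildren (first cousins).
three_gen_pedigree <- function() {
  ped <- data.frame(
    family_id = "F1",
    individual_id = c("gp1", "gp2", "sp1", "sp2", "c1", "c2", "g1", "g2", "g3"),
    father_id = c(NA, NA, NA, NA, "gp1", "gp1", "c1", "c1", "c2"),
    mother_id = c(NA, NA, NA, NA, "gp2", "gp2", "sp1", "sp1", "sp2"),
    sex = c(1L, 2L, 2L, 2L, 1L, 1L, 1L, 2L, 1L),
    stringsAsFactors = FALSE)
  class(ped) <- c("methgene_pedigree", "data.frame")
  ped
}
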