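#' Fit the stage-2 model for one SNP-CpG pair
#'
#' Least-squares regression of the stage-1 residuals on SNP minor-allele
#' count, CpG methylation score and their interaction, returning the
#' overall-model F-test p-value: the joint test of
#' `beta_S = beta_C = beta_SC = 0` on `(3, n - 4)` degrees of freedom. An
#' intercept is included by default (the slope terms are tested with the
#' intercept unconstrained); `include_intercept = FALSE` replicates the
#' literal no-intercept model, testing all three coefficients against the
#' zero model on `(3, n - 3)` df. Individuals with missing genotype are
#' dropped pairwise. Rank-deficient designs (zero-variance SNP or CpG,
#' exact collinearity) are handled as `lm()` handles aliasing: the aliased
#' columns are dropped and the F-test covers the remaining slope terms on
#' `(rank - 1, n - rank)` df, so with CPG identically 0 the fit reduces to
#' the single-SNP regression. Such fits carry `degenerate = TRUE`; if no
#' testable slope remains (e.g. both SNP and CpG constant) the p-value is
#' 1. P-values are clamped to `[1e-300, 1]` so their logarithm is finite.
#'
#' @param r Residual vector from [fit_stage1()].
#' @param snp Genotype column (0/1/2, `NA` allowed).
#' @param cpg Methylation column in \[0, 1\] (no missing values).
#' @param include_intercept Include an intercept (default `TRUE`).
#' @param p_floor Lower clamp for the p-value.
#' @return A list of class `pair_fit`: `coefficients` (`beta_S`, `beta_C`,
#'   `beta_SC`), `F`, `df`, `p_value`, `degenerate`, `n_obs`.
#' @export
fit_pair <- function(r, snp, cpg, include_intercept = TRUE,
                     p_floor = 1e-300) {
  if (!all(is.finite(r))) stop("residuals must be finite")
  if (!all(is.finite(cpg))) stop("methylation values must be finite")
  if (length(snp) != length(r) || length(cpg) != length(r)) {
    stop("r, snp and cpg must have equal length")
  }
  keep <- !is.na(snp)
  r0 <- r[keep]; s <- snp[keep]; cg <- cpg[keep]
  n <- length(r0)
  np <- if (include_intercept) 4L else 3L
  if (n - np < 10L) stop("need at least 10 more observations than parameters")
  X <- if (include_intercept) {
    cbind("(Intercept)" = 1, beta_S = s, beta_C = cg, beta_SC = s * cg)
  } else {
    cbind(beta_S = s, beta_C = cg, beta_SC = s * cg)
  }
  qx <- qr(X)
  rank <- qx$rank
  degenerate <- rank < ncol(X)
  df1 <- rank - as.integer(include_intercept)
  df2 <- n - rank
  coefs <- qr.coef(qx, r0)
  if (include_intercept) coefs <- coefs[c("beta_S", "beta_C", "beta_SC")]
  names(coefs) <- c("beta_S", "beta_C", "beta_SC")
  ssr0 <- if (include_intercept) sum((r0 - mean(r0))^2) else sum(r0^2)
  if (df1 <= 0L || ssr0 <= 0) {  # nothing testable, or constant response
    return(structure(list(coefficients = coefs, F = NA_real_,
                          df = c(max(df1, 0L), df2), p_value = 1,
                          degenerate = TRUE, n_obs = n),
                     class = "pair_fit"))
  }
  sse <- sum(qr.resid(qx, r0)^2)
  Fstat <- ((ssr0 - sse) / df1) / (sse / df2)   # sse = 0 gives F = Inf, p = floor
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  p <- min(max(p, p_floor), 1)
  structure(list(coefficients = coefs, F = Fstat, df = c(df1, df2),
                 p_value = p, degenerate = degenerate, n_obs = n),
            class = "pair_fit")
}

#' Fit the stage-2 model for every SNP-CpG pair
#'
#' Applies [fit_pair()] to each pair of a `pair_map`, in the map's order.
#'
#' @param r Residual vector.
#' @param geno,meth `snp_matrix` / `cpg_matrix` containing the paired
#'   columns.
#' @param pairs A `pair_map`.
#' @param include_intercept Passed to [fit_pair()].
#' @return A data frame of class `pair_pvalues` with one row per pair:
#'   `snp_id`, `cpg_id`, `beta_S`, `beta_C`, `beta_SC`, `F`, `p`,
#'   `degenerate`, `n_obs`. `p` entries lie in `[1e-300, 1]`.
#' @export
fit_all_pairs <- function(r, geno, meth, pairs, include_intercept = TRUE) {
  pp <- pairs$pairs
  scol <- match(pp$snp_id, geno$info$snp_id)
  ccol <- match(pp$cpg_id, meth$info$cpg_id)
  if (anyNA(scol) || anyNA(ccol)) stop("pair map references markers absent from the matrices")
  k <- nrow(pp)
  out <- data.frame(snp_id = pp$snp_id, cpg_id = pp$cpg_id,
                    beta_S = rep(NA_real_, k), beta_C = rep(NA_real_, k),
                    beta_SC = rep(NA_real_, k), F = rep(NA_real_, k),
                    p = rep(NA_real_, k), degenerate = rep(FALSE, k),
                    n_obs = rep(NA_integer_, k), stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    fit <- fit_pair(r, geno$values[, scol[j]], meth$values[, ccol[j]],
                    include_intercept = include_intercept)
    out$beta_S[j] <- fit$coefficients[["beta_S"]]
    out$beta_C[j] <- fit$coefficients[["beta_C"]]
    out$beta_SC[j] <- fit$coefficients[["beta_SC"]]
    out$F[j] <- fit$F
    out$p[j] <- fit$p_value
    out$degenerate[j] <- fit$degenerate
    out$n_obs[j] <- fit$n_obs
  }
  ndeg <- sum(out$degenerate)
  if (ndeg > 0) message(ndeg, " degenerate pair(s): p set to 1")
  class(out) <- c("pair_pvalues", "data.frame")
  out
}
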