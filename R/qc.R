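#' Hardy-Weinberg equilibrium test
#'
#' Goodness-of-fit test of the three genotype counts against their expected
#' Hardy-Weinberg frequencies at the sample allele frequency. The default is
#' the 1-df chi-square test without continuity correction; a Levene-Haldane
#' exact test (summing probabilities of heterozygote counts no more likely
#' than the observed one) is available via `method = "exact"`. Monomorphic
#' SNPs return `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (vectorized).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return The p-value(s).
#' @examples
#' hwe_test(25, 50, 25)  # exactly at HWE: p = 1
#' hwe_test(30, 40, 30)  # chi-square = 4
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  counts <- cbind(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts)) {
    stop("genotype counts must be non-negative integers")
  }
  n <- rowSums(counts)
  if (any(n == 0)) stop("total genotype count must be positive")
  if (method == "chisq") {
    p_hat <- (2 * n_AA + n_Aa) / (2 * n)
    exp_counts <- cbind(n * p_hat^2, 2 * n * p_hat * (1 - p_hat), n * (1 - p_hat)^2)
    chi2 <- numeric(k)
    poly <- p_hat > 0 & p_hat < 1
    if (any(poly)) {
      chi2[poly] <- rowSums((counts[poly, , drop = FALSE] -
                             exp_counts[poly, , drop = FALSE])^2 /
                            exp_counts[poly, , drop = FALSE])
    }
    out <- rep(1, k)
    out[poly] <- pchisq(chi2[poly], df = 1, lower.tail = FALSE)
    return(out)
  }
  vapply(seq_len(k), function(i) hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i]),
         numeric(1))
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa            # copies of the rarer-or-not allele A
  if (nA == 0 || nA == 2 * n) return(1)
  if (nA > n) return(hwe_exact_one(n_aa, n_Aa, n_AA))
  het <- seq(nA %% 2, nA, by = 2)  # feasible heterozygote counts
  # log P(n_Aa = h | nA) up to a constant (Levene-Haldane)
  logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (nA + het) / 2 + 1) + het * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  sum(pr[pr <= pr[match(n_Aa, het)] * (1 + 1e-12)])
}

#' QC thresholds for SNP filtering
#'
#' Defaults follow standard GWAS practice: keep a SNP iff its HWE p-value
#' exceeds `1e-6`, its minor allele frequency exceeds 1%, and its missing
#' data rate is below 5% (all inequalities strict).
#'
#' @param hwe_p_min Minimum (exclusive) HWE p-value.
#' @param maf_min Minimum (exclusive) minor allele frequency.
#' @param missing_max Maximum (exclusive) missing-call proportion.
#' @param hwe_method Passed to [hwe_test()].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.01,
                          missing_max = 0.05, hwe_method = "chisq") {
  vals <- c(hwe_p_min, maf_min, missing_max)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 missing_max = missing_max, hwe_method = hwe_method),
            class = "qc_thresholds")
}

#' SNP quality-control filter
#'
#' Keeps a SNP iff `hwe_p > hwe_p_min` AND `maf > maf_min` AND
#' `missing_rate < missing_max`. MAF is computed on non-missing calls and
#' folded to be at most 0.5. SNPs with no non-missing calls are dropped and
#' reported.
#'
#' @param geno A `snp_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A named logical keep-mask over SNPs, with the per-SNP statistics
#'   attached as attribute `"qc_stats"` (data frame: `snp_id`, `maf`,
#'   `hwe_p`, `missing_rate`, `kept`).
#' @export
qc_filter <- function(geno, thresholds = qc_thresholds()) {
  v <- geno$values
  if (!all(v[!is.na(v)] %in% 0:2)) stop("genotype codes must be 0, 1, 2 or missing")
  miss <- colMeans(is.na(v))
  n0 <- colSums(v == 0, na.rm = TRUE)
  n1 <- colSums(v == 1, na.rm = TRUE)
  n2 <- colSums(v == 2, na.rm = TRUE)
  ncall <- n0 + n1 + n2
  all_missing <- ncall == 0
  af <- ifelse(all_missing, NA_real_, (2 * n2 + n1) / (2 * pmax(ncall, 1)))
  maf <- pmin(af, 1 - af)
  hwe_p <- rep(NA_real_, length(ncall))
  ok <- !all_missing
  hwe_p[ok] <- hwe_test(n0[ok], n1[ok], n2[ok], method = thresholds$hwe_method)
  keep <- ok & hwe_p > thresholds$hwe_p_min & maf > thresholds$maf_min &
    miss < thresholds$missing_max
  if (any(all_missing)) {
    message(sum(all_missing), " SNP(s) dropped: no non-missing calls")
  }
  names(keep) <- geno$info$snp_id
  attr(keep, "qc_stats") <- data.frame(snp_id = geno$info$snp_id, maf = maf,
                                       hwe_p = hwe_p, missing_rate = miss,
                                       kept = keep, row.names = NULL)
  keep
}

#' Subset a snp_matrix (or cpg_matrix) by a keep-mask or index
#'
#' @param x A `snp_matrix` or `cpg_matrix`.
#' @param keep Logical mask or index vector over markers.
#' @return The subsetted object, same class.
#' @export
subset_markers <- function(x, keep) {
  x$values <- x$values[, keep, drop = FALSE]
  x$info <- x$info[keep, , drop = FALSE]
  rownames(x$info) <- NULL
  x
}
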