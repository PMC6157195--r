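#' Gene-based p-value combination statistics
#'
#' Six combiners map a gene's vector of per-pair p-values `p_1, ..., p_m`
#' to one statistic `G`, uniformly oriented so that a SMALLER `G` is MORE
#' extreme (stronger evidence):
#'
#' * `sum_ln_p` — `sum(ln p_j)` (Fisher / burden-type averaging);
#' * `sum_neg_sq_ln_p` — `sum(-(ln p_j)^2)` (variance-components-type);
#' * `min_p` — `min(p_j)`, robust when few pairs are causal;
#' * `pt_0.01`, `pt_0.05`, `pt_0.10` — truncated threshold statistics
#'   `sum over {p_j <= T} of -(ln(p_j / T))^2`: pairs with `p_j > T`
#'   contribute exactly 0, so non-significant "noise" pairs cannot dilute
#'   the statistic, and each branch gives 0 at `p_j = T` (continuity).
#'
#' All combiners require p-values in `(0, 1]` (upstream clamping guarantees
#' `p >= 1e-300`), are invariant to the ordering of `p`, and are monotone
#' non-increasing as any single `p_j` decreases. `threshold_stat(p, 1)`
#' coincides with `sum_neg_sq_ln_p(p)`.
#'
#' @param p Numeric vector of p-values in `(0, 1]`, length `m >= 1`.
#' @param threshold Truncation threshold `T` in `(0, 1]`.
#' @return The statistic `G` (scalar).
#' @examples
#' sum_ln_p(c(0.1, 0.01))       # -6.907755
#' threshold_stat(0.005, 0.05)  # -(ln 0.1)^2
#' @name gene_stats
NULL

check_pvec <- function(p) {
  if (length(p) < 1L) stop("p-value vector must be non-empty")
  if (anyNA(p) || !is.numeric(p)) stop("p-values must be numeric and non-missing")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  invisible(p)
}

#' @rdname gene_stats
#' @export
sum_ln_p <- function(p) {
  check_pvec(p)
  sum(log(p))
}

#' @rdname gene_stats
#' @export
sum_neg_sq_ln_p <- function(p) {
  check_pvec(p)
  -sum(log(p)^2)
}

#' @rdname gene_stats
#' @export
min_p <- function(p) {
  check_pvec(p)
  min(p)
}

#' @rdname gene_stats
#' @export
threshold_stat <- function(p, threshold) {
  check_pvec(p)
  if (length(threshold) != 1L || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a single value in (0, 1]")
  }
  -sum(ifelse(p <= threshold, log(p / threshold)^2, 0))
}

#' Names of the six gene-statistic methods
#'
#' @return Character vector of method labels used throughout the package.
#' @export
gene_stat_methods <- function() {
  c("sum_ln_p", "sum_neg_sq_ln_p", "min_p", "pt_0.01", "pt_0.05", "pt_0.10")
}

#' Compute all gene statistics for one p-value vector
#'
#' @param p P-values in `(0, 1]`.
#' @param methods Subset of [gene_stat_methods()].
#' @return Named numeric vector of statistics (smaller = more extreme).
#' @export
gene_statistics <- function(p, methods = gene_stat_methods()) {
  methods <- match.arg(methods, gene_stat_methods(), several.ok = TRUE)
  vapply(methods, function(m) {
    switch(m,
           sum_ln_p = sum_ln_p(p),
           sum_neg_sq_ln_p = sum_neg_sq_ln_p(p),
           min_p = min_p(p),
           "pt_0.01" = threshold_stat(p, 0.01),
           "pt_0.05" = threshold_stat(p, 0.05),
           "pt_0.10" = threshold_stat(p, 0.10))
  }, numeric(1))
}

#' Single-marker Bonferroni comparator
#'
#' A gene is declared significant by the single-marker rule iff at least
#' one of its `m` per-pair p-values falls below `alpha / m` (strict
#' inequality).
#'
#' @param p Per-pair p-values of the gene.
#' @param alpha Gene-wise significance level (default 0.05).
#' @return Logical scalar.
#' @examples
#' single_marker_decision(c(0.004, rep(0.5, 9)))  # 0.004 < 0.05/10
#' @export
single_marker_decision <- function(p, alpha = 0.05) {
  check_pvec(p)
  min(p) < alpha / length(p)
}
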