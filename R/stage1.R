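#' Derive the change-in-ln-TG phenotype and stage-1 covariates
#'
#' Each visit variable with duplicate measurements is ln-transformed first
#' and the transformed values averaged (ln-before-averaging), then the
#' change score is the follow-up average minus the baseline average. The
#' same ln-then-average rule builds the baseline ln-TG and ln-HDL
#' covariates. Individuals lacking any measurement for a required variable
#' are excluded with a message.
#'
#' @param pt A `phenotype_table` (see [simulate_phenotype()]).
#' @return Data frame with `individual_id`, the response `y`, and the
#'   stage-1 covariates (`age`, `center`, `smoking`, `msdx_score`,
#'   `fasting_time`, `ln_hdl_base`, `ln_tg_base`).
#' @examples
#' # ln-first matters: baseline {1, e^2} gives (0 + 2)/2 = 1, not ln(mean)
#' @export
derive_phenotype <- function(pt) {
  ln_avg <- function(m1, m2) {
    m <- cbind(m1, m2)
    if (any(m <= 0, na.rm = TRUE)) {
      stop("TG/HDL measurements must be strictly positive for the ln transform")
    }
    out <- rowMeans(log(m), na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_   # rowMeans over all-NA rows gives NaN
    out
  }
  ln_tg_base <- ln_avg(pt$tg_base_1, pt$tg_base_2)
  ln_tg_fu <- ln_avg(pt$tg_followup_1, pt$tg_followup_2)
  ln_hdl_base <- ln_avg(pt$hdl_base_1, pt$hdl_base_2)
  out <- data.frame(individual_id = pt$individual_id,
                    y = ln_tg_fu - ln_tg_base,
                    age = pt$age,
                    center = pt$center,
                    smoking = pt$smoking,
                    msdx_score = pt$msdx_score,
                    fasting_time = pt$fasting_time,
                    ln_hdl_base = ln_hdl_base,
                    ln_tg_base = ln_tg_base,
                    stringsAsFactors = FALSE)
  drop_ <- !complete.cases(out)
  if (any(drop_)) {
    message("excluding ", sum(drop_),
            " individual(s) with no usable baseline or follow-up measurement")
    out <- out[!drop_, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Fit the stage-1 kinship mixed model and extract residuals
#'
#' Restricted maximum likelihood fit of `y = X beta + g + e` with
#' `cov(g) = 2 * Phi * sigma2_g` and `cov(e) = sigma2_e * I`, solved by one
#' eigendecomposition of `2 * Phi` followed by a 1-D profile optimization
#' over the variance ratio `lambda = sigma2_g / sigma2_e`. Residuals follow
#' the convention `residual = yhat - y`; by default `yhat` includes the BLUP of
#' the polygenic effect (conditional residuals), which makes the residuals
#' approximately exchangeable for the downstream permutation engine. The
#' marginal alternative (`yhat = X beta`) is also returned.
#'
#' @param y Numeric response vector.
#' @param covariates Data frame of covariates; expanded with
#'   `model.matrix(~ .)` (intercept added, factors dummy-coded).
#' @param kinship Kinship matrix `Phi` (symmetric PSD after scaling by 2).
#' @param lambda_max Upper bound for the profiled variance ratio.
#' @param kinship_eigen Optional precomputed `eigen(2 * Phi,
#'   symmetric = TRUE)`, useful when many phenotypes share one pedigree.
#' @param constrain_null If `TRUE`, force `sigma2_g = 0` (ordinary least
#'   squares; useful for diagnostics).
#' @return A list of class `stage1_fit`: fixed-effect estimates, variance
#'   components `sigma2_g` / `sigma2_e`, `lambda`, REML log-likelihood, the
#'   conditional `residuals` (`yhat - y`, named by individual if `y` is),
#'   `marginal_residuals`, fitted values and BLUPs.
#' @export
fit_stage1 <- function(y, covariates, kinship, lambda_max = 1e6,
                       kinship_eigen = NULL, constrain_null = FALSE) {
  X <- model.matrix(~ ., data = as.data.frame(covariates))
  n <- length(y)
  if (nrow(X) != n || nrow(kinship) != n || ncol(kinship) != n) {
    stop("dimensions of y, covariates and kinship disagree")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  p <- ncol(X)
  if (is.null(kinship_eigen)) kinship_eigen <- eigen(2 * kinship, symmetric = TRUE)
  d <- kinship_eigen$values
  if (min(d) < -1e-8 * max(abs(d))) stop("kinship matrix is not positive semidefinite")
  d <- pmax(d, 0)
  U <- kinship_eigen$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  profile_fit <- function(lambda) {
    w <- 1 / (1 + lambda * d)
    M <- crossprod(Xt, Xt * w)
    v <- crossprod(Xt, yt * w)
    beta <- solve(M, v)
    res <- yt - drop(Xt %*% beta)
    rss <- sum(w * res^2)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + sum(log(1 + lambda * d)) +
                  as.numeric(determinant(M, logarithm = TRUE)$modulus) -
                  p * log(s2e))
    list(lambda = lambda, beta = drop(beta), res_t = res, w = w,
         sigma2_e = s2e, reml = ll)
  }
  # REML criterion: -0.5[(n-p)(log 2*pi*s2e + 1) + log|V*| + log|X' V*^-1 X / s2e|]
  # with V* = I + lambda*D; the p*log(s2e) term moves the determinant onto
  # the s2e scale.
  if (constrain_null) {
    best <- profile_fit(0)
  } else {
    obj <- function(loglam) -profile_fit(exp(loglam))$reml
    opt <- optimize(obj, interval = c(log(1e-8), log(lambda_max)), tol = 1e-8)
    best <- profile_fit(exp(opt$minimum))
    at0 <- profile_fit(0)
    if (at0$reml >= best$reml) best <- at0
  }
  lambda <- best$lambda
  sigma2_e <- best$sigma2_e
  sigma2_g <- lambda * sigma2_e
  # BLUP of g: shrink the transformed GLS residual by lambda*d/(1 + lambda*d)
  shrink <- lambda * d * best$w
  g_hat <- drop(U %*% (shrink * best$res_t))
  fitted_marginal <- drop(X %*% best$beta)
  fitted <- fitted_marginal + g_hat
  r <- fitted - y
  names(r) <- names(y) %||% rownames(kinship)
  structure(list(fixed_effects = setNames(best$beta, colnames(X)),
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e, lambda = lambda,
                 loglik_reml = best$reml,
                 residuals = r,
                 marginal_residuals = setNames(fitted_marginal - y, names(r)),
                 fitted = fitted, blup = g_hat, n = n),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("Stage-1 kinship mixed model (REML)\n")
  cat(sprintf("  n = %d, sigma2_g = %.4f, sigma2_e = %.4f (lambda = %.4f)\n",
              x$n, x$sigma2_g, x$sigma2_e, x$lambda))
  cat(sprintf("  REML log-likelihood: %.3f\n", x$loglik_reml))
  invisible(x)
}
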