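make_pt <- function(tg_b1, tg_b2, tg_f1, tg_f2) {
  n <- length(tg_b1)
  data.frame(individual_id = paste0("i", seq_len(n)),
             age = 50, center = "A", smoking = "never", msdx_score = 0,
             fasting_time = 10, hdl_base_1 = 50, hdl_base_2 = NA,
             tg_base_1 = tg_b1, tg_base_2 = tg_b2,
             tg_followup_1 = tg_f1, tg_followup_2 = tg_f2,
             stringsAsFactors = FALSE)
}

test_that("change score ln-transforms before averaging", {
  # baseline {e^2, e^4} -> mean ln = 3; follow-up {e^3} -> 3; change = 0
  pt <- make_pt(exp(2), exp(4), exp(3), NA)
  expect_equal(derive_phenotype(pt)$y, 0)

  # one measurement each: plain ln difference
  pt2 <- make_pt(100, NA, 150, NA)
  expect_equal(derive_phenotype(pt2)$y, log(150) - log(100))

  # ln-first differs from averaging-first: baseline {1, e^2}
  pt3 <- make_pt(1, exp(2), exp(1), NA)
  expect_equal(derive_phenotype(pt3)$y, 1 - 1)            # ln-first: (0+2)/2 = 1
  expect_false(isTRUE(all.equal(derive_phenotype(pt3)$y,
                                1 - log((1 + exp(2)) / 2))))  # not ln(mean)

  # all-missing baseline excludes the individual
  pt4 <- make_pt(c(100, NA), c(110, NA), c(120, 130), c(NA, NA))
  expect_message(out <- derive_phenotype(pt4), "excluding 1")
  expect_equal(nrow(out), 1L)

  expect_error(derive_phenotype(make_pt(-1, NA, 10, NA)), "positive")
})

sim_mixed <- function(n, lambda = 1, sigma2_e = 1, seed = 1,
                      sibship = 2:4, p_cov = 3) {
  set.seed(seed)
  ped <- build_pedigree(n, sibship_sizes = sibship)
  K <- kinship_from_pedigree(ped)
  X <- cbind(1, matrix(rnorm(n * p_cov), n))
  beta <- rnorm(p_cov + 1)
  g <- sqrt(lambda * sigma2_e) * drop(crossprod(chol(2 * K), rnorm(n)))
  y <- drop(X %*% beta) + g + rnorm(n, 0, sqrt(sigma2_e))
  list(y = y, X = X, covars = as.data.frame(X[, -1, drop = FALSE]), K = K)
}

test_that("REML matches a dense grid-search oracle on small instances", {
  for (s in 1:10) {
    d <- sim_mixed(50, lambda = exp(runif(1, -1, 1)), seed = s)
    fit <- fit_stage1(d$y, d$covars, d$K)
    grid <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 200)))
    Xm <- cbind(1, as.matrix(d$covars))
    ll <- sapply(grid, function(l) oracle_reml_ll(l, d$y, Xm, 2 * d$K))
    # the fitted lambda must be at least as good as the best grid point
    ll_fit <- oracle_reml_ll(fit$lambda, d$y, Xm, 2 * d$K)
    expect_gte(ll_fit, max(ll) - 1e-6)
  }
})

test_that("with the polygenic component constrained off, residuals are OLS residuals", {
  d <- sim_mixed(80, lambda = 0, seed = 3)
  fit <- fit_stage1(d$y, d$covars, d$K, constrain_null = TRUE)
  ols <- stats::lm(d$y ~ ., data = d$covars)
  # package residuals follow the yhat - y convention: negated OLS residuals
  expect_equal(unname(fit$residuals), -unname(stats::resid(ols)),
               tolerance = 1e-10)
  expect_equal(fit$sigma2_g, 0)
})

test_that("residuals are equivariant under consistent reordering of individuals", {
  d <- sim_mixed(60, seed = 5)
  fit <- fit_stage1(d$y, d$covars, d$K)
  set.seed(6); perm <- sample(60)
  fitp <- fit_stage1(d$y[perm], d$covars[perm, , drop = FALSE],
                     d$K[perm, perm])
  expect_equal(unname(fitp$residuals), unname(fit$residuals[perm]),
               tolerance = 1e-6)
})

test_that("downstream pair p-values are invariant to the residual sign convention", {
  set.seed(7)
  n <- 60; r <- rnorm(n); s <- rbinom(n, 2, 0.3); cg <- rbeta(n, 2, 2)
  expect_equal(fit_pair(r, s, cg)$p_value, fit_pair(-r, s, cg)$p_value,
               tolerance = 1e-12)
})

test_that("variance-ratio recovery is unbiased enough at moderate n", {
  lams <- vapply(1:12, function(s) {
    d <- sim_mixed(400, lambda = 1, seed = 100 + s)
    fit_stage1(d$y, d$covars, d$K)$lambda
  }, numeric(1))
  expect_lt(abs(mean(lams) - 1), 0.35)
})

test_that("residual types carry the predicted familial correlation structure", {
  # marginal residuals keep the polygenic covariance (sib ICC ~ 2*phi*s2g);
  # conditional (BLUP-subtracted) residuals have cov ~ s2e^2 * V^{-1}, whose
  # within-family entries are mildly negative
  iccs <- sapply(1:8, function(s) {
    set.seed(400 + s)
    ped <- build_pedigree(670, sibship_sizes = 2)
    K <- kinship_from_pedigree(ped)
    g <- sqrt(0.3) * drop(crossprod(chol(2 * K), rnorm(670)))
    y <- g + rnorm(670, 0, sqrt(0.7))
    covars <- data.frame(x = rnorm(670))
    fit <- fit_stage1(y, covars, K)
    r <- unname(fit$residuals)
    sib1 <- which(!is.na(ped$father_id))[c(TRUE, FALSE)]
    c(cond = stats::cor(r[sib1], r[sib1 + 1]),
      marg = stats::cor(fit$marginal_residuals[sib1],
                        fit$marginal_residuals[sib1 + 1]))
  })
  expect_lt(abs(mean(iccs["marg", ]) - 0.15), 0.06)  # 2 * 0.25 * 0.3
  expect_lt(mean(iccs["cond", ]), 0)
  expect_gt(mean(iccs["cond", ]), -0.25)
})

test_that("rank-deficient covariates are reported by name", {
  d <- sim_mixed(40, seed = 9)
  covars <- d$covars
  covars$dup <- covars[[1]]
  expect_error(fit_stage1(d$y, covars, d$K), "dup")
})
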