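test_that("realized relationship matrix matches direct standardization", {
  # two samples, one variant: standardization forces +-1 entries
  g <- genotype_data(matrix(c(0, 2), 2, 1), "v1", "1", 100)
  K <- realized_relationship(g)
  expect_equal(K$matrix, matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)

  # brute-force oracle: independently coded standardizer
  g <- make_geno(n = 25, f = 12, seed = 3)
  D <- g$dosages
  Z <- apply(D, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  })
  expect_lt(max(abs(realized_relationship(g)$matrix - tcrossprod(Z) / ncol(Z))),
            1e-10)

  # diagonal concentrates near 1 for a binomial panel
  set.seed(9)
  g <- genotype_data(matrix(rbinom(10 * 50, 2, 0.3), 10, 50))
  expect_lt(abs(mean(diag(realized_relationship(g)$matrix)) - 1), 0.3)

  # symmetry and PSD
  K <- realized_relationship(make_geno(n = 40, f = 20, seed = 4))
  ev <- eigen(K$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(K$matrix - t(K$matrix))), 1e-12)
  expect_gte(min(ev), -1e-8 * max(ev))

  # all variants monomorphic
  g0 <- genotype_data(matrix(1, 5, 2))
  expect_error(realized_relationship(g0), "no informative variants")
  # partial monomorphism drops columns with a warning
  gm <- genotype_data(cbind(c(0, 1, 2, 1), rep(2, 4)))
  expect_warning(realized_relationship(gm), "zero-variance")
})

test_that("missing dosages are mean-imputed before standardization", {
  D <- cbind(c(0, 1, 2, NA, 1), c(2, 0, NA, 1, 1))
  g <- genotype_data(D, paste0("v", 1:2), c("1", "1"), c(1, 2))
  Dimp <- D
  Dimp[4, 1] <- mean(D[-4, 1]); Dimp[3, 2] <- mean(D[-3, 2])
  Z <- apply(Dimp, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  expect_equal(realized_relationship(g)$matrix, tcrossprod(Z) / 2,
               tolerance = 1e-12)
})

test_that("null fit under identity kinship collapses to OLS", {
  set.seed(11)
  n <- 40
  y <- rnorm(n)
  fit <- fit_lmm_null(y, identity_kinship(n))
  expect_identical(fit$delta, Inf)
  ols <- lm(y ~ 1)
  expect_equal(fit$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
  expect_equal(fit$sigma_bg2, 0)
  expect_error(fit_lmm_null(y, kinship(-diag(n))), "positive semi-definite")
  expect_error(fit_lmm_null(y, identity_kinship(n),
                            covariates = matrix(rnorm(n * n), n)), "covariates")
})

test_that("fitted delta beats a fine grid of alternatives", {
  set.seed(12)
  n <- 60
  K <- realized_relationship(make_geno(n = n, f = 80, seed = 12))
  rot <- kinship_rotation(K)
  u <- drop(rot$U %*% (sqrt(rot$S) * rnorm(n)))
  y <- u + rnorm(n) * 0.7
  fit <- fit_lmm_null(y, K, rotation = rot)
  yr <- drop(crossprod(rot$U, y)); Cr <- crossprod(rot$U, rep(1, n))
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 100))
  ll_grid <- vapply(grid, netlmm:::.ll_at_delta, numeric(1),
                    yr = yr, Cr = Cr, S = rot$S)
  expect_gte(fit$loglik + 1e-6, max(ll_grid))
})

test_that("null fit recovers the simulated variance ratio", {
  set.seed(13)
  n <- 379
  K <- realized_relationship(make_geno(n = n, f = 600, seed = 13))
  rot <- kinship_rotation(K)
  L <- rot$U %*% diag(sqrt(rot$S * 2))
  deltas <- replicate(50, {
    y <- drop(L %*% rnorm(n)) + rnorm(n)   # u ~ N(0, 2K), e ~ N(0, I)
    d <- fit_lmm_null(y, K, rotation = rot)$delta
    min(d, 10)
  })
  expect_gt(mean(deltas), 0.3)   # true delta = 0.5
  expect_lt(mean(deltas), 0.9)
})

test_that("single-variant association behaves like the model says", {
  set.seed(14)
  n <- 50
  x <- rbinom(n, 2, 0.4)
  # perfect fit
  null <- fit_lmm_null(x, identity_kinship(n))
  r <- lmm_assoc(x, x, null)
  expect_equal(r$beta, 1, tolerance = 1e-8)
  expect_lt(r$pvalue, 1e-10)
  expect_error(lmm_assoc(rep(1, n), x, null), "monomorphic")

  # identity kinship: equals the OLS likelihood-ratio test
  y <- 0.3 * x + rnorm(n)
  null <- fit_lmm_null(y, identity_kinship(n))
  r <- lmm_assoc(x, y, null)
  lrt_ols <- 2 * (logLik(lm(y ~ x)) - logLik(lm(y ~ 1)))
  expect_equal(r$lrt_stat, as.numeric(lrt_ols), tolerance = 1e-8)
  expect_equal(r$pvalue, pchisq(as.numeric(lrt_ols), 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # p-value is the chi-square survival function of the statistic
  expect_equal(r$pvalue, pchisq(r$lrt_stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("mixed-model test agrees with a dense whitening oracle", {
  set.seed(15)
  n <- 50
  K <- realized_relationship(make_geno(n = n, f = 70, seed = 15))
  x <- rbinom(n, 2, 0.3)
  rot <- kinship_rotation(K)
  u <- drop(rot$U %*% (sqrt(rot$S * 3) * rnorm(n)))   # strong background
  y <- 0.2 * x + u + rnorm(n) * 0.5
  null <- fit_lmm_null(y, K)
  expect_true(is.finite(null$delta))
  r <- lmm_assoc(x, y, null)
  # dense: whiten with chol(K + delta I) at the fitted delta, then OLS LRT
  V <- K$matrix + null$delta * diag(n)
  ch <- chol(V)
  yw <- forwardsolve(t(ch), y); xw <- forwardsolve(t(ch), x)
  cw <- forwardsolve(t(ch), rep(1, n))
  rss0 <- sum(lm.fit(cbind(cw), yw)$residuals^2)
  rss1 <- sum(lm.fit(cbind(cw, xw), yw)$residuals^2)
  p_dense <- pchisq(n * (log(rss0) - log(rss1)), 1, lower.tail = FALSE)
  expect_equal(r$pvalue, p_dense, tolerance = 1e-6)
})

test_that("likelihood-ratio statistic is invariant to affine rescaling of y", {
  set.seed(16)
  n <- 45
  K <- realized_relationship(make_geno(n = n, f = 60, seed = 16))
  x <- rbinom(n, 2, 0.4)
  y <- 0.3 * x + rnorm(n)
  r1 <- lmm_assoc(x, y, fit_lmm_null(y, K))
  r2 <- lmm_assoc(x, 5.5 * y - 3, fit_lmm_null(5.5 * y - 3, K))
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-8)
})

test_that("scan equals the single-test path on a degenerate grid", {
  set.seed(17)
  g <- make_geno(n = 35, f = 1, seed = 17)
  e <- make_expr(n = 35, tg = 1, seed = 18)
  K <- identity_kinship(35)
  sc <- lmm_scan(g, e, K)
  r <- lmm_assoc(g$dosages[, 1], e$values[, 1], fit_lmm_null(e$values[, 1], K))
  expect_equal(sc$pvalues[1, 1], r$pvalue, tolerance = 1e-12)
  expect_equal(sc$betas[1, 1], r$beta, tolerance = 1e-12)
})

test_that("scan p-values are calibrated and uniform under the null", {
  set.seed(19)
  n <- 150
  g <- make_geno(n = n, f = 200, seed = 19)
  K <- realized_relationship(g)
  e <- make_expr(n = n, tg = 20, seed = 20)
  sc <- lmm_scan(g, e, K)
  p <- as.vector(sc$pvalues)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
  expect_gt(ks.test(sample(p, 2000), "punif")$p.value, 0.01)
})

test_that("a planted 20% effect ranks first among its gene's variants", {
  hits <- vapply(1:100, function(s) {
    set.seed(s + 400)
    n <- 379; f <- 50
    D <- vapply(runif(f, 0.1, 0.5), function(m) rbinom(n, 2, m), numeric(n))
    g <- genotype_data(D)
    K <- realized_relationship(g)
    y <- netlmm:::scale_to_share(D[, 7], 0.2) +
      netlmm:::scale_to_share(rnorm(n), 0.8)
    e <- expression_data(matrix(y, n, 1))
    sc <- lmm_scan(g, e, K)
    which.min(sc$pvalues[1, ]) == 7
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("monomorphic variants give NA scan entries with a message", {
  g <- make_geno(n = 30, f = 4, seed = 21)
  g$dosages[, 2] <- 1
  e <- make_expr(n = 30, tg = 2, seed = 22)
  expect_message(sc <- lmm_scan(g, e, identity_kinship(30)), "monomorphic")
  expect_true(all(is.na(sc$pvalues[, 2])))
  expect_true(all(!is.na(sc$pvalues[, -2])))
})
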