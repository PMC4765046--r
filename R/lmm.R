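# Linear mixed model association machinery.
#
# Model for a single gene y (Step 1 of the algorithm):
#   y ~ N(C alpha + x beta, sigma_bg^2 K + sigma_n^2 I)
# The noise/background variance ratio delta = sigma_n^2 / sigma_bg^2 is fit
# once per gene on the null model (beta = 0) by maximum likelihood and then
# held fixed across all variant tests for that gene (EMMA-X approximation).
# With the eigendecomposition K = U S U', all tests reduce to weighted least
# squares in the rotated basis with weights 1 / (S_i + delta).

#' Eigendecomposition of a kinship matrix
#'
#' Precomputes the rotation `K = U diag(S) U'` that every per-gene fit
#' works in; pass it to [fit_lmm_null()], [lmm_scan()] or
#' [fit_lowrank_null()] to avoid refactorizing `K` for each gene.
#'
#' @param K a [kinship] object or PSD matrix.
#' @return List with orthonormal `U` and eigenvalues `S` (clamped at 0).
#' @export
kinship_rotation <- function(K) {
  K <- as_kinship(K, n = nrow(as.matrix(if (inherits(K, "kinship")) K$matrix else K)))
  e <- eigen(K$matrix, symmetric = TRUE)
  list(U = e$vectors, S = pmax(e$values, 0))
}

# Profiled log marginal likelihood at a fixed delta in the rotated basis.
# yr, Cr: rotated response/covariates; S: kinship eigenvalues.
.ll_at_delta <- function(delta, yr, Cr, S) {
  n <- length(yr)
  if (is.infinite(delta)) {
    fit <- lm.fit(Cr, yr)
    rss <- sum(fit$residuals^2)
    return(-n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n))
  }
  w <- 1 / (S + delta)
  sw <- sqrt(w)
  fit <- lm.fit(Cr * sw, yr * sw)
  rss <- sum(fit$residuals^2)
  -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n) - sum(log(S + delta)) / 2
}

#' Fit the per-gene null mixed model
#'
#' Maximizes the marginal likelihood of `y ~ N(covariates alpha,
#' sigma_bg^2 K + sigma_n^2 I)` over the variance ratio
#' `delta = sigma_n^2 / sigma_bg^2` by maximum likelihood (not REML): a
#' 100-point log-spaced grid over `[1e-4, 1e4]` followed by bounded
#' refinement around the grid optimum. The boundary `delta = +Inf` (all
#' variance attributed to iid noise; the model collapses to ordinary least
#' squares) is used whenever it attains the optimum, which is the
#' deterministic convention when `K` is the identity and delta is
#' unidentifiable.
#'
#' @param y numeric response vector (one gene's expression).
#' @param K a [kinship] object or PSD matrix.
#' @param covariates optional N x P fixed-effect matrix; an intercept column
#'   is added when absent.
#' @param rotation optional precomputed [kinship_rotation()] of `K`.
#' @return Object of class `lmm_null`: `delta`, `sigma_bg2`, `sigma_n2`,
#'   `loglik`, and the cached rotation/weighted projections reused by
#'   [lmm_assoc()] and [lmm_scan()].
#' @export
fit_lmm_null <- function(y, K, covariates = NULL, rotation = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(is.finite(y))) stop("y must be finite")
  covariates <- prepare_covariates(covariates, n)
  if (is.null(rotation)) rotation <- kinship_rotation(K)
  U <- rotation$U; S <- rotation$S
  yr <- drop(crossprod(U, y))
  Cr <- crossprod(U, covariates)

  grid <- exp(seq(log(1e-4), log(1e4), length.out = 100))
  ll_grid <- vapply(grid, .ll_at_delta, numeric(1), yr = yr, Cr = Cr, S = S)
  i <- which.max(ll_grid)
  lo <- log(grid[max(1L, i - 1L)]); hi <- log(grid[min(100L, i + 1L)])
  opt <- stats::optimize(function(ld) .ll_at_delta(exp(ld), yr, Cr, S),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum); ll <- opt$objective
  ll_inf <- .ll_at_delta(Inf, yr, Cr, S)
  if (ll_inf >= ll - 1e-10) {
    delta <- Inf; ll <- ll_inf
  }

  w <- if (is.infinite(delta)) rep(1, n) else 1 / (S + delta)
  sw <- sqrt(w)
  qrC <- qr(Cr * sw)
  ry <- qr.resid(qrC, yr * sw)
  rss0 <- sum(ry^2)
  sigma2 <- rss0 / n
  if (is.infinite(delta)) {
    sigma_bg2 <- 0; sigma_n2 <- sigma2
  } else {
    sigma_bg2 <- sigma2; sigma_n2 <- delta * sigma2
  }
  structure(list(delta = delta, sigma_bg2 = sigma_bg2, sigma_n2 = sigma_n2,
                 loglik = ll, rotation = rotation, sw = sw, qrC = qrC,
                 resid_y = ry, rss0 = rss0, n = n, p = ncol(covariates)),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("lmm_null: delta = %.4g, loglik = %.4f\n", x$delta, x$loglik))
  invisible(x)
}

#' Single-variant mixed model association test
#'
#' Generalized least squares for one variant at the delta fixed by
#' [fit_lmm_null()]; the p-value is a 1-df chi-squared likelihood-ratio test
#' with the overall variance scale profiled out
#' (`lrt = N log(RSS0 / RSS1)` in the whitened basis).
#'
#' @param x genotype dosage vector (mean-imputed if it contains `NA`).
#' @param y expression vector the null model was fit on.
#' @param null an `lmm_null` from [fit_lmm_null()].
#' @return List of class `association_result`: `beta`, `pvalue`, `lrt_stat`,
#'   `n_conditioned` (0 here).
#' @export
lmm_assoc <- function(x, y, null) {
  x <- as.numeric(x)
  if (any(is.na(x))) x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (stats::var(x) == 0) stop("monomorphic variant")
  xr <- drop(crossprod(null$rotation$U, x)) * null$sw
  rx <- qr.resid(null$qrC, xr)
  den <- sum(rx^2)
  num <- sum(rx * null$resid_y)
  beta <- num / den
  rss1 <- max(null$rss0 - num^2 / den, .Machine$double.xmin)
  lrt <- max(null$n * (log(null$rss0) - log(rss1)), 0)
  structure(list(beta = beta, pvalue = stats::pchisq(lrt, 1, lower.tail = FALSE),
                 lrt_stat = lrt, n_conditioned = 0L),
            class = "association_result")
}

#' Genome-wide eQTL scan
#'
#' For every gene: one [fit_lmm_null()], then a vectorized
#' [lmm_assoc()]-equivalent test against every variant. Monomorphic variants
#' yield `NA` entries (count reported via a message).
#'
#' @param genotypes [genotype_data].
#' @param expression [expression_data].
#' @param K background [kinship]; identity when `NULL`.
#' @param covariates optional fixed-effect matrix.
#' @param rotation optional precomputed [kinship_rotation()].
#' @return An `association_scan`: genes x variants matrices `pvalues`,
#'   `betas`, `lrt`, plus `gene_ids`, `variant_ids`, per-gene `deltas`, and
#'   an `n_conditioned` matrix (all zero for this unconditioned scan).
#' @export
lmm_scan <- function(genotypes, expression, K = NULL, covariates = NULL,
                     rotation = NULL) {
  check_paired(genotypes, expression)
  n <- n_samples(genotypes)
  K <- as_kinship(K, n)
  if (is.null(rotation)) rotation <- kinship_rotation(K)
  X <- genotypes$dosages
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }
  xvar <- apply(X, 2, stats::var)
  bad <- xvar == 0
  if (any(bad)) message(sprintf("scan: %d monomorphic variant(s) set to NA", sum(bad)))
  Xr <- crossprod(rotation$U, X)

  tg <- ncol(expression$values); f <- ncol(X)
  P <- matrix(NA_real_, tg, f, dimnames = list(expression$gene_ids, genotypes$variant_ids))
  B <- P; L <- P
  deltas <- numeric(tg)
  ok <- which(!bad)
  for (t in seq_len(tg)) {
    null <- fit_lmm_null(expression$values[, t], K, covariates, rotation = rotation)
    deltas[t] <- null$delta
    Xw <- Xr[, ok, drop = FALSE] * null$sw
    RX <- qr.resid(null$qrC, Xw)
    den <- colSums(RX^2)
    num <- colSums(RX * null$resid_y)
    rss1 <- pmax(null$rss0 - num^2 / den, .Machine$double.xmin)
    lrt <- pmax(null$n * (log(null$rss0) - log(rss1)), 0)
    P[t, ok] <- stats::pchisq(lrt, 1, lower.tail = FALSE)
    B[t, ok] <- num / den
    L[t, ok] <- lrt
  }
  association_scan(P, B, lrt = L, gene_ids = expression$gene_ids,
                   variant_ids = genotypes$variant_ids, deltas = deltas)
}

#' Association scan container
#'
#' @param pvalues,betas genes x variants matrices.
#' @param lrt optional matching matrix of likelihood-ratio statistics.
#' @param gene_ids,variant_ids row/column identifiers.
#' @param deltas optional per-gene variance ratios.
#' @param n_conditioned optional matrix of conditioning-set sizes (0 default).
#' @export
association_scan <- function(pvalues, betas, lrt = NULL, gene_ids = rownames(pvalues),
                             variant_ids = colnames(pvalues), deltas = NULL,
                             n_conditioned = NULL) {
  pvalues <- as.matrix(pvalues); betas <- as.matrix(betas)
  stopifnot(all(dim(pvalues) == dim(betas)))
  if (is.null(n_conditioned))
    n_conditioned <- matrix(0L, nrow(pvalues), ncol(pvalues))
  structure(list(pvalues = pvalues, betas = betas, lrt = lrt,
                 gene_ids = gene_ids, variant_ids = variant_ids,
                 deltas = deltas, n_conditioned = n_conditioned),
            class = "association_scan")
}

#' @export
print.association_scan <- function(x, ...) {
  cat(sprintf("association_scan: %d genes x %d variants; min p = %.3g\n",
              nrow(x$pvalues), ncol(x$pvalues), min(x$pvalues, na.rm = TRUE)))
  invisible(x)
}
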