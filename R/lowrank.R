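# Low-rank three-variance-component LMM used to condition association tests
# on a small set of exogenous gene expression vectors:
#   y ~ N(C alpha + x beta,
#         sigma_bg^2 K + sigma_exo^2 B B' + sigma_n^2 I),   B = [y_B1 ... y_BR]
# In the kinship eigenbasis (K = U S U') the covariance becomes
#   sigma_n^2 (exp(t1) S + exp(t2) G G' + I),  G = U' B,
# with t1 = log(sigma_bg^2/sigma_n^2), t2 = log(sigma_exo^2/sigma_n^2) and
# sigma_n^2 profiled out. Solves and log-determinants use the Woodbury
# identity so each likelihood evaluation costs O(N R^2), never refactorizing
# a dense N x N covariance.

# Centre and scale columns to unit (1/N) variance.
standardize_columns <- function(B) {
  B <- as.matrix(B)
  Bc <- sweep(B, 2, colMeans(B), "-")
  v <- colMeans(Bc^2)
  if (any(v == 0)) stop("constant exogenous column")
  sweep(Bc, 2, sqrt(v), "/")
}

# V^{-1} %*% B and log|V| for V = diag(d) + A A', via Woodbury.
.lowrank_solve <- function(d, A, B) {
  Bd <- B / d
  Ad <- A / d
  M <- diag(ncol(A)) + crossprod(A, Ad)
  M <- (M + t(M)) / 2
  ch <- chol(M)
  sol <- Bd - Ad %*% backsolve(ch, forwardsolve(t(ch), crossprod(A, Bd)))
  list(sol = sol, logdet = sum(log(d)) + 2 * sum(log(diag(ch))))
}

# Negative profiled log-likelihood at (t1, t2) with analytic gradient
# (compiled kernel; one evaluation shared between optim's fn and gr calls).
.lowrank_objective <- function(yr, Cr, G, S) {
  cache <- list(theta = NULL, res = NULL)
  eval_at <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) {
      cache$res <<- lowrank_nll_grad_cpp(theta, yr, Cr, G, S)
      cache$theta <<- theta
    }
    cache$res
  }
  list(fn = function(theta) eval_at(theta)$value,
       gr = function(theta) eval_at(theta)$grad)
}

# Pure-R negative profiled log-likelihood at (t1, t2); reference path kept
# for the compiled kernel's regression tests.
.lowrank_nll <- function(theta, yr, Cr, G, S) {
  n <- length(yr)
  d <- exp(theta[1]) * S + 1
  A <- G * sqrt(exp(theta[2]))
  ls <- .lowrank_solve(d, A, cbind(Cr, yr))
  p <- ncol(Cr)
  VC <- ls$sol[, seq_len(p), drop = FALSE]
  Vy <- ls$sol[, p + 1L]
  CtVC <- crossprod(Cr, VC)
  CtVy <- crossprod(Cr, Vy)
  alpha <- solve(CtVC, CtVy)
  rss <- drop(crossprod(yr, Vy) - crossprod(CtVy, alpha))
  if (rss <= 0) return(1e10)
  n / 2 * (log(2 * pi) + 1) + n / 2 * log(rss / n) + ls$logdet / 2
}

#' Fit the conditioned (three-component) null model
#'
#' Maximum-likelihood fit of the variance components `(sigma_bg^2,
#' sigma_exo^2, sigma_n^2)` of the null model (no tested variant) for one
#' gene and one conditioning set. Exogenous columns are standardized to unit
#' variance before forming the rank-R covariance. Optimization is over the
#' two log variance ratios with multi-start L-BFGS-B; the overall scale is
#' profiled out.
#'
#' @param y expression vector of the focal gene.
#' @param K background [kinship].
#' @param exo N x R matrix of exogenous-gene expression vectors (R >= 1).
#' @param covariates optional fixed effects (intercept added when absent).
#' @param rotation optional precomputed [kinship_rotation()].
#' @param max_rank maximum permitted rank; extra columns (beyond the first
#'   `max_rank`, which callers order by relevance) are dropped with a message.
#' @param standardize centre and scale the exogenous columns to unit
#'   variance before forming the covariance (disable when the caller passes
#'   a pre-scaled covariance square root).
#' @return Object of class `lowrank_null` with the fitted components and
#'   cached projections for fast per-variant tests.
#' @export
fit_lowrank_null <- function(y, K, exo, covariates = NULL, rotation = NULL,
                             max_rank = 10L, standardize = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  exo <- as.matrix(exo)
  if (ncol(exo) < 1L) stop("need at least one exogenous column")
  if (ncol(exo) > max_rank) {
    message(sprintf("conditioning set truncated from %d to %d genes",
                    ncol(exo), max_rank))
    exo <- exo[, seq_len(max_rank), drop = FALSE]
  }
  covariates <- prepare_covariates(covariates, n)
  if (is.null(rotation)) rotation <- kinship_rotation(K)
  U <- rotation$U; S <- rotation$S
  yr <- drop(crossprod(U, y))
  Cr <- crossprod(U, covariates)
  G <- crossprod(U, if (standardize) standardize_columns(exo) else exo)

  obj <- .lowrank_objective(yr, Cr, G, S)
  # coarse value-only grid including large-positive ratios: with a
  # wide-spectrum kinship the ML can sit at the vanishing-noise boundary,
  # which purely interior starts would miss
  grid <- as.matrix(expand.grid(t1 = c(-8, -2, 2, 8), t2 = c(-8, -2, 2, 8)))
  vals <- apply(grid, 1, obj$fn)
  best <- stats::optim(grid[which.min(vals), ], obj$fn, obj$gr,
                       method = "L-BFGS-B",
                       lower = c(-20, -20), upper = c(20, 20),
                       control = list(factr = 1e4, maxit = 500))
  t1 <- best$par[1]; t2 <- best$par[2]

  d <- exp(t1) * S + 1
  A <- G * sqrt(exp(t2))
  ls <- .lowrank_solve(d, A, cbind(Cr, yr))
  p <- ncol(Cr)
  VC <- ls$sol[, seq_len(p), drop = FALSE]
  Vy <- ls$sol[, p + 1L]
  CtVC <- crossprod(Cr, VC)
  CtVy <- crossprod(Cr, Vy)
  alpha <- solve(CtVC, CtVy)
  rss0 <- drop(crossprod(yr, Vy) - crossprod(CtVy, alpha))
  sigma_n2 <- rss0 / n
  structure(list(t1 = t1, t2 = t2,
                 sigma_n2 = sigma_n2,
                 sigma_bg2 = sigma_n2 * exp(t1),
                 sigma_exo2 = sigma_n2 * exp(t2),
                 loglik = -best$value,
                 rank = ncol(G),
                 rotation = rotation, d = d, A = A, Cr = Cr, yr = yr,
                 Vy = Vy, VC = VC, CtVC = CtVC, CtVy = CtVy,
                 rss0 = rss0, n = n),
            class = "lowrank_null")
}

#' @export
print.lowrank_null <- function(x, ...) {
  cat(sprintf(
    "lowrank_null (rank %d): sigma_bg2 = %.4g, sigma_exo2 = %.4g, sigma_n2 = %.4g\n",
    x$rank, x$sigma_bg2, x$sigma_exo2, x$sigma_n2))
  invisible(x)
}

# Vectorized conditioned tests of many variants against one fitted
# lowrank_null (or a plain variant via lmm_assoc_conditioned below).
# Xr: rotated genotype matrix (columns = variants). Returns beta/lrt/p.
.lowrank_tests <- function(null, Xr) {
  VX <- .lowrank_solve(null$d, null$A, Xr)$sol
  xVx <- colSums(Xr * VX)
  CtVX <- crossprod(null$Cr, VX)
  xVy <- drop(crossprod(Xr, null$Vy))
  sol <- solve(null$CtVC, CtVX)
  den <- xVx - colSums(CtVX * sol)
  num <- xVy - drop(crossprod(CtVX, solve(null$CtVC, null$CtVy)))
  beta <- num / den
  rss1 <- pmax(null$rss0 - num^2 / den, .Machine$double.xmin)
  lrt <- pmax(null$n * (log(null$rss0) - log(rss1)), 0)
  list(beta = beta, lrt = lrt,
       pvalue = stats::pchisq(lrt, 1, lower.tail = FALSE))
}

#' Conditioned single-variant association test
#'
#' Tests the variant effect beta in `y ~ N(x beta + C alpha, sigma_bg^2 K +
#' sigma_exo^2 B B' + sigma_n^2 I)`. Variance components are those of the
#' supplied (or freshly fitted) [fit_lowrank_null()] and held fixed; the
#' p-value is the 1-df likelihood-ratio test with the scale profiled.
#'
#' @inheritParams fit_lowrank_null
#' @param x genotype dosage vector.
#' @param null optional prefitted `lowrank_null` (for one gene and one
#'   conditioning set shared across variants).
#' @return `association_result` with `n_conditioned` set to the rank used.
#' @export
lmm_assoc_conditioned <- function(x, y, K, exo, covariates = NULL, null = NULL,
                                  rotation = NULL, max_rank = 10L) {
  if (is.null(null))
    null <- fit_lowrank_null(y, K, exo, covariates, rotation = rotation,
                             max_rank = max_rank)
  x <- as.numeric(x)
  if (any(is.na(x))) x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (stats::var(x) == 0) stop("monomorphic variant")
  xr <- crossprod(null$rotation$U, x)
  r <- .lowrank_tests(null, xr)
  structure(list(beta = r$beta[1], pvalue = r$pvalue[1], lrt_stat = r$lrt[1],
                 n_conditioned = null$rank),
            class = "association_result")
}
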