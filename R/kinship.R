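# Standardize a dosage matrix column-wise: mean-impute missing calls, centre,
# scale to unit population variance (1/N divisor). Zero-variance columns are
# dropped. Returns the standardized matrix plus the kept column index.
standardize_genotypes <- function(dosages) {
  X <- as.matrix(dosages)
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) {
      m <- mean(X[!miss, j])
      if (is.nan(m)) m <- 0
      X[miss, j] <- m
    }
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  v <- colMeans(Xc^2)
  keep <- which(v > 0)
  if (length(keep) == 0L) stop("no informative variants")
  Z <- sweep(Xc[, keep, drop = FALSE], 2, sqrt(v[keep]), "/")
  list(Z = Z, keep = keep, dropped = ncol(X) - length(keep))
}

#' Realized relationship matrix
#'
#' Kinship estimate from standardized genotypes, K = Z Z' / F, where Z holds
#' the mean-imputed, centred, unit-variance dosage columns and F is the number
#' of informative (non-monomorphic) variants. Used as the background random
#' effect covariance of the association models, adjusting for population
#' structure and relatedness.
#'
#' @param genotypes a [genotype_data] object.
#' @return An object of class `kinship`: list with `matrix` (N x N, symmetric
#'   positive semi-definite), `kind = "realized-relationship"`, and `n_variants`
#'   (variants used after dropping zero-variance columns, which emits a
#'   warning).
#' @export
realized_relationship <- function(genotypes) {
  std <- standardize_genotypes(genotypes$dosages)
  if (std$dropped > 0L)
    warning(sprintf("dropped %d zero-variance variant(s)", std$dropped))
  K <- tcrossprod(std$Z) / ncol(std$Z)
  K <- (K + t(K)) / 2
  kinship(K, kind = "realized-relationship", n_variants = ncol(std$Z))
}

#' Kinship constructor
#'
#' Wraps an N x N covariance matrix with validation (symmetry to 1e-10,
#' positive semi-definiteness up to a relative eigenvalue tolerance of 1e-8).
#'
#' @param matrix symmetric PSD matrix.
#' @param kind one of `"realized-relationship"`, `"identity"`, `"custom"`.
#' @param n_variants optional count of variants the matrix was built from.
#' @export
kinship <- function(matrix, kind = c("custom", "realized-relationship", "identity"),
                    n_variants = NA_integer_) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("kinship matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-10) stop("kinship matrix must be symmetric")
  ev <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("kinship matrix must be positive semi-definite")
  structure(list(matrix = matrix, kind = kind, n_variants = n_variants),
            class = "kinship")
}

#' Identity kinship (no background structure)
#' @param n sample count.
#' @export
identity_kinship <- function(n) {
  kinship(diag(n), kind = "identity")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship (%s): %d x %d\n", x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

as_kinship <- function(K, n) {
  if (is.null(K)) return(identity_kinship(n))
  if (inherits(K, "kinship")) return(K)
  kinship(K)
}
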