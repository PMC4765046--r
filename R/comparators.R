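# Reference comparator methods sharing the LMM engine: principal-component
# random effects (with and without genetic-association screening of the
# PCs), the empirical expression-covariance random effect (ICE), and oracle
# conditioning on the simulated ground truth.

# Scan all genes against all variants with one shared low-rank random-effect
# term G (N x R), three variance components refit per gene on the null.
.lowrank_scan <- function(genotypes, expression, K, G, covariates = NULL,
                          rotation = NULL, exclude = NULL,
                          standardize = TRUE) {
  n <- n_samples(genotypes)
  K <- as_kinship(K, n)
  if (is.null(rotation)) rotation <- kinship_rotation(K)
  X <- genotypes$dosages
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }
  ok <- which(apply(X, 2, stats::var) > 0)
  Xr <- crossprod(rotation$U, X[, ok, drop = FALSE])
  tg <- ncol(expression$values); f <- ncol(X)
  P <- matrix(NA_real_, tg, f, dimnames = list(expression$gene_ids,
                                               genotypes$variant_ids))
  B <- P; L <- P
  NC <- matrix(0L, tg, f)
  for (t in seq_len(tg)) {
    Gt <- if (is.null(exclude)) G else G[, setdiff(seq_len(ncol(G)), exclude[[t]]),
                                         drop = FALSE]
    null3 <- fit_lowrank_null(expression$values[, t], K, Gt, covariates,
                              rotation = rotation, max_rank = ncol(Gt),
                              standardize = standardize)
    res <- .lowrank_tests(null3, Xr)
    P[t, ok] <- res$pvalue; B[t, ok] <- res$beta; L[t, ok] <- res$lrt
    NC[t, ] <- ncol(Gt)
  }
  association_scan(P, B, lrt = L, gene_ids = expression$gene_ids,
                   variant_ids = genotypes$variant_ids, n_conditioned = NC)
}

#' Principal-component random-effect scan (PC-LMM / PCselect-LMM)
#'
#' Computes the top `n_pcs` principal components of the column-standardized
#' expression matrix and adds their (standardized) score vectors as a second
#' random-effect covariance next to the genetic background. With
#' `select = TRUE`, each PC is first mapped as a quantitative trait with the
#' standard LMM; PCs with any Benjamini-Hochberg q-value below
#' `pc_qval_cutoff` across the PC x variant tests are excluded before
#' conditioning (screening out PCs that absorb genetic signal).
#'
#' @param genotypes,expression paired data.
#' @param K background [kinship] (realized relationship matrix when `NULL`).
#' @param n_pcs number of leading PCs (0 gives the plain LMM scan).
#' @param select screen out genetically associated PCs.
#' @param pc_qval_cutoff q-value threshold of the screen.
#' @param covariates optional fixed effects.
#' @return [association_scan].
#' @export
run_pc_lmm <- function(genotypes, expression, K = NULL, n_pcs = 10L,
                       select = FALSE, pc_qval_cutoff = 0.2,
                       covariates = NULL) {
  check_paired(genotypes, expression)
  n <- n_samples(genotypes)
  if (n_pcs >= n) stop("n_pcs must be smaller than the sample count")
  if (is.null(K)) K <- realized_relationship(genotypes)
  K <- as_kinship(K, n)
  rotation <- kinship_rotation(K)
  if (n_pcs == 0L)
    return(lmm_scan(genotypes, expression, K, covariates, rotation = rotation))
  Ys <- standardize_columns(expression$values)
  sv <- svd(Ys, nu = n_pcs, nv = 0)
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*% diag(sv$d[seq_len(n_pcs)],
                                                          n_pcs)
  if (select) {
    pc_expr <- expression_data(scores, gene_ids = paste0("PC", seq_len(n_pcs)),
                               chrom = rep("0", n_pcs), tss = seq_len(n_pcs))
    pc_scan <- lmm_scan(genotypes, pc_expr, K, covariates, rotation = rotation)
    q <- matrix(stats::p.adjust(pc_scan$pvalues, method = "BH"),
                nrow = n_pcs)
    drop_pc <- apply(q, 1, function(v) any(v < pc_qval_cutoff, na.rm = TRUE))
    if (all(drop_pc)) {
      warning("all PCs genetically associated; falling back to the plain LMM")
      return(lmm_scan(genotypes, expression, K, covariates, rotation = rotation))
    }
    scores <- scores[, !drop_pc, drop = FALSE]
  }
  .lowrank_scan(genotypes, expression, K, scores, covariates, rotation)
}

#' Empirical expression-covariance random-effect scan (ICE-LMM)
#'
#' Adds `Y Y' / T` of the standardized expression matrix as a second random
#' effect next to the genetic background (three variance components refit
#' per gene on the null), then scans as usual.
#'
#' @inheritParams run_pc_lmm
#' @param exclude_focal drop the focal gene's own column from the empirical
#'   covariance for each gene's scan.
#' @export
run_ice_lmm <- function(genotypes, expression, K = NULL, covariates = NULL,
                        exclude_focal = FALSE) {
  check_paired(genotypes, expression)
  tg <- ncol(expression$values)
  if (tg < 2L) stop("ICE requires at least 2 genes")
  if (is.null(K)) K <- realized_relationship(genotypes)
  Ys <- standardize_columns(expression$values) / sqrt(tg)
  if (exclude_focal) {
    return(.lowrank_scan(genotypes, expression, K, Ys, covariates,
                         exclude = as.list(seq_len(tg))))
  }
  # Y Y'/T has rank <= min(N, T); represent it by its exact square root so
  # the per-evaluation cost never exceeds O(N^3)
  if (tg > nrow(Ys)) {
    sv <- svd(Ys, nv = 0)
    keep <- sv$d > sv$d[1] * 1e-12
    Ys <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  }
  .lowrank_scan(genotypes, expression, K, Ys, covariates,
                standardize = FALSE)
}

# Genetic reachability: gene_snp_dep[g, ] lists the cis-anchor variants of g
# and of all its regulatory ancestors.
.genetic_ancestry <- function(truth) {
  adj <- truth$adjacency
  tg <- ncol(adj)
  reach <- (adj > 0)           # reach[j, t]: j is an ancestor of t
  repeat {
    nxt <- reach | ((reach %*% (adj > 0)) > 0)
    if (all(nxt == reach)) break
    reach <- nxt
  }
  dep <- vector("list", tg)
  for (t in seq_len(tg)) {
    genes <- c(t, which(reach[, t]))
    dep[[t]] <- unique(truth$cis_anchor[genes][!is.na(truth$cis_anchor[genes])])
  }
  list(ancestors = reach, snp_dep = dep)
}

#' Oracle conditioning scans (ideal-LMM / coreg-LMM)
#'
#' Uses the simulated ground truth to pick conditioning sets. `"ideal"`
#' conditions, per (SNP, gene) test, on the true parents of the focal gene
#' that are genetically independent of the tested SNP, plus all confounder
#' factors. `"coreg"` conditions on co-regulated genes: genes whose genetic
#' ancestry contains the tested SNP but that are not ancestors of the focal
#' gene (on the basic power motif this is exactly the downstream gene D).
#'
#' @inheritParams run_pc_lmm
#' @param truth a [network_truth] from the simulator.
#' @param mode `"ideal"` or `"coreg"`.
#' @param max_rank rank cap of the conditioning covariance.
#' @export
run_oracle_lmm <- function(genotypes, expression, K = NULL, truth,
                           mode = c("ideal", "coreg"), covariates = NULL,
                           max_rank = 10L) {
  mode <- match.arg(mode)
  if (is.null(truth)) stop("simulation truth is required")
  check_paired(genotypes, expression)
  n <- n_samples(genotypes)
  if (is.null(K)) K <- realized_relationship(genotypes)
  K <- as_kinship(K, n)
  rotation <- kinship_rotation(K)
  anc <- .genetic_ancestry(truth)
  tg <- ncol(expression$values); f <- ncol(genotypes$dosages)

  X <- genotypes$dosages
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }
  ok <- which(apply(X, 2, stats::var) > 0)
  Xr <- crossprod(rotation$U, X[, ok, drop = FALSE])
  confs <- truth$confounders

  P <- matrix(NA_real_, tg, f, dimnames = list(expression$gene_ids,
                                               genotypes$variant_ids))
  B <- P; L <- P
  NC <- matrix(0L, tg, f)
  for (t in seq_len(tg)) {
    y <- expression$values[, t]
    if (mode == "ideal") {
      parents <- which(truth$adjacency[, t] == 1)
      set_of <- lapply(ok, function(s)
        parents[!vapply(parents, function(p) s %in% anc$snp_dep[[p]], TRUE)])
    } else {
      affected <- lapply(ok, function(s)
        which(vapply(seq_len(tg), function(g) s %in% anc$snp_dep[[g]], TRUE)))
      set_of <- lapply(affected, function(g)
        setdiff(g, c(t, which(anc$ancestors[, t]))))
    }
    sig <- vapply(set_of, paste, "", collapse = ",")
    for (g in unique(sig)) {
      cols <- which(sig == g)
      set <- set_of[[cols[1]]]
      exo <- expression$values[, set, drop = FALSE]
      if (mode == "ideal" && !is.null(confs)) exo <- cbind(exo, confs)
      if (ncol(exo) == 0L) {
        null1 <- fit_lmm_null(y, K, covariates, rotation = rotation)
        Xw <- Xr[, cols, drop = FALSE] * null1$sw
        RX <- qr.resid(null1$qrC, Xw)
        den <- colSums(RX^2); num <- colSums(RX * null1$resid_y)
        rss1 <- pmax(null1$rss0 - num^2 / den, .Machine$double.xmin)
        lrt <- pmax(null1$n * (log(null1$rss0) - log(rss1)), 0)
        P[t, ok[cols]] <- stats::pchisq(lrt, 1, lower.tail = FALSE)
        B[t, ok[cols]] <- num / den
        L[t, ok[cols]] <- lrt
      } else {
        keep <- seq_len(min(ncol(exo), max_rank))
        null3 <- fit_lowrank_null(y, K, exo[, keep, drop = FALSE], covariates,
                                  rotation = rotation, max_rank = max_rank)
        res <- .lowrank_tests(null3, Xr[, cols, drop = FALSE])
        P[t, ok[cols]] <- res$pvalue
        B[t, ok[cols]] <- res$beta
        L[t, ok[cols]] <- res$lrt
        NC[t, ok[cols]] <- length(keep)
      }
    }
  }
  association_scan(P, B, lrt = L, gene_ids = expression$gene_ids,
                   variant_ids = genotypes$variant_ids, n_conditioned = NC)
}

#' Choose the PC count maximizing the number of trans associations
#'
#' Runs [run_pc_lmm()] over a grid of PC counts and returns the scan of the
#' count yielding the most trans associations below a p-value threshold.
#'
#' @inheritParams run_pc_lmm
#' @param grid candidate PC counts.
#' @param threshold significance threshold on the (Bonferroni-adjusted)
#'   p-values.
#' @param trans_window_bp minimum TSS-variant distance for a trans call.
#' @return list(`n_pcs`, `scan`, `counts`).
#' @export
choose_n_pcs <- function(genotypes, expression, K = NULL,
                         grid = c(10, 20, 30, 40, 50), select = FALSE,
                         threshold = 0.05, trans_window_bp = 5e6,
                         covariates = NULL) {
  if (is.null(K)) K <- realized_relationship(genotypes)
  trans_mask <- outer(seq_along(expression$gene_ids),
                      seq_along(genotypes$variant_ids),
                      function(i, j)
                        expression$chrom[i] != genotypes$chrom[j] |
                        abs(expression$tss[i] - genotypes$pos[j]) > trans_window_bp)
  counts <- integer(length(grid))
  scans <- vector("list", length(grid))
  ntest <- sum(trans_mask)
  for (i in seq_along(grid)) {
    scans[[i]] <- run_pc_lmm(genotypes, expression, K, n_pcs = grid[i],
                             select = select, covariates = covariates)
    counts[i] <- sum(scans[[i]]$pvalues[trans_mask] * ntest < threshold,
                     na.rm = TRUE)
  }
  best <- which.max(counts)
  list(n_pcs = grid[best], scan = scans[[best]],
       counts = data.frame(n_pcs = grid, n_trans = counts))
}
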