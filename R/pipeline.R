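# Three-step network-guided trans-eQTL pipeline:
#   1. genome-wide LMM scan (one null fit per gene, EMMA-X fixed delta);
#   2. V-structure discovery seeded by cis/trans anchor genes;
#   3. conditioned re-tests of every (SNP, gene) pair with a nonempty
#      conditioning set, grouped by unique (gene, set) so the three-component
#      null is fit once per group.
# Entries without a conditioning set are copied unchanged from Step 1, so
# with no detectable anchors or V-structures the method reverts exactly to
# the standard LMM scan.

#' Run the network-guided LMM pipeline
#'
#' @param genotypes [genotype_data].
#' @param expression [expression_data].
#' @param covariates optional fixed-effect matrix (intercept added).
#' @param K background [kinship]; by default the realized relationship
#'   matrix of `genotypes`.
#' @param cfg [threshold_config()].
#' @param max_rank maximum conditioning-set rank; larger sets keep the
#'   `max_rank` genes with smallest V-structure partial-correlation p-values.
#' @param out_dir optional checkpoint directory: the Step-1 scan, the
#'   V-structure table and the updated scan are written as TSV after each
#'   step, and reused on a rerun when `resume = TRUE`.
#' @param resume reuse existing checkpoint files in `out_dir`.
#' @return Object of class `netlmm_result`: `initial_scan`, `updated_scan`,
#'   `anchors`, `vstructures`, `conditioning`, `K`, `config`, `provenance`.
#' @export
run_netlmm <- function(genotypes, expression, covariates = NULL, K = NULL,
                       cfg = threshold_config(), max_rank = 10L,
                       out_dir = NULL, resume = TRUE) {
  check_paired(genotypes, expression)
  n <- n_samples(genotypes)
  if (is.null(K)) K <- realized_relationship(genotypes)
  K <- as_kinship(K, n)
  rotation <- kinship_rotation(K)
  ckpt <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # Step 1
  f1 <- ckpt("scan_initial.tsv")
  if (!is.null(f1) && resume && file.exists(f1)) {
    initial <- read_scan(f1)
  } else {
    initial <- lmm_scan(genotypes, expression, K, covariates, rotation = rotation)
    if (!is.null(f1)) write_scan(initial, f1)
  }

  # Step 2
  anchors <- find_anchor_genes(initial, genotypes, expression, cfg)
  f2 <- ckpt("vstructures.tsv")
  if (!is.null(f2) && resume && file.exists(f2)) {
    vs <- read_vstructures(f2)
  } else {
    vs <- find_vstructures(anchors, initial, expression, genotypes, cfg)
    if (!is.null(f2)) write_vstructures(vs, f2)
  }
  cs <- build_conditioning_sets(vs)

  # Step 3
  updated <- initial
  if (length(cs$sets)) {
    sets_trunc <- lapply(cs$sets, function(s) s[seq_len(min(length(s), max_rank))])
    sig <- paste(cs$keys$focal_index,
                 vapply(sets_trunc, paste, "", collapse = ","), sep = ":")
    for (g in unique(sig)) {
      rows <- which(sig == g)
      focal <- cs$keys$focal_index[rows[1]]
      set <- sets_trunc[[rows[1]]]
      null3 <- fit_lowrank_null(expression$values[, focal], K,
                                expression$values[, set, drop = FALSE],
                                covariates, rotation = rotation,
                                max_rank = max_rank)
      snps <- cs$keys$snp_index[rows]
      X <- genotypes$dosages[, snps, drop = FALSE]
      for (j in seq_len(ncol(X))) {
        miss <- is.na(X[, j])
        if (any(miss)) X[miss, j] <- mean(X[!miss, j])
      }
      ok <- apply(X, 2, stats::var) > 0
      if (!any(ok)) next
      res <- .lowrank_tests(null3, crossprod(rotation$U, X[, ok, drop = FALSE]))
      idx <- cbind(focal, snps[ok])
      updated$pvalues[idx] <- res$pvalue
      updated$betas[idx] <- res$beta
      if (!is.null(updated$lrt)) updated$lrt[idx] <- res$lrt
      updated$n_conditioned[idx] <- length(set)
    }
  }
  f3 <- ckpt("scan_updated.tsv")
  if (!is.null(f3)) write_scan(updated, f3)

  structure(list(initial_scan = initial, updated_scan = updated,
                 anchors = anchors, vstructures = vs, conditioning = cs,
                 K = K, config = cfg, max_rank = max_rank,
                 provenance = list(time = format(Sys.time()),
                                   n_samples = n,
                                   n_genes = ncol(expression$values),
                                   n_variants = ncol(genotypes$dosages),
                                   package = as.character(utils::packageVersion("netlmm")))),
            class = "netlmm_result")
}

#' @export
print.netlmm_result <- function(x, ...) {
  cat(sprintf(paste0("netlmm_result: %d genes x %d variants; %d anchor pair(s), ",
                     "%d V-structure(s), %d conditioned test(s)\n"),
              x$provenance$n_genes, x$provenance$n_variants, nrow(x$anchors),
              nrow(x$vstructures), sum(x$updated_scan$n_conditioned > 0)))
  invisible(x)
}

#' Permutation calibration of the final association tests
#'
#' Builds an empirical null by permuting the sample order of each tested
#' genotype vector -- breaking the SNP-gene link while preserving the
#' expression covariance and the identified conditioning sets -- and
#' re-running only the final association tests (variance components held at
#' their fitted values). Tests are stratified by the presence of exogenous
#' genes: every conditioned (SNP, gene) pair is permuted, together with an
#' equal number of unconditioned pairs (deterministically drawn).
#'
#' @param genotypes,expression the data the result was computed on.
#' @param result a [run_netlmm()] result.
#' @param n_perm permutations per pair (>= 10).
#' @param seed integer seed for the permutation streams.
#' @param covariates optional fixed effects used in the original run.
#' @param n_null_pairs number of unconditioned pairs for the without-exogenous
#'   stratum (default: the size of the conditioned stratum, at least 10).
#' @return data.frame with columns `snp_id`, `gene_id`, `perm`, `pvalue`,
#'   `has_exo`.
#' @export
permutation_calibration <- function(genotypes, expression, result, n_perm,
                                    seed = 1L, covariates = NULL,
                                    n_null_pairs = NULL) {
  if (n_perm < 10) stop("n_perm must be at least 10")
  check_paired(genotypes, expression)
  n <- n_samples(genotypes)
  K <- result$K
  rotation <- kinship_rotation(K)
  cs <- result$conditioning
  max_rank <- result$max_rank

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  perm_tests <- function(null, x) {
    Xp <- vapply(perms, function(p) x[p], numeric(n))
    if (inherits(null, "lowrank_null")) {
      .lowrank_tests(null, crossprod(rotation$U, Xp))$pvalue
    } else {
      Xw <- crossprod(rotation$U, Xp) * null$sw
      RX <- qr.resid(null$qrC, Xw)
      den <- colSums(RX^2); num <- colSums(RX * null$resid_y)
      rss1 <- pmax(null$rss0 - num^2 / den, .Machine$double.xmin)
      lrt <- pmax(null$n * (log(null$rss0) - log(rss1)), 0)
      stats::pchisq(lrt, 1, lower.tail = FALSE)
    }
  }
  impute <- function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x }

  out <- list()
  # stratum with exogenous genes
  if (length(cs$sets)) {
    sets_trunc <- lapply(cs$sets, function(s) s[seq_len(min(length(s), max_rank))])
    sig <- paste(cs$keys$focal_index,
                 vapply(sets_trunc, paste, "", collapse = ","), sep = ":")
    for (g in unique(sig)) {
      rows <- which(sig == g)
      focal <- cs$keys$focal_index[rows[1]]
      null3 <- fit_lowrank_null(expression$values[, focal], K,
                                expression$values[, sets_trunc[[rows[1]]], drop = FALSE],
                                covariates, rotation = rotation, max_rank = max_rank)
      for (s in cs$keys$snp_index[rows]) {
        x <- impute(genotypes$dosages[, s])
        if (stats::var(x) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          snp_id = genotypes$variant_ids[s],
          gene_id = expression$gene_ids[focal],
          perm = seq_len(n_perm), pvalue = perm_tests(null3, x),
          has_exo = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  # stratum without exogenous genes
  n_with <- length(cs$sets)
  if (is.null(n_null_pairs)) n_null_pairs <- max(n_with, 10L)
  tg <- ncol(expression$values); f <- ncol(genotypes$dosages)
  cond_keys <- paste(cs$keys$snp_index, cs$keys$focal_index)
  pool_g <- sample.int(tg, n_null_pairs, replace = TRUE)
  pool_s <- sample.int(f, n_null_pairs, replace = TRUE)
  keep <- !(paste(pool_s, pool_g) %in% cond_keys)
  for (i in which(keep)) {
    x <- impute(genotypes$dosages[, pool_s[i]])
    if (stats::var(x) == 0) next
    null1 <- fit_lmm_null(expression$values[, pool_g[i]], K, covariates,
                          rotation = rotation)
    out[[length(out) + 1L]] <- data.frame(
      snp_id = genotypes$variant_ids[pool_s[i]],
      gene_id = expression$gene_ids[pool_g[i]],
      perm = seq_len(n_perm), pvalue = perm_tests(null1, x),
      has_exo = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
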