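# V-structure (collider) discovery: for each anchored (SNP A, gene A) pair
# and candidate focal gene C, find genes B such that
#   (1) dep(y_A, y_C)        adjusted p <  p_dep
#   (2) dep(y_B, y_C)        adjusted p <  p_dep
#   (3) ind(y_A, y_B)        raw      p >= p_ind
#   (4) dep(y_A, y_B | y_C)  adjusted p <  p_dep   (collider-induced)
#   (5) dep(x_A, y_A)        anchor condition (cis or trans association)
#   (6) ind(x_A, y_B)        raw scan p >= p_snp_ind  (synthetic-association
#                                                      guard)
# The partial correlation (4) is only computed when (1)-(3) and the anchor
# condition already hold.

#' Threshold configuration for V-structure discovery
#'
#' @param preset `"default"` (Bonferroni-adjusted dependence calls, genome
#'   scale) or `"basic"` (stricter raw-p thresholds for small simulated
#'   networks with a handful of genes).
#' @param p_dep adjusted-p threshold for (conditional) gene-gene dependence.
#' @param p_ind raw-p threshold for gene-gene independence.
#' @param p_anchor adjusted-p threshold for the SNP-anchor association.
#' @param p_snp_ind raw-p threshold for SNP-exogenous-gene independence.
#' @param anchor_mode `"cis"` restricts anchor genes to the cis window of the
#'   SNP; `"trans"` admits any associated gene.
#' @param cis_window half-width in base pairs for cis classification
#'   (window inclusive of both endpoints).
#' @param dep_family multiple-testing family for gene-gene dependence calls:
#'   `"pairs"` (Bonferroni by the number of gene pairs, T(T-1)/2), `"none"`
#'   (raw p), or a positive number used as the Bonferroni factor.
#' @param anchor_family family for anchor association calls: `"all-tests"`
#'   (T x F), `"none"`, or a number.
#' @param condition_on conditioning variable of criterion (4):
#'   `"expression"` (the focal gene's expression, the default) or `"both"`
#'   (additionally require dependence given the genotype of the variant
#'   nearest the focal gene's TSS, for sensitivity analyses).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(preset = c("default", "basic"),
                             p_dep = NULL, p_ind = NULL, p_anchor = NULL,
                             p_snp_ind = NULL,
                             anchor_mode = c("cis", "trans"),
                             cis_window = 1e6,
                             dep_family = NULL, anchor_family = NULL,
                             condition_on = c("expression", "both")) {
  preset <- match.arg(preset)
  def <- if (preset == "default") {
    list(p_dep = 0.01, p_ind = 0.1, p_anchor = 0.05, p_snp_ind = 0.1,
         dep_family = "pairs", anchor_family = "all-tests")
  } else {
    list(p_dep = 0.001, p_ind = 0.1, p_anchor = 0.001, p_snp_ind = 0.1,
         dep_family = "none", anchor_family = "none")
  }
  cfg <- list(
    preset = preset,
    p_dep = if (is.null(p_dep)) def$p_dep else p_dep,
    p_ind = if (is.null(p_ind)) def$p_ind else p_ind,
    p_anchor = if (is.null(p_anchor)) def$p_anchor else p_anchor,
    p_snp_ind = if (is.null(p_snp_ind)) def$p_snp_ind else p_snp_ind,
    anchor_mode = match.arg(anchor_mode),
    cis_window = cis_window,
    dep_family = if (is.null(dep_family)) def$dep_family else dep_family,
    anchor_family = if (is.null(anchor_family)) def$anchor_family else anchor_family,
    condition_on = match.arg(condition_on))
  for (f in c("p_dep", "p_ind", "p_anchor", "p_snp_ind"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0, 1)")
  if (cfg$p_dep >= cfg$p_ind) stop("p_dep must be smaller than p_ind")
  class(cfg) <- "threshold_config"
  cfg
}

#' Pearson correlation test
#'
#' Two-sided test of zero correlation via `t = r sqrt((N-2)/(1-r^2))` with
#' N-2 degrees of freedom.
#'
#' @param a,b numeric vectors of equal length (N >= 4), non-constant.
#' @return List with `r` and `pvalue`.
#' @export
correlation_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 4) stop("need at least 4 observations")
  if (stats::var(a) == 0 || stats::var(b) == 0) stop("zero-variance input")
  r <- stats::cor(a, b)
  list(r = r, pvalue = .cor_pvalue(r, n, df = n - 2))
}

.cor_pvalue <- function(r, n, df) {
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.xmin))
  2 * stats::pt(tstat, df, lower.tail = FALSE)
}

#' First-order partial correlation test
#'
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`, tested
#' two-sided with N-3 degrees of freedom. Equals the correlation of the
#' residuals of `a` and `b` after regressing each on `c`.
#'
#' @param a,b,c numeric vectors of equal length (N >= 5).
#' @return List with `r` (the partial correlation) and `pvalue`.
#' @export
partial_correlation_test <- function(a, b, c) {
  n <- length(a)
  if (length(b) != n || length(c) != n) stop("length mismatch")
  if (n < 5) stop("need at least 5 observations")
  r_ab <- stats::cor(a, b); r_ac <- stats::cor(a, c); r_bc <- stats::cor(b, c)
  .partial_cor(r_ab, r_ac, r_bc, n)
}

.partial_cor <- function(r_ab, r_ac, r_bc, n) {
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
    stop("degenerate conditioning")
  r <- (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  r <- max(min(r, 1), -1)
  list(r = r, pvalue = .cor_pvalue(r, n, df = n - 3))
}

# All pairwise gene-gene correlations and their raw two-sided p-values.
gene_correlations <- function(expression) {
  R <- stats::cor(expression$values)
  n <- nrow(expression$values)
  P <- .cor_pvalue(R, n, df = n - 2)
  diag(P) <- 0
  list(r = R, p = P, n = n)
}

.family_size <- function(spec, t_genes, f_variants) {
  if (is.numeric(spec)) return(spec)
  switch(spec,
         "pairs" = t_genes * (t_genes - 1) / 2,
         "all-tests" = t_genes * f_variants,
         "none" = 1,
         stop("unknown family spec: ", spec))
}

#' Find anchor genes per SNP
#'
#' Anchor genes seed the V-structure search: genes with a significant
#' association to the SNP (adjusted p strictly below `p_anchor`), restricted
#' in cis mode to genes whose TSS lies within `cis_window` of the variant on
#' the same chromosome.
#'
#' @param scan the Step-1 [association_scan].
#' @param genotypes,expression the paired data the scan was computed on.
#' @param cfg a [threshold_config].
#' @return data.frame with columns `snp_index`, `snp_id`, `gene_index`,
#'   `gene_id`, `pvalue`, `p_adjusted` (possibly zero rows).
#' @export
find_anchor_genes <- function(scan, genotypes, expression, cfg = threshold_config()) {
  tg <- length(scan$gene_ids); f <- length(scan$variant_ids)
  fam <- .family_size(cfg$anchor_family, tg, f)
  padj <- pmin(scan$pvalues * fam, 1)
  hit <- which(!is.na(padj) & padj < cfg$p_anchor, arr.ind = TRUE)
  if (nrow(hit) && cfg$anchor_mode == "cis") {
    same <- expression$chrom[hit[, 1]] == genotypes$chrom[hit[, 2]]
    near <- abs(expression$tss[hit[, 1]] - genotypes$pos[hit[, 2]]) <= cfg$cis_window
    hit <- hit[same & near, , drop = FALSE]
  }
  data.frame(snp_index = as.integer(hit[, 2]),
             snp_id = scan$variant_ids[hit[, 2]],
             gene_index = as.integer(hit[, 1]),
             gene_id = scan$gene_ids[hit[, 1]],
             pvalue = scan$pvalues[hit],
             p_adjusted = padj[hit],
             stringsAsFactors = FALSE)
}

#' Discover V-structures
#'
#' Applies the six (in)dependence criteria to every (anchor SNP, anchor
#' gene, focal gene, candidate exogenous gene) quartet. Candidate focal
#' genes exclude the anchor gene itself and genes within the cis window of
#' the anchor SNP; partial correlations are evaluated lazily, only for
#' candidates passing the marginal criteria.
#'
#' @param anchors output of [find_anchor_genes()].
#' @param scan the Step-1 [association_scan] (criterion 6 reuses its
#'   p-values as the SNP-gene independence test).
#' @param expression,genotypes paired data.
#' @param cfg a [threshold_config].
#' @return data.frame of class `vstructure_set`: one row per accepted
#'   quartet with the marginal correlations `r_ac`, `r_bc`, `r_ab`, the
#'   partial correlation `r_ab_c`, and its raw p-value `p_partial`.
#' @export
find_vstructures <- function(anchors, scan, expression, genotypes,
                             cfg = threshold_config()) {
  gc_ <- gene_correlations(expression)
  tg <- ncol(expression$values); f <- ncol(genotypes$dosages)
  fam <- .family_size(cfg$dep_family, tg, f)
  dep <- !is.na(gc_$p) & pmin(gc_$p * fam, 1) < cfg$p_dep
  diag(dep) <- FALSE
  out <- vector("list", 64); nout <- 0L

  for (k in seq_len(nrow(anchors))) {
    s <- anchors$snp_index[k]; a <- anchors$gene_index[k]
    cis_of_s <- expression$chrom == genotypes$chrom[s] &
      abs(expression$tss - genotypes$pos[s]) <= cfg$cis_window
    focals <- which(dep[a, ] & !cis_of_s)
    focals <- setdiff(focals, a)
    if (!length(focals)) next
    snp_ind <- !is.na(scan$pvalues[, s]) & scan$pvalues[, s] >= cfg$p_snp_ind
    for (cc in focals) {
      bs <- which(dep[, cc] & gc_$p[a, ] >= cfg$p_ind & snp_ind)
      bs <- setdiff(bs, c(a, cc))
      for (b in bs) {
        pc <- tryCatch(.partial_cor(gc_$r[a, b], gc_$r[a, cc], gc_$r[b, cc], gc_$n),
                       error = function(e) NULL)
        if (is.null(pc)) next
        if (pmin(pc$pvalue * fam, 1) >= cfg$p_dep) next
        if (cfg$condition_on == "both") {
          xc <- .nearest_cis_variant(genotypes, expression, cc, cfg$cis_window)
          if (!is.na(xc)) {
            x <- genotypes$dosages[, xc]
            if (any(is.na(x))) x[is.na(x)] <- mean(x, na.rm = TRUE)
            if (stats::var(x) > 0) {
              pcx <- .partial_cor(gc_$r[a, b],
                                  stats::cor(expression$values[, a], x),
                                  stats::cor(expression$values[, b], x), gc_$n)
              if (pmin(pcx$pvalue * fam, 1) >= cfg$p_dep) next
            }
          }
        }
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- data.frame(
          snp_index = s, snp_id = genotypes$variant_ids[s],
          anchor_index = a, anchor_gene = expression$gene_ids[a],
          focal_index = cc, focal_gene = expression$gene_ids[cc],
          exo_index = b, exo_gene = expression$gene_ids[b],
          r_ac = gc_$r[a, cc], r_bc = gc_$r[b, cc], r_ab = gc_$r[a, b],
          r_ab_c = pc$r, p_partial = pc$pvalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  vs <- if (nout) do.call(rbind, out[seq_len(nout)]) else data.frame(
    snp_index = integer(), snp_id = character(), anchor_index = integer(),
    anchor_gene = character(), focal_index = integer(), focal_gene = character(),
    exo_index = integer(), exo_gene = character(), r_ac = numeric(),
    r_bc = numeric(), r_ab = numeric(), r_ab_c = numeric(),
    p_partial = numeric(), stringsAsFactors = FALSE)
  class(vs) <- c("vstructure_set", "data.frame")
  vs
}

.nearest_cis_variant <- function(genotypes, expression, gene_index, window) {
  same <- genotypes$chrom == expression$chrom[gene_index]
  d <- abs(genotypes$pos - expression$tss[gene_index])
  ok <- which(same & d <= window)
  if (!length(ok)) return(NA_integer_)
  ok[which.min(d[ok])]
}

#' Group accepted V-structures into conditioning sets
#'
#' Exogenous genes are grouped by (SNP, focal gene), deduplicated, and
#' ordered by ascending partial-correlation p-value so that rank truncation
#' in the conditioned test is deterministic.
#'
#' @param vstructures a `vstructure_set` from [find_vstructures()].
#' @return Object of class `conditioning_sets`: data.frame `keys`
#'   (`snp_index`, `focal_index`) and list `sets` of integer gene-index
#'   vectors, aligned by row.
#' @export
build_conditioning_sets <- function(vstructures) {
  if (nrow(vstructures) == 0L) {
    return(structure(list(keys = data.frame(snp_index = integer(),
                                            focal_index = integer()),
                          sets = list()),
                     class = "conditioning_sets"))
  }
  vs <- vstructures[order(vstructures$p_partial), , drop = FALSE]
  key <- paste(vs$snp_index, vs$focal_index, sep = "|")
  sp <- split(vs$exo_index, factor(key, levels = unique(key)))
  sets <- lapply(sp, function(v) unique(as.integer(v)))
  kk <- do.call(rbind, strsplit(names(sets), "|", fixed = TRUE))
  structure(list(keys = data.frame(snp_index = as.integer(kk[, 1]),
                                   focal_index = as.integer(kk[, 2])),
                 sets = unname(sets)),
            class = "conditioning_sets")
}

#' @export
print.conditioning_sets <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("conditioning_sets: %d (SNP, gene) pairs; set sizes %s\n",
              length(x$sets),
              if (length(sz)) paste0("[", min(sz), ", ", max(sz), "]") else "[]"))
  invisible(x)
}

#' @export
print.vstructure_set <- function(x, ...) {
  cat(sprintf("vstructure_set: %d accepted quartet(s)\n", nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x)))
  invisible(x)
}
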