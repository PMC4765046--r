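# Benchmark evaluation: truth labelling of simulated scans, partial-AUC
# power at low false-positive rates, hotspot stratification, and null
# calibration summaries.

#' Label scan entries against the simulated truth
#'
#' An association (gene, variant) is a true positive when the truth
#' adjacency contains a direct regulator of the gene whose cis-anchor
#' variant lies within `tp_window_bp` (inclusive) of the tested variant on
#' the same chromosome. Putative cis associations -- tested variant within
#' `cis_exclusion_bp` of the gene's own position -- are excluded from the
#' ROC; everything else is a false positive.
#'
#' @param scan an [association_scan].
#' @param truth a [network_truth] aligned to the scan's genes.
#' @param genotypes,expression data providing variant and gene coordinates.
#' @param tp_window_bp true-positive window around the regulator's anchor.
#' @param cis_exclusion_bp cis exclusion window around the focal gene.
#' @return data.frame of class `labelled_associations` with columns
#'   `gene_id`, `variant_id`, `pvalue`, `label` in
#'   \{`TP`, `FP`, `excluded-cis`\}.
#' @export
label_truth <- function(scan, truth, genotypes, expression,
                        tp_window_bp = 2000, cis_exclusion_bp = 5e6) {
  tg <- length(scan$gene_ids); f <- length(scan$variant_ids)
  stopifnot(tg == ncol(truth$adjacency))
  lab <- matrix("FP", tg, f)
  for (t in seq_len(tg)) {
    regs <- which(truth$adjacency[, t] == 1)
    anchors <- truth$cis_anchor[regs]
    anchors <- anchors[!is.na(anchors)]
    if (length(anchors)) {
      for (a in anchors) {
        tp <- genotypes$chrom == genotypes$chrom[a] &
          abs(genotypes$pos - genotypes$pos[a]) <= tp_window_bp
        lab[t, tp] <- "TP"
      }
    }
    cis <- genotypes$chrom == expression$chrom[t] &
      abs(genotypes$pos - expression$tss[t]) <= cis_exclusion_bp
    lab[t, cis] <- "excluded-cis"
  }
  out <- data.frame(gene_id = rep(scan$gene_ids, times = f),
                    variant_id = rep(scan$variant_ids, each = tg),
                    pvalue = as.vector(scan$pvalues),
                    label = as.vector(lab),
                    stringsAsFactors = FALSE)
  class(out) <- c("labelled_associations", "data.frame")
  out
}

#' Partial AUC power at a false-positive-rate cap
#'
#' Associations are ranked by ascending p-value (ties processed as a block,
#' giving the averaged diagonal step); the ROC is integrated by the
#' trapezoidal rule over FPR in `[0, fpr_max]`. `power` is the area divided
#' by `fpr_max`, so a perfect ranking scores 1 and a random ranking
#' `fpr_max / 2` normalized.
#'
#' @param labels a [label_truth()] table (excluded entries are ignored).
#' @param fpr_max upper false-positive-rate bound.
#' @return List of class `power_result`: `partial_auc_raw`, `power`,
#'   `n_tp`, `n_fp`.
#' @export
partial_auc <- function(labels, fpr_max = 0.05) {
  d <- labels[labels$label != "excluded-cis" & !is.na(labels$pvalue), ]
  n_tp <- sum(d$label == "TP"); n_fp <- sum(d$label == "FP")
  if (n_tp == 0) stop("undefined power: no true positives")
  if (n_fp == 0) stop("undefined power: no false positives")
  d <- d[order(d$pvalue), ]
  is_tp <- d$label == "TP"
  blocks <- cumsum(!duplicated(d$pvalue))
  cum_tp <- cumsum(is_tp); cum_fp <- cumsum(!is_tp)
  last <- !duplicated(blocks, fromLast = TRUE)
  fpr <- c(0, cum_fp[last] / n_fp)
  tpr <- c(0, cum_tp[last] / n_tp)
  keep <- fpr <= fpr_max
  xs <- fpr[keep]; ys <- tpr[keep]
  if (max(fpr) > fpr_max) {
    y_at <- stats::approx(fpr, tpr, xout = fpr_max, ties = "ordered")$y
    xs <- c(xs, fpr_max); ys <- c(ys, y_at)
  }
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(partial_auc_raw = area, power = area / fpr_max,
                 n_tp = n_tp, n_fp = n_fp),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result: power = %.4f (raw pAUC %.5f; %d TP, %d FP)\n",
              x$power, x$partial_auc_raw, x$n_tp, x$n_fp))
  invisible(x)
}

#' Hotspot stratification table
#'
#' For each significance threshold, counts the genes each variant regulates
#' in trans (variant-TSS distance beyond `trans_window_bp`, or different
#' chromosomes) and summarizes the hotspot-size distribution.
#'
#' @param scan an [association_scan].
#' @param genotypes,expression coordinate sources.
#' @param significance_grid p-value thresholds.
#' @param trans_window_bp minimum distance for a trans call.
#' @return List of class `hotspot_table`: `counts` (threshold, variant,
#'   regulated genes), `histogram` (threshold, hotspot size, variants), and
#'   `totals` (threshold, total trans associations).
#' @export
hotspot_table <- function(scan, genotypes, expression,
                          significance_grid = c(1e-4, 1e-5, 1e-6),
                          trans_window_bp = 2e7) {
  tg <- length(scan$gene_ids)
  trans <- outer(seq_len(tg), seq_along(scan$variant_ids),
                 function(i, j)
                   expression$chrom[i] != genotypes$chrom[j] |
                   abs(expression$tss[i] - genotypes$pos[j]) > trans_window_bp)
  counts <- do.call(rbind, lapply(significance_grid, function(th) {
    hit <- !is.na(scan$pvalues) & scan$pvalues < th & trans
    data.frame(threshold = th, variant_id = scan$variant_ids,
               n_regulated = colSums(hit), stringsAsFactors = FALSE)
  }))
  histogram <- do.call(rbind, lapply(split(counts, counts$threshold), function(d) {
    tab <- table(d$n_regulated[d$n_regulated > 0])
    if (!length(tab))
      return(data.frame(threshold = numeric(), hotspot_size = integer(),
                        n_variants = integer()))
    data.frame(threshold = d$threshold[1],
               hotspot_size = as.integer(names(tab)),
               n_variants = as.integer(tab))
  }))
  rownames(histogram) <- NULL
  totals <- stats::aggregate(n_regulated ~ threshold, counts, sum)
  names(totals)[2] <- "n_trans"
  structure(list(counts = counts, histogram = histogram, totals = totals),
            class = "hotspot_table")
}

#' @export
print.hotspot_table <- function(x, ...) {
  print(x$totals)
  invisible(x)
}

#' Null calibration summary
#'
#' Kolmogorov-Smirnov comparison of a p-value set against Uniform(0, 1) plus
#' the tail fraction at the nominal 0.05 level.
#'
#' @param pvalues at least 100 p-values obtained under the null.
#' @return List with `ks_stat`, `ks_pvalue`, `fraction_below_0.05`, `n`.
#' @export
qq_calibration <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 100) stop("need at least 100 null p-values")
  ks <- suppressWarnings(stats::ks.test(pvalues, "punif"))
  list(ks_stat = unname(ks$statistic), ks_pvalue = ks$p.value,
       fraction_below_0.05 = mean(pvalues < 0.05), n = length(pvalues))
}
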