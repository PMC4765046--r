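test_that("truth labelling applies windows exactly", {
  # 3 genes, adjacency g1 -> g2; g1's anchor is variant 2
  adj <- matrix(0, 3, 3); adj[1, 2] <- 1
  w <- adj
  vf <- data.frame(gene = paste0("g", 1:3), cis = 0.1, network = 0,
                   confounding = 0, noise = 0.9)
  truth <- network_truth(adj, w, c(2L, NA, NA), matrix(0, 0, 3), vf)
  pos <- c(1e6, 2e7, 2e7 + 2000, 2e7 + 2001, 9e7)
  geno <- genotype_data(matrix(rep(c(0, 1, 2), 5), 3, 5),
                        paste0("v", 1:5), rep("1", 5), pos)
  expr <- expression_data(matrix(rnorm(9), 3, 3), paste0("g", 1:3),
                          rep("1", 3), c(2e7, 5e7, 9.2e7))
  sc <- association_scan(matrix(runif(15), 3, 5), matrix(0, 3, 5),
                         gene_ids = paste0("g", 1:3),
                         variant_ids = paste0("v", 1:5))
  lab <- label_truth(sc, truth, geno, expr)
  get <- function(g, v) lab$label[lab$gene_id == g & lab$variant_id == v]
  expect_equal(get("g2", "v2"), "TP")        # exactly at the anchor
  expect_equal(get("g2", "v3"), "TP")        # +2000 bp: window inclusive
  expect_equal(get("g2", "v4"), "FP")        # +2001 bp: outside
  expect_equal(get("g1", "v2"), "excluded-cis")  # variant at g1's own TSS
  expect_equal(get("g3", "v5"), "excluded-cis")  # within 5 Mb of g3
  expect_equal(get("g3", "v1"), "FP")

  # brute-force relabelling oracle on a larger random truth
  set.seed(81)
  tg <- 10; f <- 30
  adj <- matrix(0, tg, tg)
  adj[upper.tri(adj)] <- rbinom(sum(upper.tri(adj)), 1, 0.15)
  w2 <- adj * 0.5
  anchors <- sample(c(seq_len(f), rep(NA, 3)), tg)
  vf <- data.frame(gene = paste0("g", 1:tg), cis = 0, network = 0,
                   confounding = 0, noise = 1)
  truth2 <- network_truth(adj, w2, as.integer(anchors), matrix(0, 0, tg), vf)
  geno2 <- make_geno(n = 20, f = f, seed = 82, pos = sort(runif(f, 1, 1e8)))
  expr2 <- make_expr(n = 20, tg = tg, seed = 83, chrom = rep("1", tg),
                     tss = runif(tg, 1, 1e8))
  sc2 <- association_scan(matrix(runif(tg * f), tg, f), matrix(0, tg, f),
                          gene_ids = expr2$gene_ids,
                          variant_ids = geno2$variant_ids)
  lab2 <- label_truth(sc2, truth2, geno2, expr2)
  for (i in sample(nrow(lab2), 200)) {
    t <- match(lab2$gene_id[i], expr2$gene_ids)
    v <- match(lab2$variant_id[i], geno2$variant_ids)
    expected <- if (abs(geno2$pos[v] - expr2$tss[t]) <= 5e6) "excluded-cis"
    else {
      regs <- which(adj[, t] == 1)
      a <- anchors[regs]; a <- a[!is.na(a)]
      if (length(a) && any(abs(geno2$pos[v] - geno2$pos[a]) <= 2000)) "TP"
      else "FP"
    }
    expect_identical(lab2$label[i], expected)
  }
})

test_that("partial AUC behaves at its extremes and under transforms", {
  lab <- function(p, l) {
    d <- data.frame(gene_id = "g", variant_id = seq_along(p), pvalue = p,
                    label = l)
    class(d) <- c("labelled_associations", "data.frame")
    d
  }
  # perfect ranking
  r <- partial_auc(lab(c(1e-8, 1e-7, 0.5, 0.6, 0.7), c("TP", "TP", "FP", "FP", "FP")))
  expect_equal(r$power, 1)
  expect_equal(r$partial_auc_raw, 0.05)
  # inverted ranking
  r0 <- partial_auc(lab(c(0.9, 0.95, 0.1, 0.2, 0.3), c("TP", "TP", "FP", "FP", "FP")))
  expect_equal(r0$power, 0)
  # all p tied: block processing gives the chance level
  rt <- partial_auc(lab(rep(0.5, 40), rep(c("TP", "FP"), 20)))
  expect_equal(rt$power, 0.025, tolerance = 1e-12)
  # invariance under strictly monotone p transforms
  set.seed(84)
  p <- runif(200); l <- sample(c("TP", "FP"), 200, TRUE)
  expect_equal(partial_auc(lab(p, l))$power, partial_auc(lab(p^3, l))$power,
               tolerance = 1e-12)
  # undefined without both classes
  expect_error(partial_auc(lab(runif(5), rep("FP", 5))), "no true positives")
  expect_error(partial_auc(lab(runif(5), rep("TP", 5))), "no false positives")
})

test_that("random rankings score at the chance level on average", {
  set.seed(85)
  pw <- replicate(400, {
    p <- runif(1000)
    d <- data.frame(gene_id = "g", variant_id = seq_along(p), pvalue = p,
                    label = rep(c("TP", "FP"), 500))
    class(d) <- c("labelled_associations", "data.frame")
    partial_auc(d)$power
  })
  expect_lt(abs(mean(pw) - 0.025), 0.005)
})

test_that("hotspot tables honour thresholds and the trans window", {
  geno <- make_geno(n = 20, f = 4, seed = 86, pos = c(1e6, 3e7, 6e7, 9e7))
  expr <- make_expr(n = 20, tg = 3, seed = 87, chrom = rep("1", 3),
                    tss = c(1.5e6, 3.1e7, 8e7))
  P <- matrix(1, 3, 4)
  P[1, 3] <- 1e-9    # trans (59 Mb away)
  P[2, 2] <- 1e-9    # cis-like (1 Mb away): inside the 20 Mb window
  P[3, 3] <- 1e-9    # 20 Mb exactly: inside the inclusive window
  sc <- association_scan(P, P * 0, gene_ids = expr$gene_ids,
                         variant_ids = geno$variant_ids)
  ht <- hotspot_table(sc, geno, expr, significance_grid = c(1e-4, 1e-12),
                      trans_window_bp = 2e7)
  c4 <- ht$counts[ht$counts$threshold == 1e-4, ]
  expect_equal(c4$n_regulated[c4$variant_id == "v3"], 1L)  # only the 59 Mb hit
  expect_equal(c4$n_regulated[c4$variant_id == "v2"], 0L)
  expect_equal(ht$totals$n_trans[ht$totals$threshold == 1e-12], 0)
  # nothing significant: all-zero histogram
  ht0 <- hotspot_table(association_scan(matrix(1, 3, 4), matrix(0, 3, 4),
                                        gene_ids = expr$gene_ids,
                                        variant_ids = geno$variant_ids),
                       geno, expr, significance_grid = 1e-4)
  expect_equal(sum(ht0$counts$n_regulated), 0)
  expect_equal(nrow(ht0$histogram), 0L)
})

test_that("hub anchors dominate the hotspot ranking on star networks", {
  top9 <- vapply(1:20, function(s) {
    p <- sim_params(n_genes = 100L, n_variants = 200L, topology = "star",
                    conf_fraction = 0, n_confounders = 0L, spacing = 1e6)
    sim <- simulate_network(p, seed = 2000 + s)
    sc <- lmm_scan(sim$genotypes, sim$expression,
                   realized_relationship(sim$genotypes))
    # hub targets share the network budget among several hub parents, so
    # per-edge signal is modest; a 1e-3 threshold separates hubs cleanly
    ht <- hotspot_table(sc, sim$genotypes, sim$expression,
                        significance_grid = 1e-3, trans_window_bp = 2e6)
    cnt <- ht$counts
    hubs <- which(rowSums(sim$truth$adjacency) > 0)
    hub_snps <- sim$genotypes$variant_ids[sim$truth$cis_anchor[hubs]]
    top <- cnt$variant_id[order(-cnt$n_regulated)][1:9]
    mean(top %in% hub_snps)
  }, numeric(1))
  expect_gte(mean(top9), 0.8)
})

test_that("calibration summaries detect uniform and degenerate p-values", {
  set.seed(88)
  ok <- qq_calibration(runif(1000))
  expect_gt(ok$ks_pvalue, 0.01)
  expect_lt(abs(ok$fraction_below_0.05 - 0.05), 0.03)
  bad <- qq_calibration(rep(0.5, 500))
  expect_lt(bad$ks_pvalue, 1e-10)
  expect_error(qq_calibration(runif(50)), "at least 100")
})
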