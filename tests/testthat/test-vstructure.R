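test_that("correlation test matches its closed form and a permutation null", {
  set.seed(41)
  a <- rnorm(10)
  r <- correlation_test(a, a)
  expect_equal(r$r, 1)
  expect_lt(r$pvalue, 1e-12)
  # constructed orthogonal pair: t-statistic exactly zero
  b <- lm.fit(cbind(1, a), rnorm(10))$residuals
  r0 <- correlation_test(a, b)
  expect_equal(r0$r, 0, tolerance = 1e-12)
  expect_equal(r0$pvalue, 1, tolerance = 1e-12)
  expect_error(correlation_test(a, rep(2, 10)), "zero-variance")
  expect_error(correlation_test(a[1:3], a[1:3]), "at least 4")

  # agrees with the t-distribution reference implementation
  x <- rnorm(50); y <- 0.2 * x + rnorm(50)
  expect_equal(correlation_test(x, y)$pvalue, cor.test(x, y)$p.value,
               tolerance = 1e-12)

  # permutation oracle at N = 50
  set.seed(42)
  obs <- correlation_test(x, y)
  nperm <- 1e5
  perm <- vapply(seq_len(nperm),
                 function(i) abs(cor(x, y[sample.int(50)])), numeric(1))
  p_perm <- (sum(perm >= abs(obs$r)) + 1) / (nperm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(obs$pvalue - p_perm), 3 * se + 1e-4)
})

test_that("partial correlation matches formula and residual regression", {
  set.seed(43)
  n <- 200
  # collider: a and b independent, c = a + b + noise
  a <- rnorm(n); b <- rnorm(n); c <- a + b + rnorm(n)
  pc <- partial_correlation_test(a, b, c)
  r_ab <- cor(a, b); r_ac <- cor(a, c); r_bc <- cor(b, c)
  expect_equal(pc$r, (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2)),
               tolerance = 1e-10)
  expect_lt(pc$pvalue, 0.01)  # collider induces conditional dependence

  # residual-regression oracle over random triplets
  for (s in 1:5) {
    set.seed(400 + s)
    a <- rnorm(40); b <- rnorm(40) + 0.4 * a; c <- rnorm(40) + 0.3 * b
    ra <- lm.fit(cbind(1, c), a)$residuals
    rb <- lm.fit(cbind(1, c), b)$residuals
    expect_equal(partial_correlation_test(a, b, c)$r, cor(ra, rb),
                 tolerance = 1e-10)
  }
  expect_error(partial_correlation_test(a, c, c), "degenerate conditioning")
})

test_that("anchor gene discovery honours windows, families and strictness", {
  tg <- 3; f <- 2
  P <- matrix(1, tg, f)
  P[1, 1] <- 1e-6   # gene 1 near variant 1: cis anchor
  P[3, 2] <- 1e-6   # gene 3 far from variant 2: trans only
  sc <- association_scan(P, P * 0, gene_ids = paste0("g", 1:3),
                         variant_ids = paste0("v", 1:2))
  geno <- genotype_data(matrix(c(0, 1, 2, 0, 1, 1), 3, 2),
                        paste0("v", 1:2), c("1", "1"), c(1e6, 2e8))
  expr <- expression_data(matrix(rnorm(9), 3, 3), paste0("g", 1:3),
                          c("1", "1", "1"), c(1.5e6, 5e7, 1e8))
  cfg <- threshold_config("basic", cis_window = 1e6)
  a_cis <- find_anchor_genes(sc, geno, expr, cfg)
  expect_equal(nrow(a_cis), 1L)
  expect_equal(a_cis$gene_id, "g1")
  cfg_t <- threshold_config("basic", cis_window = 1e6, anchor_mode = "trans")
  a_trans <- find_anchor_genes(sc, geno, expr, cfg_t)
  expect_setequal(a_trans$gene_id, c("g1", "g3"))

  # Bonferroni family T x F and strict inequality at the threshold
  P2 <- matrix(1, tg, f)
  P2[1, 1] <- 0.05 / (tg * f)          # adjusted p exactly at threshold
  sc2 <- association_scan(P2, P2 * 0, gene_ids = paste0("g", 1:3),
                          variant_ids = paste0("v", 1:2))
  cfg_d <- threshold_config("default", cis_window = 1e6)
  expect_equal(nrow(find_anchor_genes(sc2, geno, expr, cfg_d)), 0L)
  P2[1, 1] <- 0.05 / (tg * f) * 0.99   # just below
  sc3 <- association_scan(P2, P2 * 0, gene_ids = paste0("g", 1:3),
                          variant_ids = paste0("v", 1:2))
  expect_equal(nrow(find_anchor_genes(sc3, geno, expr, cfg_d)), 1L)
})

test_that("V-structures are recovered on the power motif and self-consistent", {
  found <- 0L
  for (s in 1:10) {
    sim <- simulate_basic("power", n = 379, f = 60, seed = 100 + s)
    K <- realized_relationship(sim$genotypes)
    sc <- lmm_scan(sim$genotypes, sim$expression, K)
    cfg <- threshold_config("basic")
    an <- find_anchor_genes(sc, sim$genotypes, sim$expression, cfg)
    vs <- find_vstructures(an, sc, sim$expression, sim$genotypes, cfg)
    if (nrow(vs) == 0L) next
    found <- found + 1L
    Y <- sim$expression$values
    n <- nrow(Y)
    for (i in seq_len(nrow(vs))) {
      a <- vs$anchor_index[i]; cc <- vs$focal_index[i]; b <- vs$exo_index[i]
      expect_true(length(unique(c(a, cc, b))) == 3L)
      expect_lt(correlation_test(Y[, a], Y[, cc])$pvalue, cfg$p_dep)
      expect_lt(correlation_test(Y[, b], Y[, cc])$pvalue, cfg$p_dep)
      expect_gte(correlation_test(Y[, a], Y[, b])$pvalue, cfg$p_ind)
      expect_lt(partial_correlation_test(Y[, a], Y[, b], Y[, cc])$pvalue,
                cfg$p_dep)
      expect_gte(sc$pvalues[b, vs$snp_index[i]], cfg$p_snp_ind)
      expect_lt(sc$pvalues[a, vs$snp_index[i]] , cfg$p_anchor)
    }
    # the recovered structure is the planted one: A -> C <- B
    expect_true(any(vs$anchor_gene == "geneA" & vs$focal_gene == "geneC" &
                      vs$exo_gene == "geneB"))
  }
  expect_gte(found, 3L)  # detection is stochastic at these thresholds
})

test_that("lazy partial-correlation evaluation equals exhaustive search", {
  set.seed(44)
  sim <- simulate_basic("power", n = 379, f = 40, seed = 103)
  K <- realized_relationship(sim$genotypes)
  sc <- lmm_scan(sim$genotypes, sim$expression, K)
  cfg <- threshold_config("basic")
  an <- find_anchor_genes(sc, sim$genotypes, sim$expression, cfg)
  vs <- find_vstructures(an, sc, sim$expression, sim$genotypes, cfg)

  # exhaustive re-implementation: loop over all quartets, no shortcuts
  Y <- sim$expression$values
  tg <- ncol(Y)
  rows <- list()
  for (k in seq_len(nrow(an))) {
    s <- an$snp_index[k]; a <- an$gene_index[k]
    for (cc in seq_len(tg)) {
      if (cc == a) next
      if (sim$expression$chrom[cc] == sim$genotypes$chrom[s] &&
          abs(sim$expression$tss[cc] - sim$genotypes$pos[s]) <= cfg$cis_window)
        next
      for (b in seq_len(tg)) {
        if (b %in% c(a, cc)) next
        ok <- correlation_test(Y[, a], Y[, cc])$pvalue < cfg$p_dep &&
          correlation_test(Y[, b], Y[, cc])$pvalue < cfg$p_dep &&
          correlation_test(Y[, a], Y[, b])$pvalue >= cfg$p_ind &&
          sc$pvalues[b, s] >= cfg$p_snp_ind &&
          partial_correlation_test(Y[, a], Y[, b], Y[, cc])$pvalue < cfg$p_dep
        if (ok) rows[[length(rows) + 1L]] <- c(s, a, cc, b)
      }
    }
  }
  exhaustive <- if (length(rows)) do.call(rbind, rows) else
    matrix(integer(), 0, 4)
  got <- as.matrix(vs[, c("snp_index", "anchor_index", "focal_index",
                          "exo_index")])
  dimnames(got) <- NULL
  expect_equal(got[order(got[, 1], got[, 2], got[, 3], got[, 4]), , drop = FALSE],
               exhaustive[order(exhaustive[, 1], exhaustive[, 2],
                                exhaustive[, 3], exhaustive[, 4]), , drop = FALSE])
})

test_that("no V-structure is emitted when gene B shares the SNP (guard)", {
  blocked <- vapply(1:20, function(s) {
    sim <- simulate_basic("confounding", n = 379, f = 60, b_associated = TRUE,
                          seed = 200 + s)
    K <- realized_relationship(sim$genotypes)
    sc <- lmm_scan(sim$genotypes, sim$expression, K)
    cfg <- threshold_config("basic")
    an <- find_anchor_genes(sc, sim$genotypes, sim$expression, cfg)
    vs <- find_vstructures(an, sc, sim$expression, sim$genotypes, cfg)
    !any(vs$exo_gene == "geneB" & vs$focal_gene == "geneC")
  }, logical(1))
  expect_true(all(blocked))
})

test_that("one dominant factor suppresses V-structure discovery", {
  set.seed(45)
  n <- 379
  geno <- simulate_genotypes(n, 40)
  factor1 <- rnorm(n)
  Y <- vapply(1:5, function(i) {
    netlmm:::scale_to_share(factor1, 0.8) + netlmm:::scale_to_share(rnorm(n), 0.2)
  }, numeric(n))
  # make gene 1 a genuine cis anchor of variant 1 on top of the factor
  Y[, 1] <- netlmm:::scale_to_share(geno$dosages[, 1], 0.15) +
    netlmm:::scale_to_share(factor1, 0.65) +
    netlmm:::scale_to_share(rnorm(n), 0.2)
  expr <- expression_data(Y, paste0("g", 1:5), chrom = c("1", rep("2", 4)),
                          tss = c(geno$pos[1], 1e6 * (1:4)))
  K <- realized_relationship(geno)
  sc <- lmm_scan(geno, expr, K)
  cfg <- threshold_config("basic")
  an <- find_anchor_genes(sc, geno, expr, cfg)
  vs <- find_vstructures(an, sc, expr, geno, cfg)
  expect_gte(nrow(an), 1L)         # the anchor exists
  expect_equal(nrow(vs), 0L)       # but all genes are pairwise dependent
})

test_that("stricter thresholds never add V-structures", {
  sim <- simulate_basic("power", n = 379, f = 60, seed = 104)
  K <- realized_relationship(sim$genotypes)
  sc <- lmm_scan(sim$genotypes, sim$expression, K)
  key <- function(vs) paste(vs$snp_index, vs$anchor_index, vs$focal_index,
                            vs$exo_index)
  base <- threshold_config("basic", p_dep = 0.01)
  loose <- find_vstructures(find_anchor_genes(sc, sim$genotypes,
                                              sim$expression, base),
                            sc, sim$expression, sim$genotypes, base)
  for (cfg in list(threshold_config("basic", p_dep = 0.001),
                   threshold_config("basic", p_dep = 0.01, p_ind = 0.3))) {
    strict <- find_vstructures(find_anchor_genes(sc, sim$genotypes,
                                                 sim$expression, cfg),
                               sc, sim$expression, sim$genotypes, cfg)
    expect_true(all(key(strict) %in% key(loose)))
  }
})

test_that("V-structures are rare when only the anchor is real", {
  # one genuine cis anchor; all other genes mutually independent
  rates <- vapply(1:25, function(s) {
    set.seed(500 + s)
    n <- 379
    geno <- simulate_genotypes(n, 30)
    tg <- 8
    Y <- matrix(rnorm(n * tg), n, tg)
    Y[, 1] <- netlmm:::scale_to_share(geno$dosages[, 1], 0.2) +
      netlmm:::scale_to_share(rnorm(n), 0.8)
    expr <- expression_data(Y, paste0("g", seq_len(tg)),
                            chrom = c("1", rep("2", tg - 1)),
                            tss = c(geno$pos[1], 1e6 * seq_len(tg - 1)))
    sc <- lmm_scan(geno, expr, realized_relationship(geno))
    cfg <- threshold_config("basic")
    an <- find_anchor_genes(sc, geno, expr, cfg)
    vs <- find_vstructures(an, sc, expr, geno, cfg)
    n_triplets <- max(1, nrow(an) * (tg - 1) * (tg - 2))
    nrow(vs) / n_triplets
  }, numeric(1))
  expect_lte(mean(rates), 0.01)
})

test_that("conditioning sets deduplicate and order by partial-correlation p", {
  empty <- build_conditioning_sets(
    find_vstructures(data.frame(snp_index = integer(), gene_index = integer()),
                     association_scan(matrix(1, 2, 2), matrix(0, 2, 2),
                                      gene_ids = c("a", "b"),
                                      variant_ids = c("v1", "v2")),
                     make_expr(tg = 2), make_geno(f = 2)))
  expect_length(empty$sets, 0L)

  vs <- data.frame(snp_index = c(1L, 1L, 1L), anchor_index = c(2L, 3L, 2L),
                   focal_index = c(4L, 4L, 4L), exo_index = c(5L, 5L, 6L),
                   p_partial = c(0.002, 0.001, 0.0005))
  class(vs) <- c("vstructure_set", "data.frame")
  cs <- build_conditioning_sets(vs)
  expect_length(cs$sets, 1L)
  # gene 6 has the smallest partial p, gene 5 deduplicated
  expect_identical(cs$sets[[1]], c(6L, 5L))
})
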