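# Simulation framework: synthetic genotype panels, small regulatory motifs,
# and 100-gene sparse / star-shaped networks with confounding. Expression is
# assembled in topological order as a linear function of incoming edges, the
# cis SNP, confounder factors and iid noise; every component vector is
# rescaled so its empirical (1/N) variance hits the sampled variance share
# exactly, and the realized shares are recorded in the ground-truth table.

#' Simulation parameter set
#'
#' Defaults reproduce the study conditions of the benchmark designs: 379
#' samples, 4030 quasi-independent common variants (MAF >= 0.05), 100-gene
#' networks, cis share 0.10, combined network+confounding share 0.80 of
#' which a 0.2 fraction is confounding, 3 confounders with on average 1 per
#' gene, and edge weights from an equal mixture of N(+1, 0.1^2) and
#' N(-1, 0.1^2).
#'
#' @param n_samples,n_variants panel dimensions.
#' @param n_genes genes in the network designs.
#' @param topology `"sparse"` or `"star"`.
#' @param var_cis variance share of each gene's cis variant.
#' @param var_network combined variance share of incoming edges and
#'   confounding.
#' @param conf_fraction fraction of `var_network` due to confounding.
#' @param n_confounders number of confounding factors.
#' @param conf_per_gene expected confounders affecting any one gene.
#' @param alpha SNP-variance split for the direct/trans basic motifs.
#' @param p_edge sparse-topology edge probability per ordered gene pair.
#' @param n_hubs hub count for the star topology.
#' @param hub_frac range of the fraction of other genes each hub regulates.
#' @param maf_range minor allele frequency range of simulated variants.
#' @param spacing base-pair spacing between consecutive variants.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_samples = 379L, n_variants = 4030L, n_genes = 100L,
                       topology = c("sparse", "star"), var_cis = 0.10,
                       var_network = 0.80, conf_fraction = 0.2,
                       n_confounders = 3L, conf_per_gene = 1,
                       alpha = 0.5, p_edge = 0.02, n_hubs = 9L,
                       hub_frac = c(0.2, 0.5), maf_range = c(0.05, 0.5),
                       spacing = 1e5) {
  p <- list(n_samples = n_samples, n_variants = n_variants, n_genes = n_genes,
            topology = match.arg(topology), var_cis = var_cis,
            var_network = var_network, conf_fraction = conf_fraction,
            n_confounders = n_confounders, conf_per_gene = conf_per_gene,
            alpha = alpha, p_edge = p_edge, n_hubs = n_hubs,
            hub_frac = hub_frac, maf_range = maf_range, spacing = spacing)
  if (var_cis + var_network > 1) stop("variance budget exceeds 1")
  class(p) <- "sim_params"
  p
}

#' Ground-truth container for simulated data
#'
#' @param adjacency T x T directed acyclic 0/1 matrix (`adjacency[j, t] = 1`
#'   means gene j regulates gene t).
#' @param weights T x T relative edge weights (nonzero exactly on edges).
#' @param cis_anchor integer vector: the cis variant index of each gene
#'   (`NA` for genes without a cis effect).
#' @param confounder_loadings C x T loading matrix.
#' @param variance_fractions data.frame of realized per-gene shares
#'   (`cis`, `network`, `confounding`, `noise`).
#' @param confounders N x C matrix of confounder factor values.
#' @export
network_truth <- function(adjacency, weights, cis_anchor, confounder_loadings,
                          variance_fractions, confounders = NULL) {
  adjacency <- as.matrix(adjacency)
  if (any((weights != 0) != (adjacency == 1)))
    stop("weights must be nonzero exactly on adjacency edges")
  if (.has_cycle(adjacency)) stop("adjacency must be acyclic")
  vf <- variance_fractions
  if (any(vf$cis + vf$network + vf$confounding > 1 + 1e-8))
    stop("variance fractions exceed 1")
  structure(list(adjacency = adjacency, weights = weights,
                 cis_anchor = cis_anchor,
                 confounder_loadings = confounder_loadings,
                 variance_fractions = variance_fractions,
                 confounders = confounders),
            class = "network_truth")
}

# Kahn-style cycle check.
.has_cycle <- function(adj) {
  indeg <- colSums(adj)
  active <- rep(TRUE, ncol(adj))
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (s in src) {
      indeg <- indeg - adj[s, ]
      active[s] <- FALSE
    }
  }
  any(active)
}

#' @export
print.network_truth <- function(x, ...) {
  cat(sprintf("network_truth: %d genes, %d edges, %d confounder(s)\n",
              ncol(x$adjacency), sum(x$adjacency),
              if (is.null(x$confounders)) 0L else ncol(x$confounders)))
  invisible(x)
}

# Centre a vector and rescale its empirical (1/N) variance to `share`.
scale_to_share <- function(v, share) {
  v <- v - mean(v)
  s2 <- mean(v^2)
  if (s2 == 0) stop("cannot scale a constant component")
  v * sqrt(share / s2)
}

#' Simulate an independent-variant genotype panel
#'
#' Dosages are Binomial(2, maf) with maf ~ Uniform(`maf_range`); variants sit
#' at fixed spacing on one synthetic chromosome.
#'
#' @param n samples; `f` variants.
#' @param f number of variants.
#' @param maf_range subset of `[0.05, 0.5]`.
#' @param seed optional integer seed.
#' @param spacing base pairs between consecutive variants.
#' @param chrom chromosome label.
#' @export
simulate_genotypes <- function(n, f, maf_range = c(0.05, 0.5), seed = NULL,
                               spacing = 1e5, chrom = "1") {
  if (!is.null(seed)) set.seed(seed)
  if (maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within [0.05, 0.5]")
  maf <- stats::runif(f, maf_range[1], maf_range[2])
  D <- vapply(maf, function(m) stats::rbinom(n, 2, m), numeric(n))
  genotype_data(D, variant_ids = sprintf("snp%04d", seq_len(f)),
                chrom = rep(chrom, f), pos = spacing * seq_len(f))
}

# Draw an edge weight from the +-1 mixture prior (sd 0.1 per component).
.mixture_weights <- function(k) {
  sign <- ifelse(stats::runif(k) < 0.5, 1, -1)
  stats::rnorm(k, mean = sign, sd = 0.1)
}

#' Simulate a basic regulatory motif
#'
#' Four small designs used to characterize power and calibration:
#' \describe{
#'   \item{power}{SNP A -> gene A; gene A, gene B -> gene C; gene C -> gene D.
#'     The cis anchor explains 10--20\% of gene A's variance and each
#'     regulating edge 10--20\% of its target's variance.}
#'   \item{direct}{SNP A -> gene A and (directly) gene C, with `alpha`
#'     splitting the SNP variance between the two targets; gene A,
#'     gene B -> gene C.}
#'   \item{trans}{SNP A -> gene A and gene D; gene A, gene B,
#'     gene D -> gene C, with `alpha` splitting the SNP variance between
#'     genes A and D.}
#'   \item{confounding}{SNP A -> gene A (and gene B when
#'     `b_associated = TRUE`, the synthetic-association guard design);
#'     confounder A -> genes A, C; confounder B -> genes B, C; confounders
#'     jointly explain 50--70\% of each affected gene. There is no causal
#'     SNP A -> gene C path, so the focal association is null.}
#' }
#' Genes other than gene A sit on a second chromosome, so the focal
#' association is trans; decoy variants are spaced 10 Mb apart so only the
#' causal variant falls in the true-positive window.
#'
#' @param motif one of `"power"`, `"direct"`, `"trans"`, `"confounding"`.
#' @param n samples.
#' @param f total variants (SNP A plus `f - 1` decoys).
#' @param cis_range,edge_range,conf_range variance-share ranges.
#' @param alpha SNP-variance split for the direct/trans motifs.
#' @param b_associated guard design flag (confounding motif only).
#' @param maf_range variant frequency range.
#' @param seed optional integer seed.
#' @return list(genotypes, expression, truth).
#' @export
simulate_basic <- function(motif = c("power", "direct", "trans", "confounding"),
                           n = 379L, f = 50L,
                           cis_range = c(0.1, 0.2), edge_range = c(0.1, 0.2),
                           conf_range = c(0.5, 0.7), alpha = 0.5,
                           b_associated = FALSE, maf_range = c(0.05, 0.5),
                           seed = NULL) {
  motif <- match.arg(motif)
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_genotypes(n, f, maf_range, spacing = 1e7)
  xA <- scale_to_share(geno$dosages[, 1], 1)
  noise <- function() stats::rnorm(n)
  u <- function(r) stats::runif(1, r[1], r[2])
  sgn <- function() if (stats::runif(1) < 0.5) 1 else -1

  genes <- if (motif == "confounding") c("A", "B", "C") else c("A", "B", "C", "D")
  tg <- length(genes)
  adj <- matrix(0, tg, tg, dimnames = list(genes, genes))
  wts <- adj
  anchor <- rep(NA_integer_, tg)
  vf <- data.frame(gene = genes, cis = 0, network = 0, confounding = 0, noise = 0)
  Y <- matrix(0, n, tg, dimnames = list(NULL, genes))
  confs <- NULL
  load <- matrix(0, 0, tg)

  add_edge <- function(j, t, share) {
    w <- sgn()
    adj[j, t] <<- 1; wts[j, t] <<- w
    vf$network[t] <<- vf$network[t] + share
    scale_to_share(w * Y[, j], share)
  }

  if (motif %in% c("power", "direct", "trans")) {
    s_cis <- u(cis_range)
    split_a <- if (motif == "power") 1 else alpha
    # gene A: cis effect plus noise
    anchor[1] <- 1L
    vf$cis[1] <- s_cis * split_a
    vf$noise[1] <- 1 - vf$cis[1]
    Y[, 1] <- scale_to_share(xA, vf$cis[1]) +
      scale_to_share(noise(), vf$noise[1])
    # gene B: exogenous noise
    vf$noise[2] <- 1
    Y[, 2] <- scale_to_share(noise(), 1)
    # gene D first in the trans motif (it feeds gene C there)
    if (motif == "trans") {
      anchor[4] <- 1L
      vf$cis[4] <- s_cis * (1 - alpha)
      vf$noise[4] <- 1 - vf$cis[4]
      Y[, 4] <- scale_to_share(xA, vf$cis[4]) +
        scale_to_share(noise(), vf$noise[4])
    }
    # gene C: incoming edges (+ direct cis effect in the direct motif)
    comps_c <- add_edge(1, 3, u(edge_range)) + add_edge(2, 3, u(edge_range))
    if (motif == "direct") {
      anchor[3] <- 1L
      vf$cis[3] <- s_cis * (1 - alpha)
      comps_c <- comps_c + scale_to_share(xA, vf$cis[3])
    }
    if (motif == "trans") comps_c <- comps_c + add_edge(4, 3, u(edge_range))
    vf$noise[3] <- 1 - vf$cis[3] - vf$network[3]
    Y[, 3] <- comps_c + scale_to_share(noise(), vf$noise[3])
    # downstream gene D in the power motif; pure noise in the direct motif
    if (motif == "power") {
      comps_d <- add_edge(3, 4, u(edge_range))
      vf$noise[4] <- 1 - vf$network[4]
      Y[, 4] <- comps_d + scale_to_share(noise(), vf$noise[4])
    } else if (motif == "direct") {
      vf$noise[4] <- 1
      Y[, 4] <- scale_to_share(noise(), 1)
    }
  } else {                                         # confounding motif
    confs <- cbind(confA = noise(), confB = noise())
    load <- matrix(0, 2, tg, dimnames = list(c("confA", "confB"), genes))
    s_cis <- u(cis_range)
    anchor[1] <- 1L
    vf$cis[1] <- s_cis
    sA <- u(conf_range)                            # gene A: confA only
    load[1, 1] <- sgn()
    vf$confounding[1] <- sA
    Y[, 1] <- scale_to_share(xA, s_cis) +
      scale_to_share(load[1, 1] * confs[, 1], sA)
    vf$noise[1] <- 1 - vf$cis[1] - sA
    Y[, 1] <- Y[, 1] + scale_to_share(noise(), vf$noise[1])

    sB <- u(conf_range)                            # gene B: confB (+ SNP A?)
    load[2, 2] <- sgn()
    vf$confounding[2] <- sB
    Y[, 2] <- scale_to_share(load[2, 2] * confs[, 2], sB)
    if (b_associated) {
      s_cisB <- u(cis_range)
      anchor[2] <- 1L
      vf$cis[2] <- s_cisB
      Y[, 2] <- Y[, 2] + scale_to_share(xA, s_cisB)
    }
    vf$noise[2] <- 1 - vf$cis[2] - sB
    Y[, 2] <- Y[, 2] + scale_to_share(noise(), vf$noise[2])

    sC <- u(conf_range)                            # gene C: both confounders
    load[1, 3] <- sgn(); load[2, 3] <- sgn()
    vf$confounding[3] <- sC
    Y[, 3] <- scale_to_share(load[1, 3] * confs[, 1], sC / 2) +
      scale_to_share(load[2, 3] * confs[, 2], sC / 2)
    vf$noise[3] <- 1 - sC
    Y[, 3] <- Y[, 3] + scale_to_share(noise(), vf$noise[3])
  }

  expr <- expression_data(
    Y, gene_ids = paste0("gene", genes),
    chrom = c("1", rep("2", tg - 1L)),
    tss = c(geno$pos[1], 1e6 * c(1, 50, 90)[seq_len(tg - 1L)]))
  truth <- network_truth(adj, wts, anchor, load, vf, confounders = confs)
  list(genotypes = geno, expression = expr, truth = truth)
}

#' Simulate a 100-gene regulatory network dataset
#'
#' Sparse topology: a random topological order with each admissible edge
#' drawn Bernoulli(`p_edge`). Star topology: `n_hubs` hub genes, each
#' regulating a Uniform(`hub_frac`) fraction of the remaining genes. Every
#' gene receives a distinct cis variant explaining `var_cis` of its
#' variance; incoming edges and confounders jointly explain `var_network`,
#' apportioned by `conf_fraction`; iid noise fills the budget. Gene TSS
#' coordinates equal their cis-variant positions.
#'
#' @param params a [sim_params()] list.
#' @param seed optional integer seed.
#' @return list(genotypes, expression, truth).
#' @export
simulate_network <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_samples; tg <- params$n_genes
  f <- params$n_variants
  if (f < tg) stop("need at least as many variants as genes")
  geno <- simulate_genotypes(n, f, params$maf_range, spacing = params$spacing)
  anchor <- sample.int(f, tg)

  # topology
  adj <- matrix(0, tg, tg)
  if (params$topology == "sparse") {
    ord <- sample.int(tg)
    for (i in seq_len(tg - 1L)) {
      js <- ord[seq_len(i)]
      t <- ord[i + 1L]
      draw <- stats::runif(i) < params$p_edge
      adj[js[draw], t] <- 1
    }
  } else {
    hubs <- sample.int(tg, params$n_hubs)
    nonhub <- setdiff(seq_len(tg), hubs)
    kmin <- ceiling(params$hub_frac[1] * (tg - 1L))
    kmax <- floor(params$hub_frac[2] * (tg - 1L))
    for (h in hubs) {
      k <- min(max(round(stats::runif(1, params$hub_frac[1], params$hub_frac[2]) *
                           (tg - 1L)), kmin), min(kmax, length(nonhub)))
      adj[h, sample(nonhub, k)] <- 1
    }
    ord <- c(hubs, nonhub)
  }
  wts <- matrix(0, tg, tg)
  ne <- sum(adj)
  wts[adj == 1] <- .mixture_weights(ne)

  # confounders
  use_conf <- params$conf_fraction > 0 && params$n_confounders > 0
  if (use_conf) {
    C <- params$n_confounders
    confs <- matrix(stats::rnorm(n * C), n, C)
    member <- matrix(stats::runif(C * tg) < min(params$conf_per_gene / C, 1), C, tg)
    load <- matrix(0, C, tg)
    load[member] <- stats::rnorm(sum(member))
  } else {
    confs <- NULL
    load <- matrix(0, 0, tg)
  }

  vf <- data.frame(gene = sprintf("gene%03d", seq_len(tg)),
                   cis = 0, network = 0, confounding = 0, noise = 0)
  Y <- matrix(0, n, tg)
  Xstd <- apply(geno$dosages[, anchor, drop = FALSE], 2,
                function(x) x - mean(x))
  net_share <- params$var_network * (1 - params$conf_fraction)
  conf_share <- params$var_network * params$conf_fraction
  for (t in ord) {
    comp <- numeric(n)
    if (stats::var(Xstd[, t]) > 0 && params$var_cis > 0) {
      vf$cis[t] <- params$var_cis
      comp <- comp + scale_to_share(Xstd[, t], params$var_cis)
    }
    parents <- which(adj[, t] == 1)
    if (length(parents) && net_share > 0) {
      raw <- Y[, parents, drop = FALSE] %*% wts[parents, t]
      if (stats::var(drop(raw)) > 0) {
        vf$network[t] <- net_share
        comp <- comp + scale_to_share(drop(raw), net_share)
      }
    }
    if (use_conf && conf_share > 0 && any(load[, t] != 0)) {
      raw <- drop(confs %*% load[, t])
      vf$confounding[t] <- conf_share
      comp <- comp + scale_to_share(raw, conf_share)
    }
    vf$noise[t] <- 1 - vf$cis[t] - vf$network[t] - vf$confounding[t]
    Y[, t] <- comp + scale_to_share(stats::rnorm(n), vf$noise[t])
  }

  expr <- expression_data(Y, gene_ids = vf$gene,
                          chrom = geno$chrom[anchor], tss = geno$pos[anchor])
  truth <- network_truth(adj, wts, anchor, load, vf, confounders = confs)
  list(genotypes = geno, expression = expr, truth = truth)
}
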