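# Readers and writers. Matrix TSVs follow the convention: first column holds
# the variant/gene identifier, the header holds sample identifiers (one row
# per variant/gene). Annotation TSVs: id, chrom, pos (genotypes) or id,
# chrom, tss (expression). Coordinates are 1-based; all windows are
# inclusive of both endpoints. Numeric columns are serialized with 17
# significant digits so write/read round-trips are exact.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_matrix_tsv <- function(mat, ids, id_col, path) {
  tm <- t(mat)  # features x samples
  chm <- matrix(.fmt_num(tm), nrow = nrow(tm), ncol = ncol(tm))
  df <- data.frame(ids, chm, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c(id_col, rownames(mat) %||% paste0("s", seq_len(nrow(mat))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- t(as.matrix(df[, -1, drop = FALSE]))  # samples x features
  storage.mode(m) <- "double"
  rownames(m) <- colnames(df)[-1]
  colnames(m) <- ids
  list(ids = ids, matrix = m, samples = colnames(df)[-1])
}

#' Read genotypes
#'
#' @param path matrix TSV (rows = variants, header = sample ids) or a PLINK
#'   prefix when `format = "plink-bed"`.
#' @param anno_path annotation TSV with columns `id`, `chrom`, `pos`
#'   (required for TSV input; ignored for PLINK, where the BIM supplies it).
#' @param format `"tsv"` or `"plink-bed"`.
#' @return [genotype_data].
#' @export
read_genotypes <- function(path, anno_path = NULL, format = c("tsv", "plink-bed")) {
  format <- match.arg(format)
  if (format == "plink-bed") return(read_plink(path))
  m <- .read_matrix_tsv(path)
  vals <- m$matrix[!is.na(m$matrix)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("genotype TSV contains values outside {0, 1, 2, NA}")
  if (is.null(anno_path)) stop("anno_path is required for TSV genotypes")
  anno <- utils::read.table(anno_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  i <- match(m$ids, anno$id)
  if (anyNA(i)) stop("variant annotation missing for: ",
                     paste(utils::head(m$ids[is.na(i)]), collapse = ", "))
  genotype_data(m$matrix, variant_ids = m$ids,
                chrom = anno$chrom[i], pos = anno$pos[i])
}

#' Write genotypes (TSV matrix + annotation)
#' @param genotypes [genotype_data].
#' @param path,anno_path output file paths.
#' @export
write_genotypes <- function(genotypes, path, anno_path) {
  m <- genotypes$dosages
  rownames(m) <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  .write_matrix_tsv(m, genotypes$variant_ids, "variant_id", path)
  utils::write.table(
    data.frame(id = genotypes$variant_ids, chrom = genotypes$chrom,
               pos = .fmt_num(genotypes$pos)),
    anno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read expression
#'
#' Genes present in the matrix but absent from the annotation are dropped
#' with a message; duplicated gene ids are an error.
#'
#' @param path matrix TSV (rows = genes, header = sample ids).
#' @param anno_path annotation TSV with columns `id`, `chrom`, `tss`.
#' @return [expression_data].
#' @export
read_expression <- function(path, anno_path) {
  m <- .read_matrix_tsv(path)
  if (anyDuplicated(m$ids)) stop("duplicated gene ids in expression matrix")
  anno <- utils::read.table(anno_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  i <- match(m$ids, anno$id)
  if (anyNA(i)) {
    message(sprintf("dropping %d gene(s) lacking annotation", sum(is.na(i))))
    keep <- !is.na(i)
    m$matrix <- m$matrix[, keep, drop = FALSE]
    m$ids <- m$ids[keep]
    i <- i[keep]
  }
  expression_data(m$matrix, gene_ids = m$ids,
                  chrom = anno$chrom[i], tss = anno$tss[i])
}

#' Write expression (TSV matrix + annotation)
#' @param expression [expression_data].
#' @param path,anno_path output file paths.
#' @export
write_expression <- function(expression, path, anno_path) {
  m <- expression$values
  rownames(m) <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  .write_matrix_tsv(m, expression$gene_ids, "gene_id", path)
  utils::write.table(
    data.frame(id = expression$gene_ids, chrom = expression$chrom,
               tss = .fmt_num(expression$tss)),
    anno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- PLINK BED/BIM/FAM ------------------------------------------------------
# SNP-major BED: magic bytes 0x6c 0x1b 0x01, then ceiling(N/4) bytes per
# variant, two bits per sample: 00 = two copies of allele 1 (dosage 2),
# 10 = heterozygous (1), 11 = zero copies (0), 01 = missing. Allele 1 of the
# BIM is taken as the counted (minor) allele.

#' Read a PLINK BED/BIM/FAM fileset
#' @param prefix path prefix (`prefix.bed`, `prefix.bim`, `prefix.fam`).
#' @return [genotype_data] with dosages counting BIM allele 1.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimdf <- utils::read.table(bim, stringsAsFactors = FALSE)
  famdf <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famdf); f_ <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed BED magic bytes")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major BED files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * f_) stop("BED size does not match BIM/FAM dimensions")
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = f_)
  # decode the four 2-bit fields of every byte
  lut <- c(2, NA, 1, 0)  # 00, 01, 10, 11
  D <- matrix(NA_real_, n, f_)
  for (shift in 0:3) {
    idx <- shift + 1L + 4L * (seq_len(bpv) - 1L)
    keep <- idx <= n
    if (!any(keep)) next
    code <- bitwAnd(bitwShiftR(body[keep, , drop = FALSE], 2L * shift), 3L)
    D[idx[keep], ] <- lut[code + 1L]
  }
  rownames(D) <- as.character(famdf[[2]])
  genotype_data(D, variant_ids = as.character(bimdf[[2]]),
                chrom = as.character(bimdf[[1]]), pos = as.numeric(bimdf[[4]]))
}

#' Write a PLINK BED/BIM/FAM fileset
#' @param genotypes [genotype_data].
#' @param prefix output path prefix.
#' @export
write_plink <- function(genotypes, prefix) {
  D <- genotypes$dosages
  n <- nrow(D); f_ <- ncol(D)
  fam <- data.frame(fid = seq_len(n),
                    iid = rownames(D) %||% paste0("s", seq_len(n)),
                    pat = 0, mat = 0, sex = 0, phen = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = genotypes$chrom, id = genotypes$variant_ids,
                    cm = 0, pos = .fmt_num(genotypes$pos), a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- matrix(1L, n, f_)           # 01 = missing
  code[!is.na(D) & D == 2] <- 0L      # 00
  code[!is.na(D) & D == 1] <- 2L      # 10
  code[!is.na(D) & D == 0] <- 3L      # 11
  bpv <- ceiling(n / 4)
  pad <- matrix(3L, 4 * bpv - n, f_)  # pad with hom allele-2 bits (ignored)
  code <- rbind(code, pad)
  bytes <- raw(bpv * f_)
  for (shift in 0:3) {
    rows <- shift + 1L + 4L * (seq_len(bpv) - 1L)
    bytes <- as.raw(bitwOr(as.integer(bytes),
                           bitwShiftL(as.vector(code[rows, , drop = FALSE]),
                                      2L * shift)))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

# ---- association scan serialization ----------------------------------------

#' Write an association scan as long-format TSV
#'
#' Columns: `gene_id`, `variant_id`, `beta`, `pvalue`, `n_conditioned`.
#' @param scan [association_scan].
#' @param path output file.
#' @export
write_scan <- function(scan, path) {
  tg <- length(scan$gene_ids); f <- length(scan$variant_ids)
  df <- data.frame(gene_id = rep(scan$gene_ids, times = f),
                   variant_id = rep(scan$variant_ids, each = tg),
                   beta = .fmt_num(as.vector(scan$betas)),
                   pvalue = .fmt_num(as.vector(scan$pvalues)),
                   n_conditioned = as.vector(scan$n_conditioned),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association scan written by [write_scan()]
#' @param path long-format TSV.
#' @return [association_scan].
#' @export
read_scan <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_ids <- unique(df$gene_id); variant_ids <- unique(df$variant_id)
  tg <- length(gene_ids); f <- length(variant_ids)
  gi <- match(df$gene_id, gene_ids); vi <- match(df$variant_id, variant_ids)
  P <- matrix(NA_real_, tg, f, dimnames = list(gene_ids, variant_ids))
  B <- P
  NC <- matrix(0L, tg, f)
  P[cbind(gi, vi)] <- df$pvalue
  B[cbind(gi, vi)] <- df$beta
  NC[cbind(gi, vi)] <- df$n_conditioned
  association_scan(P, B, gene_ids = gene_ids, variant_ids = variant_ids,
                   n_conditioned = NC)
}

#' Write a V-structure set as TSV
#' @param vstructures `vstructure_set`.
#' @param path output file.
#' @export
write_vstructures <- function(vstructures, path) {
  df <- as.data.frame(vstructures)
  for (cl in c("r_ac", "r_bc", "r_ab", "r_ab_c", "p_partial"))
    df[[cl]] <- .fmt_num(df[[cl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a V-structure set written by [write_vstructures()]
#' @param path TSV file.
#' @export
read_vstructures <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(snp_id = "character",
                                         anchor_gene = "character",
                                         focal_gene = "character",
                                         exo_gene = "character"))
  class(df) <- c("vstructure_set", "data.frame")
  df
}

# ---- preprocessing utilities -----------------------------------------------

#' Quantile-normalize to a standard normal
#'
#' Maps ranks (ties averaged) to normal quantiles via
#' `qnorm((rank - 0.5) / n)`.
#'
#' @param y numeric vector, length >= 2, non-constant.
#' @return Normalized vector.
#' @export
quantile_normalize <- function(y) {
  if (length(y) < 2) stop("need at least 2 values")
  if (stats::var(y) == 0) stop("constant vector cannot be quantile normalized")
  stats::qnorm((rank(y, ties.method = "average") - 0.5) / length(y))
}

#' Residualize covariates, then quantile-normalize
#'
#' Regresses known covariates (e.g. age, sex) out of an expression vector
#' and maps the residuals back to standard-normal quantiles.
#'
#' @param y expression vector.
#' @param covariates N x P covariate matrix (intercept added when absent).
#' @return Normalized residual vector.
#' @export
residualize_normalize <- function(y, covariates) {
  covariates <- prepare_covariates(covariates, length(y))
  quantile_normalize(stats::lm.fit(covariates, y)$residuals)
}

# ---- flat key=value config --------------------------------------------------

#' Read a threshold configuration from a flat key=value file
#'
#' Recognized keys mirror the arguments of [threshold_config()]; unknown
#' keys are an error.
#'
#' @param path config file.
#' @param preset base preset the file overrides.
#' @export
read_threshold_config <- function(path, preset = "default") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  known_num <- c("p_dep", "p_ind", "p_anchor", "p_snp_ind", "cis_window")
  known_chr <- c("anchor_mode", "condition_on", "dep_family", "anchor_family", "preset")
  bad <- setdiff(keys, c(known_num, known_chr))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list(preset = preset)
  for (i in seq_along(keys)) {
    v <- if (keys[i] %in% known_num) as.numeric(vals[i]) else vals[i]
    if (keys[i] %in% c("dep_family", "anchor_family") &&
        !is.na(suppressWarnings(as.numeric(v)))) v <- as.numeric(v)
    args[[keys[i]]] <- v
  }
  do.call(threshold_config, args)
}

#' Write a threshold configuration as a flat key=value file
#' @param cfg [threshold_config()] object.
#' @param path output file.
#' @export
write_threshold_config <- function(cfg, path) {
  keys <- c("preset", "p_dep", "p_ind", "p_anchor", "p_snp_ind", "anchor_mode",
            "cis_window", "dep_family", "anchor_family", "condition_on")
  writeLines(sprintf("%s=%s", keys,
                     vapply(keys, function(k) as.character(cfg[[k]]), "")),
             path)
  invisible(path)
}
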