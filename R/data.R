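#' Genotype container
#'
#' Bundles a samples x variants dosage matrix with per-variant genomic
#' annotation. Dosages count copies of the annotated (minor) allele, so all
#' non-missing entries are 0, 1 or 2; missing entries are `NA` and are
#' mean-imputed downstream (kinship construction, association testing).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2\} or `NA`.
#' @param variant_ids character vector of unique variant identifiers.
#' @param chrom chromosome label per variant.
#' @param pos 1-based base-pair position per variant.
#' @return An object of class `genotype_data` with fields `dosages`,
#'   `variant_ids`, `chrom`, `pos`.
#' @export
genotype_data <- function(dosages, variant_ids = colnames(dosages),
                          chrom = rep("1", ncol(dosages)),
                          pos = seq_len(ncol(dosages))) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) < 2L) stop("need at least 2 samples")
  if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_len(ncol(dosages)))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != ncol(dosages)) stop("variant_ids length mismatch")
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  if (length(chrom) != ncol(dosages) || length(pos) != ncol(dosages))
    stop("annotation length mismatch")
  if (any(pos < 0, na.rm = TRUE)) stop("positions must be non-negative")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("non-missing dosages must be in {0, 1, 2}")
  colnames(dosages) <- variant_ids
  structure(list(dosages = dosages, variant_ids = variant_ids,
                 chrom = as.character(chrom), pos = as.numeric(pos)),
            class = "genotype_data")
}

#' Expression container
#'
#' Samples x genes expression matrix with per-gene transcription start site
#' (TSS) annotation, used for cis/trans classification of associations.
#'
#' @param values numeric matrix, samples in rows, genes in columns; finite.
#' @param gene_ids character vector of unique gene identifiers.
#' @param chrom chromosome label per gene.
#' @param tss 1-based transcription start position per gene.
#' @return An object of class `expression_data`.
#' @export
expression_data <- function(values, gene_ids = colnames(values),
                            chrom = rep("1", ncol(values)),
                            tss = seq_len(ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(values)) stop("gene_ids length mismatch")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(chrom) != ncol(values) || length(tss) != ncol(values))
    stop("annotation length mismatch")
  if (!all(is.finite(values))) stop("expression values must be finite")
  colnames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids,
                 chrom = as.character(chrom), tss = as.numeric(tss)),
            class = "expression_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d samples x %d variants (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("expression_data: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

#' @export
dim.expression_data <- function(x) dim(x$values)

n_samples <- function(x) {
  if (inherits(x, "genotype_data")) nrow(x$dosages) else nrow(x$values)
}

check_paired <- function(genotypes, expression) {
  if (nrow(genotypes$dosages) != nrow(expression$values))
    stop("genotypes and expression must share the sample dimension")
  invisible(TRUE)
}

# Intercept-first covariate matrix; validates or builds the default.
prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop("covariate rows must match sample count")
  has_intercept <- any(apply(covariates, 2, function(v) all(v == v[1] & v[1] != 0)))
  if (!has_intercept) covariates <- cbind(intercept = 1, covariates)
  if (n <= ncol(covariates)) stop("more covariates than samples")
  covariates
}
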