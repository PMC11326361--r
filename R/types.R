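#' Construct a genotype matrix
#'
#' Container for biallelic SNP dosages. `snps` carries one row per variant
#' (id, chromosome, 1-based position, ref/alt alleles); `dosage` is an
#' integer matrix of alt-allele counts in {0, 1, 2, NA}, one row per variant
#' in the same order, one column per individual.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param dosage integer matrix, `nrow(snps)` x n individuals, dimnames
#'   `(snp_id, sample_id)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, dosage) {
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  stopifnot(is.data.frame(snps), all(required %in% names(snps)),
            is.matrix(dosage), nrow(dosage) == nrow(snps))
  if (any(snps$pos < 1)) stop("positions must be 1-based (>= 1)")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- snps$snp_id
  structure(list(snps = as.data.frame(snps, stringsAsFactors = FALSE),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d individuals\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of individuals / SNP ids of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return `n_individuals()`: integer; `snp_ids()`: character vector.
#' @export
n_individuals <- function(x) ncol(x$dosage)

#' @rdname n_individuals
#' @export
snp_ids <- function(x) x$snps$snp_id

#' Subset a genotype matrix by SNP and/or sample
#' @param x a `genotype_matrix`.
#' @param snps,samples character vectors of ids to keep (NULL = all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, snps = NULL, samples = NULL) {
  keep_snp <- if (is.null(snps)) rep(TRUE, nrow(x$dosage)) else x$snps$snp_id %in% snps
  keep_smp <- if (is.null(samples)) colnames(x$dosage) else samples
  genotype_matrix(x$snps[keep_snp, , drop = FALSE],
                  x$dosage[keep_snp, keep_smp, drop = FALSE])
}

#' Construct an expression dataset
#'
#' Pairs a gene x sample matrix of log2-normalized expression with per-sample
#' metadata. Metadata must contain `sample_id` and `time_h` (time of day in
#' hours); `time_h` is reduced modulo 24 so 24.0 becomes 0.0. Any further
#' columns are treated as categorical covariates.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param metadata data.frame with `sample_id`, `time_h`, and optional
#'   covariate columns.
#' @return An object of class `expression_dataset` with elements `values`
#'   and `metadata` (row order matching the column order of `values`).
#' @export
expression_dataset <- function(values, metadata) {
  stopifnot(is.matrix(values), is.data.frame(metadata),
            all(c("sample_id", "time_h") %in% names(metadata)))
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  if (!setequal(colnames(values), metadata$sample_id))
    stop("sample sets of values and metadata differ")
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  if (any(!is.finite(metadata$time_h))) stop("time_h must be finite")
  metadata$time_h <- metadata$time_h %% 24
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  covs <- setdiff(names(x$metadata), c("sample_id", "time_h"))
  cat(sprintf("<expression_dataset> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  covariates: %s\n",
              if (length(covs)) paste(covs, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Subset an expression dataset to a set of samples
#' @param x an `expression_dataset`.
#' @param samples sample ids to keep.
#' @return An `expression_dataset`.
#' @export
subset_samples <- function(x, samples) {
  expression_dataset(x$values[, samples, drop = FALSE],
                     x$metadata[x$metadata$sample_id %in% samples, , drop = FALSE])
}

#' Construct a gene annotation table
#'
#' One transcription start site (TSS) per gene, 1-based.
#'
#' @param gene_id,chrom,tss,strand equal-length vectors; `strand` in `+`/`-`.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand = "+") {
  strand <- rep_len(strand, length(gene_id))
  stopifnot(all(strand %in% c("+", "-")), all(tss >= 1))
  if (anyDuplicated(gene_id)) stop("one TSS per gene required")
  structure(data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
                       strand = strand, stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}
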