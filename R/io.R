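#' Read a genotype matrix from VCF or TSV
#'
#' The VCF dialect is v4.2 with a GT FORMAT field; multiallelic records are
#' skipped with a warning (the count is kept in the `n_skipped` attribute)
#' and missing genotypes (`./.`) are preserved as `NA`. The TSV dialect is
#' the one written by [write_genotypes()]: columns `snp_id, chrom, pos, ref,
#' alt` followed by one dosage column per sample.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return A [genotype_matrix()]; attribute `n_skipped` counts dropped
#'   multiallelic records.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^##fileformat=VCF", first))
    stop("malformed VCF header at line 1: expected ##fileformat=VCF...")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_skipped <- sum(multi)
  if (n_skipped > 0)
    warning(sprintf("skipped %d multiallelic record(s)", n_skipped))
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alt alleles in a GT string like 0/1 or 1|1
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt)
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  known <- ok & alleles1 %in% c("0", "1") & alleles2 %in% c("0", "1")
  dosage[known] <- (alleles1[known] == "1") + (alleles2[known] == "1")
  keep <- !multi
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM, fix$POS)[is.na(ids) | ids == "."]
  gm <- genotype_matrix(
    data.frame(snp_id = ids[keep], chrom = fix$CHROM[keep],
               pos = as.integer(fix$POS[keep]), ref = fix$REF[keep],
               alt = fix$ALT[keep], stringsAsFactors = FALSE),
    dosage[keep, , drop = FALSE])
  attr(gm, "n_skipped") <- n_skipped
  gm
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(df)))
    stop("genotype TSV must have columns: ", paste(meta_cols, collapse = ", "))
  dosage <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- df$snp_id
  genotype_matrix(df[meta_cols], dosage)
}

#' Write a genotype matrix
#'
#' `format = "vcf"` writes a minimal VCF v4.2 (GT only, unphased); `"tsv"`
#' writes the flat dosage table read back by [read_genotypes()].
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "genotype_matrix"))
  if (format == "tsv") {
    df <- cbind(x$snps[c("snp_id", "chrom", "pos", "ref", "alt")],
                as.data.frame(x$dosage, check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(x$dosage), ncol(x$dosage))
    ok <- !is.na(x$dosage)
    gt[ok] <- gt_code[as.character(x$dosage[ok])]
    body <- paste(x$snps$chrom, x$snps$pos, x$snps$snp_id, x$snps$ref,
                  x$snps$alt, ".", ".", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", colnames(x$dosage)), collapse = "\t"),
                 body), path)
  }
  invisible(path)
}

#' Read an expression dataset (values + sample metadata)
#'
#' The expression TSV has genes in rows (`gene_id` column) and samples in
#' columns; the metadata TSV has `sample_id`, `time_h` and covariate
#' columns. The dataset is restricted to the intersection of the two sample
#' sets (its size is reported via `message`); `time_h` is reduced mod 24.
#'
#' @param expr_path,metadata_path file paths.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(expr_path, metadata_path) {
  expr <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(expr)) stop("expression TSV must have a gene_id column")
  md <- read.delim(metadata_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "time_h") %in% names(md)))
    stop("metadata TSV must have sample_id and time_h columns")
  genes <- expr$gene_id
  cols <- expr[, setdiff(names(expr), "gene_id"), drop = FALSE]
  num_ok <- vapply(cols, is.numeric, TRUE)
  if (!all(num_ok)) {
    bad <- names(num_ok)[!num_ok][1]
    cell <- which(is.na(suppressWarnings(as.numeric(cols[[bad]]))) &
                    !is.na(cols[[bad]]))[1]
    stop(sprintf("non-numeric expression value for gene %s, sample %s",
                 genes[if (is.na(cell)) 1L else cell], bad))
  }
  vals <- as.matrix(cols)
  rownames(vals) <- genes
  shared <- intersect(colnames(vals), md$sample_id)
  if (length(shared) == 0) stop("no shared samples between expression and metadata")
  message(sprintf("read_expression: %d shared sample(s) retained", length(shared)))
  expression_dataset(vals[, shared, drop = FALSE],
                     md[md$sample_id %in% shared, , drop = FALSE])
}

#' Write an expression dataset to a pair of TSV files
#' @param x an [expression_dataset()].
#' @param expr_path,metadata_path output paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(x, expr_path, metadata_path) {
  stopifnot(inherits(x, "expression_dataset"))
  df <- cbind(data.frame(gene_id = rownames(x$values), stringsAsFactors = FALSE),
              as.data.frame(x$values, check.names = FALSE))
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

#' Read a gene TSS annotation table
#'
#' TSV with columns `gene_id, chrom, tss` and optional `strand` (1-based
#' TSS). Strand is carried but the cis window is symmetric around the TSS.
#'
#' @param path file path.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "tss") %in% names(df)))
    stop("annotation TSV must have gene_id, chrom, tss columns")
  gene_annotation(df$gene_id, df$chrom, df$tss,
                  strand = df$strand %||% "+")
}

#' Read a BED3 interval file as merged 1-based ranges
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based closed
#' (`start+1 .. end`), with overlapping intervals merged per chromosome. A
#' 1-based point `p` lies in BED interval `[s, e)` iff `s < p <= e`.
#'
#' @param path BED3 file (no header; tab or space separated).
#' @return A reduced `GRanges`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 3)) stop("BED parse error: fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1)
  start0 <- as.numeric(vapply(parts, `[[`, "", 2))
  end0 <- as.numeric(vapply(parts, `[[`, "", 3))
  if (any(is.na(start0)) || any(is.na(end0))) stop("BED parse error: non-numeric coordinate")
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("BED parse error at record %d: start >= end", bad[1]))
  GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start0 + 1, end = end0)))
}

#' Write 1-based ranges as BED3
#' @param gr a `GRanges` (1-based closed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  writeLines(sprintf("%s\t%d\t%d",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
             path)
  invisible(path)
}

#' Write / read a planted-truth table
#' @param truth data.frame as returned by [simulate_expression()].
#' @param path TSV path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the data.frame.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read.delim(path, stringsAsFactors = FALSE)
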