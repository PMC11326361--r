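#' Minor allele frequency from dosages
#'
#' @param dosages integer vector of alt-allele counts (0/1/2, NA allowed).
#' @return `min(f_alt, 1 - f_alt)` over non-missing samples.
#' @examples
#' maf(c(0, 1, 2))  # 0.5
#' @export
maf <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  if (length(dosages) == 0) stop("all dosages missing")
  f <- sum(dosages) / (2 * length(dosages))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts (the PLINK-style test): given
#' the observed allele counts, the p-value is the sum of probabilities of
#' all heterozygote counts whose conditional probability does not exceed
#' that of the observed count. Probabilities are computed by the standard
#' recurrence over heterozygote counts of matching parity.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (dosage 0 / 1 / 2).
#' @return p-value in `[0, 1]`.
#' @examples
#' hwe_exact_p(25, 50, 25)
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  n_a <- n_Aa + 2 * n_aa              # rarity is symmetric; use either allele
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # unnormalized log-probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_hom1 * n_hom2 / ((h+2) * (h+1))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    logp[i] <- logp[i - 1] +
      log(4 * hom_minor * hom_major) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(min(n_Aa, n_minor), hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Filter variants on MAF, Hardy-Weinberg equilibrium and chromosome
#'
#' Standard pre-mapping QC: retain SNPs with MAF >= `maf_min`, exact HWE
#' p >= `hwe_p_min` (both boundaries inclusive) and, by default, autosomal
#' location (`chr1..chr22` or `1..22`). Per-filter removal counts are
#' attached as attribute `qc_log` and reported via `message`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param autosomes_only drop non-autosomal SNPs (default TRUE).
#' @return Filtered [genotype_matrix()] with attribute `qc_log`.
#' @export
qc_variants <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-6,
                        autosomes_only = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  mafs <- apply(d, 1, function(x) if (all(is.na(x))) 0 else maf(x))
  hwe <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(0)
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  autosome <- genotypes$snps$chrom %in% c(paste0("chr", 1:22), as.character(1:22))
  fail_maf <- mafs < maf_min
  fail_hwe <- hwe < hwe_p_min
  fail_chr <- autosomes_only & !autosome
  keep <- !(fail_maf | fail_hwe | fail_chr)
  log <- c(n_input = nrow(d), removed_maf = sum(fail_maf),
           removed_hwe = sum(fail_hwe), removed_chrom = sum(fail_chr),
           n_retained = sum(keep))
  message(sprintf("qc_variants: %d/%d retained (maf: -%d, hwe: -%d, chrom: -%d)",
                  log["n_retained"], log["n_input"], log["removed_maf"],
                  log["removed_hwe"], log["removed_chrom"]))
  if (!any(keep)) warning("no variants pass QC")
  out <- subset_genotypes(genotypes, snps = genotypes$snps$snp_id[keep])
  attr(out, "qc_log") <- log
  out
}

#' Regress categorical covariates out of expression
#'
#' Per gene, fits expression on indicator variables for every covariate
#' column of the metadata (all treated as categorical) and replaces values
#' with residuals plus the gene's mean, so values stay on the original log2
#' scale and fold-change thresholds remain meaningful. Perfectly collinear
#' indicator columns are dropped (with a warning) via the pivoted QR.
#'
#' @param dataset an [expression_dataset()].
#' @param covariates covariate column names (default: every metadata column
#'   other than `sample_id` and `time_h`).
#' @return An [expression_dataset()] with residualized values.
#' @export
regress_covariates <- function(dataset,
                               covariates = setdiff(names(dataset$metadata),
                                                    c("sample_id", "time_h"))) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(covariates) == 0) return(dataset)
  md <- dataset$metadata[covariates]
  md[] <- lapply(md, factor)
  X <- model.matrix(~ ., data = md)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning(sprintf("dropped %d collinear covariate column(s)",
                    ncol(X) - qx$rank))
  Y <- dataset$values
  resid <- t(qr.resid(qx, t(Y)))
  vals <- resid + rowMeans(Y)
  dimnames(vals) <- dimnames(Y)
  expression_dataset(vals, dataset$metadata)
}

#' Build cis (or trans) variant-gene pairs with genotype groups
#'
#' Cis pairs are SNP-gene combinations on the same chromosome with
#' `|pos - TSS| <= window` (boundary inclusive); trans pairs are the
#' complement (different chromosome, or distance strictly greater than the
#' window). For each pair, samples are grouped by dosage over the
#' `samples` universe; groups with more than `n_min` members are retained
#' and the pair is kept when at least two groups survive.
#'
#' @param genotypes a [genotype_matrix()] (after QC).
#' @param annotation a [gene_annotation()].
#' @param window cis window in bp around the TSS (default 1e6).
#' @param mode `"cis"` or `"trans"`.
#' @param n_min groups must have strictly more than `n_min` samples
#'   (default 50).
#' @param samples sample universe (default: all genotyped samples); use the
#'   expression sample set so group sizes reflect analyzable samples.
#' @return data.frame, one row per retained pair: `snp_id, gene_id, chrom,
#'   pos, tss, distance, n_0, n_1, n_2, retained_groups` (comma-separated
#'   dosage codes).
#' @export
build_pairs <- function(genotypes, annotation, window = 1e6,
                        mode = c("cis", "trans"), n_min = 50, samples = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samples <- samples %||% colnames(genotypes$dosage)
  missing_smp <- setdiff(samples, colnames(genotypes$dosage))
  if (length(missing_smp))
    stop("samples not in genotype matrix: ", paste(head(missing_smp), collapse = ", "))
  snps <- genotypes$snps
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    same_chr <- snps$chrom == g$chrom
    dist <- ifelse(same_chr, abs(snps$pos - g$tss), NA_real_)
    sel <- if (mode == "cis") same_chr & dist <= window
           else (!same_chr) | dist > window
    if (!any(sel)) next
    rows <- lapply(which(sel), function(j) {
      dos <- genotypes$dosage[j, samples]
      counts <- vapply(0:2, function(k) sum(dos == k, na.rm = TRUE), 0L)
      retained <- which(counts > n_min) - 1L
      if (length(retained) < 2) return(NULL)
      data.frame(snp_id = snps$snp_id[j], gene_id = g$gene_id,
                 chrom = snps$chrom[j], pos = snps$pos[j], tss = g$tss,
                 distance = if (same_chr[j]) abs(snps$pos[j] - g$tss) else NA_real_,
                 n_0 = counts[1], n_1 = counts[2], n_2 = counts[3],
                 retained_groups = paste(retained, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(), gene_id = character(),
                      chrom = character(), pos = integer(), tss = integer(),
                      distance = numeric(), n_0 = integer(), n_1 = integer(),
                      n_2 = integer(), retained_groups = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Genotype groups (sample ids per dosage) for one SNP
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_id SNP identifier.
#' @param samples sample universe (default all).
#' @param n_min retain groups with strictly more than `n_min` samples;
#'   use `n_min = 0` with care (a group needs n >= 4 for a cosinor fit).
#' @return Named list (names = dosage codes) of sample-id vectors, retained
#'   groups only. Samples with a missing dosage at this SNP are excluded.
#' @export
genotype_groups <- function(genotypes, snp_id, samples = NULL, n_min = 50) {
  samples <- samples %||% colnames(genotypes$dosage)
  if (!snp_id %in% rownames(genotypes$dosage)) stop("unknown SNP: ", snp_id)
  dos <- genotypes$dosage[snp_id, samples]
  groups <- lapply(0:2, function(k) samples[!is.na(dos) & dos == k])
  names(groups) <- as.character(0:2)
  groups[lengths(groups) > n_min]
}

#' Select the two largest genotype groups
#'
#' Ties in size are broken deterministically toward the smaller dosage code.
#'
#' @param groups named list of sample vectors, as from [genotype_groups()].
#' @return The list restricted to the top two groups, ordered largest first.
#' @export
top_two_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least two genotype groups")
  ord <- order(-lengths(groups), as.integer(names(groups)))
  groups[ord[1:2]]
}
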