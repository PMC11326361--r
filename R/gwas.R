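#' Quality-filter GWAS Catalog associations
#'
#' Removes associations with p above genome-wide significance, associations
#' from non-European studies (when `european_only`), and SNPs inside the
#' HLA locus (default hg38 chr6:29,723,339-33,087,199, boundary inclusive).
#' Per-filter removal counts are attached as attribute `filter_log`.
#'
#' @param associations data.frame with columns `snp_id, chrom, pos, trait,
#'   category, p, ancestry`.
#' @param p_max associations with `p > p_max` are removed (default 5e-8).
#' @param hla list `(chrom, start, end)` for the HLA exclusion window.
#' @param european_only keep only rows whose `ancestry` is "European"
#'   (case-insensitive).
#' @return Filtered data.frame with attribute `filter_log`.
#' @export
filter_gwas_catalog <- function(associations, p_max = 5e-8,
                                hla = list(chrom = "chr6",
                                           start = 29723339, end = 33087199),
                                european_only = TRUE) {
  stopifnot(all(c("snp_id", "chrom", "pos", "p") %in% names(associations)))
  fail_p <- associations$p > p_max
  fail_anc <- if (european_only && "ancestry" %in% names(associations))
    tolower(associations$ancestry) != "european" else rep(FALSE, nrow(associations))
  fail_hla <- associations$chrom == hla$chrom &
    associations$pos >= hla$start & associations$pos <= hla$end
  keep <- !(fail_p | fail_anc | fail_hla)
  out <- associations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(n_input = nrow(associations),
                               removed_p = sum(fail_p),
                               removed_ancestry = sum(fail_anc),
                               removed_hla = sum(fail_hla),
                               n_retained = sum(keep))
  out
}

#' Extend a tag-SNP set with perfect-LD partners
#'
#' Adds every SNP in complete linkage disequilibrium (r^2 = 1, within
#' numerical tolerance) with a tag SNP; pairs are treated symmetrically.
#'
#' @param tag_snps character vector of SNP ids.
#' @param ld_pairs data.frame with columns `snp1, snp2, r2` (r2 in [0, 1]).
#' @return Character vector: tags plus perfect-LD partners, unique.
#' @export
ld_extend <- function(tag_snps, ld_pairs) {
  if (is.null(ld_pairs) || nrow(ld_pairs) == 0) return(unique(tag_snps))
  stopifnot(all(c("snp1", "snp2", "r2") %in% names(ld_pairs)),
            all(ld_pairs$r2 >= 0 & ld_pairs$r2 <= 1))
  perfect <- ld_pairs[abs(ld_pairs$r2 - 1) <= 1e-9, , drop = FALSE]
  add <- c(perfect$snp2[perfect$snp1 %in% tag_snps],
           perfect$snp1[perfect$snp2 %in% tag_snps])
  unique(c(tag_snps, add))
}

#' Greedy lead-SNP clumping of GWAS results
#'
#' Significant SNPs (`p <= p_max`) are visited in order of ascending p
#' (ties by chromosome then position); a SNP becomes a lead unless it lies
#' within `window_bp` of an already-accepted lead on the same chromosome,
#' or (when an LD table is supplied) is in LD r^2 > `r2_max` with one.
#' The result is independent of input row order.
#'
#' @param stats data.frame with `snp_id, chrom, pos, p`.
#' @param p_max significance threshold (default 5e-8).
#' @param window_bp distance window (default 1e6).
#' @param ld_pairs optional data.frame `snp1, snp2, r2`.
#' @param r2_max LD ceiling for independence (default 0.001).
#' @return data.frame of lead SNPs (subset of `stats` rows, ordered by p).
#' @export
clump_lead_snps <- function(stats, p_max = 5e-8, window_bp = 1e6,
                            ld_pairs = NULL, r2_max = 0.001) {
  stopifnot(all(c("snp_id", "chrom", "pos", "p") %in% names(stats)))
  if (nrow(stats) == 0) stop("empty GWAS table")
  sig <- stats[stats$p <= p_max, , drop = FALSE]
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  ld_lookup <- NULL
  if (!is.null(ld_pairs) && nrow(ld_pairs) > 0) {
    high <- ld_pairs[ld_pairs$r2 > r2_max, , drop = FALSE]
    ld_lookup <- rbind(data.frame(a = high$snp1, b = high$snp2),
                       data.frame(a = high$snp2, b = high$snp1))
  }
  leads <- integer(0)
  for (i in seq_len(nrow(sig))) {
    near <- FALSE
    if (length(leads)) {
      same <- sig$chrom[leads] == sig$chrom[i]
      near <- any(same & abs(sig$pos[leads] - sig$pos[i]) <= window_bp)
      if (!near && !is.null(ld_lookup))
        near <- any(sig$snp_id[leads] %in%
                      ld_lookup$b[ld_lookup$a == sig$snp_id[i]])
    }
    if (!near) leads <- c(leads, i)
  }
  out <- sig[leads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a lead-SNP region by its rhyQTL and eQTL content
#'
#' Counts rhyQTL and eQTL SNPs within +/- `window` of the lead position on
#' the lead's chromosome. The region is flagged `rhy_contributed` when it
#' holds at least `min_rhy` rhyQTLs, and `rhy_exclusive` when additionally
#' no eQTL falls in the region (the rhyQTLs explain the GWAS signal
#' independently of expression-level QTLs).
#'
#' @param lead list or one-row data.frame with `chrom`, `pos`.
#' @param rhyqtls,eqtls data.frames with `chrom`, `pos`.
#' @param window half-width in bp (default 1e6).
#' @param min_rhy rhyQTL count needed to claim contribution (default 5).
#' @return list `(rhy_count, eqtl_count, rhy_contributed, rhy_exclusive)`.
#' @export
classify_lead_region <- function(lead, rhyqtls, eqtls, window = 1e6, min_rhy = 5) {
  in_region <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(0L)
    sum(df$chrom == lead$chrom & abs(df$pos - lead$pos) <= window)
  }
  rhy_count <- in_region(rhyqtls)
  eqtl_count <- in_region(eqtls)
  contributed <- rhy_count >= min_rhy
  list(rhy_count = rhy_count, eqtl_count = eqtl_count,
       rhy_contributed = contributed,
       rhy_exclusive = contributed && eqtl_count == 0)
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / n_tests`; `report` truncates (not rounds) to two significant
#' figures, the convention used when printing genome-wide thresholds
#' (0.05 / 644,251 is reported as 7.7e-8).
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @param report truncate to 2 significant figures (default FALSE).
#' @return numeric threshold.
#' @examples
#' bonferroni_threshold(644251, report = TRUE)
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05, report = FALSE) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  th <- alpha / n_tests
  if (report) truncate_signif(th, 2) else th
}
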