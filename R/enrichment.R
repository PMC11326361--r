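#' Odds ratio and Fisher exact p for a 2x2 contingency table
#'
#' `OR = (a*d)/(b*c)` with `a` = in both classes, `b` = row-only, `c` =
#' column-only, `d` = neither. When `b*c = 0` with `a*d > 0` the OR is
#' `Inf`; an all-zero table is an error. The p-value is the two-sided
#' Fisher exact test (the sample OR is reported, not the conditional MLE).
#'
#' @param a,b,c,d non-negative counts.
#' @return list `(or, p, a, b, c, d)`.
#' @examples
#' odds_ratio(10, 90, 10, 890)
#' @export
odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  if (a + b + c + d == 0) stop("all-zero table")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  list(or = or, p = p, a = a, b = b, c = c, d = d)
}

#' Draw a background SNP set matched on the MAF distribution
#'
#' Number-matched random sampling: SNPs are binned by MAF (bins of width
#' `bin_width` over `[0.01, 0.50]`) and, for every occupied bin of the
#' target set, the same number of pool SNPs from that bin is drawn without
#' replacement.
#'
#' @param target_maf MAFs of the target (QTL) set.
#' @param pool_maf MAFs of the candidate pool, named or indexable; the
#'   return value indexes into this vector.
#' @param seed integer seed.
#' @param bin_width MAF bin width (default 0.01).
#' @return Integer indices into `pool_maf` of the sampled SNPs
#'   (`length(target_maf)` of them).
#' @export
maf_matched_sample <- function(target_maf, pool_maf, seed, bin_width = 0.01) {
  breaks <- seq(0.01, 0.50, by = bin_width)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                                  1L), length(breaks) - 1L)
  tb <- table(bin_of(target_maf))
  pool_bins <- bin_of(pool_maf)
  withr::with_seed(seed, {
    picks <- lapply(names(tb), function(b) {
      avail <- which(pool_bins == as.integer(b))
      need <- tb[[b]]
      if (length(avail) < need)
        stop(sprintf("MAF bin %s: pool has %d SNP(s), need %d",
                     b, length(avail), need))
      if (length(avail) == 1) avail else sample(avail, need)
    })
  })
  unlist(picks, use.names = FALSE)
}

#' Baseline-normalized enrichment of QTLs in an annotation category
#'
#' For each of `n_iter` iterations, a MAF-matched, number-matched background
#' SNP set is drawn from the non-QTL SNPs inside the baseline regions (the
#' usual case-control convention: controls exclude cases; with genome-scale
#' SNP universes the two pool definitions are indistinguishable) and the
#' enrichment
#' `(EObs/EExp) / (BObs/BExp)` is computed, where EObs/EExp are the observed
#' QTL and background counts inside the category and BObs/BExp the
#' corresponding counts inside the baseline. The reported enrichment is the
#' median over iterations.
#'
#' @param snps data.frame with `chrom`, `pos`, `maf` and logical `is_qtl`
#'   covering the full SNP universe.
#' @param category,baseline `GRanges` (1-based closed), e.g. from
#'   [read_intervals()].
#' @param n_iter iterations (default 30).
#' @param seed root seed.
#' @return list of class `baseline_enrichment`: `enrichment` (the median),
#'   `per_iteration`, `n_iter`, `n_excluded` (iterations with a zero
#'   denominator, excluded), `EObs`, `BObs`.
#' @export
baseline_enrichment <- function(snps, category, baseline, n_iter = 30, seed = 1) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "maf", "is_qtl") %in% names(snps)))
  in_cat <- points_in_intervals(snps$chrom, snps$pos, category)
  in_base <- points_in_intervals(snps$chrom, snps$pos, baseline)
  if (!any(in_base)) stop("baseline contains no SNPs")
  qtl <- which(snps$is_qtl)
  pool <- which(in_base & !snps$is_qtl)  # background: non-QTLs inside baseline
  if (length(pool) == 0) stop("no non-QTL SNP inside baseline regions")
  EObs <- sum(in_cat[qtl])
  BObs <- sum(in_base[qtl])
  if (BObs == 0) stop("no QTL inside baseline regions")
  vals <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    idx <- pool[maf_matched_sample(snps$maf[qtl], snps$maf[pool],
                                   derive_seed(seed, "enrich_iter", i))]
    EExp <- sum(in_cat[idx])
    BExp <- sum(in_base[idx])
    if (EExp == 0 || BExp == 0) next     # flagged below, excluded
    vals[i] <- (EObs / EExp) / (BObs / BExp)
  }
  n_excluded <- sum(is.na(vals))
  if (n_excluded > 0)
    warning(sprintf("%d iteration(s) with empty denominator excluded", n_excluded))
  if (all(is.na(vals))) stop("no usable iteration")
  structure(list(enrichment = median(vals, na.rm = TRUE),
                 per_iteration = vals, n_iter = n_iter,
                 n_excluded = n_excluded, EObs = EObs, BObs = BObs),
            class = "baseline_enrichment")
}

#' @export
print.baseline_enrichment <- function(x, ...) {
  cat(sprintf("<baseline_enrichment> median=%.3f over %d iteration(s)\n",
              x$enrichment, x$n_iter - x$n_excluded))
  invisible(x)
}

#' Per-motif enrichment of QTLs in transcription-factor motif hits
#'
#' For each motif, builds the 2x2 table of (QTL x inside-motif) over the
#' common SNP universe and applies [odds_ratio()]. Motif hits are supplied
#' as a precomputed long table (e.g. from an external genome-wide motif
#' scan).
#'
#' @param qtl_flags named logical vector over SNP ids (`TRUE` = QTL).
#' @param motif_hits data.frame with columns `snp_id`, `motif_id`; rows are
#'   SNP-in-motif occurrences. SNPs absent from `names(qtl_flags)` are
#'   ignored.
#' @return data.frame, one row per motif: `motif_id, a, b, c, d, or, p`.
#'   Motifs with zero usable hits get `NA` results.
#' @export
motif_enrichment <- function(qtl_flags, motif_hits) {
  stopifnot(!is.null(names(qtl_flags)),
            all(c("snp_id", "motif_id") %in% names(motif_hits)))
  motif_hits <- motif_hits[motif_hits$snp_id %in% names(qtl_flags), , drop = FALSE]
  n_qtl <- sum(qtl_flags)
  n_all <- length(qtl_flags)
  motifs <- unique(motif_hits$motif_id)
  rows <- lapply(motifs, function(m) {
    inm <- unique(motif_hits$snp_id[motif_hits$motif_id == m])
    a <- sum(qtl_flags[inm])
    b <- n_qtl - a
    c <- length(inm) - a
    d <- (n_all - n_qtl) - c
    if (length(inm) == 0)
      return(data.frame(motif_id = m, a = NA, b = NA, c = NA, d = NA,
                        or = NA_real_, p = NA_real_))
    res <- odds_ratio(a, b, c, d)
    data.frame(motif_id = m, a = a, b = b, c = c, d = d,
               or = res$or, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
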