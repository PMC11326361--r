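#' Classify a peak phase as morning (AM) or afternoon (PM)
#'
#' AM means peak phase in `[0, 12)` hours, PM in `[12, 24)`; 12.0 is PM
#' (half-open convention).
#'
#' @param phase hours in `[0, 24)` (vectorized).
#' @return character vector of `"AM"` / `"PM"`.
#' @export
classify_am_pm <- function(phase) {
  if (any(phase < 0 | phase >= 24)) stop("phase must be in [0, 24)")
  ifelse(phase < 12, "AM", "PM")
}

#' Circular histogram of peak phases
#'
#' Equal-width bins `[24k/n_bins, 24(k+1)/n_bins)` over the day.
#'
#' @param phases hours in `[0, 24)`.
#' @param n_bins number of bins (default 24).
#' @return Named integer vector of counts (names = bin left edges); sums to
#'   `length(phases)`.
#' @export
phase_histogram <- function(phases, n_bins = 24) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (length(phases) && any(phases < 0 | phases >= 24))
    stop("phases must be in [0, 24)")
  edges <- 24 * seq_len(n_bins + 1) / n_bins - 24 / n_bins
  bin <- findInterval(phases, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  names(counts) <- formatC(edges[-(n_bins + 1)], format = "g")
  counts
}

#' Summarize peak phases of called rhyGenes
#'
#' Takes a pipeline result table, keeps rhyQTL-positive rows, and for each
#' distinct gene reports the phase of its most rhythmic genotype group
#' (smallest cosinor p among the top-two groups) together with the AM/PM
#' class.
#'
#' @param result data.frame from [run_map_pipeline()].
#' @param n_bins histogram bins (default 24).
#' @return list: `genes` (data.frame `gene_id, phase, am_pm`) and
#'   `histogram` (from [phase_histogram()]).
#' @export
phase_summary <- function(result, n_bins = 24) {
  hit <- result[result$is_rhyqtl, , drop = FALSE]
  if (nrow(hit) == 0)
    return(list(genes = data.frame(gene_id = character(), phase = numeric(),
                                   am_pm = character()),
                histogram = phase_histogram(numeric(0), n_bins)))
  phase <- ifelse(hit$p_A <= hit$p_B, hit$phase_A, hit$phase_B)
  keep <- !duplicated(hit$gene_id)
  genes <- data.frame(gene_id = hit$gene_id[keep], phase = phase[keep],
                      am_pm = classify_am_pm(phase[keep]),
                      stringsAsFactors = FALSE)
  list(genes = genes, histogram = phase_histogram(genes$phase, n_bins))
}
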