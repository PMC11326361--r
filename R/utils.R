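#' Derive a reproducible integer seed from a root seed and labels
#'
#' All stochastic steps in the package draw their RNG state from a single
#' root seed combined with string labels (e.g. SNP id, pair id, repeat
#' index). This makes per-unit output independent of processing order: the
#' stream used for SNP "snp_0007" is the same whether it is simulated first
#' or last.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return An integer in `[0, 2^31 - 20)`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "geno", 3)
#' @export
derive_seed <- function(root, ...) {
  parts <- c(as.character(root), vapply(list(...), as.character, character(1)))
  h <- 0
  # 2147483629 is prime and < 2^31, keeping the fold exact in doubles
  for (p in parts) {
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% 2147483629
  }
  as.integer(h)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test 1-based point positions for membership in an interval set
#'
#' @param chrom,pos character/integer vectors of equal length (1-based
#'   positions).
#' @param intervals a `GRanges` (1-based, closed), e.g. from
#'   [read_intervals()].
#' @return Logical vector, `TRUE` where the point falls in an interval.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) == 0L) return(logical(0))
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
  IRanges::overlapsAny(pts, intervals, ignore.strand = TRUE)
}

# Truncate (not round) a positive number to a given number of significant
# figures; used to report Bonferroni thresholds the way journals print them
# (0.05 / 644251 = 7.760...e-8 -> 7.7e-8).
truncate_signif <- function(x, digits = 2) {
  stopifnot(x > 0, digits >= 1)
  e <- floor(log10(x)) - (digits - 1)
  floor(x / 10^e) * 10^e
}
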