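#' The five rhythm-sharing models compared between two genotype groups
#'
#' Every model keeps a group-specific mesor (so a pure expression-level
#' difference, i.e. an eQTL effect, can never drive a differential-rhythm
#' call); they differ in how the 24-h cosine/sine coefficients are shared:
#' absent in both (`M_NONE`), present only in group A (`M_A_ONLY`) or only
#' in group B (`M_B_ONLY`), equal across groups (`M_SHARED`), or
#' group-specific (`M_DISTINCT`). Free-parameter counts are 2, 4, 4, 4, 6.
#' `M_A_ONLY`, `M_B_ONLY` and `M_DISTINCT` are the differential-rhythm
#' models.
#'
#' @return data.frame with columns `model`, `k`, `is_differential`.
#' @export
rhythm_models <- function() {
  data.frame(model = c("M_NONE", "M_A_ONLY", "M_B_ONLY", "M_SHARED", "M_DISTINCT"),
             k = c(2L, 4L, 4L, 4L, 6L),
             is_differential = c(FALSE, TRUE, TRUE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

#' Fit the five rhythm-sharing models and score them by BIC
#'
#' Each model is ordinary least squares on the pooled samples of both
#' groups, with the design encoding the model's parameter sharing. BIC uses
#' the Gaussian profile form `n * ln(RSS/n) + k * ln(n)`; the residual
#' variance is common to all models and cancels in comparisons.
#'
#' @param timesA,valuesA group A sampling times (h) and log2 expression.
#' @param timesB,valuesB group B.
#' @return data.frame with one row per model: `model, k, rss, bic,
#'   is_differential`, plus attribute `best` (the argmin-BIC model id).
#' @export
fit_model_set <- function(timesA, valuesA, timesB, valuesB) {
  stopifnot(length(timesA) == length(valuesA), length(timesB) == length(valuesB))
  nA <- length(valuesA); nB <- length(valuesB)
  if (nA < 4 || nB < 4) stop("both groups need n >= 4")
  y <- c(valuesA, valuesB)
  t <- c(timesA, timesB) %% 24
  inA <- c(rep(1, nA), rep(0, nB))
  inB <- 1 - inA
  w <- 2 * pi * t / 24
  cw <- cos(w); sw <- sin(w)
  n <- nA + nB
  designs <- list(
    M_NONE     = cbind(inA, inB),
    M_A_ONLY   = cbind(inA, inB, cw * inA, sw * inA),
    M_B_ONLY   = cbind(inA, inB, cw * inB, sw * inB),
    M_SHARED   = cbind(inA, inB, cw, sw),
    M_DISTINCT = cbind(inA, inB, cw * inA, sw * inA, cw * inB, sw * inB))
  mods <- rhythm_models()
  rss <- vapply(designs, function(X) {
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X)) stop("singular design in model fit")
    sum(fit$residuals^2)
  }, 0)
  rss <- pmax(rss, 1e-300)
  mods$rss <- unname(rss)
  mods$bic <- n * log(mods$rss / n) + mods$k * log(n)
  best <- mods$model[which.min(mods$bic)]
  attr(mods, "best") <- best
  mods
}

#' Downsample the larger of two groups to equal size
#'
#' The larger group is sampled without replacement down to the size of the
#' smaller; the smaller group is returned unchanged. Deterministic given
#' `seed`.
#'
#' @param groupA,groupB vectors (e.g. sample ids).
#' @param seed integer seed.
#' @return list with `A` and `B`, both of length `min(|A|, |B|)`.
#' @export
downsample_equal <- function(groupA, groupB, seed) {
  if (length(groupA) == 0 || length(groupB) == 0) stop("empty group")
  m <- min(length(groupA), length(groupB))
  withr::with_seed(seed, {
    if (length(groupA) > m) groupA <- sample(groupA, m)
    if (length(groupB) > m) groupB <- sample(groupB, m)
  })
  list(A = groupA, B = groupB)
}

#' G-test (log-likelihood ratio goodness of fit)
#'
#' `G = 2 * sum over non-zero cells of O * ln(O/E)`, compared to a
#' chi-square with `#categories - 1` degrees of freedom.
#'
#' @param observed,expected non-negative counts with equal sums; every
#'   expected cell must be positive.
#' @return list `(G, df, p)`.
#' @examples
#' g_test(c(20, 0, 0, 0, 0), rep(4, 5))
#' @export
g_test <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) stop("expected counts must all be > 0 (pool cells first)")
  if (abs(sum(observed) - sum(expected)) > 1e-8)
    stop("observed and expected totals differ")
  if (sum(observed) <= 0) stop("empty table")
  nz <- observed > 0
  G <- 2 * sum(observed[nz] * log(observed[nz] / expected[nz]))
  df <- length(observed) - 1L
  list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE))
}

#' Repeated equal-size downsampling with BIC model selection
#'
#' The rhyQTL resampling statistic: `n_repeats` times, downsample the larger
#' genotype group to the smaller group's size (per-repeat seeds derived from
#' `(seed, pair_id, repeat)`, so results do not depend on pair processing
#' order), select the argmin-BIC model among the five rhythm-sharing models,
#' and tally the selected-model frequencies. A G-test then asks whether the
#' frequencies deviate from a uniform expectation over the five models
#' (`expected = n_repeats / 5` each); consistent selection of one model
#' yields a small p. The modal model is the most frequent one, with ties
#' broken toward differential models, then toward the lower model index.
#'
#' @param times,values named numeric vectors over samples (times in hours,
#'   log2 expression).
#' @param groupA,groupB sample-id vectors for the two genotype groups.
#' @param pair_id identifier used in seed derivation.
#' @param n_repeats number of downsampling repeats (default 20).
#' @param seed root seed.
#' @return list of class `model_selection_result`: `pair_id`, `n_repeats`,
#'   `selected` (model per repeat), `freq` (named counts over the 5 models),
#'   `G`, `df`, `p_g`, `modal_model`, `modal_is_differential`,
#'   `n_inestimable`.
#' @export
repeat_model_selection <- function(times, values, groupA, groupB, pair_id,
                                   n_repeats = 20, seed = 1) {
  mods <- rhythm_models()
  selected <- character(0)
  n_bad <- 0L
  for (r in seq_len(n_repeats)) {
    ds <- downsample_equal(groupA, groupB, derive_seed(seed, pair_id, r))
    best <- tryCatch(
      attr(fit_model_set(times[ds$A], values[ds$A],
                         times[ds$B], values[ds$B]), "best"),
      error = function(e) NA_character_)
    if (is.na(best)) n_bad <- n_bad + 1L else selected <- c(selected, best)
  }
  if (length(selected) == 0) stop("no estimable downsampling repeat")
  freq <- table(factor(selected, levels = mods$model))
  gt <- g_test(as.integer(freq), rep(length(selected) / 5, 5))
  modal <- modal_model(freq)
  structure(list(pair_id = pair_id, n_repeats = n_repeats,
                 selected = selected, freq = freq,
                 G = gt$G, df = gt$df, p_g = gt$p,
                 modal_model = modal,
                 modal_is_differential = mods$is_differential[mods$model == modal],
                 n_inestimable = n_bad),
            class = "model_selection_result")
}

modal_model <- function(freq) {
  mods <- rhythm_models()
  freq <- as.integer(freq[mods$model])
  # highest frequency; ties prefer differential models, then lower index
  ord <- order(-freq, !mods$is_differential, seq_len(5))
  mods$model[ord[1]]
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat(sprintf("<model_selection_result> %s: modal=%s G=%.2f p=%.3g\n",
              x$pair_id, x$modal_model, x$G, x$p_g))
  print(x$freq)
  invisible(x)
}

#' Call a rhyQTL from per-genotype fits and the resampling statistic
#'
#' A variant-gene pair is called a rhyQTL when all three criteria hold:
#' (1) at least one retained genotype group is rhythmic (cosinor p <=
#' `p_max` and peak-to-trough fold change >= `fc_min`); (2) the modal model
#' over downsampling repeats is a differential-rhythm model; (3) the G-test
#' on selected-model frequencies has p < `g_p_max`.
#'
#' @param fits named list of [fit_harmonic()] results, one per retained
#'   genotype group (fit on the full group).
#' @param msr a [repeat_model_selection()] result for the same pair.
#' @param p_max,fc_min rhythmicity thresholds for criterion 1 (defaults
#'   1e-4, 1.5).
#' @param g_p_max G-test threshold for criterion 3 (default 0.05, strict).
#' @return list of class `rhyqtl_call`: the three criterion flags and
#'   `is_rhyqtl` (their conjunction), plus the inputs.
#' @export
call_rhyqtl <- function(fits, msr, p_max = 1e-4, fc_min = 1.5, g_p_max = 0.05) {
  stopifnot(inherits(msr, "model_selection_result"),
            all(vapply(fits, inherits, TRUE, "harmonic_fit")))
  crit1 <- any(vapply(fits, is_rhythmic, TRUE, p_max = p_max, fc_min = fc_min))
  crit2 <- isTRUE(msr$modal_is_differential)
  crit3 <- msr$p_g < g_p_max
  structure(list(pair_id = msr$pair_id,
                 crit1_rhythmic_any_genotype = crit1,
                 crit2_differential_modal = crit2,
                 crit3_gtest = crit3,
                 is_rhyqtl = crit1 && crit2 && crit3,
                 fits = fits, msr = msr),
            class = "rhyqtl_call")
}

#' @export
print.rhyqtl_call <- function(x, ...) {
  cat(sprintf("<rhyqtl_call> %s: rhythmic=%s differential=%s gtest=%s -> %s\n",
              x$pair_id, x$crit1_rhythmic_any_genotype,
              x$crit2_differential_modal, x$crit3_gtest,
              if (x$is_rhyqtl) "rhyQTL" else "not a rhyQTL"))
  invisible(x)
}

#' Two-cohort replication criterion for differential rhythm
#'
#' Two cosinor fits (top-two genotype groups in an independent cohort) show
#' a differential rhythm when any of: exactly one group is rhythmic at
#' `p_max`; the ratio of their peak-to-trough fold changes exceeds
#' `fc_ratio_min`; or their peak phases differ by more than `phase_min_h`
#' hours (circular).
#'
#' @param fitA,fitB [fit_harmonic()] results.
#' @param p_max per-group rhythmicity p threshold (default 0.05).
#' @param fc_ratio_min fold-change ratio threshold (default 1.5, strict).
#' @param phase_min_h phase-difference threshold in hours (default 3,
#'   strict).
#' @return logical.
#' @export
replication_differential <- function(fitA, fitB, p_max = 0.05,
                                     fc_ratio_min = 1.5, phase_min_h = 3) {
  stopifnot(inherits(fitA, "harmonic_fit"), inherits(fitB, "harmonic_fit"))
  rhyA <- fitA$p_value < p_max
  rhyB <- fitB$p_value < p_max
  fc_ratio <- max(fitA$fc_ptt, fitB$fc_ptt) / min(fitA$fc_ptt, fitB$fc_ptt)
  xor(rhyA, rhyB) ||
    fc_ratio > fc_ratio_min ||
    phase_difference(fitA$phase, fitB$phase) > phase_min_h
}
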