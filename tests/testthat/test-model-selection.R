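test_that("BIC model selection recovers planted sharing patterns", {
  # both groups flat noise -> no-rhythm model
  p0 <- make_pair(n_per_group = 100, ampA = 0, ampB = 0, noise_sd = 1, seed = 101)
  m0 <- fit_model_set(p0$times[p0$A], p0$values[p0$A],
                      p0$times[p0$B], p0$values[p0$B])
  expect_equal(attr(m0, "best"), "M_NONE")
  # strong rhythm in A only
  p1 <- make_pair(n_per_group = 100, ampA = 2, ampB = 0, noise_sd = 0.1, seed = 102)
  m1 <- fit_model_set(p1$times[p1$A], p1$values[p1$A],
                      p1$times[p1$B], p1$values[p1$B])
  expect_equal(attr(m1, "best"), "M_A_ONLY")
  # identical strong rhythm in both
  p2 <- make_pair(n_per_group = 100, ampA = 2, ampB = 2, noise_sd = 0.1, seed = 103)
  m2 <- fit_model_set(p2$times[p2$A], p2$values[p2$A],
                      p2$times[p2$B], p2$values[p2$B])
  expect_equal(attr(m2, "best"), "M_SHARED")
  # distinct phases in the two groups
  p3 <- make_pair(n_per_group = 100, ampA = 2, ampB = 2, phaseA = 2,
                  phaseB = 14, noise_sd = 0.1, seed = 104)
  m3 <- fit_model_set(p3$times[p3$A], p3$values[p3$A],
                      p3$times[p3$B], p3$values[p3$B])
  expect_equal(attr(m3, "best"), "M_DISTINCT")
  # bookkeeping: 5 models, stated parameter counts
  expect_equal(m0$k, c(2L, 4L, 4L, 4L, 6L))
  expect_equal(sum(m0$is_differential), 3)
})

test_that("an eQTL-only difference never selects a differential model", {
  p <- make_pair(n_per_group = 150, ampA = 0, ampB = 0, mesorA = 5, mesorB = 7,
                 noise_sd = 0.5, seed = 105)
  m <- fit_model_set(p$times[p$A], p$values[p$A], p$times[p$B], p$values[p$B])
  expect_equal(attr(m, "best"), "M_NONE")
})

test_that("argmin-BIC agrees with an independent exhaustive refit oracle", {
  # oracle: rebuild each design from its parameter-sharing definition and
  # solve the normal equations directly
  oracle_best <- function(tA, yA, tB, yB) {
    y <- c(yA, yB); t <- c(tA, tB)
    iA <- c(rep(1, length(yA)), rep(0, length(yB))); iB <- 1 - iA
    cw <- cos(2 * pi * t / 24); sw <- sin(2 * pi * t / 24)
    X <- list(M_NONE = cbind(iA, iB),
              M_A_ONLY = cbind(iA, iB, cw * iA, sw * iA),
              M_B_ONLY = cbind(iA, iB, cw * iB, sw * iB),
              M_SHARED = cbind(iA, iB, cw, sw),
              M_DISTINCT = cbind(iA, iB, cw * iA, sw * iA, cw * iB, sw * iB))
    n <- length(y)
    bic <- vapply(X, function(M) {
      beta <- solve(crossprod(M), crossprod(M, y))
      rss <- sum((y - M %*% beta)^2)
      n * log(rss / n) + ncol(M) * log(n)
    }, 0)
    names(which.min(bic))
  }
  withr::with_seed(301, {
    for (rep in 1:20) {
      p <- make_pair(n_per_group = sample(20:60, 1),
                     ampA = runif(1, 0, 1.5), ampB = runif(1, 0, 1.5),
                     phaseA = runif(1, 0, 24), phaseB = runif(1, 0, 24),
                     noise_sd = runif(1, 0.2, 1), seed = 400 + rep)
      got <- attr(fit_model_set(p$times[p$A], p$values[p$A],
                                p$times[p$B], p$values[p$B]), "best")
      expect_identical(got, oracle_best(p$times[p$A], p$values[p$A],
                                        p$times[p$B], p$values[p$B]))
    }
  })
})

test_that("downsampling equalizes group sizes deterministically", {
  a <- sprintf("a%03d", 1:100); b <- sprintf("b%03d", 1:60)
  ds <- downsample_equal(a, b, seed = 5)
  expect_equal(length(ds$A), 60)
  expect_identical(ds$B, b)                     # smaller group untouched
  expect_identical(downsample_equal(a, b, 5), ds)
  expect_false(identical(downsample_equal(a, b, 6)$A, ds$A))
  eq <- downsample_equal(a, a, seed = 5)
  expect_identical(eq$A, a); expect_identical(eq$B, a)
  expect_error(downsample_equal(character(0), b, 1), "empty")
})

test_that("G-test matches hand-computed values", {
  id <- g_test(rep(4, 5), rep(4, 5))
  expect_equal(id$G, 0); expect_equal(id$p, 1); expect_equal(id$df, 4)
  g2 <- g_test(c(10, 10, 0, 0, 0), rep(4, 5))
  expect_equal(g2$G, 40 * log(2.5), tolerance = 1e-12)
  g3 <- g_test(c(20, 0, 0, 0, 0), rep(4, 5))
  expect_equal(g3$G, 2 * 20 * log(5), tolerance = 1e-12)
  expect_equal(round(g3$G, 2), 64.38)
  expect_lt(g3$p, 1e-12)
  expect_error(g_test(c(1, 1), c(2, 0)), "expected")
  expect_error(g_test(c(1, 1), c(3, 3)), "totals differ")
})

test_that("repeated downsampling concentrates on the planted model", {
  p <- make_pair(n_per_group = 150, ampA = 1, ampB = 0, noise_sd = 0.5, seed = 201)
  msr <- repeat_model_selection(p$times, p$values, p$A, p$B,
                                pair_id = "pair1", n_repeats = 20, seed = 2)
  expect_equal(sum(msr$freq), 20)
  expect_gte(msr$freq[["M_A_ONLY"]], 15)
  expect_true(msr$modal_is_differential)
  expect_lt(msr$p_g, 0.05)
  # determinism and independence from which group is larger
  msr2 <- repeat_model_selection(p$times, p$values, p$A, p$B,
                                 pair_id = "pair1", n_repeats = 20, seed = 2)
  expect_identical(msr$selected, msr2$selected)
})

test_that("equal-size groups with one repeat equal the full-group fit", {
  p <- make_pair(n_per_group = 80, ampA = 1.2, ampB = 0, noise_sd = 0.4, seed = 202)
  msr <- repeat_model_selection(p$times, p$values, p$A, p$B,
                                pair_id = "x", n_repeats = 1, seed = 9)
  full <- fit_model_set(p$times[p$A], p$values[p$A], p$times[p$B], p$values[p$B])
  expect_equal(msr$selected, attr(full, "best"))
})

test_that("modal-model ties prefer differential models, then lower index", {
  freq <- table(factor(c(rep("M_NONE", 10), rep("M_A_ONLY", 10)),
                       levels = rhythm_models()$model))
  expect_equal(rhyqtl:::modal_model(freq), "M_A_ONLY")
  freq2 <- table(factor(c(rep("M_A_ONLY", 10), rep("M_B_ONLY", 10)),
                        levels = rhythm_models()$model))
  expect_equal(rhyqtl:::modal_model(freq2), "M_A_ONLY")
  freq3 <- table(factor(c(rep("M_NONE", 10), rep("M_SHARED", 10)),
                        levels = rhythm_models()$model))
  expect_equal(rhyqtl:::modal_model(freq3), "M_NONE")
})

test_that("the three-criterion rhyQTL call behaves on planted scenarios", {
  # planted rhyQTL: rhythmic in one genotype only
  p <- make_pair(n_per_group = 150, ampA = 1, ampB = 0, noise_sd = 0.5, seed = 203)
  fits <- list(`0` = fit_harmonic(p$times[p$A], p$values[p$A]),
               `1` = fit_harmonic(p$times[p$B], p$values[p$B]))
  msr <- repeat_model_selection(p$times, p$values, p$A, p$B, "p1", seed = 3)
  call <- call_rhyqtl(fits, msr)
  expect_true(call$is_rhyqtl)
  # identical shared rhythm: criterion 1 holds, criterion 2 fails
  ps <- make_pair(n_per_group = 150, ampA = 1, ampB = 1, noise_sd = 0.5, seed = 204)
  fits_s <- list(`0` = fit_harmonic(ps$times[ps$A], ps$values[ps$A]),
                 `1` = fit_harmonic(ps$times[ps$B], ps$values[ps$B]))
  msr_s <- repeat_model_selection(ps$times, ps$values, ps$A, ps$B, "p2", seed = 3)
  call_s <- call_rhyqtl(fits_s, msr_s)
  expect_true(call_s$crit1_rhythmic_any_genotype)
  expect_false(call_s$crit2_differential_modal)
  expect_false(call_s$is_rhyqtl)
  # no rhythm anywhere: criterion 1 fails
  pn <- make_pair(n_per_group = 150, ampA = 0, ampB = 0, noise_sd = 0.5, seed = 205)
  fits_n <- list(`0` = fit_harmonic(pn$times[pn$A], pn$values[pn$A]),
                 `1` = fit_harmonic(pn$times[pn$B], pn$values[pn$B]))
  msr_n <- repeat_model_selection(pn$times, pn$values, pn$A, pn$B, "p3", seed = 3)
  call_n <- call_rhyqtl(fits_n, msr_n)
  expect_false(call_n$crit1_rhythmic_any_genotype)
  expect_false(call_n$is_rhyqtl)
})

test_that("replication criteria flag rhythmicity, amplitude or phase differences", {
  # phase difference 4.5 h > 3 h
  a <- fake_fit(p_value = 1e-3, fc_ptt = 2, phase = 2)
  b <- fake_fit(p_value = 1e-3, fc_ptt = 2, phase = 6.5)
  expect_true(replication_differential(a, b))
  # identical fits are not differential
  expect_false(replication_differential(a, a))
  # fold-change ratio 3.2 / 1.6 = 2 > 1.5
  c1 <- fake_fit(p_value = 1e-3, fc_ptt = 3.2, phase = 0)
  c2 <- fake_fit(p_value = 1e-3, fc_ptt = 1.6, phase = 0)
  expect_true(replication_differential(c1, c2))
  # exactly one group rhythmic at p < 0.05
  d1 <- fake_fit(p_value = 0.01, fc_ptt = 1.2, phase = 0)
  d2 <- fake_fit(p_value = 0.5, fc_ptt = 1.2, phase = 0)
  expect_true(replication_differential(d1, d2))
  # boundary: ratio exactly 1.5 and phase exactly 3 h do not qualify
  e1 <- fake_fit(p_value = 0.01, fc_ptt = 3.0, phase = 0)
  e2 <- fake_fit(p_value = 0.01, fc_ptt = 2.0, phase = 3)
  expect_false(replication_differential(e1, e2))
})
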