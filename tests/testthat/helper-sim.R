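# Shared fixtures: every dataset is generated in code at test time.

# One synthetic variant-gene pair: two genotype groups with their own cosinor
# parameters, times uniform over the day. Used by the differential-rhythmicity
# and acceptance tests.
make_pair <- function(n_per_group = 150, ampA = 1, ampB = 0, phaseA = 8,
                      phaseB = 8, mesorA = 5, mesorB = 5, noise_sd = 0.5,
                      seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    times <- runif(n, 0, 24)
    ids <- sprintf("S%04d", seq_len(n))
    groupA <- ids[seq_len(n_per_group)]
    groupB <- ids[-seq_len(n_per_group)]
    mesor <- c(rep(mesorA, n_per_group), rep(mesorB, n_per_group))
    amp <- c(rep(ampA, n_per_group), rep(ampB, n_per_group))
    phase <- c(rep(phaseA, n_per_group), rep(phaseB, n_per_group))
    values <- mesor + amp * cos(2 * pi * (times - phase) / 24) +
      rnorm(n, 0, noise_sd)
    names(times) <- names(values) <- ids
    list(times = times, values = values, A = groupA, B = groupB)
  })
}

# Fabricate a harmonic_fit with given summary statistics (for threshold tests
# that need exact p / fold-change values).
fake_fit <- function(p_value, fc_ptt = NULL, amplitude = NULL, phase = 0, n = 100) {
  if (is.null(amplitude)) amplitude <- log2(fc_ptt) / 2
  if (is.null(fc_ptt)) fc_ptt <- 2^(2 * amplitude)
  structure(list(n = n, mesor = 0, coef_cos = amplitude, coef_sin = 0,
                 amplitude = amplitude, phase = phase, f_stat = NA_real_,
                 p_value = p_value, log2_ptt = 2 * amplitude, fc_ptt = fc_ptt),
            class = "harmonic_fit")
}

# A small complete study with planted effects for pipeline-level tests.
make_study <- function(n_individuals = 320, seed = 7, noise_sd = 0.5,
                       maf_range = c(0.3, 0.4)) {
  cfg <- sim_config(
    n_individuals = n_individuals, n_snps = 5, maf_range = maf_range,
    noise_sd = noise_sd,
    effects = list(
      rhy_effect("snp_0001", "geneA", mesor = 5, amplitude = c(1, 0, 0), phase = 8),
      rhy_effect("snp_0002", "geneB", mesor = 5, amplitude = 0.8, phase = 2)),
    n_null_genes = 2, seed = seed)
  c(simulate_rhyqtl_study(cfg), list(config = cfg))
}

quiet_pipeline <- function(...) suppressMessages(run_map_pipeline(...))
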