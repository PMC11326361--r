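#' Run the full rhyQTL mapping pipeline
#'
#' Executes, in order: variant QC ([qc_variants()]), covariate
#' residualization ([regress_covariates()]), cis variant-gene pairing
#' ([build_pairs()]) over the samples shared between genotypes and
#' expression, per-genotype cosinor fits on the full retained groups,
#' repeated-downsampling BIC model selection between the top-two genotype
#' groups ([repeat_model_selection()]) and the three-criterion rhyQTL call
#' ([call_rhyqtl()]).
#'
#' @param genotypes a [genotype_matrix()].
#' @param dataset an [expression_dataset()].
#' @param annotation a [gene_annotation()].
#' @param window cis window in bp (default 1e6).
#' @param mode `"cis"` or `"trans"` pairing.
#' @param n_min genotype groups need strictly more than `n_min` samples
#'   (default 50).
#' @param n_repeats downsampling repeats (default 20).
#' @param p_max,fc_min rhythmicity thresholds (defaults 1e-4, 1.5).
#' @param g_p_max G-test threshold (default 0.05).
#' @param maf_min,hwe_p_min QC thresholds (defaults 0.01, 1e-6).
#' @param regress run covariate residualization when covariates are present
#'   (default TRUE).
#' @param seed root seed for all downsampling.
#' @return data.frame, one row per analyzed pair: pair coordinates,
#'   per-group cosinor summaries for the top-two groups (suffix `_A` =
#'   larger, `_B` = smaller), model frequencies, `G`, `p_g`, `modal_model`,
#'   the three criterion flags and `is_rhyqtl`. Attribute `params` records
#'   all thresholds and the seed.
#' @export
run_map_pipeline <- function(genotypes, dataset, annotation, window = 1e6,
                             mode = "cis", n_min = 50, n_repeats = 20,
                             p_max = 1e-4, fc_min = 1.5, g_p_max = 0.05,
                             maf_min = 0.01, hwe_p_min = 1e-6,
                             regress = TRUE, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(dataset, "expression_dataset"))
  params <- list(window = window, mode = mode, n_min = n_min,
                 n_repeats = n_repeats, p_max = p_max, fc_min = fc_min,
                 g_p_max = g_p_max, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, seed = seed)
  shared <- intersect(colnames(genotypes$dosage), dataset$metadata$sample_id)
  if (length(shared) == 0) stop("pipeline: no shared samples between genotypes and expression")
  gt <- qc_variants(subset_genotypes(genotypes, samples = shared),
                    maf_min = maf_min, hwe_p_min = hwe_p_min)
  ds <- subset_samples(dataset, shared)
  covs <- setdiff(names(ds$metadata), c("sample_id", "time_h"))
  if (regress && length(covs) > 0) ds <- regress_covariates(ds)
  ann <- annotation[annotation$gene_id %in% rownames(ds$values), , drop = FALSE]
  dropped <- setdiff(annotation$gene_id, ann$gene_id)
  pairs <- build_pairs(gt, ann, window = window, mode = mode,
                       n_min = n_min, samples = shared)
  if (nrow(pairs) == 0) {
    warning("pipeline: no variant-gene pair passes the group-size filter")
    return(structure(empty_pipeline_result(), params = params))
  }
  times <- setNames(ds$metadata$time_h, ds$metadata$sample_id)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    pair_id <- paste(pr$snp_id, pr$gene_id, sep = ":")
    values <- ds$values[pr$gene_id, ]
    groups <- genotype_groups(gt, pr$snp_id, samples = shared, n_min = n_min)
    fits <- lapply(groups, function(s) fit_harmonic(times[s], values[s]))
    tt <- top_two_groups(groups)
    msr <- repeat_model_selection(times, values, tt[[1]], tt[[2]],
                                  pair_id = pair_id, n_repeats = n_repeats,
                                  seed = seed)
    call <- call_rhyqtl(fits, msr, p_max = p_max, fc_min = fc_min,
                        g_p_max = g_p_max)
    fA <- fits[[names(tt)[1]]]; fB <- fits[[names(tt)[2]]]
    rows[[i]] <- data.frame(
      snp_id = pr$snp_id, gene_id = pr$gene_id, chrom = pr$chrom,
      pos = pr$pos, distance = pr$distance,
      dosage_A = names(tt)[1], n_A = fA$n, amp_A = fA$amplitude,
      phase_A = fA$phase, p_A = fA$p_value, fc_A = fA$fc_ptt,
      dosage_B = names(tt)[2], n_B = fB$n, amp_B = fB$amplitude,
      phase_B = fB$phase, p_B = fB$p_value, fc_B = fB$fc_ptt,
      freq = paste(as.integer(msr$freq), collapse = ","),
      G = msr$G, p_g = msr$p_g, modal_model = msr$modal_model,
      crit1_rhythmic = call$crit1_rhythmic_any_genotype,
      crit2_differential = call$crit2_differential_modal,
      crit3_gtest = call$crit3_gtest, is_rhyqtl = call$is_rhyqtl,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (length(dropped))
    attr(res, "dropped_genes") <- dropped
  structure(res, params = params)
}

empty_pipeline_result <- function() {
  data.frame(snp_id = character(), gene_id = character(), chrom = character(),
             pos = integer(), distance = numeric(), dosage_A = character(),
             n_A = integer(), amp_A = numeric(), phase_A = numeric(),
             p_A = numeric(), fc_A = numeric(), dosage_B = character(),
             n_B = integer(), amp_B = numeric(), phase_B = numeric(),
             p_B = numeric(), fc_B = numeric(), freq = character(),
             G = numeric(), p_g = numeric(), modal_model = character(),
             crit1_rhythmic = logical(), crit2_differential = logical(),
             crit3_gtest = logical(), is_rhyqtl = logical(),
             stringsAsFactors = FALSE)
}

#' Discovery power across cohort sizes
#'
#' For each requested size, subsamples that many individuals (without
#' replacement, seed-derived), reruns [run_map_pipeline()] on the subset,
#' and reports the numbers of called rhyQTLs and rhyGenes. Used to ask how
#' many samples the design needs before discovery saturates.
#'
#' @param genotypes,dataset,annotation study inputs as for
#'   [run_map_pipeline()].
#' @param sizes integer vector of cohort sizes (each <= available samples).
#' @param seed root seed (drives both the subsampling and the pipeline).
#' @param ... further arguments passed to [run_map_pipeline()].
#' @return data.frame `n, n_pairs_tested, n_rhyqtl, n_rhygene`, one row per
#'   size in the given order.
#' @export
power_analysis <- function(genotypes, dataset, annotation, sizes, seed = 1, ...) {
  all_samples <- intersect(colnames(genotypes$dosage), dataset$metadata$sample_id)
  if (any(sizes > length(all_samples)))
    stop(sprintf("requested size exceeds the %d available samples",
                 length(all_samples)))
  rows <- lapply(sizes, function(nn) {
    smp <- if (nn == length(all_samples)) all_samples
           else withr::with_seed(derive_seed(seed, "power", nn),
                                 sample(all_samples, nn))
    res <- suppressWarnings(
      run_map_pipeline(subset_genotypes(genotypes, samples = smp),
                       subset_samples(dataset, smp), annotation,
                       seed = seed, ...))
    data.frame(n = nn, n_pairs_tested = nrow(res),
               n_rhyqtl = sum(res$is_rhyqtl),
               n_rhygene = length(unique(res$gene_id[res$is_rhyqtl])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
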