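#' Declare a planted genotype-dependent rhythm effect
#'
#' Describes, for one SNP-gene pair, the cosinor parameters of the gene in
#' each dosage group (0/1/2 alt alleles): mesor (log2 units), amplitude
#' (half peak-to-trough, log2 units) and peak phase (hours). The truth flags
#' are derived from the parameter table: `is_rhyqtl` is `TRUE` when the
#' rhythm itself differs across dosages (amplitude or phase differs, or only
#' some dosages are rhythmic); `is_eqtl` when the mesor differs.
#'
#' @param snp_id,gene_id identifiers, must exist in the simulated study.
#' @param mesor,amplitude,phase numeric length 3 (dosages 0, 1, 2);
#'   amplitudes >= 0, phases in `[0, 24)`. Scalars are recycled.
#' @return A list of class `rhy_effect`.
#' @examples
#' rhy_effect("snp_0001", "geneA", mesor = 5,
#'            amplitude = c(1, 0, 0), phase = 8)
#' @export
rhy_effect <- function(snp_id, gene_id, mesor = 5, amplitude = 0, phase = 0) {
  mesor <- rep_len(as.numeric(mesor), 3)
  amplitude <- rep_len(as.numeric(amplitude), 3)
  phase <- rep_len(as.numeric(phase), 3)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(phase < 0 | phase >= 24)) stop("phases must be in [0, 24)")
  rhythmic <- amplitude > 0
  # phase only matters for rhythmic dosages
  ph <- phase[rhythmic]
  is_rhyqtl <- (any(rhythmic) && !all(rhythmic)) ||
    (length(unique(amplitude[rhythmic])) > 1) ||
    (length(ph) > 1 && max(vapply(ph, phase_difference, 0, phi2 = ph[1])) > 0)
  structure(list(snp_id = snp_id, gene_id = gene_id, mesor = mesor,
                 amplitude = amplitude, phase = phase,
                 is_rhyqtl = is_rhyqtl,
                 is_eqtl = length(unique(mesor)) > 1),
            class = "rhy_effect")
}

#' Configure a synthetic rhyQTL study
#'
#' Holds every knob of the generator: cohort size, SNP panel, allele
#' frequencies, sampling-time distribution, residual noise, categorical
#' covariates and the list of planted effects. Defaults reflect a
#' population-cohort design: Hardy-Weinberg genotypes, donor sampling times
#' uniform over the day, Gaussian noise on the log2 scale.
#'
#' @param n_individuals cohort size (> 0).
#' @param n_snps number of simulated SNPs.
#' @param maf_range interval within `(0, 0.5]`; each SNP's minor (= alt)
#'   allele frequency is drawn uniformly from it. Use `c(f, f)` to fix it.
#' @param time_distribution `"uniform"` on `[0, 24)`, or a list
#'   `list(type = "clustered", centers =, sd =)` emulating death-time-like
#'   clustering of donor times.
#' @param noise_sd residual SD in log2 units (>= 0).
#' @param covariates named list: each element
#'   `list(levels = c(...), effects = c(...))` gives a categorical covariate,
#'   levels assigned uniformly at random, with the given additive offsets
#'   (log2 units).
#' @param effects list of [rhy_effect()] objects.
#' @param n_null_genes extra genes with flat (noise-only) expression.
#' @param snp_spacing distance in bp between consecutive simulated SNPs on
#'   the synthetic chromosome.
#' @param seed integer root seed; all draws derive from it via
#'   [derive_seed()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_snps = length(effects),
                       maf_range = c(0.05, 0.5),
                       time_distribution = "uniform",
                       noise_sd = 0.5, covariates = list(),
                       effects = list(), n_null_genes = 0,
                       snp_spacing = 10000, seed = 1) {
  if (n_individuals <= 0) stop("n_individuals must be > 0")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_snps < 1) stop("n_snps must be >= 1")
  stopifnot(all(vapply(effects, inherits, TRUE, "rhy_effect")))
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 time_distribution = time_distribution, noise_sd = noise_sd,
                 covariates = covariates, effects = effects,
                 n_null_genes = as.integer(n_null_genes),
                 snp_spacing = snp_spacing, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype matrix under Hardy-Weinberg proportions
#'
#' Each SNP draws its alt-allele frequency from `maf_range`, then each
#' individual's dosage as Binomial(2, p), i.e. genotype frequencies
#' ((1-p)^2, 2p(1-p), p^2). SNPs are laid out on a synthetic autosome
#' ("chr1") at `snp_spacing` intervals. Per-SNP RNG streams are derived from
#' the root seed, so a SNP's genotypes do not depend on how many other SNPs
#' are simulated before it.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  ids <- sprintf("snp_%04d", seq_len(m))
  mafs <- withr::with_seed(derive_seed(config$seed, "maf"),
                           runif(m, config$maf_range[1], config$maf_range[2]))
  dosage <- matrix(NA_integer_, m, n,
                   dimnames = list(ids, sprintf("IND%04d", seq_len(n))))
  for (j in seq_len(m)) {
    dosage[j, ] <- withr::with_seed(derive_seed(config$seed, "geno", ids[j]),
                                    rbinom(n, 2L, mafs[j]))
  }
  snps <- data.frame(snp_id = ids, chrom = "chr1",
                     pos = as.integer(seq_len(m) * config$snp_spacing),
                     ref = "A", alt = "G", maf_true = mafs,
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, dosage)
}

#' Simulate per-sample metadata (sampling times and covariates)
#'
#' Times are drawn from the configured distribution on `[0, 24)`; each
#' categorical covariate level is assigned uniformly at random.
#'
#' @param config a [sim_config()].
#' @return data.frame with `sample_id`, `time_h` and one column per covariate.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  td <- config$time_distribution
  times <- withr::with_seed(derive_seed(config$seed, "times"), {
    if (identical(td, "uniform")) {
      runif(n, 0, 24)
    } else if (is.list(td) && identical(td$type, "clustered")) {
      centers <- sample(td$centers, n, replace = TRUE)
      (centers + rnorm(n, 0, td$sd)) %% 24
    } else stop("unknown time_distribution")
  })
  md <- data.frame(sample_id = sprintf("IND%04d", seq_len(n)), time_h = times,
                   stringsAsFactors = FALSE)
  for (cv in names(config$covariates)) {
    lv <- config$covariates[[cv]]$levels
    md[[cv]] <- withr::with_seed(derive_seed(config$seed, "cov", cv),
                                 sample(lv, n, replace = TRUE))
  }
  md
}

#' Simulate expression with planted genotype-conditional rhythms
#'
#' For a sample with dosage g at an effect's SNP, expression of the effect's
#' gene is
#' `mesor_g + A_g * cos(2*pi*(t - phi_g)/24) + covariate offsets + N(0, noise_sd^2)`.
#' Genes listed in `n_null_genes` are flat noise (mesor 5). The returned
#' truth table restates the planted parameters and flags verbatim.
#'
#' @param genotypes a [genotype_matrix()] containing every effect SNP.
#' @param metadata per-sample data.frame as from [simulate_metadata()]; its
#'   sample set must equal the genotype columns.
#' @param config a [sim_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (data.frame, one row per effect, with per-dosage parameters and the
#'   `is_rhyqtl` / `is_eqtl` flags).
#' @export
simulate_expression <- function(genotypes, metadata, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  if (!setequal(metadata$sample_id, colnames(genotypes$dosage)))
    stop("sample sets of genotypes and metadata differ")
  metadata <- metadata[match(colnames(genotypes$dosage), metadata$sample_id), ,
                       drop = FALSE]
  t <- metadata$time_h
  n <- length(t)
  cov_offset <- rep(0, n)
  for (cv in names(config$covariates)) {
    spec <- config$covariates[[cv]]
    cov_offset <- cov_offset +
      spec$effects[match(metadata[[cv]], spec$levels)]
  }
  eff_genes <- vapply(config$effects, `[[`, "", "gene_id")
  null_genes <- if (config$n_null_genes > 0)
    sprintf("gene_null_%03d", seq_len(config$n_null_genes)) else character(0)
  genes <- c(eff_genes, null_genes)
  if (anyDuplicated(genes)) stop("duplicated gene ids across effects")
  vals <- matrix(0, length(genes), n,
                 dimnames = list(genes, metadata$sample_id))
  for (ef in config$effects) {
    if (!ef$snp_id %in% snp_ids(genotypes))
      stop("effect references unknown SNP: ", ef$snp_id)
    g <- genotypes$dosage[ef$snp_id, ] + 1L   # index into per-dosage params
    signal <- ef$mesor[g] +
      ef$amplitude[g] * cos(2 * pi * (t - ef$phase[g]) / 24)
    noise <- withr::with_seed(derive_seed(config$seed, "expr", ef$gene_id),
                              rnorm(n, 0, config$noise_sd))
    vals[ef$gene_id, ] <- signal + cov_offset + noise
  }
  for (gn in null_genes) {
    vals[gn, ] <- 5 + cov_offset +
      withr::with_seed(derive_seed(config$seed, "expr", gn),
                       rnorm(n, 0, config$noise_sd))
  }
  truth <- do.call(rbind, lapply(config$effects, function(ef) {
    data.frame(snp_id = ef$snp_id, gene_id = ef$gene_id,
               mesor_0 = ef$mesor[1], mesor_1 = ef$mesor[2], mesor_2 = ef$mesor[3],
               amp_0 = ef$amplitude[1], amp_1 = ef$amplitude[2], amp_2 = ef$amplitude[3],
               phase_0 = ef$phase[1], phase_1 = ef$phase[2], phase_2 = ef$phase[3],
               is_rhyqtl = ef$is_rhyqtl, is_eqtl = ef$is_eqtl,
               stringsAsFactors = FALSE)
  }))
  list(dataset = expression_dataset(vals, metadata), truth = truth)
}

#' Simulate a complete study: genotypes, metadata, expression, annotation
#'
#' Convenience wrapper producing every input [run_map_pipeline()] needs.
#' Each effect gene's TSS is placed 1 kb from its SNP (so the pair is cis);
#' null genes are assigned TSSs cycling over the SNP panel, giving them cis
#' variants too.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `dataset`, `annotation`, `truth`.
#' @export
simulate_rhyqtl_study <- function(config) {
  gt <- simulate_genotypes(config)
  md <- simulate_metadata(config)
  ex <- simulate_expression(gt, md, config)
  eff_genes <- vapply(config$effects, `[[`, "", "gene_id")
  eff_snps <- vapply(config$effects, `[[`, "", "snp_id")
  null_genes <- setdiff(rownames(ex$dataset$values), eff_genes)
  anchor <- c(match(eff_snps, snp_ids(gt)),
              rep_len(seq_len(config$n_snps), length(null_genes)))
  ann <- gene_annotation(gene_id = c(eff_genes, null_genes),
                         chrom = gt$snps$chrom[anchor],
                         tss = pmax(1L, gt$snps$pos[anchor] + 1000L))
  list(genotypes = gt, dataset = ex$dataset, annotation = ann,
       truth = ex$truth)
}

#' Simulate SNP/annotation tables with a planted enrichment odds ratio
#'
#' Builds a SNP universe with a QTL subset, a category interval set in which
#' QTL membership has the planted odds ratio relative to non-QTLs, and a
#' baseline covering all SNPs. MAF is drawn independently of membership, so
#' MAF-matched background sampling is unbiased. Category membership rates:
#' non-QTLs enter with probability `base_rate`; QTLs with the probability
#' whose odds are `planted_or` times the non-QTL odds.
#'
#' @param n_snps SNP universe size.
#' @param n_categories number of category interval sets to emit (>= 1).
#' @param planted_or true odds ratio (> 0) of QTL vs non-QTL membership.
#' @param seed integer seed.
#' @param qtl_fraction fraction of SNPs labelled QTL (default 0.2).
#' @param base_rate non-QTL category membership probability (default 0.05;
#'   small enough that an odds ratio approximates the category risk ratio,
#'   large enough that category counts at the default SNP universe sizes
#'   have a few-percent relative sampling error).
#' @return list with `snps` (data.frame `snp_id, chrom, pos, maf, is_qtl`),
#'   `categories` (list of `GRanges`), `baseline` (`GRanges` covering all
#'   SNPs) and `planted_or`.
#' @export
simulate_enrichment_tables <- function(n_snps, n_categories = 1, planted_or,
                                       seed = 1, qtl_fraction = 0.2,
                                       base_rate = 0.05) {
  if (planted_or <= 0) stop("planted_or must be > 0")
  if (n_categories < 1) stop("n_categories must be >= 1")
  odds1 <- planted_or * base_rate / (1 - base_rate)
  p_qtl <- odds1 / (1 + odds1)
  snps <- withr::with_seed(derive_seed(seed, "enrich_snps"), {
    data.frame(snp_id = sprintf("s%06d", seq_len(n_snps)), chrom = "chr1",
               pos = seq_len(n_snps) * 100L,
               maf = runif(n_snps, 0.01, 0.5),
               is_qtl = seq_len(n_snps) %in%
                 sample.int(n_snps, round(qtl_fraction * n_snps)),
               stringsAsFactors = FALSE)
  })
  categories <- lapply(seq_len(n_categories), function(k) {
    member <- withr::with_seed(derive_seed(seed, "cat", k),
                               runif(n_snps) < ifelse(snps$is_qtl, p_qtl, base_rate))
    if (!any(member)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(start = snps$pos[member], width = 1L)))
  })
  baseline <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = 1L, end = max(snps$pos)))
  list(snps = snps, categories = categories, baseline = baseline,
       planted_or = planted_or)
}
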