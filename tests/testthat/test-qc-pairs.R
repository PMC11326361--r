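test_that("minor allele frequency handles edge dosages", {
  expect_equal(maf(c(0, 0, 0)), 0)
  expect_equal(maf(c(0, 1, 2)), 0.5)
  expect_equal(maf(c(0, 0, 1)), 1 / 6)
  expect_equal(maf(c(2, 2, 2)), 0)        # folded to the minor allele
  expect_equal(maf(c(0, NA, 1)), 0.25)    # missing excluded
  expect_error(maf(c(NA, NA)), "missing")
})

test_that("exact HWE test reproduces hand-derived cases", {
  # balanced: the observed het count is the most probable one
  expect_equal(hwe_exact_p(25, 50, 25), 1, tolerance = 1e-12)
  # zero heterozygotes at allele frequency 0.5 is astronomically unlikely
  expect_lt(hwe_exact_p(50, 0, 50), 1e-20)
  # monomorphic SNPs have a single possible configuration
  expect_equal(hwe_exact_p(40, 0, 0), 1)
  expect_error(hwe_exact_p(-1, 0, 1), ">= 0")
})

test_that("exact HWE test matches a factorial-weight enumeration oracle", {
  # oracle: P(h) proportional to 2^h / (hom_minor! h! hom_major!) over all
  # het counts h with the parity of the minor-allele count
  oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nm <- min(nAa + 2 * naa, nAa + 2 * nAA)
    if (nm == 0) return(1)
    hets <- seq(nm %% 2, nm, by = 2)
    logw <- vapply(hets, function(h) {
      h * log(2) - lfactorial((nm - h) / 2) - lfactorial(h) -
        lfactorial(n - h - (nm - h) / 2)
    }, 0)
    w <- exp(logw - max(logw)); w <- w / sum(w)
    sum(w[w <= w[match(nAa, hets)] * (1 + 1e-12)])
  }
  cases <- list(c(5, 10, 5), c(10, 2, 8), c(3, 7, 0), c(1, 1, 18),
                c(12, 0, 3), c(7, 13, 30))
  for (cs in cases)
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
})

test_that("variant QC applies inclusive MAF/HWE thresholds and drops non-autosomes", {
  n <- 500
  make_dos <- function(p) rbinom(n, 2, p)
  withr::with_seed(77, {
    dos <- rbind(make_dos(0.009 / 2), make_dos(0.3), make_dos(0.3), make_dos(0.3))
    # row 1: MAF below 0.01 (expected ~0.0045); row 4 will sit on chrX
    dos[3, ] <- c(rep(0L, 250), rep(2L, 250))   # gross HWE violation
  })
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("S%03d", 1:n)
  snps <- data.frame(snp_id = paste0("v", 1:4), chrom = c("chr1", "chr1", "chr1", "chrX"),
                     pos = 1:4 * 1000L, ref = "A", alt = "G")
  gm <- genotype_matrix(snps, dos)
  out <- suppressMessages(qc_variants(gm))
  expect_equal(snp_ids(out), "v2")
  log <- attr(out, "qc_log")
  expect_equal(unname(log["removed_chrom"]), 1)
  # exact boundary: MAF exactly 0.01 is retained
  dos2 <- matrix(c(rep(1L, 2), rep(0L, 98)), 1)
  colnames(dos2) <- sprintf("S%03d", 1:100)
  gm2 <- genotype_matrix(data.frame(snp_id = "b", chrom = "chr1", pos = 1L,
                                    ref = "A", alt = "G"), dos2)
  expect_equal(maf(dos2[1, ]), 0.01)
  expect_equal(snp_ids(suppressMessages(qc_variants(gm2))), "b")
})

test_that("variant QC is idempotent", {
  cfg <- sim_config(n_individuals = 300, n_snps = 10, maf_range = c(0.02, 0.5),
                    seed = 19)
  gm <- simulate_genotypes(cfg)
  once <- suppressMessages(qc_variants(gm))
  twice <- suppressMessages(qc_variants(once))
  expect_identical(once$dosage, twice$dosage)
  expect_identical(once$snps, twice$snps)
})

test_that("covariate residualization preserves signal and removes offsets", {
  withr::with_seed(23, {
    n <- 500
    md <- data.frame(sample_id = sprintf("S%03d", 1:n), time_h = runif(n, 0, 24),
                     sex = sample(c("M", "F"), n, TRUE))
    sexoff <- ifelse(md$sex == "F", 0.8, 0)
    vals <- rbind(
      indep = 5 + rnorm(n, 0, 0.5),                       # covariate-independent
      offset_only = 2 + sexoff,                           # pure sex offset
      rhythm = 5 + sexoff + 1 * cos(2 * pi * (md$time_h - 7) / 24) +
        rnorm(n, 0, 0.3))
    colnames(vals) <- md$sample_id
    ds <- expression_dataset(vals, md)
    rs <- regress_covariates(ds)
    expect_gt(cor(rs$values["indep", ], vals["indep", ]), 0.99)
    expect_lt(var(rs$values["offset_only", ]), 1e-20)
    fit <- fit_harmonic(md$time_h, rs$values["rhythm", ])
    expect_lt(abs(fit$amplitude - 1), 0.05)
    # values stay on the original scale (gene mean preserved)
    expect_equal(mean(rs$values["rhythm", ]), mean(vals["rhythm", ]))
  })
})

test_that("residualization then refit is unbiased over many genes", {
  withr::with_seed(41, {
    n <- 300; n_genes <- 200
    md <- data.frame(sample_id = sprintf("S%03d", 1:n), time_h = runif(n, 0, 24),
                     batch = sample(c("a", "b", "c"), n, TRUE))
    off <- c(a = 0, b = 0.5, c = -0.3)[md$batch]
    A <- runif(n_genes, 0.5, 1.5)
    phi <- runif(n_genes, 0, 24)
    vals <- t(vapply(seq_len(n_genes), function(g)
      5 + off + A[g] * cos(2 * pi * (md$time_h - phi[g]) / 24) + rnorm(n, 0, 0.3),
      numeric(n)))
    rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
    colnames(vals) <- md$sample_id
    rs <- regress_covariates(expression_dataset(vals, md))
    amp_err <- vapply(seq_len(n_genes), function(g)
      fit_harmonic(md$time_h, rs$values[g, ])$amplitude - A[g], 0)
    expect_lt(abs(mean(amp_err)), 0.02)
  })
})

test_that("collinear covariate columns are dropped with a warning", {
  withr::with_seed(6, {
    n <- 60
    md <- data.frame(sample_id = sprintf("S%02d", 1:n), time_h = runif(n, 0, 24),
                     sex = rep(c("M", "F"), n / 2))
    md$sex_copy <- md$sex                          # perfectly collinear
    vals <- matrix(rnorm(n), 1, dimnames = list("g1", md$sample_id))
    expect_warning(regress_covariates(expression_dataset(vals, md)), "collinear")
  })
})

test_that("cis pairing respects the window boundary and group-size rule", {
  dos <- withr::with_seed(3, {
    rbind(a = rbinom(200, 2, 0.4), b = rbinom(200, 2, 0.4), c = rbinom(200, 2, 0.4))
  })
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("S%03d", 1:200)
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(1000000L + 5000L, 2000000L + 5000L + 1L, 5000L),
                     ref = "A", alt = "G")
  gm <- genotype_matrix(snps, dos)
  ann <- gene_annotation("g1", "chr1", 5000)
  pairs <- build_pairs(gm, ann, window = 1e6, n_min = 50)
  # SNP exactly 1 Mb away is included; 1 Mb + 1 bp is not
  expect_setequal(pairs$snp_id, c("a", "c"))
  # trans mode is the complement
  trans <- build_pairs(gm, ann, window = 1e6, mode = "trans", n_min = 50)
  expect_equal(trans$snp_id, "b")
})

test_that("group retention requires strictly more than n_min samples", {
  # dosage counts 60 / 55 / 10: groups {0,1} retained
  dos <- matrix(c(rep(0L, 60), rep(1L, 55), rep(2L, 10)), 1)
  colnames(dos) <- sprintf("S%03d", 1:125)
  gm <- genotype_matrix(data.frame(snp_id = "v", chrom = "chr1", pos = 100L,
                                   ref = "A", alt = "G"), dos)
  ann <- gene_annotation("g1", "chr1", 50)
  pairs <- build_pairs(gm, ann, n_min = 50)
  expect_equal(pairs$retained_groups, "0,1")
  # 50/50/50: no group exceeds 50, pair dropped
  dos2 <- matrix(rep(0:2, each = 50L), 1)
  storage.mode(dos2) <- "integer"
  colnames(dos2) <- sprintf("S%03d", 1:150)
  gm2 <- genotype_matrix(data.frame(snp_id = "v", chrom = "chr1", pos = 100L,
                                    ref = "A", alt = "G"), dos2)
  expect_equal(nrow(build_pairs(gm2, ann, n_min = 50)), 0)
})

test_that("pair construction agrees with a brute-force distance scan", {
  cfg <- sim_config(n_individuals = 150, n_snps = 30, maf_range = c(0.2, 0.5),
                    snp_spacing = 90000, seed = 55)
  gm <- simulate_genotypes(cfg)
  ann <- gene_annotation(c("g1", "g2"), "chr1", c(200000, 2500000))
  pairs <- build_pairs(gm, ann, window = 1e6, n_min = 20)
  brute <- expand.grid(snp = snp_ids(gm), gene = ann$gene_id,
                       stringsAsFactors = FALSE)
  brute$keep <- vapply(seq_len(nrow(brute)), function(i) {
    pos <- gm$snps$pos[gm$snps$snp_id == brute$snp[i]]
    tss <- ann$tss[ann$gene_id == brute$gene[i]]
    if (abs(pos - tss) > 1e6) return(FALSE)
    counts <- table(factor(gm$dosage[brute$snp[i], ], levels = 0:2))
    sum(counts > 20) >= 2
  }, TRUE)
  expect_setequal(paste(pairs$snp_id, pairs$gene_id),
                  paste(brute$snp[brute$keep], brute$gene[brute$keep]))
})

test_that("top-two group selection breaks ties toward the lower dosage", {
  g <- list(`0` = sprintf("a%d", 1:200), `1` = sprintf("b%d", 1:100),
            `2` = sprintf("c%d", 1:60))
  expect_equal(names(top_two_groups(g)), c("0", "1"))
  g2 <- list(`0` = sprintf("a%d", 1:80), `1` = sprintf("b%d", 1:80))
  expect_equal(names(top_two_groups(g2)), c("0", "1"))
  g3 <- list(`1` = sprintf("b%d", 1:80), `2` = sprintf("c%d", 1:80))
  expect_equal(names(top_two_groups(g3)), c("1", "2"))
  expect_error(top_two_groups(g["0"]), "two genotype groups")
})

test_that("samples with missing dosage are excluded from that SNP only", {
  dos <- matrix(c(0L, 1L, NA, 2L,
                  0L, 1L, 1L, 2L), 2, byrow = TRUE)
  colnames(dos) <- c("s1", "s2", "s3", "s4")
  rownames(dos) <- c("v1", "v2")
  gm <- genotype_matrix(data.frame(snp_id = c("v1", "v2"), chrom = "chr1",
                                   pos = c(1L, 2L), ref = "A", alt = "G"), dos)
  g1 <- genotype_groups(gm, "v1", n_min = 0)
  expect_false("s3" %in% unlist(g1))
  g2 <- genotype_groups(gm, "v2", n_min = 0)
  expect_true("s3" %in% unlist(g2))
})
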