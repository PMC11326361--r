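---
title: "Methods: mapping rhythmic QTLs with rhyqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping rhythmic QTLs with rhyqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhyqtl)
```

## The problem

Bulk expression cohorts such as population biobanks record, for each donor,
a genome-wide genotype and a single expression snapshot taken at a known (or
inferable) time of day. Averaged over the whole cohort, many genes look
arrhythmic; but if a nearby genetic variant gates the gene's circadian
regulation, the 24-h rhythm may be present only in the subpopulation carrying
a particular genotype, with the other genotype groups diluting it away. A
*rhythmic QTL* (rhyQTL) is a variant whose genotype is associated with such
variation in rhythm — presence/absence, amplitude, or peak phase — of a
nearby gene; the affected gene is a *rhyGene*. This is distinct from an
ordinary eQTL, which shifts a gene's mean level without touching its rhythm.

`rhyqtl` implements the full mapping procedure and its downstream analyses,
plus a synthetic-data generator with known ground truth, so that every stage
can be validated end to end without access to protected cohort data.

## The cosinor model

Within one genotype group, expression of a gene at time-of-day $t$ (hours) is
modelled by a single-harmonic cosinor at a fixed 24-h period:

$$ y = m + a\cos(2\pi t/24) + b\sin(2\pi t/24) + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2) $$

fit by ordinary least squares (`fit_harmonic()`). The derived quantities are
the amplitude $A = \sqrt{a^2+b^2}$ (half the peak-to-trough difference, in
log2 expression units), the peak phase $\varphi = \frac{24}{2\pi}
\operatorname{atan2}(b, a) \bmod 24$ (hours), and an F-test of $(a, b)$
against the intercept-only model with $(2, n-3)$ degrees of freedom. Because
inputs are log2-normalized, the linear-scale peak-to-trough fold change is
$2^{2A}$. A group is *rhythmic* when $p \le 10^{-4}$ and $2^{2A} \ge 1.5$;
both comparisons are inclusive, so exact ties pass.

Assumptions worth stating: a single 24-h harmonic (no period estimation, no
higher harmonics), Gaussian residuals on the log2 scale, and sampling times
that are informative — i.e. spread over the day. With $n < 4$ or all times
equal (mod 24) the fit is refused rather than silently degenerate; a constant
response returns $A = 0$, $F = 0$, $p = 1$.

## From variants to testable pairs

1. **Variant QC** (`qc_variants()`): biallelic SNPs with minor allele
   frequency $\ge 0.01$, exact Hardy–Weinberg p $\ge 10^{-6}$ (both
   boundaries inclusive), autosomes only. The HWE test is the exact
   conditional test on heterozygote counts given allele counts, computed by
   the standard probability recurrence.
2. **Covariate residualization** (`regress_covariates()`): every metadata
   column other than `sample_id`/`time_h` is treated as categorical;
   per-gene least-squares residuals are re-centred on the gene mean so
   values stay on the log2 scale and fold-change thresholds keep their
   meaning. Collinear indicator columns are dropped via the pivoted QR.
3. **Pairing** (`build_pairs()`): cis pairs are SNP–gene combinations on
   the same chromosome with $|pos - TSS| \le 1$ Mb (inclusive; the window is
   symmetric and strand-agnostic). Trans mode takes the complement. Samples
   are grouped by dosage (0/1/2); a group is retained when it has strictly
   more than 50 samples ("greater than 50" read literally as $n \ge 51$),
   and a pair survives when at least two groups are retained. Samples with
   a missing dosage at a SNP are excluded from that SNP only; group sizes
   are counted after intersecting with the expression samples.

## The differential-rhythmicity statistic

For each pair, the two largest genotype groups are compared (ties in size
break toward the lower dosage code). Five rhythm-sharing models are fit to
the pooled samples by least squares, every model keeping a group-specific
mesor so that a pure expression-level (eQTL) difference can never masquerade
as a rhythm difference:

| model | rhythm coefficients | free parameters |
|---|---|---|
| `M_NONE` | absent in both groups | 2 |
| `M_A_ONLY` | present only in group A | 4 |
| `M_B_ONLY` | present only in group B | 4 |
| `M_SHARED` | equal in both groups | 4 |
| `M_DISTINCT` | group-specific | 6 |

Models are scored by the Gaussian profile BIC, $n\ln(RSS/n) + k\ln n$; the
residual variance is common to all five models and cancels in comparisons.
`M_A_ONLY`, `M_B_ONLY` and `M_DISTINCT` are the differential-rhythm models
(`M_DISTINCT` subsumes amplitude-only and phase-only changes; the model
space does not split them further).

To remove the bias a size imbalance would introduce, the larger group is
downsampled without replacement to the smaller group's size, 20 times
(`repeat_model_selection()`). Each repeat selects the argmin-BIC model; the
selected-model frequencies over the 20 repeats are then tested with a
G-test, $G = 2\sum O\ln(O/E)$ on 4 degrees of freedom, against a uniform
expectation ($E = 4$ per model). The uniform expectation is a deliberate
design choice — it asks "is selection consistent, rather than scattered as
it would be if downsampling noise dominated?"; a unanimous 20/20 selection
gives $G = 40\ln 5 = 64.38$. The alternative (expectation concentrated on
the full-data argmin model) is stricter about *which* model recurs; the
uniform version is the one whose two-sided behaviour we validate.

A pair is called a rhyQTL when all three criteria hold
(`call_rhyqtl()`):

1. at least one retained genotype group is rhythmic ($p \le 10^{-4}$,
   fold change $\ge 1.5$) — evaluated on the full groups, not the
   downsampled subsets;
2. the modal selected model is a differential-rhythm model (ties prefer
   differential models, then the lower model index — deterministic, and
   conservative in that a differential call requires at least a tie);
3. the G-test has $p < 0.05$ (strict, matching the call's "less than"
   wording, in contrast to the inclusive rhythmicity thresholds).

For replicating calls in an independent cohort (`replication_differential()`),
two group fits count as differential when exactly one group is rhythmic at
$p < 0.05$, or the fold-change ratio exceeds 1.5, or the peak phases differ
by more than 3 h (circular distance); all three strict.

## Reproducible randomness

All stochastic steps — genotype draws, sampling times, noise, downsampling,
background SNP draws — derive their RNG stream from a single root seed
combined with string labels (`derive_seed(root, label, ...)`, a 31-ary
modular fold). Per-SNP, per-gene, per-pair and per-repeat streams are
therefore independent of processing order: permuting the SNP rows of the
input leaves every call identical, which the test suite asserts.

## Enrichment statistics

`odds_ratio()` reports the sample odds ratio $ad/bc$ of a 2×2 table with the
two-sided Fisher exact p (degenerate tables: $OR = 0$ when $a = 0$, $+\infty$
when $bc = 0 < ad$). `motif_enrichment()` applies it per transcription-factor
motif over a precomputed SNP-in-motif hit table.

For annotation categories, `baseline_enrichment()` computes
$(E_{Obs}/E_{Exp})/(B_{Obs}/B_{Exp})$: observed QTL counts inside the
category and inside the baseline regions, each normalized by the counts of a
number-matched background SNP set with the same MAF histogram (bins of width
0.01 over $[0.01, 0.50]$), drawn without replacement from the non-QTL SNPs
inside the baseline — the usual case-control convention; at genome scale the
distinction from "all SNPs" is negligible, and excluding cases keeps the
estimator unbiased when QTLs are a sizeable fraction of a small simulated
universe. Thirty draws are made and the median reported; iterations with an
empty denominator are excluded and counted.

GWAS utilities follow the same conventions as the mapping stage:
`filter_gwas_catalog()` (genome-wide significance $p \le 5\times10^{-8}$,
European-study filter, HLA window chr6:29,723,339–33,087,199 removed),
`ld_extend()` (tags plus partners with $r^2 = 1$, tolerance $10^{-9}$,
symmetric), `clump_lead_snps()` (greedy by ascending p; a candidate is
rejected within 1 Mb of, or at $r^2 > 0.001$ with, an accepted lead; ties
by position — row-order independent), `classify_lead_region()` (a lead
region "is contributed to" by rhyQTLs when $\ge 5$ fall within $\pm 1$ Mb,
and "exclusively" so when no eQTL does), and `bonferroni_threshold()`
(whose reporting helper truncates — not rounds — to two significant
figures, reproducing $0.05/644{,}251 \to 7.7\times10^{-8}$).

Phase reporting classifies peaks at or after 12:00 as PM (half-open
boundary; "0:00–12:00" is boundary-ambiguous, and the half-open convention
makes AM/PM an exact partition of $[0, 24)$).

## What the generator emulates — and what it does not

`simulate_rhyqtl_study()` draws biallelic genotypes at Hardy–Weinberg
proportions with configurable MAF, donor times uniform on $[0, 24)$ by
default (a declared assumption — organ-donor cohorts inherit death-time
distributions that are not public; a clustered alternative is available),
and expression as mesor + genotype-conditional cosinor + categorical
covariate offsets + Gaussian log2 noise. Planted effects carry their truth
flags (`is_rhyqtl`, `is_eqtl`) derived from the per-dosage parameter table.

It does **not** simulate read-level RNA-seq, linkage disequilibrium between
SNPs (LD tables are supplied directly where needed), population structure,
or non-Gaussian noise. Passing tests therefore demonstrate correctness of
the statistics under the stated model, and calibration against planted
truth; they do not demonstrate robustness to LD-induced correlated tests or
heavy-tailed expression noise in real cohorts.

`simulate_enrichment_tables()` plants a known odds ratio for QTL membership
in a category (defaults: 20% of SNPs are QTLs, non-QTL membership rate 5%).
The rates are chosen once so that the baseline-normalized estimator — a
risk-ratio-like quantity — approximates the planted odds ratio (small base
rate) while category counts at a 50,000-SNP universe carry only a
few-percent relative sampling error; a planted OR of 3 is recovered near
2.7, the small deficit being the odds-ratio-to-risk-ratio gap, not
estimator bias.

## Validation design and problem sizes

The test suite pins every statistic to an independent oracle: the cosinor
fit against a refined phase-grid search, BIC selection against an
exhaustive normal-equations refit, the exact HWE test against a
factorial-weight enumeration, Fisher p against hypergeometric enumeration,
interval membership against a per-base scan, and the G statistic against
direct arithmetic over all relevant frequency compositions.

Operating characteristics are measured at the design conditions of the
statistic: sensitivity on 200 pairs with a one-genotype-only rhythm
(amplitude 1.0 log2, noise sd 0.5, 150 samples/group, 20 downsampling
repeats) and false-positive rate on 200 pairs with an identical shared
rhythm; cosinor null calibration on 1000 pure-noise fits at $n = 100$;
enrichment null and planted-OR recovery at 50,000 SNPs with 30 iterations;
and a discovery-power curve at cohort sizes 50/150/400 on a study whose
eight planted effects sit on separate cis windows with MAFs spanning
0.12–0.45, so the $n > 50$ group rule gates discovery as the cohort grows.
These sizes make the full suite run in well under a minute while leaving
the Monte-Carlo bands comfortably narrower than the properties they check.
`scripts/acceptance.R` recomputes all of these from scratch at a
caller-supplied seed.

## Known limitations

* Only two genotype groups enter the model-selection statistic (the top two
  by size); a heterozygote-specific rhythm in the smallest group is
  invisible to criterion 2, though criterion 1 still sees it.
* The G-test's uniform expectation is an interpretive choice (see above);
  both it and every threshold are arguments, not constants.
* No multiple-testing correction is applied across pairs — calls use
  per-pair thresholds by design, mirroring standard practice for this
  statistic; genome-wide use should treat the call set as a candidate list.
* Trans pairing is provided (`mode = "trans"`), but the package does not
  model the indirect regulatory chains that make trans effects hard to
  interpret.
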