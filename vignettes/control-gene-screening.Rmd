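---
title: "Screening RNA-seq expression matrices for stable endogenous control genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening RNA-seq expression matrices for stable endogenous control genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlscreen)
```

## The problem

Relative quantification by qRT-PCR normalizes a target gene's threshold
cycle (Ct) against an endogenous control gene that is assumed to be
expressed at a constant level across samples. In cancer cohorts that
assumption often fails badly: conventional controls such as *GAPDH*,
*ACTB* or *B2M* can vary several-fold between patients, which directly
distorts every relative quantification computed against them. Given
gene-by-sample RPKM matrices from RNA-seq cohorts, one can instead
measure each gene's expression consistency empirically and select
controls with demonstrably low variability. `ctrlscreen` implements
that screen end to end, together with the qPCR-side statistics used to
validate a chosen control.

## Stability statistics

For each gene, across the samples of one dataset:

* **mean RPKM** — the expression level; controls must be comfortably
  detectable, so very weakly expressed genes are excluded from
  candidacy.
* **CV%** — coefficient of variation, `sd / mean * 100`. This is the
  primary stability statistic and genes are ranked by it (lowest =
  rank 1, ties broken lexicographically by gene id so the ranking is
  deterministic).
* **MFC** — maximum fold change, `max / min`. MFC is deliberately
  sensitive to single outlier samples, which the CV can average away.
  A gene observed at zero in any sample gets `MFC = Inf` and can never
  pass an MFC threshold — a gene that switches off entirely in some
  samples is useless as a control regardless of its CV.

The standard deviation uses the sample (n−1) denominator by default. At
the cohort sizes this screen targets (tens to thousands of samples) the
choice is numerically irrelevant; `sd_denom = "n"` switches to the
population form for exact comparison against tools that use it.

Both CV and MFC are invariant under multiplication of all values by a
positive scalar, per gene or globally — so they are insensitive to the
units of the expression measure, and library-depth rescaling of a whole
sample cancels out of MFC-style ratios only gene-by-gene, not across
genes; normalized units (RPKM) remain the intended input.

## Stratified selection and cross-dataset scoring

Candidates are selected from a discovery dataset under strict
thresholds, `CV < 25%` and `MFC < 5`, within two expression strata:
mean RPKM above 100, and between 25 and 100. The strata exist because a
usable control should roughly match the expression range of the targets
it will normalize; the 25 RPKM floor removes genes too weak to assay
reliably. Thresholds are strict inequalities, so a gene at exactly CV
25% is excluded.

Candidates are then confronted with additional datasets. Each dataset
contributes **two** independent pass flags per gene — one for the CV
criterion, one for the MFC criterion — and the score is the total
number of raised flags divided by two. A gene passing both criteria in
all of 10 datasets scores 10.0; half-integer scores arise when a gene
passes only one criterion in some dataset. Counting the two criteria
separately (rather than jointly per dataset) is what makes
half-integer scores possible at all, and is how the published
score tables with values such as 7.5 or 6.5 must have been computed.
Ranking is by descending score, ties broken by ascending mean CV across
datasets, then gene id.

## Background quantile curves

Expression variability depends on expression level, so a gene's CV is
only meaningful relative to genes of similar abundance. The package
computes rolling-window quantile curves: genes are ranked by mean RPKM
and, over a window of 2000 consecutively ranked genes (the default;
any window from 2 up to the gene count is accepted), the 5th, 25th,
50th and 75th quantiles of CV are recorded against the window's mean
expression. `quantile_position()` then classifies a gene by the
smallest curve level at or above its CV ("at or above" rather than
strictly above, so a gene sitting exactly on a curve classifies at that
curve's level). The window step defaults to 1 (fully rolling); the
orchestrated screen uses step 25 for transcriptome-scale matrices,
which changes the curves only cosmetically while cutting compute
25-fold.

## GeNorm M values

On the qPCR side, Ct values are first converted to relative quantities
with the efficiency transform `quantity = E^(minCt − Ct)` (default
`E = 2`, a perfect doubling per cycle, appropriate for assays tuned by
standard-curve analysis; per-gene efficiencies can be supplied). The
GeNorm pairwise variation between genes *j* and *k* is the standard
deviation across samples of `log2(q_j / q_k)`, and `M(j)` is the mean
pairwise variation of *j* against all other panel genes. Two genes that
are proportional across samples have pairwise variation 0; a gene whose
expression moves independently of the panel gets a high M. M is
invariant under per-gene and per-sample rescaling, so neither input
amounts nor the choice of quantity units affect the ranking. The
stepwise mode repeatedly removes the highest-M gene (ties: the
lexicographically larger id) down to a final pair.

## ddCt relative quantification and validation statistics

`dCt = Ct(target) − Ct(control)` within a sample;
`ddCt = dCt(sample) − dCt(calibrator)` against the mean dCt of the
calibrator sample(s); `RQ = 2^(−ddCt)`. The identity `RQ = 2^(−ddCt)`
holds to machine precision for all outputs, and normalizing a gene
against itself yields RQ exactly 1 in every sample.

Two validation statistics quantify how much the choice of control
matters:

* the **Spearman correlation** between a target's RPKM and its dCt
  across samples (average-rank tie handling). Because lower Ct means
  more template, a faithful control yields a strongly negative rho; a
  variable control injects its own variance into dCt and pulls rho
  toward zero.
* the **CV% and MFC of the RQ values** of a gene that is itself stable.
  Under a good control the RQ panel is flat; under a variable control
  the apparent fold changes are artifacts of the denominator. The
  calibrator samples are excluded from this summary by default (their
  RQ is 1 by construction when a single calibrator is used).

## The synthetic-data generator

No generative model is published for the cohorts this screen was
designed around, so the generator is an explicit stand-in built to
reproduce the *ranges* that matter to the screen, not any particular
cohort. Per-gene values are log-normal: a gene with target CV `c` (as a
fraction) gets log-scale standard deviation `sigma = sqrt(log(1 + c^2))`
— from the log-normal identity `CV^2 = exp(sigma^2) − 1` — and a
log-mean chosen so the arithmetic mean equals the gene's drawn mean
RPKM. Gene means are log2-uniform over 2..12 (≈4–4096 RPKM), spanning
the few-to-thousands RPKM range where published per-gene means of both
conventional controls and screen candidates fall. A planted fraction
(default 5%) of genes is "stable" with a 10% CV target; the rest draw
CV targets uniformly from 40–120%, matching the observed spread of
conventional control genes in real cohorts. The default study is 10
datasets of 2000 genes × 100 samples.

Matched Ct tables come from a log-linear observation model,
`Ct = intercept − slope·log2(RPKM) + N(0, sd)`, defaulting to an
intercept of 32 cycles at 1 RPKM, slope 1 cycle per log2 (perfect
efficiency), and 0.15 cycles of Gaussian noise — a typical technical
replicate spread for a well-behaved TaqMan-style assay. With the noise
at zero the model makes the Spearman correlation between log2 RPKM and
Ct exactly −1, which the tests assert.

Reproducibility: a single master seed drives everything; gene-universe
draws and each dataset's sample draws use fixed-offset substreams, so
regenerating a study is bit-identical and adding datasets never
perturbs earlier ones.

What the generator deliberately does **not** emulate: count-level
sampling noise (a negative binomial on reads collapsed through library
size), batch effects or cohort-specific shifts (datasets are
independent draws from identical per-gene laws), gene–gene correlation,
dropout zeros, and assay-specific PCR efficiencies. Passing tests
therefore demonstrate that the statistics, selection logic and scoring
behave correctly on data whose marginal structure matches real RPKM
cohorts — not that the screen's thresholds are optimal for any
particular tissue.

## Numerical and design choices

* Quantiles use R's default (type 7) definition; the median is the
  middle value or the mean of the two central values.
* Ranking tie-breaks are lexicographic everywhere, making every table
  a deterministic function of its input.
* Expression matrices must be complete and non-negative; Ct tables may
  contain missing values (qPCR dropouts are real), and genes with
  incomplete Ct rows are excluded from GeNorm with a warning rather
  than imputed.
* Dataset combination pools samples over the gene-id intersection and
  namespaces sample ids as `label:sample`; intersection (rather than
  union with imputation) guarantees every statistic is computed on
  complete rows.
* Printed-table display rounds to one decimal, but all internal
  computation and all tests (except those reproducing printed numbers)
  run at full double precision.
* The screen's orchestrated run (`run_screen()`) treats the first
  dataset as the discovery cohort, mirroring the design where one
  deeply characterized cohort proposes candidates and the others
  arbitrate them.

## Worked example

```{r}
cfg <- synthetic_config(n_genes = 300, n_samples = 40, n_datasets = 4,
                        seed = 7)
study <- generate_study(cfg)
res <- run_screen(study, output_dir = NULL, verbose = FALSE)
head(res$scorecard, 3)

labels <- planted_labels(study[[1]])
card <- score_across_datasets(res$tables, selection_criteria(),
                              labels$gene_id)
recover_planted(card, labels)
```

The problem sizes used throughout the package's tests follow the same
pattern: full-scale synthetic studies (2000 genes × 100 samples × 10
datasets) for the recovery checks, and small randomized instances
(3–12 genes/samples, hundreds of repetitions) for the oracle
comparisons.

## Limitations

The screen measures consistency, not biological inertness: a gene can
be statistically stable in the surveyed cohorts yet respond to a
treatment of interest, so validation in the experimental system at hand
remains necessary. MFC is sensitive to cohort size (the expected
max/min ratio grows with n), so MFC thresholds should be compared only
across datasets of similar size. And the half-integer score treats the
CV and MFC criteria as exchangeable evidence, which is a modelling
convenience rather than a calibrated combination rule.
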