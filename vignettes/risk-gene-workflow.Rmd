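---
title: "Identifying risk genes from matched transcriptome and methylome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying risk genes from matched transcriptome and methylome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskomics)
```

## The design and the question

`riskomics` implements an integrated transcriptome--methylome screen for a
three-group cohort: healthy **controls**, unaffected **high-risk**
individuals (typically first-degree relatives of patients, such as
offspring of an affected parent) and **patients**. The question is which
genes mark *risk* rather than illness: features altered in the high-risk
group *and* in the patient group, relative to controls, are candidate risk
markers, while features altered in only one of the two groups are not.

The pipeline has five stages:

1. **Differential expression** per control-referenced contrast: two-sided
   Student's *t*-test with pooled variance on (quantile-normalised,
   log-scale) array signal intensities, Benjamini--Hochberg adjustment, and
   selection at BH `q <= deFdr` together with `-log10(p) > 1.5`.
2. **Differential methylation** per contrast on Infinium-style beta values:
   group mean betas, `delta beta = mean(comparison) - mean(reference)`, a
   two-sided *t*-test, and selection at `p < 0.01` with
   `|delta beta| >= 0.3`.
3. **Concordance**: the risk-gene set is the union of (a) genes selected in
   *both* expression contrasts and (b) genes annotated to probes selected
   in *both* methylation contrasts, with per-gene `E`/`M`/`E+M` evidence
   flags. The patient-vs-high-risk contrast gets its own combined list.
4. **Correlation integration** (eQTM-style): Pearson correlation of
   expression against beta for every annotated gene--probe pair, pooled
   across all samples, filtered at `|r| > 0.8`.
5. **Enrichment**: right-tailed hypergeometric (one-sided Fisher) test of
   the risk genes against a GMT pathway collection, BH-adjusted across
   sets.

```{r quick}
cohort <- simulateCohort(simConfig(seed = 1))
res <- runRiskGeneAnalysis(cohort)
res$riskGeneSet
```

## Statistical choices, and why

**Student's t with pooled variance.** Both omics layers are tested with the
classical two-sample *t* (df `n1 + n2 - 2`). With six samples per group
there is little information for per-feature variance moderation, and the
plain *t* keeps the selection rule transparent; moderated (empirical-Bayes)
alternatives are deliberately out of scope. Genes with zero pooled variance
are untestable: they get missing p- and q-values, are never selected, and
are excluded from the BH multiplicity count (the conservative choice).

**The dual expression threshold.** Array-era selection rules often stack an
FDR level, a nominal alpha and a raw-p cutoff. These are not equivalent
constraints, so the package applies every one that can bind conjunctively:
selection needs BH `q <= deFdr` (default 0.01) *and*
`-log10(p) > deNeglog10pCutoff` (default 1.5, i.e. p < 0.0316, strict).
The nominal `deAlpha` (0.05) binds neither rule — a p-value passing the
`-log10` cutoff always passes 0.05 — so it is carried only as metadata.
Both knobs are independently configurable rather than second-guessing a
single intent.

**Delta beta on the beta scale.** The methylation effect filter
(`|delta beta| >= 0.3`, inclusive, versus strict `p < 0.01`) is defined on
beta values, so the test runs on the same scale; one coherent convention
beats mixing beta-scale effects with M-value-scale tests. The
Illumina-style DiffScore `10 * sign(delta beta) * (-log10 p)` is reported
for reference only. At these thresholds the delta-beta filter dominates
selection; the precise form of the p-value model matters little.

**Concordance direction.** "Altered in both contrasts" could mean mere
membership of both selected lists or membership with a consistent direction
of change. The biologically coherent default demands the same direction
(`requireSameDirection = TRUE`), for methylation compared at the *probe*
level before gene mapping; the permissive reading stays available as a
switch. Probes without gene annotation are reported in
`unannotatedProbes()`, never silently dropped and never counted as genes.

**Correlation selection ignores p.** The `|r| > 0.8` filter (strict) is an
effect-size criterion; at 18 samples it is already far out in the null
tail (two-sided p around 7e-5), and p-values are reported alongside without
entering selection. Multi-probe genes are kept per pair, with a max-|r|
per-gene summary, so no aggregation choice hides information.

**Enrichment and the derived universe.** Over-representation uses the right
tail P(X >= k) of Hypergeometric(N, K, q) via `phyper`. Commercial pathway
tools rarely publish their reference-set size N, but any pathway of size 1
has the closed form P(X >= 1) = q/N, so a printed singleton-pathway p-value
inverts to `N = round(q / p1)` (`deriveUniverse()`). With
`deriveUniverse(0.00198, 41) = 20707`, the package reproduces a published
13-pathway table within 1% relative error on every row whose overlap is
printed — the residual discrepancy on multi-overlap rows traces to the
rounding of the printed three-significant-figure anchor. The shipped
`canonical_pathways_synthetic.gmt` mirrors that table's set sizes and
overlap genes with synthetic filler members; it is a test fixture, not a
pathway database.

```{r enrich}
gsc <- readGMT(system.file("extdata", "canonical_pathways_synthetic.gmt",
                           package = "riskomics"))
risk <- readResultTable(system.file("extdata", "bd_risk_genes.tsv",
                                    package = "riskomics"))
N <- deriveUniverse(0.00198, length(risk$gene))
head(enrichSets(risk$gene, gsc, universeSize = N)$table[, 1:6])
```

## What the generator emulates

`simulateCohort()` produces the cohort structure the analysis assumes, with
a ground-truth table for recovery testing:

* **Design**: three matched groups of `nPerGroup = 6`; feature counts
  default to 2,000 genes and 2,000 probes — array-like structure at a size
  where a full analysis runs in well under a second (tests use 100--2,000
  features depending on what they measure).
* **Expression**: `exp(Normal(mu_g, noiseSdExpr))` per gene with
  `mu_g ~ Normal(6, 1)`, so signals are positive and right-skewed like
  array intensities. Planted effects are *down*-shifts of `exprEffect = 2`
  natural-log units: shared (`risk_expr`) effects hit both risk groups with
  the same sign and size — exactly the structure the concordance step is
  built to find — while `offspring_only` and `patient_only` classes plant
  group-specific effects that a correct pipeline must *exclude* from the
  risk set. The default plants more high-risk-specific than
  patient-specific effects (40 vs 10), mirroring the reported pattern that
  the high-risk group showed more expression alterations than patients.
* **Methylation**: noise is Normal on the M-value (logit) scale with
  `noiseSdMvalue = 0.3`, mapped back by the inverse logit, which keeps
  every beta strictly inside (0,1) and matches the usual heteroscedastic
  beta-value behaviour. Planted probes start from baseline betas in
  0.15--0.35 and are shifted on the logit scale by the amount that makes
  the *expected* beta difference equal `deltaBetaEffect = 0.35` — the
  expectation `E[logistic(m + sd Z)]` is computed by numerical integration
  and the shift solved with `uniroot`, because the logit-normal mean is not
  `logistic(m)`. A shift that would push the expected beta past 1 is a
  configuration error, not a silent clamp.
* **Coupling**: `nCoupled` genes have log-expression
  `a + b * beta + Normal(0, sigma)` against their probe, with negative `b`
  (the canonical repressive direction of promoter methylation) and `sigma`
  solved from the logit-normal beta SD so the population |r| equals
  `couplingR = 0.92`. The target sits above the 0.85 floor one would
  minimally require because the downstream filter acts on *sample*
  correlations: at 18 samples, Fisher's z puts P(sample |r| > 0.8) at about
  0.93 for a population r of 0.90 but about 0.97 at 0.92, which is the
  margin a recovery test needs to be meaningful rather than borderline.
* **Covariates**: family cohesion, family conflict and a global-functioning
  score are drawn per sample from group-dependent Normal means (cohesion
  8.16 / 5.5 / 4.66, conflict 0.83 / 4.0 / 5.16, functioning 88.3 / 89.2 /
  49.8 for control / high-risk / patient, SDs 1.5--4), following published
  cohort demographics. Because planted risk effects reduce expression in
  the risk groups where cohesion is low and conflict high, gene--cohesion
  correlations come out positive and gene--conflict correlations negative —
  the sign structure the covariate-correlation stage should recover.

**What it does not emulate** — and therefore what passing recovery tests do
*not* establish about real data: probe-level chip artifacts and detection
failures, batch effects, cell-type composition differences between groups
(a known confounder of blood methylation), genotype-driven effects,
medication exposure, multi-probe genes beyond one planted probe per gene,
and correlated noise across features. Recovery rates on this generator are
upper bounds for field performance.

## Numerical and degenerate-input conventions

* Files are UTF-8, tab-separated, `.` decimal, `NA` for missing; doubles
  are written as `%.17g` so every reader/writer pair round-trips
  bit-exactly. Annotation gene fields split on `;` and deduplicate
  preserving order; positions are 1-based and carried but unused.
* Quantile normalisation (via `limma::normalizeQuantiles`, ties averaged)
  refuses missing values rather than imputing silently; a single-column
  matrix is returned unchanged.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` with the
  multiplicity count equal to the number of non-missing p-values; the test
  suite verifies it against a brute-force implementation of the step-up
  definition.
* The hypergeometric tail uses `stats::phyper` (log-gamma arithmetic
  internally); tests verify it against exhaustive enumeration over binomial
  coefficients for every parameter combination with N <= 60.
* Selection lists sort by p ascending with ties broken by feature id, so
  output order is deterministic.
* Pearson correlations use pairwise-complete observations, require at least
  3 pairs and non-zero variance, clamp r to [-1, 1] against rounding, and
  assign p = 0 at |r| = 1.

## Limitations

The pipeline analyses each feature marginally: no covariate adjustment
(ANCOVA-style modelling is out of scope), no variance moderation, no
region-level methylation calling, no cell-composition correction, and no
causal claim in the expression--methylation correlations. The derived
enrichment universe reproduces a published table's arithmetic; it cannot
recover what an unpublished proprietary knowledge base actually contained.
At n = 6 per group the screen is exploratory by construction — the
package's job is to make that screen reproducible, testable and honest
about its thresholds.
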