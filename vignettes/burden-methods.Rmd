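---
title: "Methods: carrier burden testing for a five-gene DCIS panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier burden testing for a five-gene DCIS panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcisburden)
```

This vignette is the package's own account of its statistical model, its
tunable parameters, the numerical conventions it fixes where the underlying
study design left them open, and what its synthetic cohorts do and do not
demonstrate about real data.

## The model

The unit of analysis is the *carrier*: an individual with at least one
QC-passing pathogenic variant in a given gene. For gene $g$ the data reduce
to a 2×2 table

|            | carrier | non-carrier |
|------------|---------|-------------|
| cases      | $a$     | $b$         |
| controls   | $c$     | $d$         |

with $a+b$ the number of cases and $c+d$ the number of controls. Counting
individuals rather than variants or alleles matters: a woman with two
pathogenic variants in one gene is one carrier of that gene, while a woman
with pathogenic variants in two genes is a carrier of each (the stratified
frequency tables additionally report variant-level counts, because the two
totals differ exactly by the number of extra variants in multi-variant
carriers, and both are clinically interesting).

**Test.** Conditional on the margins, $a$ is hypergeometric; the reported
p-value is the exact upper tail $P(X \ge a)$ — Fisher's exact test,
one-sided toward *enrichment* of carriers in the first group. The one-sided
choice encodes the a-priori direction (predisposition genes do not protect);
the case-only analyses reuse the same machinery with the exposed stratum
(younger age, positive family history) as the first row. No
multiple-testing adjustment is applied anywhere: with five genes and a small
number of pre-specified strata the raw p-values are the honest summary, and
any correction is left to the reader.

**Effect size.** The odds ratio $\widehat{OR} = ad/bc$ with the Woolf
(logit) interval
$\exp\!\left(\log \widehat{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d}\right)$,
no continuity correction. The interval method is a deliberate design choice:
the study design this package models reports odds ratios and 95% intervals
without naming the interval construction, and the Woolf interval reproduces
every all-cells-positive published interval to printed precision (verified
in `tests/testthat/test-acceptance.R` before the choice was frozen). An
alternative (conditional maximum-likelihood intervals, as returned by
`fisher.test()`) does not. Degenerate tables use fixed conventions rather
than corrections: $c = 0 < a$ reports `Inf` with no interval, $a = 0 < c$
reports 0, $a = c = 0$ is undefined (`NA`), and intervals are only reported
when all four cells are positive. We chose sentinels over Haldane-style
0.5-cell corrections because the published convention we mirror prints
"inf", and a corrected interval for a zero cell would suggest spurious
precision.

Note that the case-only interval construction is knowingly uniform: the
published case-only intervals are not all reproducible by the Woolf interval
that reproduces the case-control ones (the construction used there is
unstated). The package reports Woolf intervals everywhere; only the
case-only *point* odds ratios are checked against published values.

## QC filter

A call passes QC iff

* read depth ≥ `depth_min` (10 reads),
* variant quality ≥ `quality_min` (20, phred-scaled),
* genotype quality ≥ `gq_min` (20, phred-scaled),
* allelic ratio ≥ `ar_min_absolute` (0.2) at any depth, and
* not (allelic ratio < `ar_min_conditional` (0.3) and depth <
  `depth_conditional` (50 reads)).

All exclusion rules are strict inequalities, so a value exactly at a
threshold passes; this is the literal reading of the thresholds the design
states, and the boundary behaviour is pinned by tests. A missing
depth/quality/GQ/allelic-ratio value fails QC with the corresponding
reason: a call that cannot be assessed is treated conservatively rather
than waved through. Every failing call records *all* reasons that fired,
so filter summaries attribute multi-reason failures to each clause and
separately tally them.

## Classification

ClinVar precedence is absolute: a variant whose normalized key
(upper-cased gene and transcript, whitespace-stripped cDNA string with a
canonical `c.` prefix, del/dup/ins spellings matched case-insensitively)
appears in the lookup takes the ClinVar label even when it contradicts the
functional class — a truncating variant labelled benign stays benign, a
missense labelled pathogenic is pathogenic. The rule engine only sees
variants absent from the lookup:

* frameshift indel / stop-gain / stop-loss → **pathogenic** (truncation);
* intronic with $|$splice distance$| \le 2$ bp → **pathogenic** (the
  essential splice dinucleotide; donor and acceptor sides are not
  distinguished because the rule names no side);
* missense / in-frame indel → **VUS**;
* everything else → **not counted**, retained and flagged for audit rather
  than deleted.

A truncating variant in the last exon is still pathogenic: escape from
nonsense-mediated decay does not rescue protein function here, and
downgrading would silently change carrier counts. Verdicts labelled
*conflicting* by ClinVar enter **neither** the pathogenic nor the VUS
burden analyses: the two categories are analysed separately and pooling a
conflicting call into either would be an unforced claim.

Known limitation: genes whose pathogenic spectrum is dominated by missense
variants (notably *TP53*) are under-called by the truncation rule unless
the ClinVar lookup covers them; the package provides no in-silico missense
predictor by design, so curating the lookup is the user's lever.

## Power calculation

`estimate_power()` is a direct Monte-Carlo implementation of the design
calculation: for a variant class of combined allele frequency $f$, the
control carrier probability is $p_0 = 2f$ (rare-variant Hardy–Weinberg:
carriers are heterozygotes, homozygotes negligible), the case carrier
probability solves $\mathrm{odds}(p_1) = OR \cdot \mathrm{odds}(p_0)$, and
each replicate draws binomial carrier counts for both arms and applies the
one-sided Fisher test at level $\alpha$.

Run at the modelled design (655 cases, 1611 controls, $f = 0.001$,
$OR = 5$, $\alpha = 0.05$), the estimate is ≈ 0.68 (Monte-Carlo s.e.
≈ 0.003 at 20 000 replicates; `scripts/acceptance.R` recomputes this). This
is noticeably below the ≈ 80% sometimes quoted for designs of this shape.
The gap is a property of the procedure, not a bug: the conditional exact
test is conservative at these tiny expected counts (≈ 3 control carriers),
and quoted design power for rare-variant panels is often derived from
normal approximations, from one-sample calculations against a fixed
population frequency, or with a much larger (reference-database-sized)
control arm — all of which yield higher numbers than honest simulation of
the two-arm exact test. The package reports what the stated procedure
actually delivers. Under the null ($OR = 1$) the rejection rate stays at or
below $\alpha$, as the suite verifies.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions at the level this package
consumes — annotated calls, not reads:

* **Carriers.** Per subject and gene, Bernoulli carrier status: controls at
  the configured control carrier frequency, cases at the odds-transformed
  frequency. Defaults use the modelled cohort's internal control
  frequencies and odds ratios for *BRCA2* (2/1611, OR 27.96), *CHEK2*
  (5/1611, OR 8.04) and *PALB2* (1/1611, OR 14.88). The internal control
  arm had *no* *BRCA1* or *TP53* carriers, and a Bernoulli model cannot
  represent frequency 0 with an infinite odds ratio, so those two genes
  default to their external-reference control frequencies (81/21384 and
  16/21384) with the replication odds ratios (1.62 and 6.14) — which
  reproduce the observed case carrier counts (4 and 3 of 655) in
  expectation.
* **Covariates** come from conditional probability tables, not regression
  models, so ground truth stays exactly computable: case age is integer
  25–49 with under-40 mass 100/655 (carriers of one designated young-onset
  gene, *BRCA2* by default, at 9/22); ER and grade marginals match the
  modelled cohort, with carriers skewed ER-positive and
  high/intermediate-grade; controls carry no family history because the
  modelled control series was screened for exactly that.
* **Calls.** Each carrier receives a variant from a template library
  (recurrent published alleles for the "known" fraction, which appear in
  the emitted ClinVar fixture; novel frameshift/stop-gain/splice templates
  otherwise), plus configurable planting of VUS, ClinVar-benign/conflicting
  and synonymous calls. Clean calls draw depth well above the conditional
  threshold and allelic ratio from a symmetric Beta(20, 20) heterozygous
  model clamped to [0.30, 0.97] — the allelic-ratio distribution of real
  amplicon data is not published, so this is an explicit assumption, and
  the clamping guarantees planted biology is never lost to QC, which is
  what makes exact ground-truth recovery testable.
* **Artifacts.** Each emitted call is independently a QC-failing artifact
  with probability `artifact_rate` (default 0.05), drawn uniformly over the
  five failure modes with metrics sampled inside the failing range.

What passing tests on these cohorts show: the pipeline's bookkeeping is
exact (planted classes and carrier counts are recovered perfectly at zero
artifact rate), the QC filter removes exactly the planted artifacts, and
the burden estimator is unbiased on the log-odds scale at moderate carrier
frequencies. What they do not show: robustness to correlated artifacts,
allele-ratio distortion near thresholds, annotation errors, population
stratification, or relatedness — none of which the generator models.

`fixture_paper_counts()` is different in kind: a deterministic cohort whose
marginals reproduce the modelled study's published counts exactly, used to
pin the headline statistics end-to-end. Three reconstruction choices were
forced by internal tensions in the published counts and are recorded here:

1. The ER-stratum denominators (89 ER-negative, 397 ER-positive among
   cases) follow the stratified frequency tables rather than the slightly
   different demographic summary (88/390); the frequency tables are the
   surface the fixture must reproduce.
2. One *TP53* carrier had bilateral disease with one ER-positive and one
   ER-negative tumour and is counted in both ER strata in the published
   frequency tables. A single-valued ER field cannot do that; the fixture
   records her as ER-positive (age 35), which preserves the ER-positive
   under-40 cell (13 variants in 11 women) and the ER-negative under-50
   total (8 of 89) at the cost of two non-headline cells (the ER-negative
   under-40 total and the ER-positive under-50 totals each shift by one).
3. The gene pairs of the four dual-gene carriers are not published; the
   fixture uses pairs (*BRCA2*+*CHEK2* twice, *BRCA2*+*BRCA1*,
   *CHEK2*+*PALB2*) consistent with every per-gene stratum count, with all
   four ER-positive and two under 40 as the woman-level totals imply.

## Problem sizes used by the test suite

Deterministic checks run on the fixture (655/1611) and on printed 2×2
tables directly. The exact-test oracle comparison enumerates every table
with both group sizes ≤ 28 and a 2000-table random sample with group sizes
≤ 60. The parameter-recovery harness runs 200 simulated cohorts of 600
cases / 1200 controls at control carrier frequency 0.04 and odds ratios
1.5–3: large enough that every replicate yields a finite log-odds-ratio
(so the mean over replicates estimates what the invariant claims) and that
the estimator's small-sample bias is an order of magnitude below the
Monte-Carlo resolution of the check. Power checks use 4000 replicates.
These sizes were chosen as the smallest that make the statistical
assertions sharp; all are set in code, not configuration.

## Degenerate inputs and other conventions

* Empty variant tables flow through the whole pipeline: all-zero tables,
  $p = 1$, undefined odds ratios, zero carrier rates.
* Subjects with unknown stratum (ER, age band, family history) are dropped
  from exactly the tables that stratify on them, never imputed, and their
  counts are logged and recorded in results.
* Calls whose gene is off-panel or whose sample is absent from the subject
  table are rejected loudly with counts; malformed numerics are row-level
  errors, never coerced.
* Every randomized component (simulator, power) takes an explicit integer
  seed and restores the caller's RNG state.
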