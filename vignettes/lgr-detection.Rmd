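---
title: "Detecting germline large genomic rearrangements from panel depth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting germline large genomic rearrangements from panel depth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgrscan)
library(dplyr)
```

## Scope

`lgrscan` detects germline large genomic rearrangements (LGRs) — whole-exon
deletions and duplications — from targeted-panel read depth, validates calls
with ddPCR-style arithmetic, computes per-sample genome-instability metrics,
and runs the cohort statistics used to profile LGR carriers. A synthetic
cohort generator reproduces the statistical structure these analyses assume,
so every stage is exercised end-to-end by the test suite without any patient
data. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic results do and do not demonstrate.

## The depth model and its normalization

A sequencing panel's per-target read counts vary over two orders of
magnitude for reasons unrelated to copy number: probe efficiency, GC
content, library size. The generator models count for target $t$ in sample
$p$ as negative binomial:

$$d_{tp} \sim \mathrm{NB}\!\left(\mu_t \, s_p \, \frac{CN_{tp}}{2},\ \phi\right),
\qquad \mathrm{Var} = \mu + \phi\,\mu^2$$

with target baselines $\mu_t$ log-normal (sdlog 0.3) around the configured
mean depth, per-sample size factors $s_p$ log-normal(0, 0.1), and $CN$ the
germline copy number. Reference normals are diploid by construction. The
dispersion default $\phi = 0.01$ gives a per-target log2ratio SD of about
0.12 at 500× — a high-quality hybrid-capture panel; raising $\phi$ or
lowering depth degrades calling in the expected direction, which the test
suite checks as a monotonicity property.

The caller inverts exactly these nuisances without knowing the truth:
per-target baselines $m_t$ are medians across size-factor-scaled reference
normals (medians resist outlying normals), the case sample's size factor is
the median of $d_t/m_t$ across targets (robust to a minority of targets
being truly deleted/duplicated), and

$$l_t = \log_2\!\left(\frac{(d_t + 0.5)/s}{m_t}\right).$$

The 0.5 pseudo-count keeps $l$ finite at zero coverage; it biases $l$ by
less than 0.002 at 300× and is irrelevant above ~50×. At least 2 normals are
required; ~20–30 are recommended for a stable baseline (the defaults use
30).

## Thresholds and event assembly

* **deletion**: $l \le -0.6$ (heterozygous loss expects $-1$),
* **duplication**: $l \ge 0.45$ (single-copy gain expects $+0.585$),
* boundaries are inclusive: a value exactly at a threshold takes the state.

These cutoffs sit roughly 2.5–3.5 noise SDs from both the neutral and the
shifted expectation at default noise, balancing per-exon sensitivity against
the false-call rate. The integer copy-state estimate is
$\max(\mathrm{round}(2 \cdot 2^{l}), 0)$.

Same-state exons of a gene merge into events; up to `gap_max = 1`
intervening neutral or QC-failed exon is bridged (a single noisy exon inside
a real multi-exon event is far more likely than two independent events 2
exons apart). After assembly, event boundaries are refined: an immediately
adjacent exon is absorbed when its log2ratio passes 75% of the calling
threshold (`extend_frac`), since a sub-threshold but clearly shifted edge
exon belongs to the event. Single-exon events are the dominant noise mode,
so they must either carry supporting SNP zygosity or reach stricter
thresholds ($l \le -0.8$ del, $\ge 0.55$ dup).

## Zygosity integration

SNP B-allele fractions constrain copy state independently of depth:

* a true CN = 1 span cannot contain heterozygous SNPs, so a candidate
  deletion is **contradicted** when more than 10% of its informative SNPs
  (depth ≥ 20) show BAF in (0.2, 0.8), and **supported** when at least one
  informative SNP exists and the het fraction stays within that tolerance;
* a CN = 3 heterozygote reads BAF 1/3 or 2/3, so a duplication is supported
  when ≥ 60% of its het-BAF SNPs fall in [0.28, 0.40] ∪ [0.60, 0.72].

Contradicted single-exon candidates are dropped (they are noise by the
argument above); contradicted multi-exon events are kept but fail QC — an
auditable flag beats silent disappearance for events large enough to be
real.

## The VP quality metric

`variance_to_previous()` computes, for an ordered span $t_1..t_k$,

$$VP = \frac{1}{k}\sum_{i=1}^{k}(l_{t_i}-l_{t_{i-1}})^2,$$

with $t_0$ the preceding target in the same gene, or the gene-median
log2ratio for spans starting at exon 1. On a flat track with white noise of
SD $\sigma$, $E[VP] \approx 2\sigma^2$.

For *event* QC the transition term is deliberately excluded: a genuine
heterozygous deletion necessarily contains a ~1-unit log2 jump at its
boundary, so a definition that includes it would reject every true call at
any useful threshold. Event QC therefore uses the within-span mean squared
successive difference (defined as 0 for single-exon events, whose quality is
governed by the stricter single-exon rules), gated at `vp_max = 0.09` —
about $2\sigma^2$ at $\sigma = 0.21$, i.e. events noisier than roughly twice
the default noise level fail QC.

## ddPCR arithmetic

A well is positive iff it holds at least 3 positive droplets **and**
strictly more than 3× the mean positive count over the negative-control
replicates; both inequalities are asserted exactly in the tests (9 positives
against a baseline mean of 3 is negative). Channel concentration is the
Poisson correction $\lambda = -\ln(1 - \text{positive}/\text{total})$ and
copy number is $CN = 2\,\lambda_{\text{target}}/\lambda_{\text{reference}}$
against the copy-number-stable reference. Saturated channels
(positive = total) are errors rather than silently clipped, and a
zero-concentration reference yields a flagged undefined estimate.

Published validation summaries print only per-gene totals, concordant
counts and sensitivity/specificity; `solve_confusion()` recovers the
underlying integer 2×2 table by exhaustive search over all non-negative
integer splits, matching percentages under half-up rounding to 2 decimals
(the convention used for all printed percentages here; base R's round-half-
to-even would mismatch printed clinical tables). For the three benchmark
gene summaries shipped in the acceptance script the solution is unique;
ambiguous inputs return all solutions with a flag, inconsistent inputs
error. ddPCR is treated as the reference method and NGS as the prediction;
the orientation is configurable by swapping arguments. The per-gene exon
totals imply pooling exons across the validated samples; concordance is
therefore computed over a pooled exon universe.

## Genome metrics

* **TMB**: non-synonymous somatic mutations per Mb of sequenced territory.
* **CIN**: the percentage of copy-number *segments* deviating from neutral —
  a segment-count definition, so splitting a segment changes the value; a
  bp-weighted variant sits behind `bp_weighted = TRUE` (default off). This
  literalism is asserted, not hidden, in the tests.
* **WGD**: strictly more than 50% of the profiled segment length at copy
  number strictly greater than 2. "Total chromosomal length" is taken as
  the length covered by the sample's segment profile, since profiles are
  the only length information available; fractional copy numbers compare
  numerically (2.3 > 2 counts as duplicated).
* **MSI**: threshold on an input unstable-site fraction, MSI-H at ≥ 0.4
  (inclusive). The upstream computation of that fraction is out of scope;
  the threshold is the documented, configurable stand-in.

## Pathogenicity rules

Classification is a pure function of annotation fields carried on the
input, replacing manual curation with an explicit precedence: curated
assertion (P/LP/B) → population frequency (benign at max AF ≥ 0.005 across
the four population databases) → rare loss-of-function on a predisposition
gene (likely pathogenic) → rare missense with ≥ 4 of 6 deleterious
predictor votes (likely pathogenic) → VUS. Raising the population
frequency can never raise the pathogenicity rank (a property test).
Whole-exon deletions of predisposition genes are pathogenic; internal
duplications likely pathogenic; whole-gene duplications default to VUS
(they leave an intact copy in place). Wherever "pathogenic carriers" are
counted, likely pathogenic is included.

The packaged 35-gene predisposition list and its pathway map (DDR, HR,
MMR, FA, NER, cell cycle, PI3K, Other) are a compact stand-in for the
~135-gene consensus lists clinical panels use; both are replaceable
arguments everywhere they appear.

## Cohort statistics

Fisher's exact test (two-sided, by summing hypergeometric outcome
probabilities not exceeding the observed table's) and the Mann–Whitney U
test are delegated to R's reference implementations; the test suite
verifies them against independent oracles — full enumeration of the
hypergeometric support for all sampled tables with totals ≤ 60, and exact
rank-count identities — and checks nominal type-I error (~5%) for the
co-occurrence screen and the rank test under simulated nulls. Odds ratios
are sample (cross-product) ratios with a Haldane 0.5 correction when a cell
is zero, so direction is always defined. Raw P < 0.05 is the significance
convention throughout, with no multiple-testing correction by default
(Benjamini–Hochberg sits behind a flag) — matching the descriptive
oncoprint-style analyses this package supports. Co-occurrence testing skips
genes with fewer than 3 carriers by default; such tables cannot reach
significance and only dilute summaries.

Patients carrying both a pathogenic LGR and a pathogenic SNV/InDel form
their own group, excluded from between-group statistics (their group
membership is ambiguous) but retained in totals. Clinical tables keep
"unknown" levels as descriptive rows but exclude them from tests; r×c
tables too large for exact computation fall back to a seeded Monte-Carlo
Fisher test.

## What the generator emulates — and what it does not

Emulated: exon-specific depth with overdispersion scaled by germline copy
number; SNP BAFs consistent with zygosity and copy state (including allele
loss inside CN = 1 spans and 1/3–2/3 shifts inside CN = 3 spans); LGR events
spanning whole exons of predisposition genes (~80% deletions, 1–5 exons);
independent LGR/SNV carrier draws at configurable prevalences (defaults 1%
and 9.1%, the structure of a large pan-cancer germline series); annotated
germline and somatic small variants; per-sample segment profiles with a WGD
subpopulation; MSI fractions; Poisson-partitioned droplet counts. One master
seed drives per-patient substreams derived by integer bit-mixing, so truth
for patient $i$ is invariant to cohort size — byte-identical reruns and
stable incremental cohorts.

Not emulated: GC and mappability waves, batch effects between case and
normal libraries, FFPE damage, tumor purity/clonality, pseudogene
cross-mapping (the classic *PMS2* failure mode), breakpoint-level structure
within introns, and linkage between carrier status and clinical covariates.
Passing tests therefore demonstrate that the implementation is correct
under the stated statistical model, not that the caller's operating point
transfers to any particular real assay; on real data the panel-of-normals
must come from the same library protocol, and genes with known pseudogene
interference need orthogonal confirmation.

## Problem sizes and test design

The caller's operating characteristics are measured on a 2000-patient
synthetic cohort (40 genes, 5–15 exons each, 500× mean depth, 30 normals,
fixed seed): event-level sensitivity for multi-exon heterozygous deletions
and the per-exon false-call rate on copy-neutral exons (bounded at 0.2%)
over ~7×10⁵ exon evaluations. Statistical calibration uses 10⁴ co-occurrence
pairs under independence and 10⁴ Mann–Whitney null replicates. These sizes
give stable estimates while keeping the full suite around two minutes on one
CPU; the generator scales linearly for larger studies.

## Known limitations

* Exon-level resolution only: no breakpoint placement, no split-read or
  discordant-pair evidence, no somatic CNV calling with purity correction.
* The VP statistic and its threshold are this package's definitions of an
  otherwise undisclosed in-house QC idea; treat cross-study VP comparisons
  accordingly.
* The pathogenicity engine is a rule-based emulation, not ACMG; its
  thresholds (AF 0.005, 4/6 predictors) are defaults, not community
  standards.
* Duplication calling is intrinsically harder (+0.585 vs −1 signal); expect
  lower duplication sensitivity at matched depth, and rely on BAF support
  for single-exon gains.
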