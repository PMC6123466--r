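---
title: "Tumor-only somatic mutation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic mutation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumoronly)
```

## The problem

Archival FFPE tumor specimens from long-follow-up breast cancer cohorts
rarely come with matched germline DNA. Calling somatic mutations from
tumor-only sequencing therefore has to separate three populations of
variant calls — true somatic mutations, residual germline polymorphisms,
and recurrent technical artifacts — using external reference data instead
of a matched normal. `tumoronly` implements that separation as a
deterministic filtering cascade, and the downstream association and
prognostic analyses that motivate it: hotspot discovery against a
multi-study mutation catalog, subtype and co-occurrence testing, and a
gated, permutation-adjusted survival screen.

## The filtering cascade

Stages run in a fixed order; every stage is evaluated for every variant
that reached the cascade (no short-circuiting), and a variant's final
status cites the first failing stage, which makes the trace table a
complete audit of every decision.

1. **Target restriction** — variants must lie inside the capture design
   (1-based inclusive intervals; BED input is converted on read).
2. **Population allele frequency** — a variant with minor allele
   frequency *strictly greater* than 0.1% in any of three population
   resources is removed. Absence from the table is informative (MAF 0).
3. **Unmatched-normal calls** — removal when the same variant was called
   in 10 or more of the 151 unmatched normal exomes. This catches common
   pipeline artifacts and polymorphisms the population resources miss.
4. **Exome read-count panel** — a panel sample "has evidence" of a
   variant when it shows at least 3 supporting reads, at least 1% VAF and
   at least 20x coverage; removal when at least 1% of the 912-sample
   panel has evidence. The fraction applies to the panel size actually
   loaded, not a hard-coded 10-of-912.
5. **Genome read-count panel** — same evidence rule over an 87-sample
   whole-genome panel, removal at 2 or more evidence samples. This
   second panel exists because some loci (two recurrent indel sites in
   the motivating data) are poorly covered by exome capture.
6. **Binomial LLR somatic classifier** — see below.

**Rescue** runs last: at curated knowledge-base sites (clinically or
functionally established hotspots), a call is emitted wherever at least 5
reads support the variant with at least 1% VAF and 20x coverage. Rescued
calls are exempt from the LLR stage and flagged `rescued` in the trace.
Boundary semantics are deliberate: "greater than 0.1%" is
strict, "10 or more" / "at least 3 / 5" / "20x" / "1%" / "80%" are
inclusive, and LLR *less than* 10 (SNV) / 6 (indel) is strict removal,
so equality with the threshold keeps the variant.

### The LLR classifier

The upstream literature names a Bayesian classifier without printing its
form. The form used here scores the supporting-read evidence against a
sequencing-error null:

$$
\mathrm{llr}(x, n) \;=\; \ln \mathrm{Bin}(x;\, n, \hat p)\; -\;
\ln \mathrm{Bin}(x;\, n, p_{\mathrm{err}}),\qquad \hat p = x/n ,
$$

which simplifies to $n \cdot \mathrm{KL}(\hat p \,\|\, p_{\mathrm{err}})$
in natural-log units ($p_{\mathrm{err}} = 0.005$ by default,
configurable). A germline-heterozygote alternative (p = 0.5) was
considered and rejected: it would eliminate the many VAF ≈ 0.5 calls in
BRCA1/2 and ATM that the downstream germline-suspicion analysis exists to
examine. The error-null form asks only "is this read support explicable
by sequencing error?", which matches the intent of the thresholds
(10 natural-log units for SNVs, 6 for indels — the lower indel bar
reflects the lower per-locus indel miscall density, so equal evidence
is stronger for an indel). The
identity with the direct pmf ratio and monotonicity in $x$ above
$p_{\mathrm{err}}$ are both enforced by property tests.

## Variant-class policies

Carrier analyses run under four nested policies: `non_silent` (missense,
nonsense, frameshift, in-frame indel, proximal splice site, plus
RNA-gene variants only for whitelisted genes — MALAT1 by default),
`missense`, `fs_ns` (truncating: frameshift or nonsense), and
`fs_ns_splice`. Splice-region, UTR, intron and silent calls never count.
The nesting (`fs_ns` ⊂ `fs_ns_splice` ⊂ `non_silent`) is a tested
invariant of the mutation matrix.

## Hotspots and panel selection

Study and reference mutations are aggregated by (gene, amino-acid
position) — the position is the first integer of the protein change, and
splice-site events key by (gene, splice junction) so that six different
alterations of one donor site count as a single hotspot. Positions with
at least three mutations in either cohort enter a two-sided Fisher's
exact test of $[[k_s, N_s - k_s], [k_r, N_r - k_r]]$ (minimum-likelihood
two-sided rule, the convention of mainstream statistical software).
Benjamini-Hochberg q-values are reported alongside raw p, and a position
is flagged novel when q < 0.05 with the study proportion above the
reference proportion. The reference denominator $N_r$ comes from the
catalog metadata, since a per-position denominator is not recoverable
from a mutation list. Gene-panel selection from the same catalog encodes
a two-clause rule: recurrence ≥ 2%, or recurrence ≥ 1% with druggability
(strictly more than two druggable categories or more than two
anti-cancer-drug interactions).

## Association testing

The choice between Fisher's exact and chi-squared tests is codified
rather than discretionary: Fisher for any 2×2 table or whenever an
expected cell is below 5, chi-squared otherwise. Continuous covariates use a
Kolmogorov–Smirnov normality screen per group (α = 0.05, configurable):
two-sample Welch t-test when both groups look normal, Mann–Whitney U
otherwise. Group-mean comparisons are unpaired (Welch): the compared
carrier and non-carrier sets are disjoint patients. Co-occurrence and mutual exclusivity are tested for all pairs among
the top seven most-mutated genes (21 tests, one BH family).
BH families elsewhere are one per (policy × covariate) across the gene
panel. The q < 0.2 reportability threshold is a label in the output,
never a filter.

The VAF germline-suspicion report counts variants at VAF strictly above
40% and 60% in flagged genes (BRCA1, BRCA2, ATM by default) — in impure
tumor samples a clonal heterozygous somatic variant is expected near
purity/2, so VAFs that high are germline-suspect — and compares mean VAF
against all other genes with the same normality-gated continuous test.

## Survival screening

Kaplan–Meier estimation and the k-group log-rank (Mantel–Cox) test back
the univariate screen; Cox proportional-hazards fits use Efron tie
handling (configurable to Breslow, recorded in the output metadata).
Screens are gated before any test: at least 15 carriers under
non-silent/missense policies, at least 8 under truncating policies;
gated-out genes are reported with their gate status and no statistics.

The multivariate model adds node status (1–3 and 4+ vs 0), grade (3 vs
1/2) and tumor-size category (2/3/4 vs 1) as dummies, with optional
pre-computed boolean covariates (e.g. CNV flags) from the configuration.
To address non-proportional hazards and separate early from late effects,
each subject is expanded into counting-process episodes split at year 5,
and every covariate receives period-specific copies, yielding early/late
coefficient pairs. Episode expansion conserves total follow-up time and
event counts (tested). A period with no episodes — or a clinical dummy
with no variation in the analyzed subset — is dropped from the design
rather than failing the fit. With two mutation coefficients per gene, the
gene-level p-value used for BH and for the permutation statistic is the
smaller of the early and late Wald p-values.

### Min-p permutation adjustment

Family-wise multiplicity is handled by outcome permutation: at each of B
permutations (default 1000), the survival outcome and clinical covariates
are permuted *jointly* while the mutation matrix stays fixed, the same
Cox model is refitted for every gated gene, and the minimum p-value
across genes is recorded. A gene's adjusted p is the proportion of
permutations whose minimum is less than or equal to the gene's observed
p — ties count against the gene, the conservative reading. Failed refits
contribute p = 1 for that permutation. Two numerical notes: the estimate
has granularity 1/B, so an observed p below 1/B can receive an adjusted
value of 0; and when there are no clinical covariates and no episode
split the refits run through a vectorized Newton solver on the partial
likelihood (Breslow weights — event times are continuous in the intended
inputs, so ties have probability zero), cross-checked against the
reference implementation to 1e-6. Observed and permuted fits always use
the same code path, so the permutation distribution matches the observed
statistic's model specification exactly.

## The synthetic cohort generator

The generator exists so that every stage above is testable without
access-restricted patient data. It emulates a targeted-capture tumor-only
FFPE cohort:

* **Read counts**: depth per site is negative-binomial (mean 135.8×,
  dispersion 8 — the coverage profile of the motivating cohorts);
  variant reads are binomial with success probability
  $v(1-e) + (1-v)e/3$ for true VAF $v$ and per-read miscall rate
  $e = 10^{-3}$.
* **Somatic variants**: clonal heterozygous, true VAF = purity/2, with
  purity ~ Beta (mean 0.60, sd 0.12, floor 0.05) reflecting
  macrodissected tumor-rich cores. Per-gene mutation probabilities
  default to the recurrence ranking of ER+ breast cancer (PIK3CA
  highest at 41%, then TP53, MLL3, MAP3K1, ...), with gene-specific
  consequence mixes, hotspot concentration for PIK3CA-like genes,
  subtype enrichment weights, and per-endpoint log-hazard ratios.
* **Germline contaminants**: Poisson(2) per sample, drawn from a pool of
  sites with population MAFs log-uniform on [1e-5, 0.2] (sampling
  weighted by MAF, as common polymorphisms are the likelier leaks), VAF
  Beta(30, 30) around 0.5 — heterozygote with FFPE noise, no new
  per-site parameters.
* **Artifacts**: Poisson(5) recurrent sites per cohort, appearing in 10%
  of tumor samples at VAF uniform on [0.01, 0.10] (the low-VAF alignment
  artifacts the read-count panels are designed to catch), with
  qualifying evidence in about 5% of panel-of-normals samples.
* **Survival**: exponential baseline (hazard 0.024/year, roughly a 30%
  15-year event rate) with per-sample hazard multiplied by
  $\exp(\sum_g \beta_g \, \mathrm{carrier}_g)$; administrative censoring
  at 25 years plus random exponential censoring at rate 0.02. A Weibull
  baseline is available through the configuration.
* **Subtypes**: multinomial over (LumA, LumB, HER2E, Basal, Normal) with
  defaults (0.50, 0.42, 0.04, 0.02, 0.02), the composition of an older
  tamoxifen-treated ER+ cohort.
* **Reference panels**: germline sites carry their assigned MAF in all
  three population resources and appear in the unmatched-normal calls at
  the carrier frequency $1-(1-q)^2$; artifact sites get qualifying
  read-count rows at the configured prevalence; somatic sites are absent
  from every panel by construction.

All randomness flows from one root seed; submodules derive child seeds
from fixed labels, so adding a generator stage never perturbs the
others, and a fixed seed gives byte-identical output files (UTF-8, LF,
fixed numeric formatting).

**What the generator does not emulate** — and what passing tests
therefore cannot show about real data: read-level errors and mapping
artifacts (no FASTQ/BAM simulation), subclonal architecture (every
somatic variant is clonal), copy-number variation and its effect on VAF,
FFPE deamination spectra beyond a symmetric VAF jitter, and germline
sites systematically absent from population resources (the de novo
BRCA1/2-like case: such variants are generated, but their panel behavior
is idealized). Cascade sensitivity/specificity measured on synthetic
cohorts is an internal-consistency check, not an estimate of performance
on real tumors.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in memory; ref/alt in VCF
  style; BED converts on IO.
* "20x coverage" is inclusive (≥) in panel-evidence and rescue rules; the
  sample-QC phrase "greater than 20x" is strict for the depth used when
  computing coverage fractions upstream. Both are configurable.
* Degenerate inputs fail loudly: empty target sets, zero-depth variants
  at the classifier, single-level factors, groups of size < 2,
  constant covariates in user-supplied Cox designs, B < 1 permutations.
* The manual-review step of the motivating study is replaced by the
  machine-readable filter trace; there is no interactive stage.
* Problem sizes in the test suite (cohorts of 50–2000 samples, B of
  10–200, 100-replicate null studies) were chosen as the smallest sizes
  at which the Monte-Carlo bounds in the checks are meaningful.

## Known limitations

The reference-cohort denominator for hotspot testing assumes all catalog
samples were assessable at every position. The permutation adjustment's
plain-proportion estimator is the definition given above; users who need
strictly positive adjusted p-values should raise B. The KS normality
screen uses estimated moments (a Lilliefors-style correction is not
applied), which is anti-conservative for small groups; with the default
α = 0.05 this errs toward the rank test, the safer branch.
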