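---
title: "Methods: cohort-level analysis of matched tumor-normal targeted panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level analysis of matched tumor-normal targeted panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcohort)
```

`panelcohort` implements the cohort-level computations used when a targeted
capture panel (here a 363-gene design) is sequenced at high depth on matched
tumor and normal samples across two clinical groups — a carcinoma group (EEC,
endometrioid endometrial carcinoma) and its precursor-lesion group (EIN,
endometrial intraepithelial neoplasia). This vignette describes each model
and procedure, the tunable parameters, what the synthetic-cohort generator
does and does not emulate, and the numerical conventions.

## Somatic QC and tumor mutational burden

A somatic call qualifies for burden counting when it is a single-nucleotide
variant with sequencing depth **strictly greater than 150 reads** and
alt-allele fraction **at or above 0.03**. Both bounds are deliberate about
their open/closed sides (a call at exactly 150 reads fails; a VAF of exactly
0.03 passes) and both are configurable through `filter_policy()`. Indels are
excluded from the default burden count because the burden definition counts
SNVs only; `snv_only = FALSE` includes them for sensitivity analyses. The
depth filter is applied to the tumor-sample depth; the panel's matched-normal
depth does not enter the filter.

TMB for a sample is

$$\mathrm{TMB} = \frac{\#\,\text{qualifying SNVs}}{\text{panel Mb}} \times f,$$

where panel Mb is the interrogated territory (default: the bundled panel's
1.2 Mb footprint) and $f$ is a single multiplicative whole-exome
extrapolation factor. Published panel pipelines extrapolate panel burden to
the exome with proprietary calibrations; in the absence of a specified
algorithm we expose the extrapolation as one explicit multiplier with
default 1 (i.e. panel-level TMB), and document that choice rather than hide
it.

**Hypermutation.** Targeted panels of this design separate cleanly into a
background population (roughly 0–48 somatic mutations per sample, median
about 6) and a hypermutated tail (about 141–277 mutations) attributable to
defects in DNA damage repair: the proofreading polymerases POLE/POLQ and the
mismatch-repair genes MSH2, MSH6, MLH1, MLH3, PMS1, PMS2. The default
hypermutation threshold of 100 mutations sits in the wide empty gap between
those two ranges; because the two populations are separated by a factor of
about three, the classification is insensitive to the exact choice. The
threshold is inclusive (a count of exactly 100 is hypermutated) and
configurable. A sample is DDR-flagged when it carries at least one somatic
variant in the DDR gene set.

**Group comparison.** TMB is compared between groups with the two-sided
Mann–Whitney rank test. The test is unnamed in most clinical reports; we
chose Mann–Whitney as the standard nonparametric median-shift test for
skewed burden distributions. When both groups have at most eight samples the
p-value is computed by exhaustive permutation enumeration (exact even under
ties, which burden counts produce often); larger groups use the normal
approximation with tie and continuity correction. `exclude_ddr = TRUE`
removes DDR-flagged samples from *both* groups before comparing, isolating
the burden difference not driven by repair-defect hypermutation.

## Region-based copy-number calling

The caller follows the depth-ratio design used by clinical panel pipelines.
Each gene's target is divided into regions (default: 100-bp tiles); for each
region the log2 ratio of tumor to matched-normal mean depth is

$$\mathrm{LRR} = \log_2 \frac{d_\mathrm{tumor}}{d_\mathrm{normal}}.$$

A region is **amplified** when LRR > 0.35 and **deleted** when LRR < −0.5,
both strict. A gene is called amplified (deleted) when that type accounts
for **strictly more than 70%** of the gene's evaluable regions; the
fraction's denominator is evaluable regions only.

Three numerical conventions deserve note:

* *Deletion bound.* The formulation this mirrors prints its deletion cutoff
  as LRR < 0.5, which cannot be meant literally — it would classify every
  neutral region (LRR ≈ 0) as deleted. We use −0.5, the negative mirror of
  a positive-side bound, keep it configurable (`cnv_thresholds()`), and flag
  the asymmetry (−0.5 vs +0.35) rather than silently symmetrise it.
* *Evaluability.* Regions with matched-normal depth below 20 reads (or zero
  tumor depth) are excluded from both numerator and denominator instead of
  producing infinite or unstable ratios. A gene with no evaluable regions
  returns an explicit no-call with a reason, not a "none".
* *Majority over evaluable regions.* Whether the 70% majority is taken over
  all regions or evaluable ones is ambiguous in the source formulation; we
  use evaluable regions, since uncovered tiles carry no copy-number
  information.

The caller performs no cross-sample normalisation, GC correction,
segmentation or purity adjustment: it is the pure paired ratio, which
presumes tumor and normal depths are library-size comparable over each
region. Coordinates follow the BED convention (0-based, half-open)
throughout.

## Mutation-frequency statistics

Per-gene prevalence counts each sample once per gene regardless of variant
multiplicity. Group differences are tested on the 2×2 table
(group × mutated status) with the standard selection policy: **Yates
continuity-corrected Pearson χ²** when every expected cell count is at
least 5 and no margin is zero, otherwise the **two-sided Fisher exact
test** (sum of all tables with point probability not exceeding the observed
one — the convention of mainstream statistical software, not tail
doubling). Cohorts of ~100 samples with genes mutated in zero to a handful
of one group sit exactly at the boundary where this choice matters, so the
test actually used is always recorded in the output. No multiple-testing
correction is applied by default (matching how such cohort tables are
conventionally reported); Benjamini–Hochberg is available behind
`correction = "BH"`.

Co-mutation treats a sample as positive when it carries at least one
somatic variant in each gene of the pair, and tests the group association of
that indicator with the same policy.

The Fisher p-value is computed in-package (vectorised over tables) because
the validation suite sweeps every 2×2 table with total up to 40; the
implementation is cross-checked in the tests both against
`stats::fisher.test` and against an independent binomial-coefficient
enumeration.

## Germline screening

Germline variants arrive annotated (ClinVar-style pathogenicity labels);
the screen never predicts pathogenicity. Only pathogenic and
likely-pathogenic records are retained. Findings are classed *Lynch*
(MLH1, MSH2, MSH6, PMS2) or *non-Lynch* by gene. Genes whose predisposition
phenotype is recessive — MUTYH by default — yield an *actionable* finding
only when the variant is biallelic (homozygous); monoallelic hits are
retained as carrier status. Other genes with occasional homozygous findings
(e.g. GALNT12) are left dominant-style, since cohort reports count such
findings without a biallelic requirement. An optional rule
(`truncating_upgrade`, off by default) promotes unannotated truncating
variants to likely-pathogenic. Carrier rates use patient-level counting:
the overall rate is carriers over all patients; the Lynch/MMR rate is
reported within the carcinoma group, matching how both rates are quoted in
cohort studies.

## The synthetic-cohort generator

Controlled-access raw data cannot ship with an analysis package, so the
generator produces cohorts with the statistical structure the analyses
assume, plus deterministic fixtures that reproduce printed count tables
exactly.

`generate_cohort()` draws, per sample: group and clinical covariates;
per-gene mutation status as independent Bernoulli trials at the configured
group prevalence (defaults: the bundled 23-gene count table for a 79 EEC /
36 EIN cohort); a background mutation count (negative binomial, mean 8,
size 1.2 — median ≈ 6, range ≈ 0–50) placed in panel genes *outside* the
prevalence map, so background noise cannot distort the configured
frequencies; hypermutator status (probability 5/115) with an excess count
(negative binomial, mean 180, size 25 — range ≈ 140–280) and a guaranteed
DDR-gene variant, mirroring the repair-defect aetiology; variant depth
(negative binomial around 1690× tumor / 2389× normal, size 50) and VAF
(Beta with mean 0.25, concentration 20, consistent with a 0.03 reporting
floor); region-depth profiles for a configurable gene subset with CNV
spike-ins multiplying carrier tumor depths by $2^{\text{fold}}$; and
germline findings at configurable carrier rates. Region pairs are drawn
depth-balanced (both members at the tumor mean): the pure paired ratio
presumes library-size-matched coverage, and the global tumor/normal mean
asymmetry is a sequencing-throughput artifact that ratio callers remove
upstream.

Everything is a deterministic function of the config, including its seed;
truth labels (hypermutators, CNV carriers, configured prevalences, germline
carriers) are attached for validating the callers.

`fixture_from_counts()` is the deterministic inverse of
`prevalence_table()`: given per-gene mutated-sample counts it places each
gene's carriers as a contiguous wrapped block of samples starting at a
per-gene offset. Marginal counts are reproduced bit-exactly, and offsets
let fixtures also encode pairwise overlaps — the bundled table's offsets
reproduce a 24/79-vs-4/36 co-mutation pattern alongside all marginals.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence-context mutation signatures, linkage or
mutual exclusivity beyond the configured pairwise overlaps, GC-dependent
coverage waves, tumor purity and subclonality (VAFs are drawn i.i.d.),
segment-scale CNV structure spanning neighbouring genes, and panel-specific
capture bias. Results on synthetic cohorts validate the *computations*, not
the biology of any particular dataset.

## Problem sizes and determinism

The test suite exercises cohorts of 10–200 samples per group (2000 per
group for the prevalence-convergence property, 100 replicates of 200+200
for the differential-power property) — sizes at which every binomial
standard error relevant to the assertions is a few percent or less.
Reports are written with doubles at six significant digits and fixed sort
orders, so repeated runs are byte-identical; missing values are encoded as
`.` in all TSV outputs.

## Known limitations

* The association-test selection policy cannot reproduce every p-value a
  mixed SPSS-style workflow produces, because such workflows do not apply
  one uniform rule at sparse tables; the policy and the test used are
  always reported instead.
* TMB extrapolation to the whole exome is a single multiplier; no
  gene-content calibration is attempted.
* The CNV caller is gene-local and threshold-based: no segmentation, no
  allele-specific copy number, no purity/ploidy model.
* Germline screening consumes annotations; it performs no ACMG criterion
  evaluation and no family-history modelling.
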