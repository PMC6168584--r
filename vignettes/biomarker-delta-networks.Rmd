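---
title: "Longitudinal biomarker change networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal biomarker change networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodelta)
```

# The analysis problem

Direct-to-consumer wellness platforms accumulate longitudinal blood-test
data on generally healthy adults: each participant has a baseline draw and
at least one follow-up draw, on one of several overlapping biomarker
panels, together with a record of which lifestyle interventions they chose.
**biodelta** implements the full analysis chain for such cohorts:

1. **Quality filtering** of physiologically implausible values by
   per-biomarker percentile limits.
2. A **biomarker-change ("delta") correlation network**: pairwise-complete
   Spearman tests on follow-up-minus-baseline changes, with
   Benjamini-Hochberg (BH) false-discovery-rate control.
3. **Community detection** on the correlation-derived distance
   $d_{ij} = 1 - |\mathrm{cor}_{ij}|$ by hierarchical clustering with an
   adaptive (dynamic) tree cut.
4. **Change testing in out-of-range subgroups**: Wilcoxon signed-rank tests
   of baseline-to-follow-up change, restricted to participants whose
   baseline lay beyond a clinical direction-of-risk threshold, with
   seasonal adjustment of vitamin D.
5. **Intervention-association scans**: Monte-Carlo chi-square tests of
   2x2 improvement-by-choice tables, BH-adjusted across the scanned family.

Because raw cohorts of this kind are not freely redistributable, the
package includes a first-class **synthetic-cohort generator** whose planted
structure (correlation blocks, panels, seasonal offsets, intervention
effects) mirrors the statistical features the analyses rely on. Every
pipeline stage is validated against that planted truth.

# Statistical model and conventions

## Deltas and pairwise-complete Spearman correlation

The unit of analysis is the per-(participant, biomarker) change
$\Delta = x_{\text{follow-up}} - x_{\text{baseline}}$, a raw difference
with no normalisation. For each unordered biomarker pair the Spearman
coefficient is the Pearson correlation of average-tied ranks over the
participants with both deltas observed; the sample size $n$ therefore
varies per pair (panel-based missingness). The two-sided p-value uses the
t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom, with $|\rho| = 1 \Rightarrow p = 0$ by convention. Pairs with
fewer than `min_n` (default 10) shared participants, or with zero rank
variance, are excluded from the analysis *and from the BH family*, so the
family is exactly the set of tested pairs — with a full 40-biomarker panel,
$\binom{40}{2} = 780$ comparisons. Edges of the reported network are the
pairs with BH-adjusted $q < \alpha$ (default 0.05), weighted by the signed
$\rho$; isolated nodes are retained.

## Community detection

The clustering distance is $d_{ij} = 1 - |\rho_{ij}|$ (untestable pairs are
imputed at $\rho = 0$, i.e. maximal distance, with a warning). Linkage is
average by default — the conventional companion of correlation-based
distances — with complete and single selectable; leaves are ordered
lexicographically before agglomeration so that merges, including ties, are
deterministic.

Since such dendrograms rarely admit a single clean cut height, clusters are
extracted with an adaptive decomposition (`dynamicTreeCut()`):

* merges above `cut_height_fraction` (default 0.99) of the maximum height
  are discarded, unless *every* merge sits above that line (a homogeneous
  tree, which stays whole — forcing the cut there would shatter a
  structureless tree into singletons);
* each remaining branch is recursively split wherever its internal merge
  heights show a gap exceeding `split_gap_fraction` (default 0.35) of the
  branch's height range, taken from zero to its top merge — using the top
  height rather than the max-min spread keeps tight blocks, whose absolute
  height spread is small, from being over-split;
* clusters smaller than `min_cluster_size` (default 3) are dissolved:
  members join their nearest cluster by average distance when that distance
  is within the cluster's own merge height, else they are labelled 0
  (unassigned).

Labels are arbitrary (1 = largest cluster): assignments are meaningful only
up to permutation, and the package does not claim label-level replication
of any particular reference implementation. Validation is by recovery:
planted blocks with within-block Pearson 0.7 at $n = 1000$ are recovered
with median adjusted Rand index above 0.9 across replicates, and whenever a
single static cut yields clean clusters the adaptive cut returns the same
partition.

## Out-of-range change testing

Each biomarker has one *direction of risk* — the side on which individuals
are most commonly out of range — and a strict threshold (a value exactly at
the threshold is in range), sex-specific where clinical practice is
(e.g. ALT >46 male / >29 female). The bundled rule set covers 17 common
markers with Quest-style cutoffs; testosterone and free testosterone are
additionally flagged for sex-stratified analysis, and participants of
unknown sex are excluded only from sex-specific rules.

Change in the out-of-range subgroup (and optionally the full population) is
tested with the Wilcoxon signed-rank test: zero differences dropped before
ranking (Pratt's treatment available behind a flag), average ties, and

* an **exact** sign-flip null distribution, conditional on the observed
  (possibly tied) ranks, for effective $n \le 25$ — computed by dynamic
  programming over doubled ranks, which reproduces brute-force enumeration
  of all $2^n$ sign patterns exactly, ties included;
* a **normal approximation** with tie-corrected variance
  $\sigma^2 = \sum_i r_i^2/4$ and continuity correction beyond that.

Groups smaller than `min_group` (default 20) are omitted and logged.
P-values in the change table are deliberately *not* multiplicity-adjusted.
Medians and IQRs are reported for exactly the tested pairs; when seasonal
adjustment applies, both the adjusted deltas and summaries refer to the
adjusted values (callers wanting raw summaries simply tabulate unadjusted
pairs, which the API keeps available). BMI change is tested with a paired
t-test.

## Seasonal adjustment

Vitamin D is seasonally elevated. The model pools *all* of the biomarker's
measurements (baseline and follow-up) and fits
$\text{value} \sim \beta_0 + \beta_1 \cdot \text{summer}$ by OLS, where
summer means a draw date in June-September. The fitted $\beta_1$ is then
subtracted from every summer measurement before change testing; winter
values are never touched, and a pair with both tests in summer has an
unchanged delta (the offset cancels). Fitting requires at least 10
measurements in each season. The bundled default configuration plants a
2.5-unit offset in the synthetic presets.

## Intervention association

For each scanned biomarker, *improvement* is any strictly nonzero delta
opposite the direction of risk (a delta of exactly 0 is not improvement —
the conservative reading of "any magnitude"). For each of the `top_k`
most-chosen interventions (ties broken lexicographically), the entire
population with a pair for that biomarker is cross-tabulated as improvement
x choice; participants with no recorded choices count as not choosing every
intervention. The Pearson chi-square statistic (no continuity correction)
gets a Monte-Carlo p-value by simulating `B` tables with both margins fixed
(multivariate hypergeometric null, Patefield's algorithm):
$p_{MC} = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(B+1)$. The asymptotic
$\chi^2_1$ p-value is reported alongside, BH adjustment is applied across
the scanned family, and nominal ($p_{MC} < 0.05$) flags are reported
separately.

A property worth knowing: $p_{MC}$ and the asymptotic p agree closely in
the significance range at cohort scale ($|p_{MC} - p_{asym}| < 0.01$ for
$N \approx 1000$ tables with $p \lesssim 0.03$), but at mid-range p the
margins-fixed null is discrete and the observed statistic's tie atom — of
order $1/\sqrt{N}$ — is counted fully in the $\ge$ tail, so differences of
a few percent are expected there (the identical behaviour is seen in
`chisq.test(simulate.p.value = TRUE)`). Decisions should rest on $p_{MC}$;
the asymptotic value is a cross-check.

# Quality filtering

Plausibility limits are the 0.5 and 99.5 percentiles of a per-biomarker
reference sample, with percentiles defined by linear interpolation between
closest order statistics (`quantile(type = 7)`) — fixed and stated because
percentile conventions differ across ecosystems. Derivation refuses
biomarkers with fewer than 200 reference values or degenerate limits. A
pair is removed when its baseline *or* follow-up lies strictly outside
`[lower, upper]` — limits are inclusive, the conservative boundary choice —
and removal is always per (participant, biomarker), never whole-participant.
The shipped default limits are synthetic: constructed once from the
marginals of the package's own `full` preset, not from any population
survey; real analyses should derive limits from a genuine reference sample
with `deriveLimits()`.

# The synthetic-cohort generator

`generateCohort()` is a deterministic function of a validated config
(including its seed) and leaves the caller's RNG untouched. Per
participant: a panel is drawn by weight; baselines are independent normals
per biomarker; deltas come from a multivariate normal with a block
correlation structure (within-block `r_within`, cross-block `r_between`,
independence outside blocks; positive semi-definiteness is validated at
construction, before any sampling). Baseline dates fall in summer
(June-September) with probability `summer_fraction` (default 0.33, roughly
the uniform-calendar value); the follow-up date adds the minimum gap plus a
log-normal extra (default median 90 days, right-skewed, emulating the
heavy-tailed retest-gap distributions such platforms see). Summer
membership of each measurement is derived from its date, never sampled
independently, and seasonal biomarkers gain their offset on summer-dated
measurements. Intervention choice is Bernoulli with a logistic boost
(`choice_oor_boost`, log-odds) when the targeted biomarker is measured and
out of range at baseline; choosing an intervention adds its planted shift
to the targeted biomarker's delta.

Because deltas are multivariate normal, the *population Spearman*
correlation implied by a planted Pearson $r$ is $(6/\pi)\arcsin(r/2)$
(`spearmanFromPearson()`); truth-recovery tests compare against this
transform, not against $r$ itself — at $r = 0.7$ the Spearman target is
about 0.683.

Presets: `full` (40 biomarkers with plausible clinical marginals,
1000 participants, 7 overlapping panels, six blocks at `r_within = 0.5`,
2.5-unit vitamin D summer offset, a dozen interventions of which five carry
planted shifts — the vitamin D supplement at +8 units with 20% base uptake
is sized to be detectable around $n \approx 300$); `tiny` (6 biomarkers,
two blocks at 0.7, 50 participants; the whole pipeline in seconds);
`null` (the full panel with every planted effect zeroed, for
calibration studies). Out-of-range enrichment is achieved by placing
baseline means near the clinical thresholds (e.g. vitamin D mean 32 against
a <30 threshold), not by truncation, keeping marginals simple.

What the generator does **not** emulate: skewed or heavy-tailed marginals
(everything is Gaussian), nonlinear or rank-degenerate dependence,
drop-out correlated with health status, adherence dynamics, or
within-participant technical replicates. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to real-data pathologies; the rank-based and margins-fixed
procedures are, however, exactly the tools one would choose for such
pathologies.

# Numerical and design choices

* **Follow-up selection** with more than two tests: earliest follow-up at
  least `min_gap_days` (default 30, whole-day arithmetic on calendar
  dates) strictly after the earliest test; `strategy = "latest"`
  selectable. Earliest maximises usable pairs and is deterministic.
* **BH family**: exactly the tested pairs; q-values come from the standard
  step-up procedure.
* **Exact-vs-normal switch** for the signed-rank test at effective
  $n = 25$; continuity correction in the normal regime.
* **Monte-Carlo seeds**: `chi2MonteCarlo()` takes an explicit seed and
  restores the caller's RNG state; `interventionScan()` derives per-test
  seeds deterministically from its seed argument.
* **Degenerate inputs**: all-zero differences give a flagged "no change"
  ($p = 1$); constant vectors are untestable for correlation; zero-margin
  tables are untestable errors; constant reference samples refuse limit
  derivation.
* **Problem sizes in the validation suite** were chosen to make the
  statistical checks sharp at interactive run times: 50-replicate designs
  at $n = 1000$-$2000$ for calibration, power and recovery; 100 replicates
  at $n = 2000$ for seasonal-offset recovery; 5000 replicates for the
  Wilcoxon type-I-error check.

# Known limitations

* The dynamic tree cut implements the adaptive-decomposition contract
  described above; it is not a line-for-line port of any published
  implementation, and label-level agreement with such implementations is
  not claimed.
* Correlation entries are marginal associations; no partial correlations
  or nonlinear dependence measures are provided.
* The out-of-range change analysis is observational: regression to the
  mean is an interpretive caveat the package deliberately does not model
  or correct.
* Units are carried as opaque strings and never converted; rule sets and
  measurement data must agree on units by construction.
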