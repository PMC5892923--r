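---
title: "Models and methods behind epidige"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epidige}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidige)
```

## The experimental design

epidige analyses paired 2D-DIGE studies: each patient contributes a
high-spiking (H) and a low-spiking (L) neocortical sample, fractionated
into cytosol, nuclear (P1) and membrane (P2) fractions, each analysed as an
independent data set. Every gel co-resolves three dye channels — the two
samples of one patient plus a pooled internal standard (Cy2) mixed from
equal amounts of every sample in the study — and every patient is run on
two technical-replicate gels with the sample dyes swapped, cancelling
dye-specific bias. `dige_design()` encodes this layout and
`validate_design()` enforces its invariants (one standard channel per gel,
reciprocal dye assignment within a replicate pair, both conditions per
patient). Six patients give 12 gels and 36 analytical images per fraction.

## Normalization

Two schemes are implemented because they answer different questions:

* **Ratiometric** (`ratiometric_normalize()`): each sample-channel volume
  is divided by the same spot's standard-channel volume on the same gel,
  and each image's ratios are then divided by their median over spots.
  The ratio to the common standard makes a spot comparable across gels;
  the median centring removes residual per-image gain *exactly* — the
  output is invariant to multiplying any image by any positive constant.
  The gel-analysis software that produces such exports does not publish
  its formula; the spot-wise ratio with median log-gain centring is this
  package's definition, chosen to reproduce the two properties downstream
  analysis relies on (cross-gel comparability through the standard,
  scale-free ratios). Whether the original centres by the median or by
  total intensity is unknown; the median is robust to a handful of
  strongly changing spots.
* **Total-volume** (`total_volume_normalize()`): every image is scaled to
  sum to 10^6 volume units. Unlike the ratiometric scheme this preserves
  proportions *between* spots on one image, so isoform spots can be
  summed into protein totals and data from all three fractions can be
  united for joint clustering. Totals-based operations
  (`aggregate_isoforms()`) refuse ratiometric input for this reason.

Technical replicates are averaged arithmetically on the normalized
abundance scale (`average_replicates()`), not on the log scale, matching
the procedure the exports are built for.

## Differential testing and SOI selection

The primary statistic is the natural-log fold change ln(H/L) per spot,
computed within each replicate gel (so each patient contributes dye-swapped
replicate values). `test_spots()` tests its mean against zero with
technical replicates nested in patients. For the balanced design this
random-intercept model reduces *exactly* to a one-sample t-test on the
per-patient replicate means with n − 1 degrees of freedom; the test suite
verifies agreement with a general REML random-intercept fit (Satterthwaite
degrees of freedom) to below 1e-6 in p. Note that `nlme::lme`'s printed
p-value for the same model uses an N − m "within-group" df convention and
therefore differs; the t statistic is identical in all three routes.

Significance uses p < 0.05 and |FC| ≥ 1.25 (ties at the threshold pass),
with no multiple-testing correction by default — recurrence across
isoforms and patients, not a corrected p, is the replication logic of this
design. Benjamini–Hochberg adjustment is available behind the `adjust`
argument.

"Variable" spots capture changes consistent within patients but
heterogeneous across them: the per-patient screen (`per_patient_screen()`)
flags |FC| ≥ 1.25, and `select_variable()` requires the flag in at least
half the patients (3 of 6). A stricter variant that additionally gates on a
per-patient one-way ANOVA of log abundances (H vs L replicates) is
available via `anova_gate = TRUE`; the FC-only rule is the default because
it is the rule that defines the published SOI sets. SOIs are the union of
significant and variable spots, with fractions kept distinct.

## Expression-pattern clustering

SOIs are clustered by how their expression varies across the 12 samples.
Profiles are built from total-volume-normalized, replicate-averaged
abundances divided by the spot's pooled-standard level (its mean
standard-channel abundance over all gels). The division is the package's
design choice where the design was genuinely open: under Gower's
range-normalization, raw total-volume profiles are dominated by baseline
spot intensity, whereas the ratio-to-standard profile expresses the level
and direction of variation relative to the internal standard — the quantity
the clustering is meant to group — while staying in the only normalization
mode that permits uniting fractions.

Dissimilarity is Gower's metric (`gower_matrix()`): the mean over samples
of |x_is − x_js| / range_s, in [0, 1], scale-invariant per sample;
zero-range samples are dropped with a warning. Linkage is Ward's
minimum-variance method (`ward_linkage()`), by default the Lance–Williams
recurrence on *squared* dissimilarities (the `ward.D2` convention), since
Gower dissimilarities are not Euclidean distances and the squared-update
form is the textbook minimum-variance criterion; the classical `ward.D`
convention is selectable. The implementation delegates to `stats::hclust`;
a naive O(n³) re-implementation lives in the test suite as an independent
oracle and agrees on merge order and heights for random instances.

The tree is cut at K groups (`cut_to_k()`, default 37, an arbitrary
granularity choice for a few-hundred-SOI dataset). Stability is assessed by
leave-one-out over *samples* (`loocv_stability()`): each of the 12 sample
columns is dropped in turn, the profiles are re-clustered at the same K,
and a cluster's stability is the mean fraction of its spot pairs still
co-assigned. Leaving out samples, not spots, is an interpretation — the
procedure probes how much a cluster depends on any single tissue sample.

Clusters are labelled by marker panels (`default_marker_panels()`:
erythrocyte HBA1/HBB/CAT/CA1/BLVRB, plasma, fibrinogen, smooth muscle,
glial) when at least two distinct panel genes occur among member spots, and
scored per patient by the median member H/L ratio — the median rather than
the mean to resist isoform outliers; the aggregation is selectable. Scores
can be correlated with an external per-patient histology measure such as
the blood-vessel length ratio (`correlate_cluster_with_external()`),
dropping patients without the external value.

## Protein roll-up

`aggregate_isoforms()` sums a protein's isoform spots per sample (for the
GFAP-like protein: six ~50 kDa spots plus five 38–40 kDa low-MW species in
the nuclear fraction, with the 50 kDa subset analysable separately).
`paired_total_test()` runs the two-sided paired t-test across patients on
the natural-log totals — the scale on which fold changes are symmetric;
the raw-vs-log choice is not documented for the reference analysis, and the
log scale keeps the roll-up consistent with the spot-level test.
`fraction_ratio()` forms the cytosol/nuclear solubility ratio per patient,
with qualitative bands anchored at "about one-quarter" (histologically
normal) and "about equal" (pronounced astrogliosis).

`correlate_fc_with_spike()` relates the per-patient fold change (low/high)
to the spike-frequency difference Δspike = H − L. It reports the Pearson
coefficient with the t-transform p (`pearson_p_from_r()`: t = r√(n−2) /
√(1−r²), n−2 df; r = 0.96 at n = 6 gives 0.002), the least-squares
regression of Δspike on fold change, and Kendall's tau with an exact
two-sided p (`kendall_exact()`). The exact null distribution of tau is the
Mahonian (inversion-count) distribution, computed by dynamic programming,
so no n! enumeration is needed; the two-sided p is the null probability of
|tau| at least as large as observed — 2/720 ≈ 0.003 for six strictly
concordant pairs. Ties are refused in exact mode and handed to the tau-b
normal approximation.

## Gene-set enrichment

`fisher_enrichment()` is the one-sided hypergeometric upper tail for the
2×2 table, equivalent to Fisher's exact test for over-representation; the
test suite checks it against exhaustive enumeration for small universes.
Per patient, the gene list is the SOIs with |FC| ≥ 1.3 (`per_patient_lists()`),
with genes supported only inside an erythrocyte-labelled cluster removed —
blood-borne proteins track vascularity, not tissue biology. The universe
defaults to all genes annotated in the dataset and is configurable, since
the proprietary knowledge base the reference analysis used cannot be
reconstructed; results are comparable in structure, not content.
`cross_patient_comparison()` applies the recurrence rule (−log10 p ≥ 1.3 in
at least 3 patients) and ranks by the summed −log10 p with per-patient
contributions retained.

## The synthetic-study generator

`simulate_study()` emulates the measurement process the analysis assumes:

* true abundances log10-normal (mean 4.0, sd 0.5) with a per-patient
  abundance effect (sd 0.15 log10) shared by the patient's two samples —
  it cancels in within-patient fold changes but shapes cross-sample
  patterns;
* measurement `V = T × gain × ε` per image, gain uniform in [0.5, 2], ε
  log-normal with CV 0.10 — the reference study reports no
  technical-replicate CV, so 10% is a free parameter at the low end of
  what DIGE labs report, not a published value;
* the pooled standard channel carries the arithmetic mean of all samples'
  true abundances, mirroring the equal-amount pooled standard;
* 40 planted differential spots at |ln FC| = ln 1.6, sign drawn per
  protein, allocated evenly across fractions;
* isoform trains of 1–11 spots per protein with geometrically decaying
  sizes; ~15% of spots unidentified;
* marker clusters (23 erythrocyte, 10 plasma, 8 fibrinogen spots in the
  cytosol; 9 smooth-muscle spots in the membrane fraction) driven by
  latent per-sample factors at a configurable signal-to-noise ratio
  (default 5× the profile noise sd); the erythrocyte factor is the latent
  vascularity;
* a GFAP-like nuclear protein whose per-patient fold change (low/high)
  follows FC = Δspike/200 + 251/200 — strictly increasing in Δspike, the
  transposed form of the published regression line — plus low-MW spots
  with a mild opposite trend and cytosolic spots tuned to a
  histopathology-dependent cytosol/nuclear ratio (0.22 for normal up to
  1.0 for diffuse gliosis);
* patient metadata defaulting to the six-patient reference cohort
  (`epilepsy_cohort_metadata()`), with spike frequencies carried as the
  unit-less counts recorded clinically.

The generator is deterministic given the seed, with per-fraction
substreams derived from it so fractions can be regenerated independently.
The ground-truth record lists planted spots, marker memberships, latent
factors and the planted GFAP relation; `truth_recovery_report()` scores
sensitivity against the planted set and FDR/specificity against all truly
changing spots (planted, marker and GFAP-like — marker spots carry real
condition effects, so counting them as false positives would misstate the
error rate).

What the generator does **not** emulate: spatial spot overlap and
mis-matching across gels, background-subtraction artefacts, saturation,
missing spots, heavy-tailed or abundance-dependent noise, and correlated
biological co-regulation beyond the planted clusters. Passing tests
therefore demonstrate the correctness and calibration of the statistical
chain under its stated model, not robustness to gel-image pathology.

## Numerical choices and problem sizes

Fold-change thresholds use ≥, so ties at 1.25 or 1.3 pass. Degenerate
inputs are flagged rather than silently handled: zero between-patient
variance yields `degenerate = TRUE` with NA p; |r| = 1 reports the limit
p = 0 with a warning; constant inputs to a correlation error. Merge
tie-breaks follow `stats::hclust`; permuting spot order changes labels but
not partitions, which is what the tests assert. The test suite and the
acceptance script run simulations at 120–400 spots per fraction (2000 for
the null-calibration study, 1500 — the generator default — for the
parameter-recovery study), sizes chosen so each check isolates its
question at comfortable statistical resolution. Kendall's tau of the
recovered GFAP relation is a discrete statistic of a six-point ordering
whose closest planted gap (~0.07 in ln FC) is comparable to its
measurement noise (~0.06 sd), so the acceptance script reports its mean
over 11 independent replicate studies rather than a single draw.

## Known limitations

The ratiometric formula is a documented stand-in for an unpublished one.
The per-patient ANOVA variant of the screen assumes exactly the
gel-per-replicate structure of the reference design. Exact Kendall p-values
require tie-free data (spike-frequency differences and fold changes are
continuous, so ties are measure-zero in practice). Enrichment content
depends entirely on the supplied GMT collections. The cluster count K has
no automatic selection; it is an analyst's granularity choice.
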