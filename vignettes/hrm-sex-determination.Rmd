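---
title: "Sex determination from duplex RT-qPCR melt curves"
author: "meltsex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex determination from duplex RT-qPCR melt curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltsex)
```

## The assay and the analysis problem

Molecular sex determination in mammals usually relies on genomic DNA
(presence or absence of Y-linked loci such as *SRY*). Gene-expression
studies, however, extract RNA, and Y-linked genes are poorly expressed
outside the testis. An RNA-native alternative uses *XIST*, the X-inactivation
transcript: it is expressed in every somatic cell carrying two or more X
chromosomes, so its presence in mRNA marks a female (or an XXY individual)
and its absence a male.

The assay this package analyses is a duplex RT-qPCR: one reaction
co-amplifies a housekeeping control transcript (*ACTB*) and *XIST*. The two
amplicons melt at distinct temperatures, so a post-PCR melt curve — relative
fluorescence units (RFU) read every 0.5 °C — distinguishes them without gels
or probes. Female reactions show two melt transitions (*XIST* near 84 °C,
*ACTB* near 85.5 °C); male reactions show the single *ACTB* transition.
High-resolution melt (HRM) analysis turns this presence/absence signature
into automated well clustering and, with a replicate majority rule, into
per-sample sex calls that can be validated against DNA-based truth labels.

`meltsex` implements the full workflow: a synthetic duplex melt-curve
simulator with ground-truth labels, plate I/O, HRM normalization and
difference curves, shape/Tm clustering, anchor-based cluster sex mapping,
the majority-rule caller, and concordance reporting.

## The melt model behind the simulator

Each amplicon *k* in a well melts as a two-state (helix–coil) transition

$$f_k(T) = \frac{1}{1 + e^{(T - T_{m,k}) / w_k}},$$

the fraction still double-stranded at temperature $T$, with melting
temperature $T_{m,k}$ and width $w_k$. A well's raw fluorescence is

$$F(T) = (b_0 + b_1 T)\,\Big(r + \sum_k a_k f_k(T)\Big) + \varepsilon(T),$$

where $b_0 + b_1 T$ is the dye/background response ($b_1 < 0$: dye
fluorescence falls with temperature), $r$ a non-melting residual fraction,
$a_k$ each product's abundance and $\varepsilon$ additive Gaussian noise
scaled to the pre-melt amplitude. A per-well log-normal gain reproduces
well-to-well RFU spread. Because the baseline factor is exactly linear, the
two-line normalization below cancels it exactly in the noiseless limit —
which is what makes the normalization contracts testable.

Scenario generation encodes the assay semantics: every valid reaction
carries *ACTB*; XX and XXY karyotypes add *XIST*. Individuals heterozygous
for an *ACTB* polymorphism melt the control as two half-abundance
sub-products 0.3 °C apart, producing the characteristic
elevation-separating plateau without leaving their sex cluster. Samples
with RNA yield below 9 ng/µl draw low-template failure modes: complete
non-amplification, *XIST* dropout (the female well renders male-like — the
assay's documented misidentification mechanism), and primer-dimer products
melting far below both amplicons with correspondingly reduced amplicon
signal.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| temperature grid | 70–95, step 0.5 | °C | instrument melt step |
| *ACTB* $T_m$ | 85.5 | °C | common transition |
| *XIST* $T_m$ | 84.0 | °C | female-specific transition |
| transition width $w$ | 0.2 | °C | sharp amplicon melts; keeps both derivative peaks resolvable on a 0.5 °C grid (see below) |
| *XIST*:*ACTB* abundance | 0.55 | – | free calibration: the relative *XIST* signal is not a measured quantity; 0.55 puts the female shape difference (~0.3) well above the broadest merge threshold (0.10) |
| noise s.d. | 0.004 | pre-melt amplitude | typical plate-reader noise |
| per-well gain s.d. | 0.1 | log scale | well-to-well RFU spread |
| $T_m$ jitter s.d. | 0.005 | °C | instrument repeatability; bounded so complete linkage can still merge a full cohort (see below) |
| dropout threshold | 9.0 | ng/µl | reliability limit of *XIST* detection |
| dropout / dimer / non-amp prob. | 0.5 / 0.3 / 0.2 | per well below threshold | reproduce the qualitative low-yield failure taxonomy |
| primer-dimer $T_m$, width, abundance | 77.5, 0.2, 0.6 | °C, °C, – | melts distinctly below both amplicons, just under the pre-melt fit window |
| cohort yield profiles | means 5.6 / 55.0 / 71.4 | ng/µl | pilot, optimized and final-season extraction yields (log-normal; sdlog 0.35/0.6/0.55 are calibration choices) |
| sex ratio | 0.4 | – | ≈ 38 females per 101 sexed individuals in the validation cohort |

Seeding: one master seed; per-well seeds are stable hashes of
`(master, well_id)`, so plates are bit-reproducible and invariant to well
reordering.

## HRM processing

**Derivative melt peaks.** `negative_derivative()` computes $-dF/dT$ by
central differences, optionally after Savitzky–Golay smoothing.
`estimate_tms()` reports local maxima passing a prominence floor and a
minimum separation (default 1 °C), each refined by a quadratic fit through
its three nearest grid points.

Two numerical choices matter here. First, the default smoothing window is 3
points — the identity for a second-order fit — because on a 0.5 °C grid the
central-difference stencil already averages over ±1 step; a 5-point
polynomial filter convolved with it spans ±1.5 °C and demonstrably erases
the dip between the *XIST* and *ACTB* peaks, which are only 1.5 °C apart.
This is also why the default transition width is 0.2 °C: for two logistic
transitions separated by 1.5 °C with abundance ratio 0.55, the inter-peak
valley exceeds the smaller peak for widths much above 0.25 °C, so no
two-peak signature would exist at any smoothing. Second, the prominence
floor is the larger of 5% of the derivative maximum and five robust noise
standard deviations of the trace (estimated from the median absolute
successive difference). The noise guard suppresses spurious bumps riding
the flat pre- and post-melt regions, where the derivative is near zero and
a pure percentage floor is easily crossed, and it leaves flat
(non-amplified) wells with an empty peak list.

**Normalization.** `normalize_curve()` fits a straight line to the
pre-melt window (upper baseline $U$) and the post-melt window (lower
baseline $L$) and rescales $(F - L)/(U - L)$, clipped to $[0, 1]$, on the
analysis window between them. Defaults are 78–82 °C and 90–94 °C. Wide
(9-point) windows are deliberate: the fitted lines are extrapolated several
degrees into the analysis window, and with 5-point windows the fit-noise
tilt (prediction s.e. ≈ 0.02 normalized units at the transition) was the
dominant well-to-well shape artifact, occasionally splitting spurious
clusters on ~200-well cohorts. The baseline lines are fitted on a lightly
smoothed trace while the normalized values use the raw one, so
normalization of an already-plateaued curve is exactly idempotent. A
non-positive $U - L$ anywhere in the window raises a degenerate-baseline
error, the signature of a flat or non-amplified well.

**Reference and difference curves.** The "typical" curve is the medoid of
the QC-passing normalized curves under the max-abs shape distance (ties
broken lexicographically by well id); the majority shape — usually the male
group — wins the medoid. Difference curves subtract the reference
pointwise: females against a male reference dip sharply near 84 °C, males
stay near zero. The commercial software's exact normalization windows and
reference rule are proprietary; the medoid rule is this package's
documented stand-in for its automatic selection.

## Clustering

`cluster_wells()` exposes the two user-facing HRM parameters: curve-shape
sensitivity (percent) and a $T_m$ difference threshold. Sensitivity maps
linearly to a merge threshold $\theta = \theta_{max}(1 - (s - 1)/99)$ with
$\theta_{max} = 0.10$, so the minimum sensitivity (1%) gives the broadest
clusters — the setting used for presence/absence discrimination, where
fine allele-level shape differences should not split clusters. Merging is
agglomerative from singletons: the pair of clusters with the smallest
complete-linkage shape distance merges, provided that distance is at most
$\theta$ and the clusters' mean primary $T_m$ (each well's
highest-prominence peak) differ by at most the threshold; it stops when no
pair qualifies. Complete linkage is chosen so one aberrant well cannot
chain two sex clusters together. Ties break toward the smallest cluster
pair after lexicographic well ordering, making the partition deterministic
and invariant to input order. Clusters smaller than `min_cluster_size`
(default 3, one triplicate) are flagged outliers — the fate of primer-dimer
wells — and excluded from calling. Whether the proprietary algorithm's
$T_m$ threshold separates or merges at exactly its boundary is unknowable
from its documentation; the semantics here (merge allowed iff
$\Delta T_m \le$ threshold) are documented, not asserted as equivalent.

The sensitivity→threshold mapping constrains the simulator: with 0.2 °C
transitions the normalized curve's slope is ≈ 1.25 per °C, so complete
linkage at $\theta = 0.10$ tolerates only ~0.08 °C of total $T_m$ spread
within a sex. The default $T_m$ jitter (s.d. 0.005 °C) and heterozygote
split (0.3 °C) sit inside that budget; larger values split heterozygous
individuals into their own cluster, contrary to the plateau-but-same-cluster
behaviour the assay shows at 1% sensitivity.

## Calling and validation

Wells are excluded (with one primary reason each) when they did not
amplify — flag, absent/late Cq (45-cycle limit), or relative fluorescence
drop below 10% — when their baselines are degenerate, or when they sit in
an outlier cluster. Cluster sexes come from known-female anchors (e.g.
females identified in the field by calf presence): the primary cluster
holding the anchor majority is female, the other male. Without anchors, a
signature fallback marks the cluster whose medoid shows two derivative
peaks as female. Evenly split anchors, or anchor and signature rules
disagreeing, leave the mapping unassigned with a warning rather than a
guess. With more than two primary clusters, the non-anchor clusters fall
back to their own medoid signature; with no anchors and all primary
medoids sharing one signature, everything stays unassigned (conservative:
two single-peak clusters could be two male allele classes or a male
cluster plus dropout females).

A sample is called female or male when at least two-thirds of its
QC-passing wells sit in one sex-mapped cluster; otherwise it is
inconclusive, or insufficient when no well passes. The majority denominator
counts only QC-passing wells in primary clusters — outlier wells leave both
numerator and denominator, matching their exclusion "from further
analysis"; whether the original procedure kept them in the denominator is
not stated, so this reading is a documented choice. Samples with RNA yield
below 9 ng/µl carry an advisory `low_yield` flag (the remedy is repeating
the extraction); flags never change calls.

`concordance()` compares calls with DNA-based labels: inconclusive and
insufficient calls count as disagreement but are itemized. Discordances are
tagged by mechanism: RNA-female/DNA-male is an `xxy_candidate` (both *XIST*
expression and *SRY* presence — the aneuploidy the two methods detect
jointly); RNA-male/DNA-female on a low-yield sample is
`xist_dropout_suspected`. Agreement is reported to two decimals.

## What the simulator does and does not show

The generator reproduces the statistical structure the analysis relies on:
two melt signatures at the right temperatures, yield-stratified failure
modes, heterozygote plateaus, anchor metadata, triplicate plate layouts and
instrument-like noise. It does not model sequence-dependent melting (no
nearest-neighbour thermodynamics), amplification kinetics beyond a scalar
Cq, temperature calibration drift between instruments, or multi-modal
baseline chemistry. Passing tests therefore demonstrate that the analysis
recovers truth under the assay's idealized physics and documented failure
modes — not that any particular instrument's export will cluster as
cleanly. The analysis path itself is format-agnostic: simulated and
imported plates flow through the same CSV dialects.

Problem sizes used in the shipped tests and acceptance script were chosen
to mirror the validation study at desk scale: 69-sample cohorts in
triplicate (207 wells) for end-to-end concordance, 24 wells per sex for
transition-temperature recovery, 200 wells for $T_m$-recovery statistics,
and ≤ 12-well plates for the brute-force clustering oracles.

## Known limitations

- The sensitivity→threshold mapping and the medoid reference rule are
  documented stand-ins for proprietary behaviour, stated in the run report
  with every analysis.
- Max-abs shape distance with complete linkage is intentionally strict;
  instruments with $T_m$ repeatability worse than ~0.1 °C would need
  a temperature-shifting overlay step (out of scope here) or a larger
  $\theta_{max}$.
- The in-silico PCR utility is exact-match only, for synthetic templates
  and primer sanity checks — not a genome-scale specificity search.
- XXY detection is a discordance *tag*, not a karyotype call: it flags
  samples whose two sex tests disagree in the direction aneuploidy would
  produce.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_cohort(12, sex_ratio = 0.5, cohort_profile = "2021",
                       seed = 42)
run <- run_hrm_pipeline(sim$curves, sim$layout, sim$metadata, cq = sim$cq)
print(run)
run$calls
run$concordance
```
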