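---
title: "Methods: ranking protein targets from an annotated-library phenotypic screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking protein targets from an annotated-library phenotypic screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemrank)
```

## The screening model

`chemrank` analyzes screens in which every library compound has predefined
protein targets, so that compound-level activity can be aggregated into
target-level evidence. The concrete assay it was built around measures
glucose production by primary human hepatocytes (absorbance of an enzymatic
glucose readout at 570 nm), with each compound tested in two arms: alone,
and on top of 1 nM insulin. Each 96-well plate carries its own MAX controls
(vehicle plus gluconeogenic substrates: full glucose output) and MIN
controls (vehicle, no substrates: basal output), and every test well is
normalized only against the controls of its own plate:

$$\%\text{Suppression} = 100 - 100\,\frac{\text{Test}-\text{Min}}{\text{Max}-\text{Min}}.$$

Per-plate normalization is deliberate: plate-to-plate drift in absolute
absorbance is the dominant nuisance in this assay format, and the plate
validation statistics (CV of each control band, Z′-factor) are themselves
per-plate quantities. Out-of-range values are retained rather than clipped
— a well above MAX (glucagon-like stimulation) is biologically meaningful
and must stay representable. The Z′-factor uses the standard
separation-band form $1 - 3(\sigma_{max}+\sigma_{min})/|\mu_{max}-\mu_{min}|$,
and CVs use the sample (n−1) standard deviation; neither convention is
forced by the assay, so both are fixed here once and used consistently.

## Hit calling

A compound × condition record becomes exactly one of four calls, in strict
precedence order:

1. `excluded_interference` — the counter assay (compound mixed with a
   fixed 37.5 µM glucose standard before detection) shows the compound
   distorts the readout chemistry. An interfering compound's suppression
   value is meaningless whatever its magnitude, so this check comes first.
   The interference criterion is a relative deviation of the measured
   signal from the compound-free reference beyond a tolerance, default
   20%. The tolerance is a package choice (no published value exists for
   it) and is exposed as a parameter.
2. `excluded_cytotoxic` — viability strictly below 60% (percent of
   vehicle-well ATP signal). The strict inequality mirrors the usual
   "<60% viability" phrasing of such exclusion rules.
3. `active` — suppression at or above 60% (inclusive, matching "≥60%").
4. `inactive` — everything else.

The 60/60 thresholds are the field's convention for this assay class and
are parameters, not constants.

## The target-ranking statistic

Evidence is split into two channels per target $j$: channel 1 aggregates
the compounds called active in the primary screen (the "active assay"),
channel 2 the remaining, non-excluded compounds (the "inactive assay").
Within a channel, $n$ compounds annotated to the target were tested and
$k$ of them were positive, $p = k/n$. The per-channel score is

$$S_{i,j} = \frac{p_{i,j}}{a \, w_{i,j}},$$

where $w$ is the width of the Wilson score interval for $p$ at 95%
confidence and $a > 0$ an adjustment factor (default 1). Dividing by the
interval width is the point of the statistic: two targets with the same
positive proportion are separated by how much evidence backs the
proportion, because $w$ contracts as $n$ grows. The Wilson interval is
used (rather than the Wald interval) because it behaves sensibly at the
small $n$ and extreme $p$ that dominate the active channel — many targets
have only one or two active compounds. The confidence level is exposed in
`ranking_config()`; 95% is the default convention.

Because far more compounds are inactive than active, the two channels'
raw scores live on very different scales (at the default simulated
conditions the per-target tested-compound counts differ by several fold,
and the suite checks this disparity). Scores are therefore standardized
per channel,

$$Z_{i,j} = (S_{i,j} - \mu_i)/\sigma_i,$$

with $\mu$ and $\sigma$ the mean and *population* (divide-by-n) standard
deviation over all eligible targets in that channel. The population form
is a package decision — "standard deviation" alone does not pin down the
convention — chosen so that the standardized vector has exactly unit mean
square, making tests deterministic. Standardization also absorbs any
positive rescaling of a channel's scores; in particular the adjustment
factor $a$ cancels entirely (the test suite asserts this).

The channels are combined with a convex balance factor,
$I_{b,j} = b_1 Z_{1,j} + b_2 Z_{2,j}$, $b_1 + b_2 = 1$, and targets are
ranked at each of 99 balance settings $b_1 = 0.01, 0.02, \ldots, 0.99$.
Rank 1 is the *largest* combined score; ties take the average of the
spanned ranks so that every rank column sums to $n(n+1)/2$ and the rank
curve moves continuously as $b_1$ crosses a tie. The final ordering ranks
targets by the area under their rank-versus-$b_1$ curve (trapezoidal rule
over the grid; on the uniform default grid this is equivalent to a scaled
mean rank), ascending: a small area means the target held a good rank
across the whole sweep. Ranking by AUC instead of by the neutral setting
$b_1 = 0.5$ demotes targets whose good neutral rank is an artifact of one
channel dominating — the rank direction and the ascending-AUC convention
are the only pair of choices under which a weighting-sensitive target is
demoted relative to its neutral rank, which is the behavior the statistic
exists to produce (a constructed instance in the test suite demonstrates
it). Ties in AUC are broken by neutral rank, then target id, to keep the
output deterministic.

**Eligibility.** Only targets with at least one positive in the active
channel are ranked (`min_active_positives = 1`); a target with no active
evidence has no meaningful $p_1$. Targets with *no tested compounds at
all* in channel 2 cannot be scored there: they are excluded from
channel-2 standardization, carry $Z_2 = 0$ (the channel is silent, not
negative), and are flagged `no_channel2_evidence` in the output.

**Channel mapping.** What exactly constitutes the "active assay" versus
the "inactive assay", and what counts as a positive within each, is
genuinely underdetermined in this assay design — the tested-count
disparity between channels constrains but does not determine it. The
package therefore injects the mapping as a function
(`default_channel_map()`), and the default implements the reading most
consistent with a two-arm (±insulin) screen: the primary-arm call decides
the channel, and confirmation on top of insulin decides positivity. A
per-row lookup table from (condition, call) to (channel, positive) cannot
express this rule, because it needs both of a compound's arms at once;
that is why the mapping is a function. Users with a different design
supply their own function of the same shape.

Kendall τ between rankings is computed as tie-adjusted τ-b (via
`stats::cor`), since tie-averaged ranks occur.

## ΔΔCT quantification

The qPCR module follows the standard array bookkeeping exactly: per
replicate, $\Delta C_T = C_T^{gene} - C_T^{ref}$; fold change is
$2^{-\Delta\Delta C_T}$ computed from the *arm means* of $\Delta C_T$;
the per-gene p-value is a two-sided pooled-variance Student's t-test on
the *replicate linear-scale* $2^{-\Delta C_T}$ values — the two scales
are intentionally different and the package keeps them distinct. Fold
regulation reports fold change symmetrically (values < 1 become the
negative reciprocal). The significance filter keeps genes with
|fold regulation| > 2 and p below a cutoff; both conventional cutoffs
(10⁻⁶ table-grade, 0.05 display-grade) ship as presets in
`qpcr_cutoffs`, and neither is hard-coded. Reference normalization uses a
single reference $C_T$ per replicate rather than reproducing any vendor's
multi-gene housekeeping scheme, which is not public. No multiple-testing
correction is applied, matching the analysis this module mirrors. Genes
whose replicates are exactly constant in both arms (possible only in
noiseless simulation) get `p_value = NA` rather than an error, so
noise-free fixtures remain analyzable.

## What the synthetic screen emulates

`simulate_screen()` generates the complete input set — plates, compound
annotations, viability, counter assay, qPCR Ct tables — with known ground
truth, at defaults matching the study conditions the pipeline was built
for:

* 1,523 compounds, each annotated to 1–5 of 200 targets; per-target
  annotation weights are gamma-distributed (shape 2), so some targets are
  heavily annotated and others barely.
* 10 planted regulator targets, drawn from the middle band (25th–75th
  percentile) of annotation counts: planting a regulator on a promiscuous
  library workhorse would flood the screen with actives well beyond the
  tens-per-1,500 yield such screens report, while a barely-annotated
  regulator (1–2 compounds) is untestable by any statistic. Compounds
  annotated to a regulator draw true suppression above the 60% threshold
  with probability 0.6; all other compounds with probability 0.02.
* Near-miss regulator compounds cluster just below threshold
  (truncated normal, mean 45, sd 10) and insulin adds a synergy shift
  (mean 12 percentage points, sd 6) for regulator-hitting compounds only,
  so a fraction of them cross 60% only in the insulin arm — this is the
  signal the inactive channel carries.
* 25% of compounds are cytotoxic (viability drawn below 60%) and 1%
  interfere with detection; interference is a multiplicative distortion
  of the glucose signal applied identically in the screen and in the
  counter assay, so the counter assay can detect exactly the compounds
  whose screen readout is corrupted.
* Plates are 96-well (controls in the first and last columns); well noise
  is Gaussian with a per-plate SD drawn as 0.04 × U(0.75, 1.75)
  absorbance units, which puts per-plate Z′ in roughly the 0.4–0.8 band
  a passing validation run shows.
* qPCR Ct tables plant per-gene log2 effects; reference Ct values cancel
  exactly in ΔCT and noise enters only the gene Ct, so the noiseless
  limit reproduces planted fold changes without error.

Everything is deterministic under a fixed seed (`withr::with_seed`), and
the generators never touch the session RNG state otherwise.

What the generator does **not** emulate: dose–response and binding
kinetics (each compound is one well per arm at one concentration),
donor-to-donor hepatocyte variability, spatial plate artifacts (edge
effects, gradients), correlated annotation structure (target families
sharing compounds non-randomly), and selectivity differences between a
compound's multiple targets (fan-out is uniform). Passing tests on
simulated data therefore demonstrate that the statistics recover planted
structure under idealized independence assumptions — not that the
pipeline is robust to the systematic artifacts of a real robotic run.

## Validation problem sizes

The test suite validates the ranking chain against a naive loop-based
reimplementation on random small instances (up to 10 targets, 50
compounds, 25 instances at 10⁻¹⁰ relative tolerance), the Wilson width
against its closed form for every (k, n) with n ≤ 30, and the end-to-end
behavior on 25 full-scale simulated screens at the default conditions
(1,523 compounds, 200 targets, 10 planted regulators), where it checks
regulator recovery in the top 20, neutral-vs-AUC rank agreement, and the
cytotoxic exclusion rate; qPCR effect recovery uses 100 seeds at noise
SD 0.1. These sizes make the full suite run in well under a minute while
keeping every Monte-Carlo margin comfortable.

## Known limitations

* The evidence score treats a compound's annotations as exchangeable;
  a promiscuous active compound inflates every one of its targets
  equally, and only the accumulation of evidence across compounds
  separates true regulators from co-annotated bystanders.
* With a single well per compound and arm, threshold noise near 60%
  suppression is irreducible; the ranking inherits it through k.
* Channel 2's positivity definition (insulin-arm activity of
  primary-inactive compounds) is one defensible reading of an ambiguous
  design; the injectable channel map is the escape hatch, not a claim of
  uniqueness.
* The AUC aggregation integrates over an arbitrary but fixed grid; a
  non-uniform grid would weight balance regions unequally and is
  supported but untested territory.
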