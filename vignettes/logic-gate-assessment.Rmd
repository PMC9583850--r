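---
title: "Assessing yeast logic-gate circuits from flow-cytometry campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing yeast logic-gate circuits from flow-cytometry campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescore)
library(dplyr)
```

## The problem

Two-input Boolean logic gates (AND, OR, NAND, NOR, XOR, XNOR) can be built
in *Saccharomyces cerevisiae* from CRISPR-dCas9 NOR-gate components, with
guide RNAs (gRNAs) carrying the signals and GFP fluorescence reading out
the final output. Because each strain produces its own inputs, a gate is
characterized by a panel of four strains — one per input state, named like
`OR01` (the OR gate holding inputs 0 and 1) — measured by flow cytometry
over many replicate wells, alongside a non-fluorescent wild-type (`WT`)
negative control and a constitutively-high `NOR00` positive control.

`gatescore` implements the complete analysis such a campaign needs:

1. **Gating** of flow-cytometry events on forward/side scatter and
   aggregation to per-well summaries;
2. **Threshold calibration** from the control wells;
3. **Correctness scoring** of replicates, strains and circuits against
   the gates' truth tables;
4. **Scatter bimodality diagnostics** (2-means clustering with
   per-cluster vs pooled regression);
5. **Plate-reader analyses**: the protocol's dilution arithmetic, OD
   growth relationships, and a cross-modality consistency check;
6. **Sequence verification** of strain builds by exact gRNA matching.

A synthetic-data generator reproduces the statistical structure of such
campaigns end to end, so every stage is tested without instrument data.

## The analysis model

### Units of analysis

All correctness calls are made at the **replicate (well)** level, never
per cell. This is both practical (a campaign produces tens of millions of
events) and principled: wells of the same strain can differ wholesale, so
pooling cells across replicates would confound the analysis. The per-well
statistic is the mean of log10 GFP over gated events. (The alternative —
log10 of the arithmetic mean of linear GFP — is available via
`classify_replicates(statistic = "log_of_mean")`; the two differ by a
Jensen gap that is small when wells are tight, and mean-of-log is the
default because per-well distributions are analysed throughout on the
log scale.)

### Gating

Events are kept when both scatter channels lie in
`[fsc_min, scatter_max] x [ssc_min, scatter_max]`. The upper cut
(default 900,000 a.u.) removes events approaching the instrument ceiling
of 1,048,575 a.u., where measurements pile up by saturation. Cytometer
units are arbitrary, so the lower debris cuts carry no universal value:
the defaults (10,000 a.u.) suit the synthetic generator's scale and are
deliberately configurable for real data. Wells retaining fewer than
10,000 gated events are dropped. Whole plates with abnormal behaviour are
removed by an explicit, curated exclusion list
(`apply_plate_exclusions()`); an optional heuristic
(`flag_outlier_plates()`, off by default) flags plates whose positive
controls under-fluoresce.

### Threshold calibration

A single high/low cut for *all* circuits is calibrated from the control
well means: composable gates need one shared interpretation of high and
low. For threshold $t$ the cost is the mean "wrong-direction" distance

$$c(t) = \frac{\sum_{x \in \text{neg}, x > t} (x - t) +
              \sum_{x \in \text{pos}, x < t} (t - x)}{n_\text{pos} + n_\text{neg}},$$

a piecewise-linear convex function of $t$ whose breakpoints are the
control values. `optimize_threshold()` therefore solves the problem
exactly by evaluating $c$ at the pooled sorted control means; when the
minimizer is a flat interval (always the case for perfectly separated
controls) the midpoint is returned and the interval reported — a
symmetric, reproducible tie-break. The denominator counts control
*wells*; it is constant in $t$, so the argmin is unaffected by reading
"samples" as wells versus events, only the reported cost value changes.
A well mean exactly at the threshold classifies as high; an exact tie
carries no information, so the convention is fixed and disclosed.

### Correctness

Each retained replicate is correct when its statistic falls on the
strain's expected side of the threshold. A strain's score is the
proportion of correct replicates (shaded green above 0.9, gray below
0.5). A circuit's score is the **minimum** over its four input strains: a
gate wrong on one input computes a different Boolean function, and
`score_circuits()` names that effective function when one input fails
systematically (a NAND stuck high on 11 is a constant-high gate).
Replicates are pooled across growth conditions by default, with a
standard-conditions (30&nbsp;°C, 16&nbsp;h, SC medium) restriction available.

### Scatter bimodality

Control scatter data can be bimodal — e.g. a subpopulation of unhealthy
or stationary-phase cells with a higher SSC/FSC ratio. `cluster_scatter()`
runs `stats::kmeans` (k = 2, 10 restarts, fixed seed) on unstandardized
(log10 FSC_A, log10 SSC_A) — both axes are in comparable log a.u. — and
names cluster 1 deterministically as the one whose center has the higher
SSC/FSC ratio. Per-cluster and pooled Pearson correlations of log SSC_A
on log FSC_A quantify the structure: pooling offset clusters attenuates
the within-cluster linear relationship, so genuinely bimodal data shows
per-cluster *r* clearly above the pooled *r*.

Whether two clusters are *real* is decided by a centroid-based
(simplified) silhouette. Calibration: splitting a **single** bivariate
log-normal cloud with 2-means scores up to ≈ 0.66 no matter how
elongated the cloud (we measured 0.46–0.66 across within-cloud
correlations 0–0.99), while genuinely separated clouds score 0.70–0.85
(≈ 0.84 at five within-cloud SDs of separation). The default flag
threshold 0.68 sits just above the unimodal ceiling, so no two-cluster
claim is made on unimodal data. `compare_cluster_gfp()` then asks
whether the secondary population matters: it contrasts the clusters'
log10-GFP kernel densities and mean difference — a near-zero difference
means the extra cluster does not bias correctness calls.

### Plate reader

`dilution_plan()` implements the protocol arithmetic: with
`fold = measured_od / target_od`, culture is mixed culture:total at
1:`fold`. Only this reading reproduces OD 1.0 → 0.01 exactly at 1:100
(culture:media 1:100 would land at 0.0099). `od_growth_correlation()`
reports Pearson ρ of initial (post-recovery) versus final OD, overall or
per group, flagging undefined, under-sized and *negative* groups —
negative growth correlation marks pathological batches.
`fc_pr_consistency()` checks the two instruments against each other:
bulk plate-reader GFP should scale as final OD × per-cell GFP, with the
cytometer statistic re-expressed on the linear scale (fluorescence is
additive over cells); wells beyond 3 residual SDs are flagged. A
near-exact fit is recognized (residual SD below 1e-8 of the response
scale) and flags nothing.

### Sequence verification

Strain builds are verified by searching raw reads for **exact** matches
to each gRNA sequence or its reverse complement (Biostrings matching; no
mismatches, ambiguous bases never match). Coding sequences and target
sites share the same DNA sequence, so matching cannot tell the roles
apart — the design matrix ORs them. Design-vs-results disagreement cells
classify as `unexpected_absence` (build error, or merely thin coverage)
or `unexpected_presence` (mislabeling, wrong design record or
contamination — the stronger signal of real trouble). Strains without a
read set are flagged `no_data`, never zero-filled.
`design_compatibility()` asks which candidate designs a strain's observed
gRNA profile could be (by default extra presences are ignored; `strict`
mode disqualifies them), and `coverage_estimate()` provides the
total-bases/genome-size context for interpreting absences.

## The synthetic generator

`sim_config()` / `simulate_campaign()` emulate, per well, 30,000 events
drawn from a three-component scatter mixture — two log10-normal clusters
plus a debris cloud (fraction 0.05) — hard-clipped at 1,048,575 a.u., and
log10-normal per-cell GFP around a **well-level** mode. The defaults are
fixed once as the package's study conditions:

* scatter clusters at (5.00, 5.45) and (5.50, 5.25) log10 a.u., SD 0.15,
  within-cluster correlation 0.95, weights 0.4/0.6 — separated enough
  that 2-means recovers them (> 99% label agreement) and arranged so the
  pooled correlation is strongly attenuated relative to the per-cluster
  values, the signature the bimodality analysis looks for;
* GFP modes at 1.5 (low) and 3.5 (high) log10 a.u., per-cell SD 0.25 and
  a per-well shift of SD 0.08 — about two log-units of band gap, and
  per-replicate SDs comfortably under the 0.613 log-unit tightness bound
  the well-level analysis assumes;
* whole-well failures: with per-strain probability `well_failure_rate` a
  well expresses the *opposite* mode — every cell shifts together, so
  failures appear as replicate-level bimodality with tight wells, which
  is exactly the structure that motivates well-level analysis;
* growth: final OD follows the saturating map `od_max * D / (D + K)`
  (od_max 2, K 0.01) in target OD `D` — increasing with diminishing
  returns — with a per-well log-normal "vigor" factor (SD 0.15) shared
  between recovery and growth phases, inducing a realistic ρ ≈ 0.4
  between initial and final OD, plus independent log-normal noise;
* bulk plate-reader GFP = final OD × mean linear per-cell GFP × gain,
  with 5% multiplicative noise;
* reads: 60 fixed-length 100-nt reads per strain with each designed gRNA
  (synthetic 20-nt library `r1`…`r13`; the real sequences are
  user-supplied inputs) embedded once, forward or reverse-complement;
  anomalies are injectable per strain ("drop" a designed gRNA, "add" an
  undesigned one) and recorded as ground truth.

Determinism: a single seed fans out to named per-well substreams, so the
same configuration reproduces a campaign byte for byte and adding wells
never changes existing ones.

What the generator does **not** emulate: spectral spillover and
compensation, doublet pulse geometry, bead-based unit calibration,
plate-position effects, sequencing errors, non-uniform genome coverage,
or cell-level mixtures within a well. Tests passing on synthetic data
therefore validate the *analysis logic* — gating algebra, calibration
optimality, scoring rules, anomaly classification — not instrument
physics; thresholds such as the lower scatter cuts must be re-examined
on real data.

## Numerical and design choices

* log10 throughout; GFP values below `gfp_floor` (1 a.u.) are clamped
  before the log, guarding against non-positive compensated values.
* Threshold tie-breaks: interval midpoint (reported with the interval).
* Classification boundary: at-threshold means classify high.
* k-means: 10 restarts, `iter.max` 100, seed fixed by the caller;
  cluster naming by center SSC/FSC ratio, so labels are stable across
  runs and event orderings.
* Gating is a pure filter — conservation, idempotence and monotonicity
  in every bound hold exactly and are tested as properties.
* Degenerate inputs: empty event tables summarize to `n_gated = 0` with
  `NA` means; empty clusters omit their density curve with a warning;
  constant OD vectors yield a flagged `undefined` correlation, not `NaN`.
* Problem sizes in the test-suite: unit tests run on hundreds-to-
  thousands of events; the end-to-end recovery check runs one full-scale
  campaign (24 strains × 12 wells × 30,000 events plus controls) — the
  scale at which the per-well statistics the analysis relies on are
  representative.

## Limitations

* The wrong-direction criterion weighs distances, not error counts; with
  very unbalanced control groups the optimum can sit closer to the
  smaller group than a count-based criterion would put it. This mirrors
  the method being implemented, not a preference of this package.
* The simplified silhouette threshold (0.68) is calibrated for roughly
  log-normal scatter clusters; heavy-tailed instruments may need a
  re-calibration via the `silhouette_min` argument.
* Exact substring matching cannot distinguish gRNA coding sequences from
  target sites and treats any single matching read as presence
  (`min_reads` raises the bar for noisy data).
* FCS binary files are not parsed; events are read from the CSV dialect
  written by the generator (channel names configurable) — export FCS to
  CSV upstream.

## A worked end-to-end run

```{r, eval = FALSE}
library(gatescore)

planted <- c(NAND11 = 0.4, NOR11 = 0.5)
cfg <- campaign_config(
  simulation = sim_config(seed = 424242L, n_replicates = 12L,
                          well_failure_rate = planted)
)
report <- run_campaign(cfg)

glance(report)                    # threshold, retained wells, shade counts
tidy(report)                      # Table-2-shaped per-strain scores
report$circuit_scores             # min-rule circuit scores
tidy(report$scatter$WT$clusters)  # Table-1-shaped r values
glance(report$dnaseq$anomalies)   # design-vs-results anomaly totals

plot_strain_histograms(report$classified, report$threshold)
autoplot(report$scatter$WT$clusters)
autoplot(report$plate_reader$consistency)
```
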