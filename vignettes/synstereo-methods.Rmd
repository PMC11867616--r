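---
title: "Methods: stereology and 3D spatial statistics of cortical synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereology and 3D spatial statistics of cortical synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstereo)
```

## What this package computes

`synstereo` implements the quantitative core of a volume-electron-microscopy
study of synaptic organization: given one record per 3D-reconstructed
synapse (centroid, synaptic apposition surface area, AS/SS type, junction
shape, postsynaptic target, spine linkage), it estimates

* synapse densities with an unbiased 3D counting frame and
  artifact-corrected volumes,
* synaptic-size (SAS area) distributions with log-normal maximum-likelihood
  fits,
* 3D spatial point-pattern statistics (F, G, K) against complete spatial
  randomness (CSR) with simulation envelopes,
* tissue volume fractions by Cavalieri point counting, and
* the composition/comparison statistics used in this literature
  (chi-square with Bonferroni, Kruskal–Wallis with Dunn post hocs,
  Mann–Whitney, Kolmogorov–Smirnov, coefficients of variation).

Because the underlying image volumes are terabyte-scale and not needed to
validate the statistics, the package ships a calibrated synthetic neuropil
generator. Its defaults encode the published per-layer measurements for the
human medial entorhinal cortex (MEC): layer densities of 0.35–0.47
synapses/µm³, AS percentages of 92.6–95.8%, and mean SAS areas of
99,489–136,111 nm² (AS) and 53,367–87,377 nm² (SS). Every downstream stage
is exercised and tested against this generator.

## The synthetic neuropil generator

A simulated stack is a box window (default 10,240 × 7,680 × 5,480 nm,
matching a 2048 × 1536-pixel field at 5 nm/pixel and ~274 serial sections
at 20 nm). Centroids are placed by one of three point processes:

* **CSR** — the default is *conditional on n* (a binomial process of
  exactly `n` i.i.d. uniform points). This matches how envelope
  simulations are built: with the same number of centroids as the observed
  pattern. Unconditional `N ~ Poisson(λV)` is available via `intensity`.
* **Matérn cluster** — Poisson parents (generated in a window dilated by
  the cluster radius, so boundary clusters contribute), Poisson offspring
  counts, offspring uniform in a sphere. Used as the positive control for
  clustering.
* **Hardcore** — sequential rejection sampling with an inhibition
  distance; fails loudly if the requested packing is infeasible within the
  proposal budget. Used as the positive control for regularity.

Attributes are drawn hierarchically: type `AS` with the layer's AS
fraction; SAS area log-normal with the type's `(µ, σ)`; shape and target
from per-type categoricals. Per-layer σ of log SAS area is not printed in
the source tables, so the default is σ = 0.8 log-units for both types with
µ solved from each layer's printed mean via `mean = exp(µ + σ²/2)`; both
are overridable in the YAML configuration. The whole-cortex aggregate
defaults for categoricals are 84% macular AS and 76% macular SS (the
complex remainder split evenly across perforated/horseshoe/fragmented,
whose individual splits are only published in supplementary figures), and
target mixes renormalised from the overall shares (59.3% of all synapses
are AS on spine heads, 34.3% AS on shafts, 0.5% AS on necks; 5.1% SS on
shafts, 0.7% SS on heads, 0.1% SS on necks), with the shaft share split
evenly between spiny and aspiny shafts.

Spine-targeted synapses are grouped into dendritic spines by drawing
occupancy classes (96% single AS, 0.73% AS+SS, 0.50% single SS, remainder
other multisynaptic) and consuming synapses from the AS and SS pools;
classes the remaining pools cannot supply are dropped from the draw, so
inconsistent configurations degrade gracefully instead of failing. Each
spine is flagged incomplete with probability 0.15 — a value chosen once as
realistic for spines truncated at stack faces (the source reports the
exclusion rule but not the rate) — and synapses on incomplete spines are
excluded from target-stratified size analyses by
`filter_for_size_analysis()`.

The spatial extent of a synapse is modelled as a sphere of radius
`sqrt(SAS area / 4π)` around the centroid. Real junctions are curved
plates, not spheres; the proxy exists so the counting-frame rule acts on
whole objects rather than centroids, which is what makes the acceptance/
exclusion geometry exercisable. What the generator deliberately does *not*
emulate: segmentation noise, membrane geometry, spatial correlation
between synapse size and position, or inhomogeneous intensity across a
stack. Tests passing on this generator therefore validate the estimators
and the pipeline plumbing, not the biology of any particular tissue
sample.

All generators take explicit seeds, restore the caller's RNG state, and
derive per-stage substreams from the single run seed, so a fixed
`(config, seed)` pair reproduces every report byte for byte.

## Counting frame and density

The counting frame is a rectangular brick with three acceptance and three
exclusion faces (default: the low-x/y/z faces exclude; any consistent 3/3
split of opposite pairs is unbiased, and the face roles are configurable).
Exclusion planes are treated as *extended* planes: a synapse is counted
when its extent intersects the brick and touches no exclusion plane, and
excluded when it lies wholly outside or touches any exclusion plane, with
exclusion dominating. This is the classical unbiased-brick rule; the
brute-force face-slab oracle in the test suite checks every combination on
random spheres. Density is counted synapses over the frame's *effective*
volume (raw volume minus the artifact fraction, supplied as stack
metadata; measured artifact fractions in the source ranged 1.4–27%, and
the default is 10%).

Shrinkage corrections divide measured volumes, areas and lengths by
0.90, 0.93 and 0.97 respectively (processed/unprocessed ratios). A density
has a volume in its denominator, so its corrected value is the measured
density multiplied by the volume factor. The published layer-I
corrected/uncorrected density pair orders the other way from all other
layers and is therefore not used as a validation anchor; the identity
above is what the report enforces, exactly, at full precision.

## Spatial statistics

F (empty space), G (nearest neighbour) and K (reduced second moment) are
estimated on the centroid pattern inside its box window:

* default r grid: 100 evenly spaced distances from 0 to a quarter of the
  shortest window side;
* default edge correction: reduced-sample (border) for G and K, minus
  sampling for F — at each distance d only points (or query locations) at
  least d from every face contribute. An uncorrected mode exists and is
  what the brute-force oracle tests pin down;
* F query locations: a regular lattice of about 10× the point count,
  jittered once per run under the seed.

Note one practical consequence of the reduced-sample estimator: because
its denominator changes with d, the corrected G/F/K curves need not be
monotone, unlike their uncorrected counterparts. The envelope machinery is
unaffected (observed and simulated curves share the estimator).

CSR envelopes are pointwise min/max bands over 99 simulations with the
same number of points in the same window (pointwise exceedance level
2/100 per side). The verdict is *random* unless the observed curve leaves
the band for at least 3 consecutive grid points; the direction of the
excursion maps to *clustered* (K or G above the band; F below) or
*regular* (the reverse). `classify_spatial_pattern()` combines the three
functions on one shared simulation set with an any-function rule, which is
intentionally stricter than any single function.

A calibration caveat worth stating explicitly: pointwise min/max bands
control the error rate per distance, not over the whole curve. Because
neighbouring distances are strongly correlated, a CSR pattern wanders
outside the band somewhere along the curve in roughly 10–15% of runs at
these problem sizes (n ≈ 150 in a 10 × 8 × 5 µm box), and the
minimum-run-length rule removes only short excursions. The acceptance
suite measures this rate directly; an independent reimplementation of the
same procedure (scipy-based) reproduces it, so it is a property of
pointwise envelopes, not of this implementation. It is also consistent
with the source study's own real-data outcome, where 12 of 63 stacks
deviated from CSR by "one or more" functions. A global rank envelope
would calibrate family-wise, but the pointwise convention is the one the
envelope-area procedure implies and is kept as the default.

Intersynaptic distances are plain nearest-neighbour distances with no
border deletion (matching how the mean intersynaptic distance is
reported); the closed-form CSR expectation `0.55396 λ^(−1/3)` is used as
an analytic oracle on interior points, since points near a face have
inflated nearest-neighbour distances.

## Sizes, stereology, inference

Log-normal fits use the closed-form MLEs on logs (σ in the population
form). Goodness of fit is a one-sample KS distance against the fitted
distribution; with estimated parameters the p-value is approximate and
anti-conservative, and is labelled so. Fitting shrinkage-corrected rather
than raw areas shifts µ by −ln(0.93) and leaves σ unchanged, so only one
set of fits is stored.

Cavalieri point counting overlays a 10 × 10 point grid (5 µm spacing,
2500 µm² coverage per placement) at uniformly random offsets, 10
placements per field by default, and divides per-class hits by total hits;
fractions sum to exactly 100%. Counts are pooled across placements before
the formula is applied (per-placement averaging is available but pooling
is the default, as the estimator is a ratio of sums).

Group comparisons follow the reporting conventions of this literature:
Mann–Whitney for two groups, Kruskal–Wallis with tie correction for
several, Dunn's pairwise z tests (Bonferroni over all pairs — the source
names no adjustment, and Bonferroni is the conservative reproducible
choice) gated on an omnibus p < 0.05; Pearson chi-square without
continuity correction for contingency tables, Bonferroni-adjusted over the
pairs actually run; and dual significance thresholds enforced by sampling
unit — 0.05 when the unit is stacks or subjects, 1e-4 when the unit is
individual synapses.

## Problem sizes and runtime choices

The shipped configuration simulates 9 stacks per layer across 7 layers
(63 stacks, ~180 synapses each at the calibrated densities), which keeps a
full pipeline run with 99-simulation envelopes on every stack to a few
minutes on one core. The test suite uses the same geometry with smaller
replicate counts for the property checks and the full 100-trial, 99-
simulation calibration for the envelope procedure. Monte-Carlo tolerances
in the tests are stated in units of the corresponding standard errors
(typically 3 SE or 3 binomial SDs) rather than absolute numbers.

## A worked example

```{r example, eval = FALSE}
cfg <- load_run_config()            # packaged MEC calibration
report <- run_pipeline(cfg, seed = 1)
format_layer_table(report)               # per-layer counts, %AS, densities, sizes
report$spatial_table                # per-stack CSR verdicts
report$vv_table                     # Cavalieri volume fractions
write_report(report, "mec_report")  # TSVs + JSON fits
```

## Known limitations

* The sphere extent proxy overstates the compactness of large junctions;
  counting-frame decisions near faces can differ from what a mesh-based
  extent would give.
* Spine composition is realised by pool consumption, so in populations
  with very few SS synapses the rare AS+SS and single-SS classes are
  supply-limited and their realised frequencies can fall slightly below
  the configured probabilities.
* The pointwise envelope verdict over-calls non-randomness at roughly the
  10–15% level discussed above; treat per-stack verdicts as screening
  calls, not tests with family-wise guarantees.
* No inhomogeneous or marked point-process statistics, no pair-correlation
  function, and no mixed-effects modelling of the case/stack hierarchy.
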