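---
title: "Synthetic-twin morphometry of stereotyped mechanosensory arbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-twin morphometry of stereotyped mechanosensory arbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborquant)
```

## The problem this package models

Identified mechanosensory neurons of the fly thorax build remarkably
stereotyped axonal arbors inside the thoracic ganglion: a posterior scutellar
axon enters through a specific mesothoracic nerve, elaborates a core set of
sixteen "skeleton" branches that recur in more than 80% of wildtype animals,
plus a handful of variable branches, and decorates its cable with axonal
varicosities — local swellings that serve as a proxy for presynaptic boutons.
Perturbing axon-guidance receptor levels changes these numbers: one receptor
class suppresses branch and varicosity formation (its knockdown *increases*
branch counts by roughly seven and nearly doubles varicosity counts), the
other promotes growth (its knockdown *decreases* branch counts and total
arbor size by about 12%, removing on average 3.3 core branches).

No raw images accompany the printed per-genotype summary statistics, so the
package treats the published cohort table as the ground truth of a
*synthetic twin*: a generator is calibrated so that its cohorts reproduce the
printed means and SEMs, the full image-analysis pipeline (render, trace,
filter, classify, count) is run on that synthetic material, and the pipeline
is judged by whether it recovers the printed numbers.

## The generator and its calibration

An arbor is sampled from a 16-branch skeleton template (branch-wise mean
lengths 13–151 µm, spanning a 135 × 245 µm field) plus interstitial variable
branches. The generative model, per cohort:

* **Presence.** Each skeletal branch is present with its template marginal
  frequency (0.92–1), scaled by a per-genotype `skeletonPresenceScale`.
  Sampling is hierarchical — a daughter can only be present when its parent
  is — because an orphaned branch has no attachment point; the packaged
  marginals are non-increasing along every root-to-tip path so that exact
  marginal control is possible. Branches with marginal frequency 1 (the
  primary trunk and its two first daughters) are treated as obligate: the
  presence scale redistributes loss over the secondary and tertiary
  branches, which is where branch loss is observed biologically.
* **Lengths.** Per-branch lengths are truncated-at-zero normal with the
  template mean times a per-genotype global scale, and a 20% coefficient of
  variation (the template default, user-overridable). Branch *endpoints* are
  stereotyped: each polyline reaches the template's nominal chord (90% of
  the scaled mean) and expresses the drawn arc length as meander
  (tortuosity), with the meander frequency chosen so the lateral amplitude
  stays near 3 µm. Without this anchoring, 20% length noise accumulated
  along root-to-tip paths scatters distal junction positions by tens of
  micrometers and produces unrealistic tangles.
* **Variable branches.** A per-arbor count with calibrated mean and SD is
  drawn as a rounded Gaussian (clamped at zero); each branch attaches
  interstitially (mid-branch, at least 5 µm from branch ends and 4 µm from
  other attachments), with a direction at least 35° away from the local host
  tangent and a path that keeps ≥4–5 µm clearance from the existing arbor
  (real collaterals grow into free neuropil; in images, closer spacing is
  unresolvable). Lengths are truncated-normal with base mean 25 µm (CV
  0.35) at the global scale, modulated by a mean-preserving compensation
  term: variable growth recovers 60% of the arbor's skeletal-length
  shortfall. The printed count and length dispersions jointly imply this
  anticorrelation — without it, the presence-driven variance of total length
  alone exceeds the printed length SEMs for the knockdown cohorts.
* **Varicosities.** Positions follow a stationary hard-core renewal process
  along each branch: gaps are 3 µm plus an exponential excess, with an
  equilibrium start, so the expected count is exactly `density × length` for
  any branch length. Positions are kept 2.5 µm clear of branch points
  (boutons and branch points are distinct structures). Diameters
  (≈2.8–4.6 µm) and intensity gains (≈2.2–3.6× the shaft) emulate the
  *large, unambiguous* varicosities that the counting convention targets as
  a lower bound on synapse number. The per-animal density factor is a
  renormalized capped gamma (cap 3.5): densities several times the cohort
  mean collide with the hard-core spacing and stop being countable objects.
* **Guidance and routing errors.** With the per-genotype guidance frequency,
  the recorded entry point is displaced into the metathoracic band (the
  arbor itself is left in place; region membership is all the downstream
  scoring uses). Skeletal branches independently suffer routing errors
  (direction rotated 55–110°) at a small per-genotype rate.
* **Animal size.** All coordinates are scaled by a per-animal size factor
  (truncated normal, CV 5%), and the recorded ganglion width scales with it;
  width normalization in the morphometry stage removes it exactly.

**Calibration.** Four mean parameters (global length scale, presence scale,
variable-branch rate, varicosity density) are moment-matched analytically —
using truncated-normal moments and the >4 µm retention probabilities — so
that the expected branch count, total length, and varicosity count equal the
configured targets; the solve is deterministic (one-dimensional root in the
length scale, the rest in closed form). Three dispersion parameters
(variable-count SD, a per-animal gamma arbor-size factor, a per-animal gamma
varicosity-density factor) are then matched to the printed cohort SEMs via
the SD = SEM·√n convention, clamped at zero when the structural variance
already exceeds the target. A pure Poisson variable-branch count cannot
reproduce the printed dispersions (its variance equals its mean, several
times larger than SEM²·n for the tightest cohorts), which is why the count
is a variance-matched rounded Gaussian instead. A second feasibility rule
couples the two dispersion targets: count dispersion propagates into
total-length variance, and two of the packaged cohorts print a count SEM
whose implied length variance exceeds the printed length SEM (the underlying
animals must anticorrelate branch number and branch length); the calibration
then takes the tighter length constraint as binding and caps the count SD
accordingly, which narrows the count dispersion but can never widen any
recovery band.

Each genotype configuration also carries an expected-skeletal-count target
(`skeletal_mean`) that splits the branch-count target into core and variable
contributions. These are derived from the printed per-genotype core/variable
statements: the wildtype arbor is ~16 core + ~6–7 variable; the driver
control has a more variable skeleton (14 consistent branches); the
growth-receptor knockdown loses 3.3 core branches relative to control; the
suppressor knockdown gains 8.6 variable branches relative to control.

## Rendering and tracing

The renderer draws each arbor as a Gaussian tube (FWHM = 1.5 µm) around the
rasterized centerlines, adds varicosities as Gaussian blobs with their own
diameter and gain, modulates 16 focal planes by a Gaussian focal profile,
blurs with a 0.6 µm PSF, and adds Poisson photon noise (variance
`noise_sd²` at unit intensity) over a 0.05 background — Poisson noise keeps
intensities nonnegative and the two-channel IHC ratios exactly linear in
expression level. Default calibration is 0.5 µm/px; the optics of the
original study are given only as magnification, so the default was chosen to
make 4 µm branches resolvable.

Tracing follows the classical recipe: maximum-intensity projection (the
analysis convention of the study), Otsu threshold, largest connected
component, Zhang–Suen thinning, then a segment graph whose nodes are
junction regions (junction pixels found by reduced-adjacency degree,
dilated by 2 px to absorb thinning artifacts) and endpoints. Crossings of
two strands (4-way nodes with two near-straight pass-through pairs) are
fused, with a connectivity guard so genuine junctions are never split;
remaining cycles are broken by detaching the lowest-intensity cycle edge at
its busier node (short cycle edges, junction artifacts, are dropped
outright). The tree is rooted at the endpoint nearest the entry hint; spurs
below 2.5 µm are pruned; a child that continues its parent within 20° is
merged back (the segment-decomposition reading of an interstitial sprout,
under which generator and tracer count the same objects); sub-4 µm internal
stubs are contracted so the countable-branch filter can never orphan a
subtree; leaf tips are extended to the mask boundary to undo thinning
retraction; polylines are lightly smoothed (window 3) to remove pixel
stair-casing without corner-cutting.

Varicosity detection realizes the counting rule — wider than the axon and
brighter — with explicit operators: local full width is twice the
medial-axis (distance-transform) value, local intensity is the projection
value along the centerline; a point is a varicosity iff width exceeds 1.5×
the median branch width *and* intensity exceeds 1.5× the median on-axon
intensity; local maxima closer than 2.5 µm merge, and detections within
1.2 µm of a junction are discarded because junction geometry mimics a
swelling.

On synthetic cohorts rendered and traced end-to-end, recovered cohort means
track ground truth to within ~5–10% for branch counts, total length and
varicosity counts in wildtype-density arbors; the densest knockdown cohorts
(≈31 branches and ≈68 varicosities in the same field) remain harder — 2-D
projections of crowded arbors contain genuinely ambiguous crossings and
merges, the same circumstance that forced the original study to exclude its
most intertwined specimens.

## Consensus skeleton and branch correspondence

Branch correspondence is hierarchical: the observed root is matched to the
template root, and at every matched pair the two broods of children are put
into optimal one-to-one correspondence (Jonker–Volgenant assignment,
verified against brute-force enumeration) under a four-term descriptor
distance — attachment fraction along the parent, topological depth,
direction (normalized to 1 at 80°), and relative length — with weights
(1, 1, 1, 0.5) and a unit gate; pairs over the gate stay unmatched, and the
recursion only descends into matched pairs. A flat, tree-wide assignment was
rejected because positional drift accumulated over 20% length noise makes
absolute descriptors unreliable; within a brood, all candidates share their
attachment point and the four spec descriptors separate cleanly
(interstitial variable branches carry attachment fractions well below 1,
which is what keeps them from filling empty skeletal slots). Matching runs
twice: the first pass estimates a global length scale from the matched
pairs, the second matches at that scale. An assigned branch whose direction
deviates by more than 45° is flagged as a routing error but remains
assigned — a routed branch is still the same branch.

The consensus builder initializes the template from a deterministically
chosen seed arbor (most branches, ties by total length), then alternates
matching all arbors against the current template with re-estimating per-slot
descriptor means and presence frequencies, opening new slots for unmatched
branches, until assignments stabilize (at most 10 rounds; a non-converged
result is flagged). Only slots whose frequency strictly exceeds 80% are
returned — the strict inequality matters at the 17/21 (in) versus 16/21
(out) boundary — and a final closed-slot pass against the converged core
re-estimates the reported statistics, which both restores invariance to
cohort ordering and pins the template's length scale to data units.

## Statistics

The cohort battery mirrors the study's: two-sided Mann–Whitney U (exact by
enumeration over rank arrangements when n₁+n₂ ≤ 12, tie-corrected normal
approximation otherwise), two-sample Kolmogorov–Smirnov with asymptotic p,
2×2 χ² on guidance-error proportions without continuity correction (flagged
when expected counts are small), one-way ANOVA with Bonferroni-corrected
pairwise comparisons (p_adj = min(1, m·p)), percent changes against the
printed reference means, the per-genotype summary table (mean ± SEM,
SEM = SD/√n), and 100 µm relative-frequency histograms of total arbor
length. Distribution tests are applied to raw per-arbor totals, not to the
binned histograms. All tests are two-sided; sidedness is not stated in the
source material.

## Problem sizes and numerical choices

* Parameter-recovery checks run 40 replicate cohorts per genotype at the
  printed cohort sizes; classification-delta checks run 25 replicates; the
  acceptance script averages 20 replicate cohorts per target and takes a
  majority over 20 seeds for the consensus size. These are the package's
  standard simulation sizes; precision scales as 1/√replicates in the usual
  way.
* The countable-branch filter is strictly exclusive (a branch of exactly
  4 µm is dropped), reading "greater than" literally. Normalization happens
  before filtering; the reference width defaults to the cohort mean.
* Ties in assignment costs are broken by the solver's scan order; with
  continuous descriptors they have probability zero.
* Degenerate inputs: empty trees pass through filtering and matching
  (everything unmatched, cost 0); identical samples give p = 1 with a
  degeneracy flag; single-arbor cohorts report SEM 0 with a flag.

## What passing tests do and do not show

The generator emulates per-genotype cohort statistics, stereotyped geometry,
image formation with realistic blur and photon noise, and the stated
filtering/threshold conventions. It does not emulate: three-dimensional
arbor geometry (everything lives in one focal plane bundle), fasciculation
or true branch-point biology, staining variability across specimens, or
out-of-plane crossings that a human tracer would disambiguate by focus.
Recovery of the printed statistics by this pipeline therefore validates the
computational chain — calibration, rendering, tracing, filtering,
correspondence, statistics — on data whose ground truth is known, not any
biological claim about real arbors.
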