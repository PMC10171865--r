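---
title: "Quantifying pulsed apical constriction and junctional anisotropy"
author: "apicodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsed apical constriction and junctional anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures
it implements: what is being measured, which parameters matter, what
the synthetic-data generator does and does not emulate, and where open
design choices were resolved.

## The measurement model

The pipeline's input is a tracked segmentation of an epithelial apical
surface: an integer label image per frame (label 0 is exterior; a
positive label means the same cell in every frame where it appears),
optional co-registered fluorescence channels, and a spatial/temporal
calibration. Everything downstream is computed from per-frame cell and
junction measurements:

* **Cell geometry.** Area is pixel count × pixel area. Elongation comes
  from the eigen-decomposition of the second central area moments: with
  equivalent-ellipse semi-axes $a \ge b$, the index is $(a-b)/(a+b)$ —
  0 for a disc, approaching 1 for a line — and the angle is the major
  axis, folded to $[0, 180)$ because cell axes are nematic (axial)
  quantities. This definition is size-invariant and pins both endpoints
  of the round-to-line scale.
* **Junction geometry.** The skeleton of the junction between labels
  $L$ and $K$ is the set of pixels 8-adjacent to exactly one other
  label; pixels adjacent to two or more other labels are
  tricellular-vertex pixels and belong to no junction (vertex staining
  puncta would otherwise bias junction means). Length is the extent of
  the skeleton along its principal axis plus one pixel — exact for the
  straight junctions of polygonal tissue — and orientation is the
  principal-axis direction. The principal axis is used rather than the
  chord between extreme pixels because the skeleton is a two-sided
  pixel set: the chord picks up a cross-axis component of one pixel
  width, which biases orientations of slanted junctions by several
  degrees (enough to corrupt polarity nematics).
* **Junctional intensity.** The skeleton dilated to a 3-px band
  (≈ 0.5 µm at the default 0.17 µm/px), clipped to the two member
  cells, excluding vertex pixels and pixels contested by a neighboring
  junction's band. Bands are therefore pairwise disjoint: painting a
  band with one value and reading the band mean are exact inverses,
  which is what makes the painted ground truth a strict oracle.
* **Medial intensity.** The mean over the cell eroded by 3 px (so
  junction bands are excluded); if erosion empties a sliver cell, the
  fall-back is the cell minus all junction bands, flagged.

## Rates, pulses, periods

The signed rate series is the backward difference converted to physical
units, with contraction positive:
$\mathrm{rate}(t) = (\mathrm{value}(t-1) - \mathrm{value}(t))/\Delta t$.
No smoothing is applied — the analysis works on per-interval
derivatives — and the telescoping identity
$\sum_t \mathrm{rate}(t)\,\Delta t = \mathrm{value}_{first} -
\mathrm{value}_{last}$ holds exactly, which the tests assert.

A **constriction pulse** is a maximal run of frames whose contraction
rate exceeds a reference threshold; its magnitude is the maximum rate
in the run. The threshold is $\mu + k\sigma$ (default $k = 1$, sample
SD) of the pooled per-frame contraction rates of reference epiblast
cells — cells that never ingress, measured in an undisturbed recording.
Under the default synthetic conditions this lands near 0.7 µm²/min.
Two caveats are deliberate:

* Runs separated by sub-threshold frames are distinct pulses unless
  `mergeGap > 0`; automation of pulse counting is this package's
  addition, its parameters are exposed rather than asserted as a
  community standard.
* Pulse **count** is *not* monotone in $k$: raising the threshold can
  split one run into two. The monotone invariant is the set of
  supra-threshold frames, and that is what the property tests check.

The **constriction period** runs from the onset of the final continual
decline to the last frame the label is present. The onset is found on a
centered moving average (window 3 frames): a *re-expansion* is a rise
of more than `reexpansionTolUm2` (default 0.5 µm²) above the running
trough; the start is the latest frame still within that tolerance of
the area peak that follows the last re-expansion. A flat plateau
followed by a decline therefore starts the period at the end of the
plateau, and an oscillating cell starts it at the final oscillation
peak. Cells whose decline from that start is less than half the start
area (`minTotalDeclineFrac = 0.5`) are flagged unclassifiable; tracks
that end at the movie end or while touching the border are censored,
not ingressions. An earlier formulation based on a suffix-maximum
placed starts many frames early on cells whose pre-constriction
oscillation drifts downward, which silently diluted the per-cell rate
summaries with oscillation frames — the running-trough rule fixes that
while preserving the flat-plateau and strict-decline behaviors.

The per-cell **mean constriction rate** over the period is
$(\mathrm{area}_{start} - \mathrm{area}_{end})/\mathrm{duration}$.
Time fractions split frames by sign of the rate (a dead-band of exactly
0 by default: rasterized areas genuinely produce zero differences);
mean contraction (expansion) rate is the mean of the positive
(absolute negative) rates.

## Events and the 30-minute rule

An ingression event is a track that terminates by label disappearance
before the final frame, away from the border. Two events are candidates
for clustering when their times differ by *less than* 30 min (30 min or
more is isolated — the boundary belongs to "isolated"); they are joined
when the two cells were adjacent. Adjacency is anchored at the last
frame both cells exist, with a lookback of one clustering window: the
shared junction of two deeply constricted cells can fall below the
skeleton retention threshold (2 px) in the final frames even though the
cells remain neighbors, and the lookback makes the rule robust to that
measurement artifact. Connected components define clusters, so chained
clusters whose extreme members are more than 30 min apart are possible
and intended. Classification is order-independent and cluster sizes
partition the events.

The per-hour ingression rate divides events in a domain within each
sliding 60-min window by the cells present in the domain at the window
start (the denominator convention is a documented default; time-averaged
occupancy would be the alternative). The streak domain is a band of
± 20 µm around a configured midline.

## Fixed-tissue quantification

Junction intensities can be normalized three ways: per-embryo grand
mean (the default for anisotropy), pooled-cohort grand mean (for
genotype comparisons, so both genotypes share one scale), or each
junction by the mean medial intensity of its member cells. Per-cell
anisotropy uses the sample SD and the Max/Min ratio of the junction
means, requiring at least 3 retained junctions and positive
intensities; junctions with the exterior are excluded by default. The
planar-polarity nematic is
$Q = \sum_j w_j e^{2i\theta_j} / \sum_j w_j$, $w_j = I_j L_j$;
intensity times length is the geometry weighting, and cell-shape
elongation is reported separately rather than folded into the weights.
Note $|Q|$ of a *uniform* channel equals the cell's length-weighted
shape nematic, which vanishes only for symmetric cells — the zero-
polarity test fixtures are therefore regular hexagons, and on irregular
tissue the polarized-versus-uniform comparison is made against the
uniform channel's baseline.

Pairwise channel correlation min–max normalizes both channels to
[0, 1] per embryo against the 1st–99th percentile range (hot-pixel
resistant; exact min/max by flag). The low-intensity filter retains
junctions whose maximum across the two normalized channels exceeds the
`q`-quantile of that maximum (default `q = 0.5`; the threshold behind
"low-intensity junctions removed" is not a community constant, so it is
exposed). Reciprocal enrichment between the actomyosin-like and
Crumbs-complex-like groups is expressed on high-intensity junctions:
unfiltered pooled correlation is near zero, the filtered correlation is
negative, and within-group pairs stay positive — the acceptance tests
check exactly this sign pattern across 100 seeded repaints.

Group comparisons use the unpaired two-sided Mann-Whitney test (exact
enumeration when the combined sample is ≤ 20 without ties, tie-corrected
normal approximation otherwise) for pairs of conditions and classic
equal-variance one-way ANOVA for multi-group comparisons; no
multiple-testing correction is applied by default, matching the
raw-p-value reporting convention of the phenotype tables. The s.e.m.
unit is cells pooled across embryos. Embryo-level mixed-effects
modelling is a known limitation, not attempted here.

## The synthetic generator

The generator exists so that every stage has a no-download oracle. It
is a geometric, not mechanical, model:

* **Tissue**: Lloyd-relaxed Voronoi partition of a square field sized
  so the mean apical area is 45 µm² (apical surfaces span roughly
  20–80 µm²), kept as a shared-vertex polygon mesh and rasterized by
  half-open scanline rules so adjacent faces partition the pixel grid
  exactly. Default 0.17 µm/px makes 3 px ≈ 0.5 µm.
* **Dynamics**: ingressing cells (45% of interior cells by default)
  receive a schedule of 2–4 constriction pulses — three-frame profiles
  with half-magnitude shoulders, magnitudes drawn around a mean of
  1.4 µm²/min — separated by 1–3 stable frames drifting at a
  sub-threshold 0.2 µm²/min (cells spend most of the constriction
  period contracting; the mean expansion rate stays near 0.1 µm²/min).
  The schedule's area budget is matched to the cell's actual initial
  polygon area; when scaling would push a pulse below 0.9 µm²/min the
  cell gets one pulse fewer instead of a truncated schedule, so every
  programmed pulse clears the ≈ 0.7 threshold. Per phase, one or two
  scheduled junctions shrink: both endpoints move toward the cell
  centroid plus toward each other (the chord scales by
  $1 - 1.5\alpha$), with $\alpha$ root-solved each frame so the face's
  polygon area follows the programmed trajectory exactly even while
  the tissue oscillates. At the frame after its last scheduled frame
  the face collapses to its centroid and the label disappears; the
  freed area passes to the neighbors, so total labelled area is
  conserved — the bookkeeping oracle asserts conservation, not
  decline.
* **Oscillation**: every vertex (except the pinned field boundary)
  follows a smooth sinusoid with random direction, phase, and period
  (~40 min), amplitude 0.7 µm. The amplitude is calibrated once so that
  the mean-plus-one-SD construction on the pooled contraction rates of
  an undisturbed recording lands near the 0.7 µm²/min reference
  threshold; balance (contracting-time fraction 0.50, population mean
  signed rate ≈ 0) follows from symmetry and is asserted, not tuned.
* **Clustering plan**: event sizes follow the observed 48/37/11/4
  percent split of cells into singles/pairs/triplets/quadruplets (or an
  explicit plan); members of one event ingress one frame apart, and
  adjacent events are separated by more than the 30-min window so the
  plan is recoverable exactly. Placement and timing are stochastic with
  retries; a genuinely unrealizable plan raises a parameter error.
* **Channels**: junction loads share a lognormal per-junction scale; on
  the top tertile a logistic latent split loads "M" (actomyosin-like)
  and "C" (Crumbs-complex-like) channels reciprocally, while channels
  within a group share the split (positive correlation, kept below 1 by
  per-channel lognormal jitter, SD 0.3). Optional planar polarity
  multiplies loads by $1 + A\cos 2(\theta - \theta_0)$; blur and
  Poisson noise are off by default. Painted per-junction means are
  recorded as ground truth.

What the generator does **not** emulate: force balance or tension
(junction moves are kinematic), neighbor exchanges (T1 transitions,
off by default), cell division, out-of-plane motion, midline-directed
convergence or cell influx, imaging noise floors, and segmentation
errors. Passing tests therefore demonstrate that the *analysis* is
correct on data with the assumed structure, not that real tissue obeys
the generator. Two consequences are worth stating: the field-level
ingression rate of a default run (~10%/hour) is far below a
streak-domain figure, because the ingressing fraction is spread over
the whole field and the whole recording with no influx; and the mean
constriction rate over the period (~0.7 µm²/min under defaults) sits
below a pulse-dominated estimate because stable phases consume a third
of the period.

## Problem sizes and numerical choices

Simulation-heavy tests and the acceptance script run at 0.3 µm/px with
80-cell fields — the same generator model at a coarser raster, where
the area quantum (0.09 µm²) keeps rate noise two orders of magnitude
below the pulse threshold. The acceptance script uses three
pseudo-embryo recordings plus one reference recording (~200 annotated
ingressing cells, ~1000 pooled reference rates) and a 70-cell painted
tissue (~190 junctions). Vertex merging in the mesh uses a 10⁻⁶ µm
tolerance; junction-move roots are solved to 10⁻¹⁰; rasterization
holes left by strongly deformed polygons (a star-shaped face can turn
non-simple near collapse) are filled with the modal neighboring label
so the partition stays valid. Tables round-trip CSV at 17 significant
digits; label TIFFs round-trip bit-exactly through 16-bit pages.

## Known limitations

* The junction skeleton rule is a documented stand-in for whatever the
  upstream segmentation tool does internally; lengths of strongly
  curved junctions are mildly underestimated by the principal-axis
  extent.
* Track bridging only spans single-frame dropouts; longer gaps split
  tracks and per-cell statistics treat the segments separately.
* The per-hour rate denominator uses cells present at window start.
* Mann-Whitney exactness is abandoned in the presence of ties even for
  small samples (the tie-corrected normal approximation is used).
* Cluster classification inherits the transitive-closure property:
  percentages by cluster size refer to cells, with chained clusters
  counted at their full size.
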