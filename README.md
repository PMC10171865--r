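# apicodyn

Quantification of pulsed apical constriction, asynchronous junction
shrinkage, ingression-event clustering, and junctional protein
anisotropy in segmented epithelial tissue.

During epithelial-to-mesenchymal transitions, single cells leave an
epithelial sheet by constricting their apical surface until it
disappears ("ingression"). In time-lapse recordings of a segmented,
tracked apical surface this shows up as a ratchet: the apical area
shrinks in discrete pulses separated by more stable phases, individual
cell–cell junctions shorten asynchronously, and neighboring cells
ingress either independently or in small clusters. In fixed tissue,
the proteins decorating apical junctions (actomyosin components on one
hand, Crumbs-complex and junctional proteins on the other) accumulate
anisotropically and reciprocally across the junctions of a cell.

`apicodyn` implements this entire quantification pipeline for tracked
label-image series (or equivalent long-format measurement tables), plus
a seeded synthetic-tissue generator so every stage can be validated
against machine-readable ground truth without microscopy data.

## The quantities it computes

* **Contraction/shrinkage rate** (contraction-positive convention):
  `rate(t) = (value(t−1) − value(t)) / Δt`, in µm²/min for apical areas
  and µm/min for junction lengths, at the native frame interval
  (default 5 min), unsmoothed.
* **Constriction pulses**: maximal runs of frames whose contraction
  rate exceeds a reference threshold `mean + k·SD` (k = 1) built from
  the pooled contraction rates of non-ingressing epiblast cells
  (≈ 0.7 µm²/min under the default conditions). Pulse magnitude is the
  maximum rate within the pulse.
* **Constriction period**: from the onset of the final continual
  decline of the (smoothed) apical area — the peak after the last
  re-expansion above a tolerance — to the last frame the label exists.
* **Ingression events and the 30-min rule**: a cell that loses its
  apical label before the movie ends (away from the border) is an
  ingression; two events are clustered when the cells were adjacent
  neighbors and ingressed less than 30 min apart, isolated at 30 min or
  more; connected components give cluster sizes (singles, pairs,
  triplets, ...).
* **Junction shrinkage by phase** and the **pairwise correlation
  matrix** of junction length series within a cell (asynchrony).
* **Junctional anisotropy** per cell: sample SD and Max/Min ratio of
  the mean junctional intensities (3-px-wide bands, ≈ 0.5 µm).
* **Planar-polarity nematic** per cell:
  `Q = Σ w_j e^{2iθ_j} / Σ w_j` with weights `w_j = I_j·L_j`
  (intensity × length); magnitude in [0, 1], axis folded to [0, 180).
* **Orientation binning** (15° half-open bins) and **pairwise channel
  correlation** with min–max normalization and the low-intensity
  junction filter that exposes reciprocal enrichment.
* **Group statistics**: unpaired two-sided Mann-Whitney (exact for
  small samples) and one-way ANOVA, with WT-vs-mutant report tables.

## Worked example

```r
library(apicodyn)

tissue <- generateTissue(nCells = 40, seed = 42)
sim    <- simulateDynamics(tissue, dynamicsParams(seed = 42))
sim
#> SegmentedFrameSeries with 42 frame(s)
#>   grid: 254 x 254 px; 40 cells in frame 1
#> Calibration: 0.17 um/px, 5 min/frame

tracks <- buildTracks(sim)

## reference threshold from an oscillation-only recording
ref <- simulateDynamics(generateTissue(nCells = 40, seed = 43),
                        dynamicsParams(fracIngressing = 0, seed = 43))
refTracks <- buildTracks(ref)
pool <- unlist(lapply(split(refTracks$cells, refTracks$cells$cell_id),
    function(tr) { r <- rateSeries(tr$area_um2, 5); r[r > 0] }))
(thr <- referenceThreshold(pool, k = 1))
#> PulseThreshold: mean 0.334 + 1 x SD 0.267 = 0.602 um^2/min

gt  <- groundTruth(sim)                   # what was programmed
cid <- gt$cells$cell_id[1]
ann <- annotateConstriction(tracks$cells[tracks$cells$cell_id == cid, ],
                            thr, max(tracks$cells$frame), 5)
ann
#> ConstrictionAnnotation: frames 10-24, 4 pulse(s), mean rate 0.64 um^2/min

ev <- detectIngressions(tracks$cells, max(tracks$cells$frame),
                        calibration(sim))
ev <- classifyEventClusters(ev, tracks$junctions)
table(ev$cluster_size)
#> 1 2
#> 5 4
```

The annotation reports the constriction period in frames, the detected
pulses (start/end/magnitude in µm²/min) and per-cell summaries (mean
constriction rate over the period, fractions of time contracting /
expanding / stable). Here the detector finds 4 supra-threshold runs for
a cell programmed with 3 pulses — the threshold from this small
reference pool (0.60) sits low enough that one pulse shoulder splits
off; with the study-scale reference pool the threshold is ≈ 0.7 and
counts match the programme for ≥ 95% of cells (see the test suite).
The event table shows 5 isolated ingressions and 2 pairs (4 cells),
recovered exactly from the generator's clustering plan.

A full run — simulate → measure → kinetics → events → anisotropy, with
every artifact and a provenance echo written to disk — is one call:

```r
runPipeline(runConfig(outDir = "run1", seed = 1, nCells = 60,
    channelSpec = list(
        ppMRLC  = list(group = "M", junctional = 4, medial = 1),
        Crumbs2 = list(group = "C", junctional = 4, medial = 1))))
```

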