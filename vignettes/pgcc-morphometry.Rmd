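---
title: "Quantifying polyploid giant cancer cells by nuclear morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polyploid giant cancer cells by nuclear morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgccscope)
```

## The measurement problem

Polyploid giant cancer cells (PGCCs) are a rare sub-population of cancer
cells carrying extra chromosome sets in one giant nucleus or several
nuclei. They resist chemotherapy and can seed relapse, so compound screens
need to report not just bulk viability but specifically how many PGCCs
survive a treatment. Flow cytometry can count PGCCs by DNA content but is
impractical for screening hundreds of compounds or for watching PGCC
induction over time. Image cytometry is: a Hoechst-stained field imaged at
4x or 10x holds thousands of cells, and PGCCs are identifiable by nuclear
area alone once dead cells are excluded.

`pgccscope` implements that pipeline in three steps:

1. **find nuclei** in the Hoechst (or nuclear-RFP) channel,
2. **gate viability** from Calcein-AM (Live) and Ethidium-homodimer (Dead)
   stain intensities — live cells are Live-bright and Dead-dim,
3. **call ploidy class** by nuclear area: a live cell whose nuclear area
   strictly exceeds the threshold is a PGCC, the rest are non-PGCCs.

## Segmentation model and its knobs

The nuclear channel is enhanced by the classic morphological combination
`img + whiteTopHat(img) - blackTopHat(img)` with a disc structuring
element, then contrast-stretched so the 1st/99th intensity percentiles map
to [0, 1] (clipped). The disc radius (default 50 px at 10x, scaled
linearly with magnification) must exceed the largest expected nucleus
radius, otherwise nuclei themselves are treated as background. Two caveats
worth knowing:

* this enhancement *boosts small-scale contrast*; it does not subtract a
  smooth gradient from the output. The useful guarantee is that nuclei
  stand further above the local background after filtering (that is what
  the binarization needs), not that the output is globally flat.
* the percentile pair is otherwise unconstrained; (1, 99) keeps up to 1%
  saturated pixels at either end, which is robust across the 2x staining
  and exposure perturbations exercised in the robustness sweep.

Binarization is Otsu's between-class-variance threshold over a 256-bin
histogram of the corrected image (a fixed threshold is available). A
single-valued image has no threshold; that case yields an all-background
mask with a warning rather than an error, so empty time-lapse frames count
zero cells.

Connected components are labeled under 8-connectivity by default
(4-connectivity available). Labels are renumbered consecutively in order
of each component's smallest column-major pixel index, which makes
labeling a pure function of the mask — re-running a plate produces
byte-identical outputs. Components touching the image border are removed
by default (partial nuclei bias areas downward). Objects smaller than
`min_area_px` (50 px at 10x, scaled with magnification squared) are
flagged as debris and excluded from all counts; the flag is a pure size
rule, so raising the cutoff can only increase the debris count.

Merged nuclei are the main residual failure mode: two nuclei closer than
about the PSF width segment as one component, which the area rule may then
miscall as a PGCC. `split_touching = TRUE` subdivides components whose
solidity drops below 0.9 using a distance-transform watershed; it is off
by default because splitting is a heuristic layered on top of the core
area rule and should be an explicit operator decision, and every record
carries its solidity so suspicious objects can be audited. At 4x (1.65
um/px) nuclei separated by less than ~4 um can still merge — in a
simulated 10,000-cell field this loses roughly 7 cells in 10,000.

Per-object measurements are taken over the object mask dilated by 2 px
(shared across channels). Where two dilated rims collide, the higher label
wins; the rims of neighbouring nuclei are at least `min_separation` apart
in all simulated data, so the tie-break is exercised only on real,
crowded fields. The rim dilution is size-dependent — small nuclei have
proportionally more rim than large ones — which inflates PGCC/non-PGCC
intensity ratios by roughly 10–30% at default geometry. The ROS
fold-change comparisons should therefore be read as approximate effect
sizes, not calibrated ratiometry; the background pedestal partly cancels
the inflation, and the simulator tests hold the recovered fold within 20%
of the planted one.

## Viability gating

The quadrant logic is `live iff mean_live > live_threshold AND mean_dead
<= dead_threshold`. Fixed thresholds (camera units) are first-class;
`auto_gates()` derives them as the Otsu split of `log10(intensity + 1)`
across records. **Auto gating presumes both populations are present in
non-negligible proportion.** A field with 0.1% dead cells gives a live
histogram with essentially one mode, and a global variance split lands
inside it, miscalling half the population. Derive auto gates from pooled
control wells that contain real dead cells (what `process_plate()` does),
or pass fixed gates — that is also why the 10,000-cell capacity runs use
fixed gates.

Dead is a terminal class: the nuclear size of a dead cell is never
interpreted as ploidy. In time-lapse mode viability staining is absent by
design (the stains are phototoxic over days), so every non-debris object
is treated as live.

## The area threshold

The threshold is 300 px at 4x and `round(300 * (10/4)^2) = 1875` px at
10x — areas scale with magnification squared — equivalently 817 um^2, a
circle of diameter `2 * sqrt(817 / pi) ≈ 32` um. Both parameterizations
are supported: pixel mode reproduces the standard per-magnification
calibration; physical mode (um^2) is magnification-independent and
preferred whenever the pixel size is known. The tie-break is strict: a
nucleus exactly at the threshold is a non-PGCC ("larger than"). The
threshold is an empirically calibrated operational definition (typically
validated against flow-cytometry DNA content); the package treats it as
a parameter and does not re-derive it.

## Screening statistics

Per-well counts of non-PGCCs, PGCCs, dead cells and debris feed
per-compound comparisons against control: two two-sided unpaired
pooled-variance t-tests (Fisher's-LSD flavour, no multiplicity correction
by default; Benjamini–Hochberg optional) on the non-PGCC and PGCC counts.
Categories combine directions of the significant differences — decreases
in both counts (`kills_both`), in PGCCs only (`kills_pgcc_only`), a PGCC
increase (`induces_pgcc`, taxane-like), a non-PGCC-only decrease
(`kills_non_pgcc_only`), else `inactive`. When both groups have zero
variance the t-statistic is degenerate; identical means give p = 1 and
different means p = 0, so total kills are still categorized.

Calibration is reported per endpoint test: over simulated inactive
compounds (all counts i.i.d. Poisson from the control distribution, and a
fresh control per compound so the rate measures the procedure rather than
one control draw) the fraction of endpoint tests rejecting at alpha =
0.05 is close to 0.05. A compound-level "any endpoint significant" rate
under two endpoints is necessarily near `1 - 0.95^2 ≈ 0.10`; that is a
property of unprotected LSD testing, not a miscalibration.

Dose–response uses the four-parameter logistic
`r(c) = bottom + (top - bottom) / (1 + (c/IC50)^hill)` fitted by
Levenberg–Marquardt on log10 concentration from a grid of 40 starts
(both hill signs, IC50 across the tested range), keeping the best
residual sum of squares. A fit is flagged non-converged when responses
are flat or the IC50 lands more than 100x outside the tested range. The
model is equivariant under concentration rescaling, so units cancel in
IC50 ratios.

## Time-lapse counting, tracking, transitions

Frames carry a nuclear-RFP channel and timestamps in minutes (typically
every 30 min); segmentation and area-based calling run per frame with no
viability gate. Tracking is greedy nearest-neighbour with a displacement
cap and a frame-gap tolerance, ties broken deterministically by lower
track id and detection label. Greedy linking is adequate at screening
densities where per-frame motion is far below the inter-nuclear distance;
it will fragment tracks in dense, fast-moving populations (a global
assignment would be the upgrade). A non-PGCC→PGCC transition is recorded
when a track's area crosses the threshold and stays above it for at least
3 consecutive frames — the persistence requirement debounces single-frame
area flicker for nuclei hovering at the threshold.

## What the simulator emulates — and what it does not

The bundled generator renders elliptical nuclei (log-normal
area-equivalent diameters; the ellipse with axis ratio q gets semi-axes
`d/2/sqrt(q)` and `d/2*sqrt(q)`, so its area is exactly `pi (d/2)^2`)
placed by grid-accelerated rejection sampling with a minimum boundary
gap, over a background of pedestal + random plane + one low-frequency
blob, blurred by a Gaussian PSF (sigma 1.5 px), with Poisson shot noise
and Gaussian read noise on a 16-bit scale. Live/Dead/ROS amplitudes are
log-normal per class: live cells Live-bright/Dead-dim, dead cells the
reverse, PGCC ROS medians a configurable fold (default 3) above
non-PGCCs. Debris is rendered as bright sub-cutoff specks (3.5–5 px),
like condensed chromatin fragments, so the size rule — not intensity — is
what excludes it.

Deliberate idealizations, all of which make the ground truth exact and
the validation interpretable rather than the images photorealistic:

* **Size distributions are truncated** away from an ambiguity band around
  the 32 um threshold (non-PGCCs below 28 um, PGCCs above 36 um medians
  15/40 um, sdlog 0.15/0.10). Real populations straddle the threshold;
  with overlap, "the true class" of a borderline cell is not well defined
  and exact count recovery would be meaningless. This mirrors common
  practice when assembling reference populations by sorting: ambiguous
  borderline cells are excluded.
* Nuclei are convex ellipses; multi-lobed PGCC nuclei and touching nuclei
  are not modeled (the watershed splitter is therefore validated only on
  synthetic dumbbells).
* The PSF is an isotropic Gaussian; no aberrations or vignetting.
* In time-lapse sequences the background/noise stream is re-seeded
  identically every frame ("frozen noise"), so a static scene renders
  bit-identical frames and sequence generation is reproducible
  frame-by-frame. Real cameras draw fresh noise per exposure; frozen
  noise correlates per-frame segmentation errors, which is conservative
  for testing determinism and harmless for counting fidelity.
* Scripted transitions grow the area-equivalent diameter geometrically
  through the threshold (factor 1.25 per frame, half-step aligned, so one
  frame before crossing a cell is ~21% below the threshold area and at
  the crossing frame ~23% above). The decisive crossing makes the true
  transition frame unambiguous against a few percent of measurement
  bias. It compresses real induction kinetics (days) into hours; the
  fidelity being tested is the detector's, not the biology's.

Passing against this simulator demonstrates that the measurement chain is
correct and robust to staining/exposure scaling; it does not certify
performance on crowded, irregular, real fields — there the solidity
audit, the watershed option and fixed gates are the operator's tools.

Problem sizes used in the validation suite: one 1024x1024 field with 105
cells plus debris for exact-recovery and the 3x3 staining/exposure sweep;
a 93-well 512x512 screen (30 compounds, 3 replicates) for planted-effect
recovery; 1000 simulated inactive compounds for calibration; 100 noisy
4PL curves; a 48-frame 896x896 sequence with 20 scripted transitions; and
one 2262x2262 field with 10,000 nuclei at 4x for capacity.

## Numerical choices

* Otsu thresholds use 256 equal-width bins over the observed range; the
  returned threshold is the upper edge of the optimal bin.
* `threshold_for_magnification` rounds to the nearest pixel
  (`round(base * ratio^2)`), reproducing 300 → 1875 exactly.
* Centroids are 0-based (row, col) means of member pixels; areas are
  pixel counts; physical areas multiply by the squared pixel size.
* Solidity is area over the convex-hull area of pixel centres, clamped to
  (0, 1] (for tiny objects the pixel-centre hull underestimates).
* Per-well simulation seeds derive from the master seed by an FNV-style
  string hash of the well id, so plate generation is independent of
  iteration order. All simulation runs under Mersenne-Twister with
  inversion sampling, restored afterwards so callers' RNG streams are
  untouched.
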