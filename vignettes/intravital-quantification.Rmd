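---
title: "Quantifying migration and lesion composition in intravital two-channel tumor movies"
author: "ivquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying migration and lesion composition in intravital two-channel tumor movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivquant)
```

# Scope and data model

ivquant quantifies time-lapse movies of tumors imaged in live mice in which
every tumor cell carries a constitutive RFP lineage label and the Lgr5⁺
stem-cell subset additionally expresses an eGFP reporter. A movie is a
`MovieStack`: a T-frame, two-channel 2D stack of 12-bit integer counts with
a pixel size (μm) and a frame interval (h). The coordinate convention is
x = column index increasing rightward, y = row index increasing downward,
origin at the center of the top-left pixel; positions are reported in μm.

The pipeline is: **register** (remove rigid XY tissue drift) → **detect and
link** (track table) → **migration metrics** (migratory flag, single/cluster
mode, per-animal fractions) → plus an independent **lesion-scoring** branch
for fixed sections, and the small **statistical toolkit** used in reports.

# Drift correction

Tissue drift between hourly frames is modelled as a per-frame rigid integer
XY translation; within-frame elastic deformation and axial (Z) motion are
out of scope here. Every frame is corrected to the first time point.

The similarity measure is the Pearson correlation computed **only on pixels
whose gray value is strictly positive in both images** (`pearsonOverlap()`).
Because shifted frames are zero-filled, vacated borders exclude themselves
from the mask automatically. Two numerical guards exist: the mask must hold
at least `minOverlap` pixels (default 64) and must have non-zero variance in
both images — both raise a *degenerate overlap* condition, deliberately
distinct from a dimension mismatch.

`greedyAlign()` hill-climbs this correlation: from the current shift, the
four unit moves (left, right, up, down) are each evaluated, and the best one
is applied if and only if it strictly increases r; the loop stops when no
move improves the coefficient or after `maxSteps` (default 200, far above
any realistic drift). Design choices worth stating:

* **Best-of-four with a fixed tie order** (left, right, up, down). Trying
  moves one at a time and accepting the first improvement would make the
  result depend on evaluation order; best-of-four is order-independent and
  reproducible, and on a unimodal correlation surface reaches the same
  optimum.
* **Only 4-neighbourhood integer moves** — no diagonals, no sub-pixel
  refinement, no rotation or scaling.
* **Warm start.** `registerMovie()` initializes each frame's search at the
  previous frame's accepted shift: drift accumulates over a session, so the
  optimum for frame t is near frame t−1's, and the greedy search then only
  has to cover the per-frame increment.
* **Degenerate frames do not abort a run**: the frame is flagged
  unconverged, inherits the previous shift, and a warning is emitted.
* The accepted-correlation sequence is strictly increasing by construction;
  the `rTrace` element exposes it for inspection.

Greedy search finds the global optimum only when the correlation-vs-shift
surface is unimodal. That holds for the fixtures used in testing (blobs and
smoothed textures on a positive background) and empirically for the
generator's movies; it is *not* guaranteed for arbitrary images, which is
why the original procedure retained a visual QC step that has no
computational counterpart here. The test suite checks equivalence with an
exhaustive search over a ±10 px window on 50 unimodal fixtures.

Correction success uses the field's operational rule: landmark (static)
cells are tracked in the corrected movie and the correction is successful
when every landmark moves **less than half a cell diameter net over 4 h**
(`validateCorrection()`, strict inequality).

# The synthetic-data generator

No imaging data accompanies the source study, so the generator is the
package's test bed and defines the study conditions under which everything
is validated.

What it emulates:

* hourly acquisition over a 4-h window (5 frames, 1 h interval) in 12-bit
  counts;
* cells as isotropic 2D Gaussian intensity blobs with σ = diameter/4,
  diameters ~ N(15, 1.5²) μm; Lgr5⁺ cells rendered with the same footprint
  in the GFP channel (the real reporter is membrane-bound; a ring render
  would not change what the disk-footprint classifier is asked to do);
* a 192 × 192 μm field at 1 μm/pixel — a typical single-field crop — with
  RFP/GFP backgrounds of 100/30 counts and blob amplitudes of 2500/2000
  counts, plus additive zero-mean Gaussian noise (default sd 20 counts,
  i.e. high SNR, with noise level freely configurable);
* rigid integer-pixel drift, by default an accumulated random walk with
  per-frame steps uniform on [−2, 2] px;
* migratory cells moving 4 μm per frame (16 μm net over the window, about
  twice the 7.5 μm migratory threshold) with constant heading plus small
  angular jitter (sd 0.1 rad); static cells jitter by 1% of their diameter
  per frame, keeping total wander far below a tenth of a diameter;
* cluster events as pairs co-moving at 0.9 × the sum of their radii —
  always in contact under the κ = 1.2 rule.

Placement makes ground-truth labels self-consistent: any two cells not in
the same cluster event keep at least 1.6 × the sum of their radii apart in
*every* frame (rejection sampling; an impossible request raises a
configuration error). Singles therefore never register sustained contact
even with moderate diameter-estimation error, and blobs stay resolvable.
Where the source protocol reports no value (cell diameters, densities,
noise), defaults were chosen once for testability and realism, not fidelity
to unpublished movies.

What it does **not** emulate — and what passing tests therefore cannot
show: elastic tissue deformation, Z drift, photobleaching, intensity decay
with depth, the collagen second-harmonic channel, cell division/merging,
and densely packed tumor parenchyma in which manual tracking judgment was
needed. Results on synthetic movies validate the algorithms' contracts, not
performance on arbitrary real tissue.

The lesion-table generator draws diameters uniformly and applies a step
rule: lesions above the plasticity threshold L\* always contain Lgr5⁺
cells; below it they do with probability p₀ — except single-cell-scale
lesions (diameter ≤ mean cell diameter), which are always Lgr5⁻. The
packaged defaults are L\* = 80 μm and p₀ = 0.4.

# Detection, classification, linking

`detectCells()` runs difference-of-Gaussian (DoG) scale-space blob detection
on the RFP channel over geometrically spaced scales spanning the expected
diameter range (default 8–30 μm, 8 scales). Detections are local maxima in
space and scale above a response threshold (default 25 counts — well above
the smoothed-noise floor at the default noise level, and zero-response blank
frames yield zero detections rather than an error). Two calibration details
matter:

* a DoG pyramid with scale ratio ρ peaks at σ_peak = σ_blob/√ρ for a
  Gaussian blob, so the blob σ is estimated as σ_peak·√ρ after parabolic
  interpolation of the response over log-scale;
* since the render model is a Gaussian with σ = diameter/4, the reported
  diameter is 4 × the estimated blob σ. On noiseless fixtures this recovers
  rendered diameters to within ~10%, which is ample for the half-diameter
  rule (migratory cells move ≈ 2 × threshold) and for the contact rule
  (margin 1.2 vs generated separation 0.9 summed radii).

Centroids are response-weighted and sub-pixel (< 1 px error on the
generator's movies). `classifyLgr5()` thresholds each detection's mean GFP
intensity measured in a disk of half the estimated diameter; with
`"otsu"` the threshold is computed once per movie from the pooled
`mean_gfp` distribution, which is strongly bimodal under the reporter
model. Fewer than two detections make Otsu meaningless and raise an error
instructing a fixed threshold.

`linkTracks()` links consecutive frames greedily in order of increasing
pair distance with a cutoff (default 1.5 × mean detected diameter). Greedy
global-distance ordering is deterministic and order-independent; the
Hungarian-style optimal assignment is kept as a test oracle only, and the
two agree on the well-separated movies the generator produces. Every
detection belongs to exactly one track; unmatched detections open tracks,
unmatched heads close them.

# Migration metrics

`computeTrackMetrics()` evaluates each track on its first 4-h sub-window:

* **net displacement** — Euclidean distance between the first and the
  window-end position. "Displacement" means net start-to-end displacement
  (the quantity the migratory rule and the displacement distributions are
  defined on); cumulative **path length** is also reported for transparency.
* **velocity** — net displacement / window by default; the alternative
  path-length/window convention is available as `velocityMode = "path"` and
  recorded in the output, since the field does not use a single fixed
  definition.
* Tracks shorter than the window, or with a detection gap inside it, are
  excluded with a logged reason rather than erroring.

The migratory rule is strict: net displacement > 0.5 × cell diameter over
4 h. The diameter defaults to the track's mean detected diameter; a global
override exists for parity with manually scored data. Track-level Lgr5
state is a majority vote over member detections, with ties resolved toward
Lgr5⁺ — the rarer class, so a tie never inflates the headline Lgr5⁻
fraction.

`classifyMode()` labels migratory tracks: two migratory cells are in
contact in a frame when their center distance is ≤ κ (r_i + r_j) with
κ = 1.2, and a track is a *cluster* when in contact with another migratory
track in at least 75% of window frames. "Maintaining cell-cell contact"
implies sustained, not incidental, contact; 0.75 encodes "sustained" while
tolerating a single missed frame in a five-frame window. Modes are
exclusive and exhaustive over migratory tracks.

`aggregateByAnimal()` computes per-animal fractions over migratory tracks
and reports the group mean ± SEM **across animal-level values**, never
pooled over cells — the animal is the unit of analysis. Animals without
migratory tracks are excluded and listed, not counted as zero.

# Lesion scoring

`scoreLesionImage()` segments lesions as connected components of the
thresholded RFP section image, discards components smaller than one cell
(default minimum area π(d/2)² at d = 15 μm), reports the equivalent-circle
diameter 2√(area/π) — the measurement convention adopted here since the
source protocol does not state Feret vs equivalent-circle — and calls a
lesion Lgr5-containing when ≥ 5 GFP-positive pixels fall inside it (a shot
noise guard, configurable).

`binComposition()` groups lesions in half-open diameter bins; the default
edges {0, 20, 40, 80, 160, 320, ∞} μm straddle the 80-μm threshold and are
fully configurable. Counts are conserved (an overflow bin catches lesions
outside user-supplied finite edges) and per-bin fractions sum to one.

`plasticityThreshold()` returns D\* = the smallest observed diameter such
that every lesion strictly larger contains Lgr5⁺ cells; when the largest
lesion is itself Lgr5⁻-only no threshold exists and `NA` is returned. With
a step-rule table D\* equals the largest Lgr5⁻ diameter, i.e. the sample
maximum of the below-threshold negatives: its error relative to the true
L\* is of the order of one spacing of those order statistics
((L\* − d_cell)/(K + 1) for K below-threshold negatives — about 1 μm at
n = 500 on [10, 300] μm). Accordingly, the recovery test asserts that the
*median* error over repeated seeds stays within one such spacing, rather
than gambling on a single draw of a max-order statistic.

# Statistical toolkit

All tests report two-sided p values (the source only reports inequalities,
so sidedness is declared here, not inferred):

* `welchT()` — unpooled-variance t with Welch–Satterthwaite df. Zero
  variance in both samples: equal means give t = 0, p = 1; unequal means
  are flagged degenerate with p = NA.
* `mannWhitneyU()` — midrank ties; exact p by full enumeration when
  n₁ + n₂ ≤ 12 and no ties (enumeration cost caps the switch), else normal
  approximation with tie and continuity correction. Exact and approximate
  p agree within 0.02 at n = 6 + 6.
* `pairedT()` — one-sample t on differences; a constant non-zero
  difference has an infinite statistic and is flagged degenerate with the
  p value reported as the smallest positive double rather than 0.
* `sem()` — sd (n − 1 denominator)/√n.
* `normalityCheck()` — a Shapiro–Wilk wrapper for report annotation only;
  it never chooses the test, the caller does.

Base R's `t.test()` and `wilcox.test()` serve as independent cross-checks
in the test suite, alongside direct-formula, full-enumeration and
10⁵-resample permutation oracles; under the null the Welch rejection rate
at α = 0.05 stays within [0.035, 0.065] over 2,000 seeded replicates.

# Problem sizes and run times

The validation suite is sized for a single CPU: movies of 192 × 192 px × 5
frames; 50 registration fixtures at 48 × 48 px with exhaustive search over
±10 px; a cohort of 9 synthetic animals × 2 movies × 11 migratory cells
(198 events) for fraction and mode recovery; lesion tables of 500 rows over
20–50 seeds; 2,000 replicates for the null-rate check. These sizes were
chosen so each property is measured with comfortable statistical margin
while the whole suite runs in well under a minute of compute per heavy
block.

# Known limitations

* Registration is rigid, integer-pixel, 2D, and assumes a climbable
  correlation surface; elastic deformation and Z motion are out of scope.
* Detection and linking are tuned for the generator's well-separated blob
  regime; dense fields, dividing cells and dim cells need the human
  judgment that manual tracking supplied in the original workflow.
* Lesion scoring is per-section 2D; no 3D reconstruction across serial
  sections, no within-lesion cell counting.
* The Lgr5⁻ migratory fraction and the plasticity threshold are recovered
  from synthetic cohorts; the published in-vivo values rest on undeposited
  animal data and are not reproducible from this package alone.
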