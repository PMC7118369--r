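# ivquant

Quantification of intravital two-channel tumor time-lapse movies: drift
correction, cell tracking, migration statistics, and metastatic-lesion
scoring — with a seeded synthetic-data generator so that every stage can be
validated against known ground truth on a desktop, without animal data.

## The problem

Intravital multiphoton imaging of tumors in live mice records, every hour
over a 4–8 h session, a field of cancer cells carrying a constitutive
Confetti-RFP lineage label, with the Lgr5⁺ stem-cell subset additionally
marked by an Lgr5-eGFP reporter. Breathing and tissue relaxation cause
frame-to-frame XY drift that must be removed before any motion of individual
cells can be measured. Once registered, the questions are: which cells are
migratory, do they escape alone or as clusters, what fraction of escapers is
Lgr5⁻ — and, in liver sections, at what lesion size does every metastasis
contain Lgr5⁺ cells again.

## The core algorithms

**Drift correction.** Every frame *t* is registered to frame 0 by maximizing
the Pearson correlation *r* computed **only over pixels with gray value > 0
in both images**. Starting from the previous frame's shift, the four unit
moves (left, right, up, down) are evaluated; the single best move is applied
iff it strictly increases *r*; iteration stops when no move improves the
coefficient. Vacated pixels are zero-filled, so they self-exclude from the
mask. Success is declared when tracked landmark cells move less than half a
cell diameter net over 4 h in the corrected movie.

**Migration.** A tracked cell is *migratory* when its net displacement *d*
over the 4-h window satisfies *d* > 0.5 × cell diameter (strict). A
migratory cell is a *cluster* escaper when it maintains cell–cell contact
(center distance ≤ 1.2 × the sum of radii) with another migratory cell in at
least 75% of window frames, else *single*. Per-animal Lgr5⁻ fractions are
averaged across animals (mean ± SEM), the animal being the unit of analysis.

**Lesion scoring.** Lesions are summarized by equivalent-circle diameter
2·√(area/π) and by whether they contain Lgr5⁺ cells; the *plasticity
threshold* D\* is the smallest observed diameter such that every larger
lesion contains Lgr5⁺ cells.

## Worked example

```r
library(ivquant)

cfg <- simConfig(seed = 7)            # 192x192 um field, 5 frames, 12 cells
sim <- simulateMovie(cfg)             # movie + ground truth
res <- registerMovie(sim$movie)       # greedy Pearson drift correction
res$shifts
#> ShiftSeries: 5 frames, 5 converged
#>   max |dx| = 1 px, max |dy| = 3 px, min r = 0.4130

det     <- classifyLgr5(detectMovie(res$movie))   # blobs + Otsu GFP call
tracks  <- linkTracks(det)
metrics <- classifyMode(tracks,
             computeTrackMetrics(tracks, frameIntervalH = 1),
             frameIntervalH = 1)
metrics[metrics$migratory,
        c("net_displacement_um", "velocity_um_per_h", "lgr5", "mode")]
#>    net_displacement_um velocity_um_per_h  lgr5    mode
#> 1                 15.9              3.97 FALSE cluster
#> 2                 15.9              3.99 FALSE  single
#> 3                 16.0              3.99 FALSE cluster
#> 5                 15.9              3.99 FALSE  single
#> 9                 16.0              3.99 FALSE  single
#> 11                16.0              3.99 FALSE  single
```

Six of the twelve cells are migratory (net displacement ≈ 16 μm > half of
their ~15 μm diameter over 4 h), four escape as singles, one pair as a
cluster, and all migratory cells here happen to be Lgr5⁻ (the generator
draws migratory cells Lgr5⁻ with probability 0.9).

```r
tab <- simulateLesionTable(500, seed = 42)        # packaged step rule
binComposition(tab$lesions)[1:5, c(1:3, 7)]
#>   bin_lo_um bin_hi_um   n frac_contains_lgr5
#> 1         0        20  18              0.333
#> 2        20        40  37              0.351
#> 3        40        80  75              0.373
#> 4        80       160 144              1.000
#> 5       160       320 226              1.000
plasticityThreshold(tab$lesions)$dStarUm
#> [1] 79.75797
```

Below 80 μm roughly 40% of lesions contain Lgr5⁺ cells; above 80 μm all do,
and the recovered threshold lands just below the generating 80 μm rule (the
estimator is the largest Lgr5⁻-only diameter in the table).

A thin command-line dispatcher over the same functions is installed at
`system.file("cli", "ivq.R", package = "ivquant")` with subcommands
`simulate`, `register`, `track`, `quantify` and `score-mets`.

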