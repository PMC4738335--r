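---
title: "Quantifying MukBEF positioning, sister-locus cohesion and matS enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MukBEF positioning, sister-locus cohesion and matS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mukcoloc)
```

## Scope

The *E. coli* condensin MukBEF forms fluorescent clusters that normally sit
near the replication origin region (*ori*), interact with topoisomerase IV,
and are displaced from the terminus region (*ter*) by MatP, which binds
13-bp *matS* sites. Asking quantitative questions about this system means
running four measurements over and over: (i) are two fluorescent foci in
the same cell "colocalized", judged against what random placement would
give; (ii) how fast do foci form when the protein is resupplied
(repletion); (iii) how long do newly replicated sister loci stay together
(cohesion time); and (iv) where on the chromosome is the protein enriched
in ChIP (IP/mock), relative to *matS* positions.

mukcoloc implements these four analyses plus a synthetic-data module that
generates every input with known ground truth, so each stage can be tested
end to end without any external data. This vignette explains the models,
the defaults and the numerical choices; it states no result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Synthetic cells and images

`generate_cells()` builds rod-shaped cells as spherocylinders (a rectangle
with semicircular caps), the minimal *E. coli*-like geometry, laid out on
a non-overlapping tile grid. Cell segmentation itself is out of scope —
masks are inputs to the analysis stages, and the generator simply makes
realistic ones. Defaults: length 2.5 µm, width 1.0 µm (slow growth in
minimal medium), pixel size 129 nm so that the conventional 2-pixel
colocalization radius equals 258 nm.

Each cell receives one focus per channel with probability
`focus_fraction`. A fraction `coloc_fraction` of two-focus cells place
the channel-B focus at the channel-A focus plus isotropic Gaussian jitter
(default sd 40 nm per axis; at that jitter the probability that a truly
colocalized pair exceeds 258 nm is below 1e-9, so the truth label and the
threshold classification agree). Non-colocalized cells draw B uniformly
from the cell, resampled until it is strictly more than 2 px from A:
truth labels are unambiguous by construction.

`render_images()` draws each focus as a symmetric 2D Gaussian
(`psf_sigma_px` default 1.3 px ≈ 168 nm, a plausible sd for a visible
fluorophore at high NA; the true instrument PSF is a free parameter, not
a claim). Amplitude 200 counts over a background of 100 gives a Poisson
peak SNR of about 11, i.e. "clearly visible but not cartoonish". A
Gaussian noise model is available for fitting tests because it makes SNR
exact. Rendering conserves mass: with noise off, the image integral above
background equals the analytic Gaussian mass within 1%.

What the generator does **not** emulate: cell-to-cell background
variation, autofluorescence gradients, out-of-focus light, overlapping or
dividing cells, segmentation errors, photobleaching. Passing tests
therefore demonstrate correctness of the estimators on clean geometry,
not robustness to every microscopy artifact.

## Focus detection

`detect_foci()` finds in-mask local maxima above the cell median plus
`k`·MAD (default `k = 3`) and refines each by least-squares fitting of a
symmetric 2D Gaussian with constant offset (`fit_spot_gaussian()`,
Levenberg–Marquardt via minpack.lm). A symmetric Gaussian is the minimal
spot model; astigmatism and 3D localization are out of scope.

Quality flags instead of exceptions: a non-convergent fit returns the
initializing pixel flagged `weak`; fitted amplitude below 3 local noise
sd is `weak`; a centroid within 1 px of the window border is `edge`; and
a fitted sd below 0.7 px is `weak`, because a diffraction-limited spot
cannot be narrower than about a pixel at 129 nm/px — sub-pixel-wide
"spots" are noise spikes, and this width test is what keeps blank frames
at zero detections while the amplitude test alone would occasionally
pass a 3.5σ spike. Candidates whose refined centroids fall within one
fitted sd of a brighter accepted spot are merged, so unresolved doublets
are not double-counted.

`brightest_pixel()` is deliberately cruder: the argmax over mask pixels,
exactly one per cell, ties broken lexicographically by (row, col). It is
the right statistic when a protein forms diffuse or multiple structures
and a single per-cell intensity proxy is wanted (used both for ParC focus
definition and for repletion time courses).

## Colocalization and the random-pixel null

`min_centroid_distance()` is the per-cell shortest Euclidean distance
between channel centroids, in nm. Cells missing a focus in either channel
return a sentinel (`NA`) and are excluded — never counted as distance 0.
`colocalization_fraction()` reports the percentage of used cells at or
below the threshold (inclusive ≤ 258 nm); denominators are conditional on
cells that have foci in both channels, with `conditional = FALSE`
available for sensitivity analysis.

The null model (`random_pixel_null()`) draws pixels uniformly from each
cell mask (default 10 draws per cell, pooled; the appropriate draw count
is not knowable a priori, so it is a parameter) and measures the distance
from the nearest channel-A centroid to each drawn pixel centre. This
answers "what fraction of cells would pass the threshold if the second
marker were placed at random in the same geometry" — the correct baseline
because the cell's size and shape bound all distances. On a disc with a
central focus the null distances follow the analytic law F(d) = (d/R)²,
which the tests verify by KS distance.

## Repletion kinetics

`build_timecourse()` aggregates per-cell brightest-pixel intensities and
focus presence per time point within replicates, then across replicates
as mean ± SEM of replicate means (replicates are the unit of biological
variation; cells within a replicate are not independent experiments).
`fit_initial_rate()` is an OLS slope over the initial window, default
0–20 min — the linear phase of a fast strain — and per-series windows are
configurable because a several-fold slower strain stays linear far longer
and is sampled longer (to 90 min). When the focus-fraction metric is
fitted, the window must also stay below the strain's steady-state
plateau; the acceptance script fits the impaired strain's fraction over
0–60 min, where a 0.47 plateau is not yet reached.

The focus-fraction adjustment: when only a fraction f of cells ever form
foci, the population-mean brightest-pixel signal is diluted by the
(1 − f) focus-less cells. The exact functional form used originally is
not published; dividing the intensity by the steady-state focus fraction
(`adjust_by_focus_fraction()`) is the simplest correction that expresses
signal per focus-competent cell, it is logged in the output metadata, and
a no-adjust path exists for comparison. The generator's `focus_coupled`
mode plants exactly this dilution so the correction can be validated:
an f = 0.47 strain adjusted by 0.47 matches an f = 1 control.

`rate_fold_difference()` is a ratio of slopes, invariant to rescaling all
intensities — folds, not absolute rates, are the portable quantity.

## Cohesion time

Tracks are per-cell time series at a fixed interval (default 5 min, 24
frames = 2 h). Three rules, each chosen to be robust to observable
artifacts:

- **Replisome end** (`call_replisome_end()`): the first frame of the
  *terminal* focus-free run. Fluorescent foci blink; a single dark frame
  followed by reappearance must not be read as termination, and the
  terminal-run rule gives that robustness without any extra parameter.
- **Segregation** (`call_segregation()`): sister foci can transiently
  separate and re-merge just after replication while catenation links
  remain, so a frame-level "two foci" observation is not segregation.
  The call requires `K = 3` consecutive separated frames and returns the
  *first frame of the qualifying run* (the run's start is when separation
  began; the later frames only confirm persistence). When centroids are
  available, frames with an inter-focus distance below 2 px can be vetoed
  as unseparated.
- **Cohesion time** (`cohesion_time()`): measured interval (segregation −
  replisome end) plus a 7-min offset. The locus replicates ~2 min before
  replication terminates and the clamp takes ~5 min to unload, so the raw
  interval underestimates time-since-replication by ~7 min. Negative
  measured intervals are legal and meaningful — a locus that segregates
  5 min before the replisome clears has a 2-min cohesion time.

Censoring (replisome never disappears, or no qualifying run before the
track ends) is explicit; censored cells carry no cohesion time and are
excluded from population denominators by default rather than imputed.

`population_segregation()` reports the step-curve t50: the first time at
which at least half the scored cells have segregated, at frame
resolution. Because events are observed on a 5-min grid, every scored
cohesion time is a multiple of 5 plus the 7-min offset, and the step t50
inherits that quantization (it can be off the true median by up to half
a frame, which is the tolerance the tests use). The acceptance script
additionally reports the *mean* cohesion time per strain: when the
replication phase is uniform relative to the imaging grid, the expected
quantized interval equals the true interval, so the mean is an unbiased
estimate of delay + 7 and can legitimately take off-grid values such as
9 min.

The time-lapse generator plants transient pre-split separations and
post-split re-mergers as short geometric runs, always shorter than K and
positioned so they cannot join or break the qualifying run — this keeps
the planted truth unambiguous, which is what lets recovery be tested
exactly. Real transients are not so considerate; with K = 3 a real
separation adjacent to the true split shifts the call earlier by at most
the transient's length.

## ChIP enrichment

Coverage is consumed as binned counts (50-bp bins by default; sonication
fragments of 200–1000 bp make finer resolution illusory, so 50-bp bins
lose nothing). Pipeline order, each step its own function:

1. **CPM normalization** (`normalize_coverage()`): each library scaled to
   one million; simple, transparent, and sufficient when comparing the
   same genome across samples.
2. **Ratio of medians** (`median_ratio_track()`): per bin, median across
   IP replicates over median across mock replicates, each plus a
   pseudocount (default 0.5 CPM) that stabilizes near-empty mock bins and
   cancels exactly when IP ≡ mock. Median-then-ratio, not
   ratio-then-median: a single aberrant replicate must not dominate.
3. **Smoothing** (`smooth_track()`): centred moving average, 2-kb window,
   wrapping across the origin on circular chromosomes (mass is conserved
   exactly in circular mode).
4. **Top-N peaks** (`call_top_peaks()`): greedy selection of smoothed
   local maxima by descending score with 2-kb exclusion zones, N = 26 by
   default. Smoothing a narrow site with a wide window produces a
   flat-topped plateau on which the argmax is positioned by noise, so
   each selected peak is refined to the summit of the *unsmoothed* ratio
   within half a smoothing window — standard peak-caller practice, and
   what makes peak positions land within two bins of planted sites.
5. **Motif scanning** (`scan_motif()`): both strands, IUPAC degeneracy,
   configurable mismatch budget, palindrome-safe (forward/reverse hits at
   one position collapse to one). The *matS* consensus is configuration,
   not code — `run_config()` defaults to the field's 13-bp consensus —
   and the generator plants whatever consensus is configured. Tests hold
   the scanner to exact equality with a position-by-position brute-force
   oracle.
6. **Annotation** (`annotate_peaks()`): nearest hit within 500 bp, with
   an exclusion list for sites deliberately left out of an analysis.
7. **Anchored profiles** (`anchored_profile()`): windows (default ±1 kb)
   around a common anchor set, aligned, median across anchors per offset.
   Peak height is the profile maximum; flatness is max/median over the
   window (≈1 for a featureless condition). Anchors should come from a
   *reference* condition (e.g. the strongest, MatP-like signal), not from
   a condition being compared: anchoring a track on its own summits
   inflates its profile maximum by selection bias, on the order of 10% at
   realistic depth.

The coverage generator draws negative-binomial counts (dispersion 0.02,
a typical replicate-level overdispersion for bacterial ChIP), default
depth 2×10⁷ reads per sample (a typical Illumina lane share; tests that
specify a 10⁶-read condition use 10⁶), log-normal library-size factors
(sd 0.15), site enrichment applied within ±2 bins of each planted site in
IP only, and highly-transcribed-region artifacts applied to IP *and*
mock — mimicking the formaldehyde hyper-reactivity of highly transcribed
genes, which is exactly the signal class that the IP/mock ratio is there
to cancel. Note the per-bin raw ratio has ~16% sd at these settings, so
individual bins inside an artifact stray outside a ±25% band by chance;
cancellation is a property of the smoothed track and of medians, and is
tested as such.

What the ChIP generator does not emulate: GC/mappability bias, read-level
positional structure within fragments, copy-number gradients from ongoing
replication, or peak-shape asymmetry.

## Problem sizes and runtime

The test suite and acceptance script run everything at the sizes the
analyses are designed for: 2000 cells per colocalization setting, 100
fitted spots for localization accuracy, 50 tracks per strain, full-length
(4.64-Mb) genomes at 50-bp bins with 3+3 replicates for enrichment, and
100 random 100-kb sequences for the motif oracle. The whole suite runs in
under two minutes on one core; the acceptance script in about ten
seconds.

## Known limitations

- The detector assumes one background level per cell; strong intracellular
  gradients would bias the candidate threshold.
- The brightest-pixel metric saturates once every cell has a bright
  focus; it is an early-kinetics statistic.
- Cohesion scoring assumes at most one replication round per track; cells
  that re-initiate before the locus splits would need lineage-aware
  tracking, which is out of scope.
- The enrichment pipeline does not do statistical peak calling with FDR
  control; "top N by smoothed score" is the faithful reproduction of the
  analysis it implements, not a general-purpose caller.
- CPM normalization is composition-sensitive: heavily enriched IP
  libraries scale their background slightly below mock (sub-1% at 26
  sites on a full-size genome, visible on toy genomes).
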