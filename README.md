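# mukcoloc

Quantitative analysis of MukBEF/MatP/TopoIV biology in *Escherichia coli*
from live-cell fluorescence microscopy and ChIP-seq coverage — plus a
synthetic-data module that makes every stage testable against known
ground truth.

The *E. coli* SMC complex MukBEF forms clusters on the nucleoid that
normally associate with the replication origin region and recruit the
decatenase topoisomerase IV; MatP, bound to *matS* sites, organizes the
terminus region and displaces MukBEF from it. Studying this system
quantitatively requires four recurring measurements, and this package
implements each as a tested pipeline stage:

- **Focus detection** — sub-pixel 2D Gaussian fitting of fluorescent foci
  inside segmented cells, and the per-cell brightest pixel as a one-pixel
  focus proxy.
- **Colocalization** — per cell, the shortest centroid distance between
  two channels; the percentage of cells with distance ≤ 258 nm (2 pixels
  at 129 nm/px), judged against a random-pixel null drawn uniformly from
  the same cell masks.
- **Repletion kinetics** — brightest-pixel and fraction-of-cells-with-foci
  time courses after protein resupply; initial OLS rates over the linear
  window and fold-differences between strains, with a steady-state
  focus-fraction adjustment.
- **Cohesion time** — from time-lapse tracks: replisome-focus
  disappearance (terminal-absence rule), persistent sister-locus
  separation (K = 3 consecutive 5-min frames), cohesion time =
  measured interval + 7 min (replication-timing offset), and population
  segregation curves with t50.
- **ChIP enrichment** — per-bin IP/mock ratio of replicate medians on
  CPM-normalized counts, 2-kb circular smoothing, top-26 peak calling
  with summit refinement, degenerate IUPAC motif scanning (both strands),
  peak–motif annotation and anchor-centred metagene profiles across
  conditions.

The synthetic-data generators produce rod-shaped (spherocylindrical)
cells with two-channel foci at a controllable colocalization fraction,
rendered images with Poisson or Gaussian noise, per-cell trajectories
with replisome disappearance, transient sister separations and true
splits, and replicated negative-binomial IP/mock coverage with planted
motif sites and shared highly-transcribed-region artifacts. Every
generator is a pure function of its spec and seed.

## Worked example

Generate a field of 2000 cells in which 86% of two-focus cells are truly
colocalized (40-nm jitter), estimate the colocalized percentage, and
compare it with the random-pixel baseline:

```r
library(mukcoloc)

sim  <- generate_cells(sim_imaging_spec(n_cells = 2000,
                                        coloc_fraction = 0.86, seed = 1))
foci <- truth_focus_table(sim$truth)

colocalization_fraction(foci, threshold_nm = 258)
#> coloc_result: 84.8% of cells at <= 258 nm (2000/2000 cells used, conditional on foci)

null <- random_pixel_null(sim$cells, foci, n_draws_per_cell = 10, seed = 2)
sprintf("random-pixel null: %.1f%%", null$null_percent)
#> "random-pixel null: 9.1%"
```

The estimate (84.8%) tracks the planted truth within sampling error,
while random placement in the same cell geometry yields only ~9% — the
gap is what "colocalized" means here.

Score cohesion times for 50 simulated tracks in which sister loci split
2 min after replisome disappearance:

```r
tl    <- generate_timelapse(sim_timelapse_spec(n_cells = 50,
                                               delay_min = 2, seed = 3))
calls <- cohesion_calls(tl$tracks, cohesion_params(K = 3, offset_min = 7))
pop   <- population_segregation(calls)
sprintf("step-curve t50: %g min; mean cohesion: %.1f min (n = %d)",
        pop$t50_min, mean(calls$cohesion_time_min[!calls$censored]),
        pop$n_used)
#> "step-curve t50: 7 min; mean cohesion: 9.0 min (n = 50)"
```

The mean cohesion time recovers the planted 2-min delay plus the 7-min
offset exactly in expectation; the step t50 is quantized to the 5-min
imaging grid. See `vignettes/methods.Rmd` for why both are reported.

A shell entry point over the same functions is installed at
`inst/scripts/mukcoloc` (stages: simulate, coloc, repletion, cohesion,
chip), and `run_pipeline()` chains stages into artifact directories with
resolved configs and JSON summaries.

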