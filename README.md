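# exofa

Analysis of single-vesicle exocytosis relative to focal adhesions in
TIRF microscopy movies, with a fully synthetic ground-truth test bed.

## The problem

Receptors such as β1 integrin are delivered to the plasma membrane by
vesicular exocytosis. With an ecto-facing pHluorin tag, a cargo-loaded
vesicle is dark at acidic vesicular pH and lights up the instant the
fusion pore opens and exposes the cargo to neutral extracellular pH.
In a TIRF movie a bona fide full-fusion event therefore shows

1. a **rapid intensity rise** at the fusion frame, and
2. a **growing full width at half maximum** (FWHM) of the spot as the
   cargo diffuses laterally in the membrane:
   `sigma^2(t) = sigma0^2 + 2 D (t - t0)`, FWHM `= 2 sqrt(2 ln 2) sigma`.

The scientific question is spatial: do these fusion events occur
preferentially near focal adhesions (FAs)? The package answers it the
way the field does — measure each event's shortest distance to the
segmented FA mask, then compare against a Monte Carlo
complete-spatial-randomness (CSR) null in which the same number of
events is placed uniformly inside the cell footprint (>= 100
repetitions per cell), using a two-sample Student's t-test on per-cell
median distances. A surface-quench assay (membrane-impermeant
anti-fluorophore antibody) and a dual-label FA ratio time course
quantify the endocytic and recycling pools, and the flow-cytometric
activation index `AI = (F - F0) / F_integrin` is included as a small
utility.

Because raw live-cell movies for this kind of study are rarely
deposited, the package ships a first-class synthetic-movie generator
with known ground truth (quenched vesicles that de-acidify and spread
diffusively, elliptical adhesions, Poisson shot noise, Gaussian read
noise, photobleaching) so that every stage — segmentation, detection,
classification, spatial statistics, pool quantification — is validated
end to end against the truth.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (each writes tables under `results/`):

```sh
Rscript analysis/01_simulate.R        # synthetic cell + ground truth
Rscript analysis/02_segment.R         # cell + adhesion masks, IoU vs truth
Rscript analysis/03_detect_fusions.R  # detect + classify + aligned profile
Rscript analysis/04_spatial_stats.R   # distances, CSR null, t-test
Rscript analysis/05_endocytosis.R     # quench, dual-label, activation index
```

Output of the spatial stage (fixed seeds):

```
observed: 7 events, median distance 0.000 um (4 inside an adhesion)
CSR null: 100 reps, mean of per-rep medians 2.732 um

running the 5-cell pipeline (adhesion-proximal placement)...
per-cell observed medians (um): 0.00 0.00 0.00 0.19 0.00
per-cell CSR mean medians (um): 3.11 2.86 2.84 3.30 2.76
Student's t = -27.08, df = 8, p = 3.7e-09
```

Events simulated with adhesion-proximal placement (exponential distance
scale 0.2 um) sit essentially on the adhesions (per-cell medians below
0.2 um), while the matched CSR nulls in the same cells put random
points ~3 um away — the targeting signal the analysis is designed to
detect, recovered with the direction and significance expected from the
generative truth. The detection stage reports recall and precision
against the generator's ground-truth table (1.00/1.00 in the run
above), and the endocytosis stage recovers an internalized fraction of
0.250 +/- 0.001 from quench traces whose true value is 0.25.

Equivalent calls from R go through one object:

```r
library(exofa)
cfg <- pipeline_config("simulate", out_dir = "results/run", seed = 1)
summary <- run_pipeline(cfg)   # writes masks, tables, summary.json
```

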