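# helixvol

Estimating the volume of the mitochondrial helix of passerine sperm cells
from scanning-electron-microscopy (SEM) width measurements, and running the
phylogenetic comparative analyses that go with it.

## The problem

In songbird spermatozoa a single elongated mitochondrion wraps helically
around the flagellum; the wrapped region is the midpiece. Midpiece *length*
is easy to measure and widely used as a proxy for mitochondrial *volume* —
but volume depends on the helix cross-section and pitch as well. SEM images
show the cell in projection, so per half-gyre one can measure the flagellum
width *d* (minimum width), the combined width *d + b* (maximum width, giving
the helix minor axis *b* by subtraction), at most one major axis *a* per
gyre, and the position of every measurement (giving the gyre interval *g*,
the helix pitch). `helixvol` estimates the helix volume per gyre as an
elliptical tube unrolled along its wrap,

    V_gyre = pi * (a/2) * (b/2) * sqrt(g^2 + (pi d)^2),

sums over gyres (imputing components missing in single gyres from cell
means, and counting gyres hidden by debris from obscured-section lengths),
and then fits the comparative models: log-log midpiece-flagellum allometry,
tapering of widths along the cell, gyre-interval scaling, volume versus
midpiece length, tail-start diameter, and nucleus-flagellum diameter
correlation — all with phylogenetic covariance (Pagel's λ PGLS for species
means, a REML phylogenetic linear mixed model for repeated measurements per
cell), plus measurement repeatability (ICC).

Because real measurement sets of this kind live in external repositories,
the package ships a first-class synthetic-data module: 3D helical cells
with numerically integrated true volumes, and simulated trait evolution on
Yule trees whose generating coefficients are exactly the estimands of the
pipeline's models. Every stage is validated against that ground truth.

Who it is for: researchers doing comparative sperm morphometrics (or any
helical-structure morphometry from projections) who want a tested,
reproducible implementation of this estimation-plus-PGLS workflow.

## Worked example

```r
library(helixvol)
set.seed(1)

# a synthetic tapering helical cell, measured noise-free vs with 2% noise
sp   <- helix_spec(flagellum_length_um = 150,
                   pitch_base_um = 4.0, pitch_tip_um = 3.8)
cell <- project_measurements(sp, noise_spec(cv = 0.02, seed = 1))
cell
#> <cell_record> synth1 (synthetic_sp)
#>   midpiece 109.22 um + tail 40.78 um = flagellum 150.00 um
#>   measurements: 140 rows, 28 gyres

cell_volume(cell)
#> <cell_volume_estimate> synth1
#>   28 measured gyres + 0 estimated missing
#>   total volume: 2.2599 um^3
true_helix_volume(sp)
#> [1] 2.321916
```

The estimate is 2.26 µm³ against an integrated true volume of 2.32 µm³ —
the ~3% shortfall is the documented straight-tube approximation of the
wrap length (the helix centreline lies slightly outside the flagellum
surface).

```r
# a simulated 40-species study, analysed by the tapering stage
study <- simulate_study(comparative_spec(n_species = 40, seed = 42))
fit <- stage_tapering(study$cells, study$tree, "flagellum_diameter",
                      include_subsets = FALSE)
summary(fit$fits$main)
#> Phylogenetic linear mixed model
#>   response ~ position01 * length_scaled
#>                       term estimate       se ci_lower ci_upper   p_value
#> 1              (Intercept)  0.34644 0.015979  0.31404  0.37885 3.381e-23
#> 2               position01 -0.11089 0.001077 -0.11307 -0.10870 0.000e+00
#> 3            length_scaled  0.04491 0.008000  0.02868  0.06113 1.330e-07
#> 4 position01:length_scaled -0.04131 0.005592 -0.05265 -0.02997 2.430e-13
#> lambda = 0.875 [0.811, 0.923]
#> variance components: phylogenetic = 0.001015, residual = 0.0001456
#> logLik = 4287.902, n_obs = 1462, n_species = 40
```

The generator's defaults put the flagellum-diameter taper at −0.11 µm per
unit of relative position, the flagellum-length effect at +0.04 µm per
100 µm, their interaction at −0.03, and the phylogenetic variance
proportion near 0.86; the fitted model recovers each within its interval.
The full pipeline over the four input files (measurement CSV, cell CSV,
species CSV, newick tree) is one call:

```r
run_all(list(measurements = "measurements.csv", cells = "cells.csv",
             species = "species.csv", tree = "tree.nwk",
             out_dir = "report", seed = 1))
```

writing one tidy coefficient CSV per stage, the per-cell volume table, a
manifest and a log. `generate_dataset("dir", comparative_spec(seed = 1))`
writes a complete synthetic input bundle with a JSON truth record.

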