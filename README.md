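# lipobind

Quantitative single-particle analysis of cholesteryl ester transfer
protein (CETP) binding to lipoprotein particles, as counted on
negative-stain electron micrographs.

CETP is a ~53 kDa banana-shaped plasma protein that shuttles cholesteryl
esters and triglycerides between lipoprotein classes (HDL, LDL, VLDL). On
a micrograph a bound CETP appears as a rod-shaped protrusion on the edge
of the projected lipoprotein sphere, so binding stoichiometry can be read
off by counting protrusions per particle — but only protrusions near the
projected silhouette are detectable, the counting design needs an
occlusion correction, and the raw counts feed class-specific binding
fractions, HDL–CETP–LDL ternary-complex fractions, chi-square condition
comparisons and particle-size distributions. `lipobind` implements that
whole analysis for people doing single-particle EM counting studies of
protein–lipoprotein interactions, together with a seeded synthetic
population generator so every estimator can be validated against known
truth.

## The models

**Visibility (occlusion) correction.** For a protrusion of length *l* on a
sphere of diameter *d*, attached at a uniformly random surface point, the
tip clears the projected silhouette iff sin θ > *d*/(*d* + 2*l*), with θ
the polar angle from the viewing axis. The visible fraction of the sphere
surface is

> ℘ = cos[ sin⁻¹( *d* / (*d* + 2*l*) ) ]

so a true binding count is the observed count divided by ℘. For an 8 nm
protrusion the implied upward correction grows from 8.3 % on a 10 nm
sphere to ~32 % on a 30 nm sphere. For bound particles carrying *k*
protrusions the package uses the refined per-particle detection
probability 1 − (1 − ℘)^*k*, which reduces to ℘ at *k* = 1.

**Fusion vs. penetration.** Two geometric hypotheses for how the CETP
β-barrel merges with the lipid surface:

* *fusion* (the barrel unfolds and spreads over the surface): occupied
  surface fraction *d*·*L* / (4·*D*) — for a 2.5 nm × 5 nm segment on a
  10 nm HDL this is 0.3125, i.e. ≥ 30 % of the surface per CETP, capping
  the plausible multiplicity at ≤ 2 once half the surface is assigned to
  apolipoproteins;
* *penetration* (the barrel inserts radially, conserving volume):
  *D*′ = (*D*³ + 3⁄2·*L*·*d*²)^(1/3) — growing a 10 nm HDL to only
  ~10.15 nm (~1.5 %), invisible against the measured diameter spread.

Observed multiplicities of four and more CETPs per particle are
compatible with penetration, not fusion.

**Counting statistics.** Per-particle records are tabulated into
free/binary/ternary counts and protrusion-multiplicity histograms;
conditions are compared with Pearson's chi-square test (Yates continuity
correction on by default, significance at p < 0.05). Particle size is the
geometric mean of two perpendicular diameter measurements, histogrammed
at 0.5 nm steps and smoothed with a 6th-degree polynomial; time-course
shrinkage is reported as percent change of the mean diameter from time 0.

## Worked example

```r
library(lipobind)

RodSphereGeometry(sphereDiameter = 10, rodLength = 8,
                  rodDiameter = 2.5, mergedLength = 5)
#> RodSphereGeometry (nm): sphere D = 10 | rod l = 8 | rod d = 2.5 | merged L = 5
#>   visibility probability = 0.9231

cfg <- simulationConfig(nParticles = 400, seed = 1)   # study-condition defaults
rep <- runPipeline(cfg, outDir = "demo_run")

subset(rep$binding_tables, class == "HDL")[, c("condition", "n_total",
       "bound_fraction", "corrected_bound_fraction")]
#>    condition n_total bound_fraction corrected_bound_fraction
#>  Anacetrapib     400         0.3975                0.4324802
#>      control     400         0.1100                0.1196801
#>  Dalcetrapib     400         0.2725                0.2964802
#>  Torcetrapib     400         0.5025                0.5467203
```

The generator drew HDL arms with binding propensities 0.099 / 0.505 /
0.292 / 0.431 (control / Torcetrapib / Dalcetrapib / Anacetrapib); the
observed fractions are thinned by occlusion, and the corrected estimator
recovers the configured truths within sampling error. Each inhibitor arm
differs from control by chi-square:

```r
subset(rep$comparisons, class == "HDL")[, c("condition", "chi_square",
       "p_display", "significant")]
#>    condition chi_square p_display significant
#>  Anacetrapib   85.78855 < 2.2e-16        TRUE
#>  Dalcetrapib   33.10200  8.74e-09        TRUE
#>  Torcetrapib  143.17926 < 2.2e-16        TRUE

rep$ternary_fractions[, c("condition", "hdl_ternary_fraction",
                          "ldl_ternary_fraction")]
#>    condition hdl_ternary_fraction ldl_ternary_fraction
#>      control               0.1300                0.208
#>  Torcetrapib               0.0825                0.132
#>  Dalcetrapib               0.1200                0.192
#>  Anacetrapib               0.0600                0.096
```

Ternary (HDL–CETP–LDL bridge) fractions fall under the inhibitors even
though binary binding rises — the package's central contrast. The control
time course shows the HDL mean diameter shrinking as cholesteryl ester is
transferred out:

```r
subset(rep$diameter_summaries, condition == "control")[, c("time_min", "n",
       "mean_diameter", "sd_diameter", "percent_change_from_t0")]
#>  time_min   n mean_diameter sd_diameter percent_change_from_t0
#>         0 400     12.328457    1.926337              0.0000000
#>        15 400     12.229271    1.948036             -0.8045323
#>        40 400     10.117551    2.021125            -17.9333579
#>       120 400      9.586763    1.931324            -22.2387475
#>       480 400      8.546800    1.925031            -30.6742148
```

`runPipeline()` also writes every table as CSV, a `report.json`, and a
provenance sidecar; reruns with the same config and seed are
byte-identical. A thin command-line wrapper with `simulate`, `analyze`,
`geometry` and `run` subcommands is installed at
`inst/scripts/lipobind`.

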