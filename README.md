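# spectrc

Absolute quantification in SPECT/CT is limited by partial-volume effects,
attenuation, scatter and reconstruction choices. Physical phantom studies
probe this with the NEMA IEC body phantom — a D-shaped torso with six
fillable spheres (37, 28, 22, 17, 13, 10 mm) — by sweeping acquisition and
reconstruction parameters and measuring how much of the true activity
concentration each sphere recovers. `spectrc` rebuilds that experiment as a
fully synthetic, testable pipeline in R: a digital phantom, a projection
simulator with realistic physics, an OSEM reconstructor with switchable
corrections, the NEMA quantification metrics, and the sweep statistics,
plus the published benchmark RC tables from a CZT SPECT/CT phantom study so
its statistical comparisons can be recomputed exactly.

It is intended for researchers in nuclear-medicine image quantification who
want a controlled sandbox: every stage is inspectable, deterministic under a
seed, and tested against closed-form oracles.

## The metrics

For hot sphere *j* with measured mean uptake *C*<sub>H,j</sub>, size-matched
background ROI mean *C*<sub>B,j</sub> (SD<sub>j</sub> across the 60
background ROIs), and true concentrations *a*<sub>H</sub>, *a*<sub>B</sub>:

- Recovery coefficient: RC = 100 · *C*<sub>H,j</sub> / *a*<sub>H</sub> (%)
- Percent contrast: *Q*<sub>H,j</sub> = 100 ·
  (*C*<sub>H,j</sub>/*C*<sub>B,j</sub> − 1) /
  (*a*<sub>H</sub>/*a*<sub>B</sub> − 1) (%)
- Background variability: *N*<sub>j</sub> = 100 · SD<sub>j</sub> /
  *C*<sub>B,j</sub> (%)

Reconstruction is multiplicative ordered-subsets EM,

x ← x / (Aᵀ1) · Aᵀ( y / (A x + s) ),

where the system matrix A contains the attenuation factors when AC is
enabled and the depth-dependent collimator PSF when RR is, and s is the
dual-energy-window scatter estimate *k* (W_pp/W_sc) C_sc when SC is.

## Worked example

Simulate the 32:1 target-to-background phantom at 120 s/frame with a 15%
photopeak window, reconstruct with all corrections, and quantify:

```r
library(spectrc)

ph  <- build_phantom(sim_phantom_spec(tb_ratio = 32))
cfg <- acquisition_config(seed = 1)
ps  <- simulate_projections(ph, cfg)
ps
#> <projection_set> 60 views, 64x36 bins, 120 s/frame, 15% window
#>   photopeak counts 9.36e+05, scatter-window counts 2.35e+05

vol <- osem_reconstruct(ps, ph$mu, recon_config(iterations = 6, subsets = 10))
quantify(vol, ph)[, c("sphere_mm", "rc", "contrast", "cov")]
#>   sphere_mm    rc contrast   cov
#> 1        37  82.9     76.6  20.5
#> 2        28  83.3     75.2  25.5
#> 3        22  76.3     68.6  30.4
#> 4        17  70.0     60.4  35.8
#> 5        13  65.6     57.1  42.0
#> 6        10  48.7     42.2  47.9
```

RC falls with sphere size — the partial-volume effect: at 60 EM-equivalent
updates the 37 mm sphere recovers ~83% of its true concentration, the 10 mm
sphere under half. `run_sweep()` drives the same chain over iterations,
subsets, post-filter FWHM, correction combinations, energy windows and
frame times (`autoplot()` shows the curves), `sweep_stats()` attaches the
Pearson/regression summaries, and `run_study()` executes the whole
sequential optimization protocol from one `study_config()`.

The published benchmark is bundled for statistical recomputation:

```r
reference_rc_tests("window")   # paired t-tests, 15% vs 20% window, n = 6
#>   tb_ratio comparison      t    df p_value
#> 1       32   15 vs 20  3.274     5  0.0223
#> ...
```

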