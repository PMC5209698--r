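# chipturnover

Genome-wide estimation of transcription-factor chromatin **residence
times** from competition ChIP time courses.

Competition ChIP measures turnover by inducing a second, alternatively
tagged copy of a transcription factor and following the ratio of
competitor to endogenous ChIP signal at each binding site over induction
time. Sites where the factor exchanges quickly track the soluble
induction curve; sites where it dwells lag behind it. `chipturnover`
turns that lag into a physical dissociation rate by fitting mass-action
kinetics of competitive binding:

    dθ_A/dt = k_a (1 − θ_A − θ_B) − k_d θ_A
    dθ_B/dt = k_a ρ(t) (1 − θ_A − θ_B) − k_d θ_B

with ρ(t) = ρ_∞ tⁿ/(tⁿ + t_indⁿ) (Hill n = 4) the measured
competitor/endogenous concentration ratio. Both tagged species share k_a
and k_d; the residence time is t₁/₂ = ln 2 / k_d. Because the occupancy
ratio θ_B/θ_A is nearly insensitive to k_a in the dilute-binding regime,
k_d is the quantity the data identify — and the delay is detectable as
soon as the induction curve clears the noise, which is what makes
residence times far shorter than the ~60-min induction resolvable
(down to ~1.3 min with the default induction constants ρ_∞ = 2.23,
t_ind = 22 min).

The package covers the full path from raw dye-swapped probe ratios to
comparative statistics:

* **Preprocessing** — dye-swap geometric averaging, normal-background
  estimation from the unenriched tail, BH-controlled signal-probe
  selection, per-time-point normalisation, peak-level aggregation
  (GenomicRanges overlaps).
* **Scaling** — per-locus sigmoid fits yield the locus background B, the
  response time t₀ and the antibody-affinity scale α = ρ_∞/amplitude;
  series are scaled onto the theory's boundary conditions (0 at t = 0,
  ρ_∞ at steady state) and screened for reliability (t₀ ≥ 24.5 min,
  residual and precision criteria).
* **Kinetic fitting** — a three-stage estimator: closed-form
  ideal-induction fit, lookup-table bias correction, and 1-D Newton
  refinement against exact ODE solutions, plus an optional joint
  rescaling refinement that profiles (B, 1/α) out linearly.
* **Statistics** — transcription efficiency TR·t₁/₂ (RNA molecules per
  binding event), KS contrasts, Spearman correlations, quartile
  stratification, and label-permutation screens with BH-FDR control.
* **Synthetic data** — a generator that inverts the pipeline with known
  per-locus ground truth, so every stage is testable without any
  external download.

## Worked example

Recover a known residence time from a model-generated occupancy-ratio
series:

```r
library(chipturnover)

curve <- induction_curve(rho_inf = 2.23, t_ind = 22, hill_n = 4)
grid  <- default_time_grid()                      # 0-70 min, 11 points

series <- list(times = grid,
               values = simulate_occupancy(kinetic_model(k_d = log(2) / 9),
                                           curve, grid))

bias <- build_bias_table(curve)                   # one-off, reusable
fit  <- fit_residence_time(series, curve, bias_table = bias)
fit
#> kinetic fit: k_d = 0.07702 /min (t1/2 = 9 min), rss = 8.19e-13, 2 iter,
#>   converged [ideal -> lookup -> newton]

eff <- transcription_efficiency(0.022, fit$t_half)
c(molecules = eff, events_per_rna = binding_events_per_rna(eff))
#>      molecules events_per_rna
#>          0.198            5.1
```

The fitted `k_d = 0.077/min` is exactly `ln 2 / 9`: the cascade recovers
the generating 9-minute residence time, and at a transcription rate of
0.022 molecules/min that locus would produce ~0.2 RNA molecules per
binding event — i.e. about five factor-binding events per transcript.

A complete synthetic study (simulate → preprocess → scale → fit → stats)
runs through one configuration object:

```r
cfg <- pipeline_config(outdir = "run", seed = 1,
                       sim = list(n_loci = 60L))
run_pipeline(cfg, "all")
```

or from a shell via the installed script: `chipturnover all --config
config.yaml`. Every output table carries the package version, a config
hash and the seed; reruns are checksum-identical.

## Layout

```
R/                   implementation (induction, preprocess, scaling,
                     kinetics, stats, synthetic, pipeline)
exec/chipturnover    command-line entry point
scripts/acceptance.R headline-number reproduction
tests/testthat/      unit, property and acceptance tests
vignettes/           methods vignette (model, assumptions, calibration)
```
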