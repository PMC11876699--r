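# mtquant

Quantification toolkit for in vitro TIRF microscopy assays of microtubule
dynamic instability and of the Elongator complex — the tRNA-modifying
machine whose Elp123 subcomplex binds microtubules and whose Elp456
subcomplex binds free (polyglutamylated) tubulin, together acting as a
microtubule polymerase.

The package reimplements, as a tested and reusable pipeline, every
measurement used in such experiments:

- **Drift registration** — rigid per-frame drift estimated from the FFT
  cross-correlation peak between successive frames (subpixel by quadratic
  peak interpolation), measured on one channel and applied to all.
- **Kymograph dynamics** — tip tracking by half-maximum crossing,
  growth-event segmentation, growth speeds from ordinary least-squares
  slopes (µm/min), lifetimes from the onset of growth to the last frame
  before a catastrophe, and polarity assignment (fast side = plus end).
- **Lifetime statistic** — maximum-likelihood gamma fit
  (shape from log k − ψ(k) = log x̄ − mean(log x), Newton iteration), the
  *lifetime at half cumulative distribution* (the fitted median
  t₅₀: P(τ ≤ t₅₀) = 0.5), and its error as the interquartile range of
  10,000 bootstrap refits.
- **Polyglutamylation score** — 2-px linescans per microtubule, background
  from the signal-free linescan edges, FOV averaging and normalization:
  100 × (mean per-MT antibody signal) / (mean seed-channel intensity).
- **Binding algebra** — the exact 1:1 quadratic depletion isotherm
  [RL] = (b − √(b² − 4·R·L))/2 with b = R + L + K_d, occupancy
  predictions between affinity variants, and K_d fitting from two-fold
  dilution titrations (log-space nonlinear least squares).
- **Synthetic data** — a first-class generator for event tables,
  kymographs, multichannel FOV images, drifting movies and titration
  curves with known ground truth, so each stage is verified by parameter
  recovery without any external data.

## Worked example

How much Elp123·Elp456 complex is lost when a mutation weakens the
interaction from K_d = 15.5 nM to 67.1 nM, at assay concentrations of
50 nM Elp123 and 100 nM Elp456?

```r
library(mtquant)
percent_reduction(15.5e-9, 67.1e-9, R_total = 50e-9, L_total = 100e-9)
#> [1] 34.13988
```

— about a 35% drop in occupancy, even though the affinity fell > 4-fold,
because the totals sit near the K_d.

End-to-end recovery of a growth speed through the imaging pipeline
(simulate events → render kymographs → track tips → segment events → OLS
slopes):

```r
r <- speed_recovery_experiment(1.002, "plus", n_events = 300, rng_seed = 11)
c(mean = r$mean, sem = r$sem, n = r$n)
#>         mean          sem            n 
#> 1.001393e+00 6.690358e-04 3.480000e+02
```

The estimator mean sits within 2 SEM of the generating 1.002 µm/min. And
the lifetime statistic on a sample whose generating gamma median is
202.61 s:

```r
fit <- lifetime_recovery_experiment(median_target = 202.61, shape = 3,
                                    n = 300, B = 10000, rng_seed = 14)
print(fit)
#> Gamma lifetime fit: shape 3.019, scale 71.72 s (n = 300, 0 censored excluded)
#> Lifetime at half cumulative distribution: 193.17 +/- 8.89 s (B = 10000)
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study on synthetic data, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_dynamics.R` | event tables for control / Elongator conditions |
| `02_growth_speeds.R` | speed recovery per condition and end; plus-end fold change |
| `03_lifetime_stats.R` | gamma fit, t₅₀ and bootstrap error per condition |
| `04_binding_affinities.R` | occupancy prediction; K_d recovery over 3 orders of magnitude |
| `05_ptm_quantification.R` | normalized polyglutamylation intensity per condition |
| `06_registration.R` | drift estimation/correction residuals |

Run any of them from the repository root, e.g.
`Rscript analysis/02_growth_speeds.R`.

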