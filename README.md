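# bipsda

Benchmarking tools for **diffusion-annealing-based Bayesian inverse problem
solvers** — samplers that combine a diffusion-model prior with an arbitrary
likelihood through decoupled noise annealing — on stylized problems whose
posterior is analytically known.

## The problem

In a Bayesian inverse problem we observe `y = f(m) + z` (or Poisson counts
with mean `f(m)`) and want the posterior `π(m | y) ∝ π_like(y | m) π_pr(m)`.
When the prior is represented implicitly by a diffusion model, a family of
recent algorithms draws posterior samples by alternating two stages over a
decreasing noise grid `t_NA > … > t_0 = 0`:

1. **Prediction** — given the current iterate `m(t)`, approximate the
   denoising distribution `π(m(0) | m(t))` by a Gaussian
   `N(m_aprx, C_aprx)` and sample the *prediction distribution*
   `π(m(0) | m(t), y) ∝ π_like(y | m) N(m; m_aprx, C_aprx)`.
2. **Corruption** — re-noise: `m(t') = m(0) + σ(t′) ζ`, with `t′` the next
   (lower) grid level and `σ(t) = t` the variance-exploding schedule.

The package implements the nine variants obtained by crossing three
denoising approximations with three prediction samplers:

| | ODE (probability-flow mean) | TU (Tweedie mean, isotropic cov) | TC (Tweedie mean + generalized-Tweedie cov) |
|---|---|---|---|
| **Lang** (Langevin) | Lang-ODE (= DAPS) | Lang-TU | Lang-TC |
| **MAP** (optimization) | MAP-ODE | MAP-TU (= DiffPIR) | MAP-TC |
| **RTO** (randomize-then-optimize) | RTO-ODE | RTO-TU | RTO-TC |

Tweedie's formula gives the exact conditional mean
`E[m(0)|m(t)] = m(t) + σ²(t) s(m(t), t)` from the noisy prior score `s`; its
generalized form gives `Cov[m(0)|m(t)] = σ²(I + σ² ∇s)`. RTO perturbs both
the data (`y′ ~ N(y, Σ_z)`) and the Gaussian factor's mean
(`m′ ~ N(m_aprx, C_aprx)`) and solves the resulting MAP problem — exact
sampling of the prediction distribution in the linear-Gaussian case.

All four benchmark problems share a ten-dimensional three-component
Gaussian-mixture prior, for which the noisy score, its Jacobian, and (for
linear-Gaussian data) the full posterior are available in closed form — so
algorithmic error can be separated from score-modeling error, and every
sampler can be scored against ground truth:

* **inpainting** (low/high noise): binary 8-of-10 mask, `τ = 0.1` or `τ = 5`;
* **x-ray tomography**: Poisson counts with mean `I₀ exp(−Cm)`, `I₀ = 1000`;
* **phase retrieval**: `f(m) = (Bm)²`, `τ = 25`.

Reference posteriors come from exact conjugate sampling (inpainting) or from
a gated differential-evolution MCMC sampler (PSRF < 1.01, effective sample
size checks; component-wise runs with evidence-weighted resampling for the
multimodal phase problem). Sample sets are compared with four metrics:
posterior-mean error, pointwise-variance error, central moment discrepancy
(CMD), and maximum mean discrepancy (MMD).

## Worked example

```r
library(bipsda)
prior <- build_prior(seed = 1)            # the benchmark mixture prior
lik   <- make_problem("inpaint_low", seed = 1)

set.seed(7)
m_true <- drop(gmm_sample(prior, 1))
y <- simulate_measurement(lik, m_true)$y

cfg <- bipsda_config("RTO-TU", N_A = 200, n_chains = 2000, seed = 7,
                     sampler_cfg = map_config("closed_form"))
draws <- bipsda_sample(lik, analytic_score(prior), y, cfg)
summary(draws)
#> Posterior summaries from 2000 draws (variant RTO-TU):
#>           m1      m2     m3     m4      m5      m6      m7      m8      m9     m10
#> mean -0.3106 -1.4132 0.7426 2.1876 -0.1549 -0.9697 -1.7586 -1.7214 -0.0484 -0.0556
#> sd    0.0995  0.0987 0.1003 0.0998  0.1010  0.1023  0.0990  0.0987  1.3901  1.4252
```

The eight observed coordinates are pinned to the data at the noise scale
(`sd ≈ τ = 0.1`) while the two unobserved coordinates (9, 10) retain the
prior-conditional spread — the posterior structure the samplers must capture.
Against exact posterior draws:

```r
ref <- exact_reference(prior, lik, y, 2000, seed = 8)
c(mean_error = mean_error(draws, ref), variance_error = variance_error(draws, ref))
#>     mean_error variance_error
#>     0.05644767     0.12174980
```

A small study (5 trials × 2000 samples) comparing two variants:

```r
rep <- run_study("inpaint_low", variants = c("RTO-TU", "MAP-TU"),
                 n_trials = 5, n_samples = 2000, seed = 42)
print(rep)
#> Benchmark study 'inpaint_low': 5 trial(s) x 2000 samples (analytic score)
#> CMD decay rate alpha = 4.926
#>    variant           mean_error       variance_error                  cmd                  mmd
#>  Reference 0.050 (0.029, 0.063) 0.063 (0.022, 0.098) 0.016 (0.011, 0.020) 0.040 (0.035, 0.047)
#>     RTO-TU 0.067 (0.050, 0.081) 0.095 (0.039, 0.158) 0.022 (0.015, 0.029) 0.047 (0.042, 0.053)
#>     MAP-TU 0.045 (0.023, 0.063) 1.069 (0.803, 1.448) 0.068 (0.049, 0.094) 0.287 (0.278, 0.294)
```

Each cell is the trial mean with the empirical interdecile range in
parentheses. The `Reference` row compares two independent reference batches —
the Monte-Carlo floor of each metric at this sample size. The pattern above
is the benchmark's headline: randomize-then-optimize tracks the reference
floor, while plain MAP prediction (`MAP-TU`) underestimates the
within-mode variance by an order of magnitude.

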