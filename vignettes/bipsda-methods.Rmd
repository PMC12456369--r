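---
title: "Methods: diffusion-annealing posterior samplers and their benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-annealing posterior samplers and their benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipsda)
```

## The sampling problem

Given a likelihood $\pi_{like}(y \mid m)$ on $m \in \mathbb{R}^D$ and a prior
represented by a variance-exploding diffusion — $m(t) = m(0) + \sigma(t)\,z$,
$\sigma(t) = t$, horizon $T = 10$ — the samplers in this package draw from the
posterior $\pi(m \mid y) \propto \pi_{like}(y \mid m)\,\pi_{pr}(m)$ by
*decoupled noise annealing*. Chains are initialized at
$m \sim N(0, \sigma^2(T) I)$ and, at each level $t_i$ of a decreasing grid,
perform

1. **prediction**: approximate the denoising distribution
   $\pi(m(0) \mid m(t_i))$ by a Gaussian $N(m_{aprx}, C_{aprx})$ and sample
   (or optimize) the prediction distribution
   $\pi_{like}(y \mid m)\, N(m;\, m_{aprx}, C_{aprx})$;
2. **corruption**: $m(t_{i-1}) = m(0) + \sigma(t_{i-1})\, \zeta$.

If the prediction stage sampled exactly, each iteration would map a draw from
the noisy posterior at level $t_i$ to one at level $t_{i-1}$; the
approximations introduced by the Gaussian denoising model and by the finite
prediction sampler are exactly what the benchmark quantifies.

### Denoising approximations

* **TU** — Tweedie's formula $m_{aprx} = m + \sigma^2 s(m, \sigma)$ with
  isotropic covariance $C = \beta(t)^2 I$, $\beta(t) = \sigma(t)$. Exact in
  the mean when the score $s$ is exact.
* **ODE** — $m_{aprx}$ from a 5-step Euler solve of the probability-flow ODE
  $dm = -\dot\sigma \sigma\, s\, dt$; same isotropic covariance. With a
  single Euler step evaluated at the current level this reduces exactly to
  Tweedie's formula.
* **TC** — Tweedie mean plus the generalized-Tweedie covariance
  $C = \sigma^2 (I + \sigma^2 \nabla s)$; hyperparameter-free, exact for a
  Gaussian prior, but requires the score Jacobian, so it is refused for
  learned scores (their Jacobians are unreliable) unless forced.

### Prediction samplers

* **Lang** — unadjusted Langevin (Euler–Maruyama) with drift coefficient
  $\eta$: $m \leftarrow m + \eta P \nabla \log p + \sqrt{2\eta} P^{1/2} z$,
  initialized at $m_{aprx}$ (the natural warm start; the Gaussian factor's
  mode). The benchmark settings are $\eta = 5\times10^{-5}$ with 100
  subiterations (inpainting), 1000 (x-ray), and Metropolis-adjusted,
  Gauss-Newton-preconditioned dynamics with $\eta = 0.2$ and 1000
  subiterations (phase retrieval), where the preconditioner is refreshed each
  outer iteration from the averaged Gauss-Newton Hessian at 8 anchor chains.
* **MAP** — the mode of the prediction distribution: closed form for the
  mask likelihood, otherwise a dense-BFGS solve with Wolfe line search (40
  iterations), warm-started at $m_{aprx}$.
* **RTO** — randomize-then-optimize: perturb $y' \sim N(y, \Sigma_z)$ and
  $m' \sim N(m_{aprx}, C_{aprx})$, then solve the perturbed MAP problem.
  Exact sampling of the prediction distribution when the likelihood is
  linear-Gaussian. For Poisson counts, which have no additive-noise
  decomposition, the perturbation uses the variance-matched Gaussian
  surrogate $y'_k \sim N(y_k, \max(y_k, 1))$ — an interpretation, stated
  prominently because the exactness property does not carry over.

## The annealing grid

The grid is polynomial with exponent $\rho = 7$ (the convention of the
annealing samplers this framework generalizes), $N_A = 200$ steps. Two
variants are provided. `make_time_grid(t_min = 0)` is the pure power law
$t_i = T (i/N_A)^\rho$. The default sampler configuration instead
interpolates (in the $1/\rho$-power domain) between $T$ and a terminal level
$t_{min} = 0.01$ before the final jump to 0. The terminal level matters for
the fixed-step Langevin sampler: the Gaussian-factor drift scales like
$1/\sigma(t_1)^2$, and the pure power grid drives $\sigma(t_1)$ to
$\sim 10^{-15}$, making the $5\times10^{-5}$ step violently unstable — every
chain diverges. With the floored grid the same step size is stable
($\eta / \beta^2 = 0.5$ at the last level). The probability-flow-ODE
denoiser uses the same convention internally: its 5-step sub-grid
interpolates from $t$ down to $t_{min}$ and stops there (residual noise
variance $10^{-4}$); `pf_ode_denoise(t_min = 0)` integrates to 0 exactly,
which is the configuration under which one Euler step equals the Tweedie
mean.

## The benchmark problems

All studies share the $D = 10$ prior
$\pi_{pr} = 0.4\,N(-5\cdot 1, I) + 0.3\,N(0, \mathrm{diag}(1,\dots,2)) +
0.3\,N(5 \cdot 1, Q \Lambda Q^T)$, where $\mathrm{diag}(1,\dots,2)$ has
entries linearly spaced on $[1, 2]$ and $Q$ is a seeded random orthonormal
basis (orthogonal factor of a QR decomposition of a standard Gaussian
matrix — any seeded orthonormal basis is admissible; exact equality with any
other instance is not expected, only distributional agreement). Its noisy
score, score Jacobian, and linear-Gaussian posterior are closed-form, so
every approximation error is measurable.

* `inpaint_low`, `inpaint_high`: $y = Am + z$, $A$ a binary mask keeping
  coordinates 1–8 (the specific coordinates are a configuration choice; only
  the 2-dimensional null space matters), $\tau = 0.1$ or $5$. Low noise gives
  an effectively unimodal posterior; high noise keeps distinct modes.
* `xray`: $y_k \sim \mathrm{Poisson}(I_0 e^{-(Cm)_k})$, $C$ 15×10 with
  entries i.i.d. uniform on $[0.01, 0.05]$, $I_0 = 1000$. The Poisson
  log-likelihood is used exactly (its log-factorial constant is dropped —
  it cancels everywhere); the negative log-posterior of the prediction
  subproblem is smooth and strictly convex in $m$.
* `phase`: $y = (Bm)^2 + z$ elementwise, $B$ 5×10 standard normal,
  $\tau = 25$. The forward map is even in $m$, so posteriors inherit a sign
  symmetry and are multimodal.

`report_snr` reports $10\log_{10}(\hat E\|f(m)\|^2 / \hat E\|z\|^2)$ under
the prior — one convention among several; it is informational only.

## Reference posteriors

For the mask studies the posterior is a Gaussian mixture in closed form and
reference draws are exact. For the nonlinear studies the reference is a
multi-chain differential-evolution MCMC sampler (DE-MC with proposals from an
archive of past states, occasional unit-gamma jumps, and snooker moves),
which must pass a convergence gate before use: split-chain
Gelman–Rubin PSRF below 1.01 in every dimension, and effective sample size
(initial-positive-sequence estimator, summed over chains) at least the number
of draws consumed. A gated reference is never silently replaced; failures
raise errors with the diagnostics attached.

The phase-retrieval posterior is handled component-wise: each prior component
defines a target $\pi_{like}\,\pi_{pr,i}$ sampled separately (Latin-hypercube
initialization over mean $\pm 6$ standard deviations), per-component
evidences $Z_i$ are estimated by reverse importance sampling with a Gaussian
fitted to the post-burn-in draws, and components are resampled with
probability $\propto w_i Z_i$. The zero-mean component straddles the sign
symmetry of $(Bm)^2$ — its posterior is exactly symmetric and bimodal — and
needs several times longer chains than the $\pm 5$ components to pass the
PSRF gate; per-component chain lengths are therefore configurable. When the
consumer of the reference is a self-distance between two resamples of the
same pool, the ESS half of the gate is optional (`n_gate = 0`): pool-level
error cancels in that comparison.

## Metrics

For sample sets $S_1$ (method) and $S_2$ (reference):

* mean error $\|\bar m_1 - \bar m_2\|_2$ and pointwise-variance error
  $\|v_1 - v_2\|_2$ (per-dimension unbiased variances);
* CMD: $\frac{1}{\alpha}\|\bar m_1 - \bar m_2\|_2 + \sum_{k=2}^{5}
  \frac{1}{\alpha^k}\|c_k(S_1) - c_k(S_2)\|_2$ with per-coordinate central
  moments $c_k$ (full moment tensors would be both infeasible and unneeded)
  and $\alpha = 4\hat\eta_{max}$, $\hat\eta_{max}$ the trial-averaged
  sup-norm of the reference's componentwise posterior standard deviation;
* MMD with the multi-bandwidth Gaussian kernel
  $\sum_{i=1}^{5}\exp(-\|m_1-m_2\|^2/(2\epsilon_i))$,
  $\epsilon_i = \bar\epsilon\, 2^{i-3}$ (factors 1/4–4; the ladder exponent
  convention and the $2\epsilon$ vs $\epsilon$ kernel scaling are both
  config-exposed since conventions differ across the literature), with
  $\bar\epsilon$ the mean squared pairwise distance among reference samples.
  The default estimator is the biased V-statistic reported on the square-root
  scale (zero for identical sets); the unbiased U-statistic is available.
  Batches larger than 2,000 are subsampled deterministically for the
  quadratic-cost kernel sums — at that size the MMD Monte-Carlo floor is
  well below the between-variant differences of interest, at 1/25th the cost.

`run_study` fixes one problem instance, draws a fresh ground truth and
measurement per trial, and reports trial means with empirical 10th–90th
percentile (interdecile) ranges, plus a `Reference` row comparing two
independent reference batches (the Monte-Carlo floor). Chains that produce
non-finite values are flagged, excluded from metrics, and counted in the
report.

## Score-model training

The learned-score path trains a *conservative* score: a scalar potential
$g_\theta(m, \sigma)$ whose exact input gradient is the score. The
architecture is a single tanh hidden layer with a linear skip term and the
noise level appended to the input; gradients of the denoising
score-matching loss (weighting $w(t) = \sigma^2(t)$, $t$ uniform on
$[T_{min}, T]$, $T_{min} = 0.01$) are derived analytically and optimized
with Adam. The default constants in `score_train_config` (80,000 training
samples, width 512, learning rate $10^{-5}$, batch 8,000, 50,000 iterations)
mirror the benchmark training protocol; the architecture itself is this
package's own design, chosen so that both the score and its training
gradient are exact rather than approximated by finite differences. Learned
scores are exercised by a training-improvement property (mean-squared error
against the analytic score must drop at least tenfold) rather than by the
full study protocol: network training is too seed-sensitive to serve as a
reproducible benchmark surface, which is also why the correlated (TC)
approximation refuses learned scores.

## Numerical choices

* Mixture responsibilities, posterior weights and evidences are computed in
  log space (log-sum-exp); per-component Cholesky factors are shared between
  the density, score and Jacobian evaluations. Noise levels up to
  $\sigma = 10$ and points far into the tails are routine.
* `tweedie_cov` symmetrizes and floors eigenvalues at $10^{-10}$, warning
  when clipping activates (expected only with learned scores).
* The per-chain MAP solves use dense BFGS (the 10-dimensional problems make
  limited-memory machinery pointless) with an Armijo backtracking line
  search, one curvature-guided expansion step, and curvature-guarded
  updates; the prior covariance seeds the initial inverse-Hessian scaling.
* The final annealing iteration performs prediction only (no corruption);
  the isotropic $C_{aprx}$ at the terminal level uses the last positive grid
  level, since $\beta(0) = 0$ would make the Gaussian factor degenerate.
* Langevin subiteration noise comes from a seeded ziggurat generator inside
  the compiled kernel; a study consumes on the order of $10^8$ draws.
* Divergent chains (non-finite states) are flagged per chain and excluded;
  a run with more than 1% divergences warns.

## Study scales

The package's standing study sizes, used by `scripts/acceptance.R` and the
acceptance tests (chosen once, as a balance between Monte-Carlo floor and
runtime on a single CPU; the floors they imply are quoted alongside the
results):

* Inpainting reference floors: the full protocol — 100 trials, two
  independent exact 10,000-draw sets per trial.
* Inpainting variant studies: 20 trials; 10,000 chains for the closed-form
  RTO variant, 2,000 for the Langevin variants. At 2,000 samples the
  variance-error floor is about $\sqrt{5}$ times the 10,000-sample floor,
  which is why the small benchmark values (reference-level variants) are
  checked at larger chain counts.
* X-ray: 8 trials, 4,000 chains, reference from 10 chains × 60,000 DE-MC
  iterations (thinned ×4), gated at PSRF < 1.01 and ESS ≥ 4,000.
* Phase retrieval: per-trial self-distance between two fully independent
  component-wise references (24 chains; 120k/400k/120k iterations per
  component, thinned ×20). Because the per-trial value is bimodal across
  trials — small when the ground truth comes from the zero-mean component,
  large when it comes from a $\pm 5$ component and the posterior spreads
  over both sign-symmetric modes — the acceptance script stratifies its
  trials over the prior components (2/1/2) and combines the stratum means
  with the prior weights: an unbiased, lower-variance estimate of the
  i.i.d. trial average, with the single-trial stratum being the one whose
  per-trial values barely vary.

## What the synthetic benchmark does and does not show

The generator emulates the structure that makes posterior sampling hard —
multimodality, nonlinearity, Poisson noise, rank-deficient forward
operators — while keeping every reference quantity checkable. It does not
emulate high-dimensional image priors, learned-prior misspecification, or
real acquisition physics; passing results here demonstrate algorithmic
correctness and calibration at benchmark scale, not performance on real
reconstruction problems. Known limitations: the Poisson RTO perturbation is
a Gaussian surrogate; the learned-score path is a property-tested
implementation, not a benchmark surface; Hamiltonian and Metropolized-RTO
prediction samplers are out of scope; and the DE-MC reference, while gated
by the same diagnostics as any engine would be, mixes more slowly across the
phase problem's symmetric modes than multi-try DREAM-type samplers, which is
absorbed by longer chains rather than engine features.
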