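---
title: "Methods: rigidity-guided Bayesian optimization of DBS frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigidity-guided Bayesian optimization of DBS frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbstune)
```

`dbstune` tunes one DBS parameter — stimulation frequency — against one
quantitative motor outcome, Parkinsonian forearm rigidity. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, what the virtual-patient simulator does and does not
emulate, and the package's known limitations.

## Rigidity quantification (RoMaR)

A robotic manipulandum imposes passive sinusoidal pronation/supination
(±40°) while a strain gauge records resistive torque at 1 kHz. The pipeline
is: low-pass filter, rectify, integrate, fit a slope.

- **Filter.** 2-pole Butterworth, 20 Hz cutoff, applied causally
  (forward-only) as in real-time use. Zero-phase (forward–backward)
  filtering is available via `zero_phase = TRUE` but off by default: the
  live protocol cannot see the future of the signal. The filter is the
  standard digital (bilinear) design from the `signal` package; its
  magnitude response tracks the analog prototype
  $|H(f)| = 1/\sqrt{1 + (f/20)^4}$ closely below ~100 Hz and falls off
  faster near Nyquist, which is immaterial here since the movement torque
  is concentrated at a few hertz.
- **Ordering.** Filtering precedes rectification: rectification is
  nonlinear and folds high-frequency noise into the band of interest, so
  denoising must come first.
- **RoMaR.** The first 5 s (warm-up) are discarded; over the next 20 s the
  rectified torque is integrated cumulatively by the trapezoidal rule and
  the angular impulse is regressed on time by ordinary least squares. The
  slope is the RoMaR value. The integration and regression schemes are
  package choices; for stationary signals the slope equals the mean
  rectified torque regardless of scheme, and for a torque sinusoid of
  amplitude $A$ it equals $2A/\pi$ (the closed form used as a test oracle).
  Traces longer than warm-up + window are truncated, not rejected; shorter
  ones raise an `insufficient-data` error. A trace whose last sample is at
  $T - 1/f_s$ counts as $T$ seconds of data.
- **Units.** RoMaR is reported in N·m (N·m·s of impulse per second).
  16-bit digitization is not modeled; inputs are real-valued.

## The rigidity GP

Rigidity versus frequency is a Gaussian process with Matérn $\nu = 3/2$
covariance

$$k(x, x') = \sigma_f^2\left(1 + \frac{\sqrt{3}\,r}{\ell}\right)
\exp\!\left(-\frac{\sqrt{3}\,r}{\ell}\right), \qquad r = |x - x'|,$$

chosen for once-differentiable sample paths: measurement-to-measurement
coarseness over a smooth trend. A general-$\nu$ Gamma/Bessel form is also
implemented and serves as an independent check of the closed form. The
scaled distance is $r/\ell$ with $\ell$ a free length-constant in Hz.

- **Mean function.** Constant, frozen at the mean of the four seed
  measurements once seeding completes. Predictions center the targets by
  this constant; the textbook predictive equations
  $\mu(x) = \mathbf{k}^\top K^{-1}\mathbf{y}$,
  $\sigma^2(x) = k(x,x) - \mathbf{k}^\top K^{-1}\mathbf{k}$ then apply to
  the centered residuals.
- **Noise.** Observation noise variance is modeled explicitly and fitted:
  RoMaR measurements are visibly noisy, and expected improvement needs a
  meaningful incumbent on noisy data. $K$ always carries
  $\sigma_n^2 I$ on its diagonal.
- **Hyperparameters.** $(\ell, \sigma_f^2, \sigma_n^2)$ maximize the log
  marginal likelihood via multi-start L-BFGS-B on log-parameters
  (8 restarts, seeded, deterministic). Bounds: $\ell \in [2.5, 350]$ Hz
  (half a grid step to twice the grid span), $\sigma_f^2 \in [10^{-4},
  10^2] \times \mathrm{var}(y)$, $\sigma_n^2 \in [10^{-6}, 10] \times
  \mathrm{var}(y)$. Hyperparameters are refit after every new observation;
  a simulation test confirms $\ell$ is recovered within a factor of 2 on
  dense data from the generative model.
- **Numerics.** Cholesky factorization with escalating diagonal jitter
  ($10^{-10}$ to $10^{-4}$ of $\sigma_f^2$, ×10 per step) before declaring
  numerical failure. Posterior variances are floored at zero.

## Acquisition and the session loop

For minimization, expected improvement uses the improvement
$I = f(x^-) - \mu(x)$ over the incumbent $f(x^-)$, the *minimum observed*
RoMaR (not the posterior-mean minimum):

$$u(x) = I\,\Phi(I/\sigma) + \sigma\,\phi(I/\sigma) \;\; (\sigma > 0),
\qquad u(x) = 0 \;\; (\sigma = 0).$$

- **Candidate grid.** 10 Hz to the tolerability ceiling in 5 Hz steps,
  matching device programmability; continuous optimization is out of scope.
- **Tie-breaking.** Equal utility resolves to the lowest frequency — the
  clinically conservative, battery-friendly choice.
- **Exploration rule.** Pure EI can oversample one region. After taking the
  EI argmax, if the posterior SD there is below
  `exploration_ratio` × $\sigma_n$ (default ratio 0.5), the proposal is
  deemed over-exploiting — a new measurement there would be dominated by
  noise — and the maximum-posterior-variance grid point is selected
  instead. This is a deliberately simple, testable reading of an
  exploration-ratio mechanism balancing exploration against sampling near
  the estimated minimum.
- **Session protocol.** Four seeds (30, 80, 90, 140 Hz — two bracketing the
  expected transition between ineffective and suppressive stimulation),
  then 8 iterations of refit → predict → select → measure, with a
  current-vs-previous preference question after every measurement from the
  second onward: 12 measurements and 11 choices in a completed session.
- **Tolerability.** An intolerable response to a proposed frequency removes
  it and everything above it from the grid; the iteration re-selects, so
  completed sessions keep their measurement count. An intolerable *seed*
  is skipped (one fewer measurement): seeds are protocol inputs, not
  algorithm proposals, and in practice the grid is capped up front by the
  ceiling discovered during the brute-force visit. Wash-in (4 min per
  setting) is logged metadata, not a simulated dynamic.
- **Brute-force visit.** The full grid in seeded pseudorandom order, with
  one measurement at the clinical frequency prepended and appended. On an
  intolerable event, untested frequencies above the new ceiling are dropped
  from the remaining order (the magnitude rule; the protocol's interaction
  between pseudorandom order and halting is ambiguous, and this reading
  reproduces the reported per-participant setting counts).

## Preference model (probit GP)

Choices between settings are modeled with a latent value function $f$ and
noise $\epsilon \sim N(0, \sigma^2)$, $\sigma = 1$ fixed:
$P(a \succ b) = \Phi\big((f(a) - f(b))/(\sqrt{2}\sigma)\big)$.

- **MAP fit.** The log posterior (Matérn GP prior over the distinct
  compared frequencies + probit log-likelihood) is maximized by
  Newton–Raphson with step-halving, gradient tolerance $10^{-8}$, 200
  iteration cap, and 25 seeded uniform $[-1,1]$ restarts; the best
  converged objective wins, ties to the lowest restart index. The log
  posterior is strictly concave, so restarts guard against slow progress
  rather than distinct optima. $\Phi$ terms are evaluated in log space to
  survive strongly decided comparisons.
- **Kernel.** Binary comparisons alone cannot identify a length-constant,
  so the pGP reuses the Matérn $\nu=3/2$ kernel with $\ell$ carried over
  from the same session's rigidity GP and $\sigma_f^2 = 1$ (the latent
  scale is set by the fixed choice noise).
- **Centering.** The likelihood is translation invariant; the proper GP
  prior makes the MAP unique, but only value *differences* are meaningful,
  so the stored `f_map` is centered to mean zero.
- **Prediction.** $\mu(x) = \mathbf{k}^\top K^{-1} f_{\mathrm{MAP}}$ and
  $\sigma^2(x) = k(x,x) - \mathbf{k}^\top (K + C^{-1})^{-1}\mathbf{k}$,
  where $C$ is the curvature of the negative log-likelihood at the MAP.
  The mean expression omits $C$ while the variance includes it; both are
  implemented exactly as written, and the asymmetry is flagged here for
  reviewers. $C$ is always singular (the ones vector is in its null
  space), so its inverse uses escalating diagonal jitter from $10^{-8}$;
  in the no-information limit $C \to 0$ the predictive variance correctly
  returns to the prior.
- **Self-comparisons.** When the algorithm re-tests the frequency it just
  measured, the current-vs-previous question compares a setting to itself.
  The record is kept in the session log (a question was asked) but dropped
  from the fitting dataset, where it carries no information.

## Virtual patients

The simulator exists so that every pipeline stage is testable without
clinical recordings. The rigidity curve is the minimal smooth family
reproducing the qualitative features reported for akinetic-rigid patients:

$$r(f) = r_{\mathrm{off}} - a_{\mathrm{dip}}\,g(f; 10, 8)
       + a_{\mathrm{worse}}\,g(f; 35, 12)
       - a_{\mathrm{ben}}\,\mathrm{logistic}\!\big((f - c)/s\big)
       + a_{\mathrm{bump}}\,g(f; 140, 10),$$

with $g$ an unnormalized Gaussian. Two profiles ship: `ar1` (ceiling
155 Hz, no bump, monotone benefit at high frequency) and `ar2` (ceiling
185 Hz, a 130–155 Hz bump). Their parameters are synthetic, not fits to
any individual's data. Design choices:

- **Benefit transition** centered at 90 Hz with slope 18 Hz: the protocol
  places two of its four seeds (80, 90 Hz) at the anticipated transition
  between ineffective and suppressive stimulation, and profile 1's
  suppression keeps improving up to its ceiling rather than saturating
  far below it.
- **Measurement noise** defaults to 5% of the curve's dynamic range
  (`ar1`: SD ≈ 0.067 on a range of ≈ 1.34) — no noise magnitude is
  established for RoMaR, and tests vary it explicitly.
- **Value function.**
  $v(f) = \mathrm{nb}(f) - \lambda\,\mathrm{softplus}\big((f -
  f_{\mathrm{se}})/s_{\mathrm{se}}\big)$, where $\mathrm{nb}$ is the
  rigidity benefit normalized by $a_{\mathrm{ben}}$ and the softplus term
  is a smoothly increasing high-frequency side-effect burden
  ($\lambda = 0.3$, onset 118 Hz for `ar1`, slope 10 Hz). Parameters are
  set so the value peak falls at the lowest grid frequency achieving ~80%
  of the maximal rigidity benefit — below the rigidity argmin, as reported
  for real patients — and construction validates that the peak is unique.
- **Choice noise** `pref_noise = 0.1` on a value scale of ~1: individual
  comparisons between similar settings are noisy (near 50/50) while
  clearly different settings are chosen consistently.
- **Torque traces.** Sinusoidal kinematics (±40°, 1 Hz) with torque
  `stiffness·θ + viscous·θ′ + noise`; stiffness is calibrated through the
  $2A/\pi$ closed form so the full signal pipeline reproduces
  `true_rigidity(f)` within a few percent, with a 10% viscous contribution
  and 1% additive noise by default.

What the simulator does **not** emulate: wash-in dynamics (measurements
are i.i.d. given frequency), medication state, fatigue or time-on-task
drift, day-to-day baseline shifts between visits, tremor/bradykinesia
outcomes, and any physiological model of basal-ganglia circuits. Passing
tests therefore demonstrate correctness of the algorithms under stationary,
Gaussian-noise conditions — not clinical performance.

## Evaluation metrics

- **Optimal frequency**: argmin of the GP posterior mean over the grid,
  ties to the lowest frequency.
- **Frequency range**: all grid frequencies with
  $\mu(x) \le \mu_{\min} + \sigma_{\min}$ (one-sided, since the fitted mean
  cannot fall below its minimum). Two summaries coexist in the literature
  this package follows: the **width** of the contiguous run containing the
  optimum (the headline metric here) and the **lower distance** from the
  optimum down to the lowest qualifying frequency; both are reported, and
  the full qualifying set is returned since contiguity is not guaranteed.
- **Equal-interval subsampling**: $n$ evenly spaced points from 10 Hz to
  the maximum tolerated frequency, rounded to the nearest tested setting
  with midpoints rounding up (3 points to a 155 Hz ceiling select 10, 85,
  155 Hz).
- **Random subsampling**: $n$ draws with replacement, 50 seeded
  repetitions by default, reported as mean ± SD of widths.
- GP refits inside these simulations use the same hyperparameter policy as
  the session, with one fixed seed per (method, n, repetition).

## Problem sizes and reproducibility

All randomness flows from one integer seed through named child streams
(`measure/3`, `fit/5`, `pref/7`, ...), so sessions are bit-reproducible
and components are independently re-runnable. The validation suite runs at
desk scale, chosen to exercise each claim while keeping the full suite in
the minutes range: 100 random instances for predictive equivalence, 50
Monte-Carlo triples at $10^6$ draws for EI, 50 replicates for
length-constant recovery, and 20 seeded replicates each for optimum
recovery, preference-peak recovery, and the BayesOpt-versus-random
efficiency ordering.

## Known limitations

- One-dimensional search only: amplitude, pulse width and contact
  configuration are fixed. The kernel architecture permits more dimensions
  but nothing multi-dimensional is implemented or tested.
- The exploration rule is one concrete reading of an exploration-ratio
  mechanism; other acquisition modifications (e.g. EI-per-cost,
  UCB) are not provided.
- The pGP predictive mean ignores likelihood curvature (see above); its
  variance does not.
- Preference querying is passive (current vs previous); active selection
  of informative comparisons is out of scope.
- Real participant-level results (e.g. specific frequency-range widths)
  depend on unavailable clinical recordings; the package reproduces
  protocol structure and algorithmic behavior on synthetic patients only.
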