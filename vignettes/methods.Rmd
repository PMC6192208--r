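---
title: "Methods: joint Bayesian fitting of relative and absolute expression data for a yeast cyclin network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint Bayesian fitting of relative and absolute expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclinpt)
```

## The model

`cyclinpt` fits a small ODE model of transcriptional regulation in the
budding-yeast cell cycle. Four cyclins (CLN3, CLN2, CLB5, CLB2) and the
transcription-factor subunits driving them (SWI4 for SBF, NDD1 for
Mcm1-Fkh, SWI5 for Swi/Snf, plus HCM1 and the repressor YOX1 in the
larger variants) are each represented by two species, mRNA and protein,
in physical units: micromolar concentrations, time in seconds. Keeping
physical units is what later allows posterior rate estimates to be
compared directly against independently measured degradation,
transcription and translation rates.

For a gene $g$ with activator protein $A$, optional transcriptional
repressor $I$ and optional degradation inhibitor $D$:

$$\frac{dm_g}{dt} = \bigl(\beta_g + \alpha_g A(t)\bigr)\,
  \frac{1}{1 + (I/K)^h} - \delta_m\, m_g,
\qquad
\frac{dP_g}{dt} = \kappa\, m_g - \delta_{p,g}\, P_g\,
  \frac{1}{1 + (D/K')^{h'}}.$$

Mass action everywhere, with one nonlinear ingredient: Hill repression
$1/(1+(x/K)^h)$. The repression form is a design choice (only "a
non-linear inhibition term" is dictated by the modeling approach we
follow); we let the exponent $h$ be a free parameter with a linear
uniform prior on $[1, 4]$, covering gentle to switch-like repression
without fixing cooperativity. The same form multiplies the degradation
term for the one degradation-inhibition edge (CLN2 protecting NDD1
protein, emulating APC inactivation). The mRNA degradation rate
$\delta_m$ and the translation rate $\kappa$ are shared across genes;
protein degradation is per gene.

Four nested variants (`build_model(1:4)`) reproduce an iterative
refinement ladder: the base seven-gene cascade; adding HCM1 (a delay
between SWI4 and NDD1); adding YOX1, which closes a negative feedback
loop onto SWI4 and CLN3 and makes sustained oscillation possible;
and adding the CLN2 to NDD1 degradation-inhibition edge. Variant
nesting is asserted structurally in the tests.

All parameters are stored on a log10 scale (except Hill exponents) with
independent uniform priors. Default bounds are configuration, not
science: rates $10^{-6}$ to $10$ (1/s or uM/s), concentrations
$10^{-5}$ to $10$ uM, error scales $10^{-2}$ to $10$; every bound can
be overridden per parameter (`default_priors(model, overrides = ...)`),
because the elicited bounds used with real data live outside this
package's scope. Initial conditions at the synchronization release
(t = 0) are free parameters: the starting state of a synchronized
culture is unknown.

## Two data channels, one likelihood

Relative time-course data (synchronized cells measured against an
unsynchronized control) inform the *shape* of expression over time but
not its scale. We model each observation as the log ratio of the
transcript concentration to its own time average over two full cell
cycles, $\log\!\big(m_g(t)/\bar m_g\big)$; the channel is exactly
invariant to rescaling a trajectory, which the tests assert
numerically. Natural log is the internal convention, with a `log2`
switch for microarray-style input. Times from experiments with
different native doubling times (60-100 min) are linearly rescaled to
a common 80-min cycle.

Absolute steady-state data (population-average concentrations in
unsynchronized cells) are modeled as the same two-cycle time average,
log10 transformed. Each published source enters as an independent
record.

Both channels use a Student-t error model with three degrees of freedom
— robust inference: a simple model of a complicated cell is guaranteed
to leave outliers, and t3 tails keep them from dominating. One error
scale per channel is inferred alongside the kinetic parameters.

The time average is a trapezoidal integral over $[0, 2T]$ starting at
t = 0 (the synchronization release) on a dense grid (481 points for an
80-min cycle; quadrature and solver refinement tests confirm
convergence). Whether the average should skip an initial transient is
genuinely open; t = 0 is the simpler convention and matches two-cycle
trajectory plots.

## Solvers

`integrate_model()` has two backends. `lsoda` (deSolve) with rtol
1e-7 / atol 1e-10 is the reference, stiff-capable path used for data
generation and reporting. The sampler's hot path uses a compiled
fixed-step RK4 whose step is capped by the fastest first-order rate in
the parameter vector ($\lambda h \le 0.25$, never above the 10 s output
spacing); across the prior box the two agree to ~1e-7 relative, far
inside the likelihood's resolution, and the equivalence is a standing
test. Solver failure is an explicit flag consumed by the likelihood as
$-\infty$, never a silent NaN.

Inference additionally treats any trajectory exceeding 1e3 uM as a
failed simulation. Millimolar mRNA is far beyond anything a yeast cell
holds, and a hard support boundary shared between the likelihood and
the calibration study's truth-generator keeps simulation-based
calibration exact (truths are drawn from the prior restricted to the
same simulable set the posterior lives on, `params_simulable()`).

## Parallel-tempered MCMC

The posterior is multimodal enough (nested feedbacks, log-scale priors
spanning decades) that a single chain stalls; we use parallel
tempering. `run_pt()` runs $n$ chains with inverse temperatures
$\beta_i = (i/(n-1))^2$ — quadratic spacing, dense near $\beta = 0$.
Only the likelihood is tempered, so chain 0 samples the prior exactly;
this makes "round trips from prior to posterior" well defined and is
why the ladder must reach $\beta = 0$. Per iteration: with probability
0.99 a random adjacent pair attempts a swap (accepted with probability
$\min\{1, e^{(\beta_i-\beta_j)(\ell_j-\ell_i)}\}$ on untempered
log-likelihoods $\ell$); otherwise every chain does five blocked
Metropolis-Hastings sweeps.

Blocking is automated: single-linkage clustering on $1 - |r|$ with a
0.5 absolute-correlation cut, re-learned every 10,000 burn-in
iterations from the cold chain's recent draws and shared across chains;
block proposal covariances are empirical covariances plus 1e-8 jitter;
zero-variance parameters get unit-variance singletons; below 100 draws
everything falls into one block. Per-chain, per-block scalar scales
adapt by a diminishing Robbins-Monro rule
$\log s \leftarrow \log s + t^{-0.6}(a - 0.23)$ toward the classic 0.23
acceptance target, interpreted per proposal; when the plan changes,
each chain's adaptation level (its scale relative to the theoretical
$2.38/\sqrt{d}$ start) carries over, so hot chains keep their wide
proposals instead of re-adapting from scratch. Adaptation and blocking
freeze at the end of burn-in (asserted by a test), so the sampling
phase is a valid Markov chain. Chains at $\beta > 0$ initialize from
prior draws with finite likelihood; the $\beta = 0$ chain initializes
from an unconditioned prior draw, because states whose simulations fail
carry genuine prior mass. Replica labels travel with states; the
full ledger of label positions supports `count_round_trips()`.

Reference settings mirror the source analysis (32 chains, swap
probability 0.99, five MH steps, subsample 1 in 2500, burn-in 1.25M /
sampling 5M iterations — these are the defaults a run-config file
inherits); the test suite and the validation studies run scaled-down
profiles, with problem sizes stated below.

## Model checking

`posterior_predictive()` propagates posterior draws through the model
and reports pointwise 5/50/95% bands of the modeled log-ratio curves —
the predictive distribution of the *mean* of the data; an option
re-adds t3 observation noise for full predictive checks.
`r_squared()` scores predictions against a null model with a separate
mean per experiment, so between-experiment offsets don't count as
explained variance. `spline_reference_r2()` gives the ceiling any
smooth curve could reach: a cubic smoothing spline per
gene-by-experiment, penalty chosen by exact leave-one-out
cross-validation over a fixed grid of 25 log-spaced values (1e-10 to
1e2) — deterministic by construction. One caveat found while testing:
at 12-25 points per experiment, leave-one-out selection occasionally
undersmooths pure noise (a known small-sample property of CV), so the
reference R² is best read as a distribution across genes, not a sharp
per-gene bound. `ci_width_summary()` reports 90% credible-interval
widths against prior ranges and counts parameters constrained to less
than half their prior range — the headline accounting of what each
data combination buys.

## The synthetic-data generator

The generator is the package's stand-in for the real thirteen-study
compendium, which has no machine-readable accessions. It emulates the
statistical structure the analysis assumes, with fixed defaults chosen
once:

* three time-course experiments with native doubling times 60, 80,
  100 min and 25, 17, 12 evenly spaced points over two native cycles,
  rescaled to the 80-min frame (matching the density of the real
  compendium's time courses);
* t3 noise with scale 0.2 on log ratios (typical microarray residual
  spread);
* two mRNA and three protein steady-state sources per species
  (mirroring SAGE + microarray and TAP + GFP + MS study counts), t3
  noise with scale 0.2 on log10 concentrations (between-study scatter);
* validation rates: per-gene values scattered log-normally (sd 0.2
  decades) around the true shared $\delta_m$, the true per-gene
  time-averaged transcription rates, and the true shared $\kappa$.

What it deliberately does not emulate: probe-level microarray noise,
synchronization decay over the second cycle, cross-platform batch
effects, or unit-conversion uncertainty for published rates. Passing
tests on synthetic data therefore certify the inferential machinery,
not the biology of any real dataset.

Two ground-truth presets are committed as fixtures and never
regenerated silently. The variant-4 preset was tuned once to sustain
oscillations: shared turnover rates 1.35e-3 /s (8.5-min half-lives),
induced transcription 2.5-fold stronger inside the
CLN3-SWI4-HCM1-NDD1-SWI5 ring, YOX1 repression with K = 0.02 uM and
h = 3.8, mild per-gene heterogeneity — giving a ~78-min period and
cyclin transcripts with two peaks over the two-cycle horizon. The
reduced preset is a single self-activating gene with moderate coupling
(induced share ~33% of mRNA input) and a 14-min mRNA half-life, chosen
so the synchronization-release transient (slow mode ~39 min) is
resolved by the experiments' sampling grids; it relaxes from low
initial concentrations to ~0.075 uM mRNA / ~0.10 uM protein.

## The reduced calibration studies

Desk-scale validation cannot re-run a sixty-hour inference, so the
sampler's correctness is certified on a reduced problem
(`reduced_problem()`): the single-gene model, both data channels, five
free parameters — $\beta$, $\delta_m$, $\kappa$ and the two error
scales — with the induced-transcription strength, protein degradation
rate and initial conditions treated as independently known. This free
set was chosen for identifiability: with $\delta_p$ known, the absolute
protein channel anchors $\kappa$ through
$\bar P = \kappa \bar m / \delta_p$, which is precisely the
data-integration mechanism the full analysis exploits, and it keeps
every named parameter's posterior concentrated enough that recovery
statements are meaningful. Freeing $\delta_p$ (or the coupling
$\alpha$) instead leaves $\kappa$ on a ridge and the study would
certify nothing. Rate priors span four decades (1e-5 to 1e-1 /s);
error-scale priors are capped at 1 (scatter above one log unit is not
credible measurement noise).

Three studies ship with the package and are recomputed from scratch by
`scripts/acceptance.R`:

* **Adaptive scaling** (`study_adaptive_scaling`): blocked adaptive MH
  on a seeded 10-d Gaussian with condition number 100; after freezing
  adaptation, the pooled per-block acceptance over the next 20,000+
  proposals should sit at 0.23 within Monte Carlo noise.
* **Ladder traffic** (`study_round_trips`): the full PT configuration
  (32 chains, quadratic ladder, swap probability 0.99) for 200,000
  iterations on the reduced problem (the first quarter as adaptive
  burn-in), counting completed prior-to-posterior-and-back replica
  journeys over the whole run. Traffic is throttled at the bottom of
  the ladder by the ~quarter of the reduced prior box whose
  self-activation dynamics diverge: such states have no likelihood and
  can only leave the prior chain through its own update moves, so
  single-run counts scatter noticeably (roughly plus or minus ten
  percent) around the hundred-trip scale.
* **Simulation-based calibration** (`study_sbc`): 50 replicates of
  draw-truth / generate-data / infer on the reduced problem (16
  chains, 24,000 iterations each), pooling indicators of whether each
  true parameter falls in its central 90% credible interval. Coverage
  should be statistically compatible with 90%; this is the strongest
  end-to-end check the package has, because it exercises the
  generator, the likelihood, the sampler and the interval machinery
  jointly and fails if any of them is biased.
* **Recovery and data integration** (`study_recovery`): on
  preset-truth data, posterior medians of $\beta$, $\delta_m$,
  $\kappa$ land within 0.3 decades of truth when both channels are
  used, and adding the absolute channel tightens their intervals —
  most dramatically for $\kappa$, whose interval collapses from
  nearly prior width to under a decade. This restates, at synthetic
  scale, the qualitative claim that combining relative dynamics with
  absolute concentrations is what pins the translation rate.

## Numerical and degenerate-input policy

* Proposals outside the prior box are rejected before any ODE solve.
* $-\infty$ is the only legal likelihood failure value; NaN from a
  posterior callable is a hard error.
* Swap and acceptance ratios handle $-\infty$ pairs explicitly (equal
  values swap; a failed state can always move toward the prior, never
  away from it).
* MAP ties resolve to the first draw; R² with a zero-variance null is
  reported missing; spline references require eight points per
  experiment.
* RK4 clamps tiny negative concentrations to zero at each step; the
  positivity of the exact flow is a structural property of the rate
  equations (tested at the boundary).

## Known limitations

The generator's realism limits what green tests mean for real data;
unit conversion for published transcription rates (molecules per minute
per cell versus uM/s) is configuration the user must supply; marginal
likelihood / formal model selection is out of scope (the nested
variants change the data they are fit to, so their marginal likelihoods
are not comparable); and the SBML export is structural Level 3 core —
it round-trips species, parameters and kinetic laws, but no external
simulator is bundled to re-integrate it.
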