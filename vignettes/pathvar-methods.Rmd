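---
title: "Models and methods behind pathvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pathvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pathvar` quantifies how cell-to-cell variation (CV) and covariation
(correlated fluctuation) of signaling-protein concentrations trade analog
single-cell transmission accuracy against population-level control of binary
cell activation. This vignette explains the models, the estimators, the
numerical choices, and the limits of what the synthetic-data tests
establish.

## The five-step linear cascade

A fold-input $R$ drives a chain of five activation/deactivation cycles,

$$\frac{dy_k^*}{dt} = \epsilon_{2k-1}\,u_{k-1}\,y_k - \epsilon_{2k}\,y_k^*,
\qquad u_0 = R,\; u_k = y_k^*,$$

with every inactive pool $y_k$ held at 1 (active forms are assumed a small
fraction of the total, so the precursor pools are not depleted). The ten
rate multipliers $\epsilon_i = e^{z_i \cdot \mathrm{CV}}$, $z_i \sim N(0,1)$,
model per-cell expression variation; the lognormal convention sets the
standard deviation of $\ln\epsilon$ equal to CV exactly (for small CV this
is also the coefficient of variation of $\epsilon$ to first order, since
$e^x \approx 1+x$). The system is linear in the active species and its
unique fixed point is the product formula implemented in
`steady_state_output()`; `simulate_population()` therefore draws multipliers
and evaluates the fixed point directly, while `simulate_trajectory()`
integrates the ODEs (adaptive `lsoda`, rtol $10^{-8}$, atol $10^{-10}$) and
is cross-checked against the closed form in the tests.

One numerical subtlety: with all rates near 1 the Jacobian has a five-fold
repeated eigenvalue, so transients decay like $t^4 e^{-t}$ rather than
$e^{-t}$. At the default horizon `t_end = 15` the trajectory is within about
$10^{-3}$ of the fixed point — visually equilibrated, which is all the
default is meant to provide — and the oracle-agreement tests integrate to
$t = 40$, where agreement is below $10^{-6}$. Equilibrium is always asserted
against the closed form (the `steady_state_error` attribute), never assumed
from the horizon. The default initial condition is the basal steady state at
$R = 1$ for the same cell's multipliers; starting from zero changes the
transient but not the terminal state, and the choice is exposed through the
`initial` argument.

Noise modes: `independent` draws all ten multipliers independently;
`sign_grouped` gives all five activating components one shared draw and all
five deactivating components another (the maximal-covariation case);
`custom` accepts any correlation matrix for the latent normals (Cholesky
factorization, with a pivoted fallback and an eigenvalue PSD check at
tolerance $10^{-10}$).

## Detection limit, Hill steepness, and the trade-off constant

For $N$ independent components the total log-output noise is
$\mathrm{CV}\sqrt{N}$. The fold-input detection limit at accuracy $a$ is

$$\mathrm{fIDL} = \exp\!\big(2\,\Phi^{-1}(a)\,\mathrm{CV}\sqrt{N}\big),$$

the factor 2 reflecting that basal and stimulated output distributions carry
the same noise, so each contributes one tail to the 5% overlap. The
simulated counterpart matches empirical quantiles (type-7, linear
interpolation) of the two log-output distributions; for the linear cascade
scale equivariance reduces this to the quantile ratio of the basal
distribution, and for non-equivariant outputs (the saturating variant)
`fidl_simulated()` bisects on $\ln R$ to tolerance $10^{-4}$ using common
random numbers. A zero-variance distribution returns exactly 1.

The binary model thresholds the same output (`y5* > 10` by default; the
value is arbitrary and the fitted steepness is insensitive to it, which the
tests check at thresholds 5/10/20 within 15%). Hill fits use
Levenberg–Marquardt on $f(R) = R^h/(k^h + R^h)$ with $R$ on its natural
scale, starting values $k$ at the grid point nearest fraction 0.5 and
$h = 2$, bounds $h \in (0, 100]$; saturated points (exact 0/1) are retained
because they carry steepness information, and a profile grid search over $h$
(optimizing $k$ at each candidate) backs up the fit on near-step data. A
curve with no interior point is step-like and is reported as an error rather
than a number.

Two calibration constants connect simulation and closed forms:
$\alpha = 2\,\Phi^{-1}(0.95) \approx 3.29$ and $\beta \approx 1.4$ in
$\mathrm{aHC} = \beta/(\mathrm{CV}\sqrt{N})$. Least-squares Hill fits of the
probit-shaped population curve systematically track
$\approx 1.70/(\mathrm{CV}\sqrt N)$ (the classical logistic-to-normal match
$\Phi(x) \approx \mathrm{logistic}(1.70\,x)$), which is why fitted
coefficients at 10% CV come out near 5.4 while the $\beta = 1.4$ closed form
predicts 4.4; the package reports both, and the acceptance band for the
regression slope (1.2–1.8) spans the two conventions. The co-dependency
product $\log_2(\mathrm{fIDL}) \cdot \mathrm{aHC} = \alpha\beta/\ln 2$ is
constant in CV and $N$ by construction; `tradeoff_curve()` verifies the
constancy to $10^{-10}$.

Partial covariation enters through standard error propagation:
$n_{cov}$ perfectly correlated components add linearly, the rest in
quadrature, giving $\mathrm{CV}_{tot} =
\mathrm{CV}\sqrt{N - n_{cov} + n_{cov}^2}$. This form is a reconstruction —
the co-dependency figure axis it supports is not accompanied by a printed
formula — and reduces correctly to the independent ($n_{cov} \le 1$) and
fully covarying ($n_{cov} = N$) limits.

## Mutual information

`mutual_information()` is the plug-in histogram estimator on
$(\log_2 R, \log_2 A^*)$ with a fixed bin width (0.05 by default), empty
bins contributing zero. No bias correction is applied, deliberately: the
estimator is meant to mirror the simple binned procedure it is compared
against, and the tests pin it to an independent double-loop oracle at
$10^{-12}$. Plug-in estimates of continuous channels at this bin width carry
substantial positive bias at moderate sample sizes, which is why the
saturation comparison (`mi_saturation_comparison()`) is read as a contrast —
saturation changes MI while leaving the quantile-matched detection limit
nearly unchanged — not as an absolute channel capacity. Inputs for that
comparison are drawn log2-uniformly over a configurable range (default
1–1000; no canonical value exists for it).

## The MAPK cascade

`mapk_model` implements a Sturm-type Raf–MEK–ERK cascade with negative
feedback intact: Michaelis–Menten Raf activation by RasGTP inhibited by
terminal pERK ($K_i = 500$, weak enough that an activated cell's reduced
drive stays inside the hysteresis of the downstream switch); a distributive
MEK tier operating far from saturation ($K_m = 300$ against a 120-unit
pool), so ppMEK scales with both the MEK pool and the square of active Raf;
and a distributive ERK tier in which both phospho-forms are handled by one
shared phosphatase working near saturation ($K_m$ of 0.5 and 2 against a
100-unit pool). The shared saturated phosphatase makes the ERK cycle
bistable, a known property of two-site modification with a common
capacity-limited demodifying enzyme. The parameterization is an in-house
calibration, shipped as `inst/extdata/mapk_cascade_synthetic.yaml` and
labelled synthetic: the cited published parameter set is not reproduced
here, and every claim made of this module is ordinal (orderings and shapes),
not quantitative, so it survives parameter-set substitution.

The bistable jump is what produces genuinely bimodal terminal pERK under
15% lognormal variation of the MEK and ERK totals (10% on the RasGTP
input): cells sit on the low or the high branch, with only the few
mid-transit cells in between. It also fixes the sign of the covariation
effect: the switching threshold falls with the MEK pool (more ppMEK drive)
and with the ERK pool (a larger pool pre-saturates the shared phosphatase),
so cells rich in either protein activate at lower doses — active cells have
higher median MEK and ERK — and making the two pools covary widens the
spread of per-cell thresholds, flattening the population dose-response
relative to independent noise of the same marginal CV. Doses are log2-spaced
(default 24 points over $2^9$–$2^{13}$, bracketing the transition near
$2^{11}$); activation is classified by terminal-time pERK against the
threshold 17, which falls between the low (~0–5) and high (~70–100) modes.
`fold_error_at_fraction()` interpolates monotone piecewise-linearly in
$(\log_2 \mathrm{dose}, \log_{10} \mathrm{fraction})$, with `cummax` applied
to the fractions to absorb Monte-Carlo jitter.

## Measurement statistics

The abundance pipeline mirrors a targeted single-cell proteomics workflow.
`correction_factors()` normalizes each reference peptide by its median
across samples, takes the per-sample median over the reference set (the 22
non-cycling peptides by default; cyclin-like proteins are excluded), and
divides the sample by it. Two properties deserve note:

- *Idempotence*: dividing a sample by a scalar divides its median
  normalized reference value by the same scalar, so a second pass against
  the **same** reference medians returns factors of exactly 1; the medians
  are therefore returned and can be passed back (`reference_medians`).
  Recomputing the anchor from corrected data shifts it by order
  noise/$\sqrt{n}$ and gives second-pass factors near, but not exactly, 1.
- *Correlation attenuation*: because the per-sample median contains the
  correlated pair's own deviations, correction deflates corrected
  between-protein correlations by a few hundredths (while raw data are
  inflated by the shared calibration error). Recovery tests therefore check
  point estimates against the planted value with a tolerance that includes
  this deflation, and confidence-interval coverage at a correspondingly
  reduced rate. Any analysis of corrected data — including real
  measurements — carries the same property.

CVs use the $n-1$ denominator (small batches of 5–10 make the distinction
material); bootstrap intervals are percentile intervals over 2,000 resamples
by default. Pairwise correlations are Pearson with two-sided t p-values
($df = n-2$), BH-adjusted over the unique unordered pairs only, with
zero-variance proteins excluded from the family; the BH step-up is pinned to
a literal brute-force oracle in the tests, and the t p-values to a
permutation null. The imaging side: 2N gating locates the lowest prominent
mode (kernel density, peaks at $\ge$ 20% of the maximum) and keeps cells
within $\pm 25$% of it — the gate is explicit and configurable since the
underlying practice is visual inspection — with an optional central-radius
filter against illumination fall-off; concentrations are antibody intensity
over total-protein-mass stain; integrated FRET activity is the trapezoidal
area under the ratio from stimulus time to trace end (no baseline
subtraction by default, available as an option); the active/inactive
threshold sits at the density minimum between the two most prominent modes
of the score distribution and fails loudly on unimodal data; extreme-group
comparisons take the top and bottom 15% by score, report medians, quartiles
and notch half-widths $1.58\,\mathrm{IQR}/\sqrt{n}$, and use a two-sided
Wilcoxon rank-sum test (a choice; the source analyses do not name their
test).

## What the synthetic data do and do not show

The generators emulate: lognormal biological variation with planted
per-protein CVs (defaults in the 5–15% range) and a planted correlation
structure (MEK–ERK and MCM5–MCM7 at $r = 0.7$); cyclin-like mid-cycle
accumulation and late degradation (qualitative shape only); per-sample
multiplicative calibration error (5% default) and per-measurement technical
noise; the standard egg designs (5 eggs $\times$ 5 timepoints; 2 timepoints
$\times$ 6 batches $\times$ 10 eggs; 30 pooled-lysate aliquots with
biological CV forced to zero, the technical-replicate design that separates
technical from biological variation); and, for imaging, lognormal mass and
correlated target concentrations, a 2N/4N DNA mixture, a logistic
activation model increasing in the summed log concentrations, and
two-class saturating-rise FRET traces at 2-minute sampling.

They do not emulate: absolute abundances of real proteins, heavy-tailed or
batch-structured technical artifacts, mis-segmentation, antibody
nonspecificity, or drift within mass-spectrometry runs. Passing recovery
tests therefore establishes that the estimators are correct under the
declared statistical model, not that real measurements satisfy that model.
Calibration and technical noise are separable only through the replicate
design, and the generator makes them identifiable only in that mode.

## Problem sizes and defaults

Simulated populations default to 5,000 cells per dose (Monte-Carlo standard
error on a fraction $\le$ 0.7 points) over 30 log-spaced doses on
$[1, 100]$; detection-limit simulations use $10^5$–$10^6$ cells; MAPK
populations use 50–200 cells per condition in the tests (each cell is an
8-species ODE solve) and are ordinal checks. The experiment runners
(`run_experiment()`) expose all of these as parameters and record the seed,
a parameter hash and the package version in a manifest next to every output
bundle.
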