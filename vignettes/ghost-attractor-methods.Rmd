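---
title: "Methods: ghost-attractor dynamics and transient memory in receptor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ghost-attractor dynamics and transient memory in receptor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ghostmem)
```

# The models

## The receptor--phosphatase toggle switch

The core object is a two-component double-negative-feedback switch
between the active fraction of a receptor, $R_a$, and the active
fraction of an inactivating enzyme (a phosphatase), $P_a$:

$$
\begin{aligned}
\frac{dR_a}{dt} &= k_R\!\left[R_i\,(\alpha_1 R_i + \alpha_2 R_a +
  \alpha_3 LR_a) - \hat\gamma\, P_a R_a\right], \\
\frac{dP_a}{dt} &= k_1\!\left[(1-P_a) - k_{21} P_a -
  \hat\beta\, P_a (R_a + LR_a)\right] .
\end{aligned}
$$

Species are fractions of conserved totals, so $R_i = 1 - R_a$ (or
$1 - R_a - LR_a$ when ligand is dynamic) and $P_i = 1 - P_a$.  The
input is the fraction of ligand-bound receptors $LR_a$.  $\hat\gamma$,
the specific reactivity of the phosphatase towards the receptor, is
proportional to the total phosphatase/receptor concentration ratio and
is the bifurcation parameter: the published organizations are 2.5
(irreversibly bistable), 2.957 (critical, at the upper saddle-node),
3.5 (reversibly bistable) and 4.3 (monostable), see
`organization_gamma()`.

A deliberate reading choice: the published rendering of the equations
drops brackets, and we take $k_R$ and $k_1$ to multiply their *entire*
bracketed rate expressions.  This is forced by the statement that they
are kinetic constants that do not influence steady states, and it is
validated numerically: the steady states are invariant under rescaling
$k_R$ or $k_1$ (a property test), and the upper fold computes to
$\hat\gamma = 2.9521$, within 0.2% of the published critical value
2.957.  With the same reading the basal stationary phosphatase fraction
is $P_a^\ast = 1/(1+k_{21})$, consistent with the basal state
$P = k_1/(k_1+k_2)$ used in the propagation-threshold analysis.

Two ligand modes are exposed and every call says which one it uses:
*parameter mode* ($LR_a$ a constant, for bifurcation analysis) and
*dynamic mode* ($LR_a$ a state driven by binding of the total ligand
$L_T$, for pulse simulations, adding $-k_{on}R_aL_T +
\tfrac12 k_{off}LR_a$ to the $R_a$ equation and
$dLR_a/dt = k_{on}(R_a+R_i)L_T - k_{off}LR_a$).  Half of the unbinding
flux returns to the active pool, as printed.

## The two-compartment trafficking model

`compartment_params()` configures the seven-species EGFR model:
plasma-membrane species ($R_a^{PM}$, $R_i^{PM}$, $LR_a^{PM}$), the
phosphatase $P_a$, endosomal species ($R_a^E$, $R_i^E$) and an
accumulator $LR_i^E$ for degraded ligand-bound receptor.  Degradation
moves mass into the accumulator, so the seven derivatives sum to zero
exactly (a property test asserts this at random states).  The total
receptor concentration $R_T$ is the bifurcation parameter.

The phosphatase equation is read the same way as in the toggle:
$dP_a/dt = k_1[(1-P_a) - k_{21}P_a - \beta\,P_a R_T(R_a^{PM} +
LR_a^{PM})]$ with $\beta = 36.0558$ the *hatted* constant.  This
reading is the one that reproduces the published geometry: the
zero-ligand fold in $R_T$ computes to 1.3502 (published critical
organization 1.3499) and the large-$k_{rec}$ fold asymptote to 1.081
(published 1.086).

The self-organization law replaces the recycling rate by
$k_{rec}\,(R_T - R_{T,asymp})/(R_T(1-LR_i^E) - R_{T,asymp})$, capped at
a multiplier of 2.5.  The published saturation statement is ambiguous
(multiplier vs product); we cap the multiplier, and a non-positive
denominator falls to the cap.

## The exponential-decay baseline

`decay_params()` implements $dR_a/dt = I\,\alpha(R_T - R_a) - \beta
R_a$ with the 0/1 pulse indicator $I$.  The five published
$(\beta, R_T)$ presets all produce the same constant-input amplitude
$\alpha R_T/(\alpha+\beta) \approx 0.816$, which equals (within 1%) the
activated response of the critically organized toggle -- that is the
calibration the presets encode, and a test asserts it.

# Time units and stimulation protocols

Model time is dimensionless.  Protocols are stated in minutes and
converted at 1 min = 60 model units (`units_per_minute()`).  The choice
is constrained by the pulse calibration: the pulse amplitude must
produce $LR_a = 0.15$ *in steady state* within a 5-min pulse, which
requires the ligand equilibration time $1/k_{off} \approx 60$ units to
fit inside the pulse.  The published dimensionless-to-minutes
conversion equates simulated to experimental phosphorylation kinetics
on data we do not have; the 60 units/min factor is a calibrated
stand-in validated by the pulse-train acceptance behaviour.

`random_pulse_train()` samples, by default, uniformly over all
*pairwise disjoint* arrangements of the pulses (the order-statistics
construction: uniform points in the slack interval plus cumulative
pulse offsets).  This was a genuinely open design point -- "randomly
distributed" does not say whether pulses may overlap -- and the
implementation settled it: with independent onsets, overlapping pulses
merge and a train can have fewer than 12 distinct on-intervals, which
caps the response interval count and drives the reversible
organization's ensemble minimum to 6, contradicting the published 7-12
range; disjoint sampling (the physically realizable perfusion
protocol: twelve distinct 5-min pulses) restores minima of 8-9.
Independent onsets with union-merge remain available via
`allow_overlap = TRUE`, and the union arithmetic is tested against a
brute-force indicator oracle and the analytic coverage expectation.
`two_pulse_protocol()` and `step_protocol()` build the probe
protocols.  The pulse amplitude defaults to
`ligand_for_target_occupancy(params, 0.15)` $= k_{off}\cdot 0.15 /
(k_{on}\cdot 0.85) \approx 0.981$.

# Numerics

* Deterministic integration: adaptive Dormand--Prince 5(4) with
  relative tolerance `1e-8`, absolute `1e-10`, stepping exactly onto
  protocol breakpoints and output times.  Time comparisons use a
  scale-aware epsilon; naive absolute tolerances stall when the gap to
  a stop point falls under the floating-point resolution of
  $t \sim 10^4$.
* Negative-state handling: round-off undershoots above $-10^{-7}$
  (consistent with the integrator tolerances) are clipped to zero;
  anything larger raises an error naming the failure time.
* Fixed points: the toggle admits an exact branch parameterization
  $\hat\gamma(R_a) = (1-R_a)(\alpha_1(1-R_a)+\alpha_2R_a+\alpha_3LR_a)
  (1+k_{21}+\hat\beta(R_a+LR_a))/R_a$ (substituting the stationary
  $P_a$); fixed points are bracketed on a 4000-point grid and polished
  with `uniroot` to near machine precision.  Stability comes from the
  eigenvalues of a central-difference Jacobian.
* Continuation: the toggle uses the closed form; the compartment model
  uses generic pseudo-arclength continuation (secant predictor, Newton
  corrector orthogonal to the tangent, step halving/growth) on the
  reduced zero-ligand system -- the conservation constraint eliminates
  $R_i^{PM}$, and the decoupled degraded pool is dropped, removing the
  two structural zero eigenvalues.  Folds are refined either exactly
  (toggle: stationary points of the closed-form branch) or by a
  bordered Newton solve of $f = 0$, $Jv = 0$, $c^{\top}v = 1$.
* The fold asymptote in $k_{rec}$ is Richardson-extrapolated in
  $1/k_{rec}$ from evaluations at 100x and 200x the default rate, with
  a convergence flag at 0.1% agreement (the pair differs by 0.13%, so
  the flag reports marginal convergence; the extrapolated value is
  within 0.5% of the published asymptote).

# Quasi-potential landscapes

The potential is accumulated along deterministic trajectories,
$dU/dt = -[(dR_a/dt)^2 + (dP_a/dt)^2]$, so $U$ is non-increasing and
stationary exactly at fixed points.  Alignment follows the published
recipe: curves in one basin are aligned at their common attractor
level; basins are aligned across *separatrix pairs* (adjacent initial
conditions whose trajectories reach different attractors), each pair
weighted by $\tfrac12(1-\cos\theta)$ of the angle between the pair's
initial velocities, which concentrates weight at the saddle where the
velocities diverge.  The recipe does not say how the pairwise
constraints combine; we solve a weighted least-squares problem for the
basin levels (one level gauged to zero) -- the minimal consistent
aggregation.

The surface is reported on the grid of initial conditions: each node
carries the exact aligned potential of its own trajectory.  (A local
weighted-plane scattered interpolator is used internally; making the
output nodes coincide with trajectory initial points removes
interpolation noise entirely, which matters because trajectory clouds
are strongly anisotropic.)  For an exactly gradient system this
recovers the generating potential: the acceptance test demands 1% RMS,
and the double-well test system recovers at ~0.1%.

Wells are extracted by *topographic persistence*
(`landscape_minima()`): minima are flooded from below with a union-find
merge and a minimum that joins a deeper basin before rising 0.1% of the
surface range above its own level is treated as noise.  For a
non-gradient field the path-dependence of the heuristic makes well
floors flat at the $10^{-3}$ level, so the argmin can sit a few grid
cells along the floor from the attractor; tests therefore assert the
attractor's node value lies within the inter-well barrier of the well
minimum (strict one-cell coincidence is asserted for the gradient
system, where the construction is exact).  At the critical
organization the vanished high-activity state remains visible as a
sub-threshold shallow feature -- the landscape signature of the ghost.

# Response metrics and ensembles

The activity threshold is the organization-adaptive half-maximum: the
midpoint between the basal response at zero input and the activated
steady response at a held input of 15% bound receptors (the published
analyses never state their threshold; about 0.48 for the canonical
organizations).  The held-input (parameter-mode) response is used here;
the dynamic-ligand activated amplitude (~0.815) is a different
quantity, used only for the decay-preset calibration cross-check.
Tests probe robustness to a 20% shift of the threshold.

The dynamic-range scan reports the *reversible* activation amplitude:
activated response minus the resting response reached after input
removal.  With the pre-stimulus basal state as reference the scan has
no interior peak; with the post-stimulation resting state the
irreversible regime's retained high state collapses the range and the
scan peaks exactly at the fold, which is the published behaviour.  Intervals are maximal runs of response at or above
threshold with crossing times refined by linear interpolation; the two
ensemble metrics are the total active fraction of the 480-min horizon
and the number of disjoint intervals, over 1,000 independent trains of
twelve 5-min pulses (ensemble size reducible; per-train seeds derive
deterministically from the master seed).

# Particle-based reaction--diffusion simulation

Molecules diffuse by Brownian steps of standard deviation
$\sqrt{2D\Delta t}$ per axis on a periodic square; with the published
defaults $4\sqrt{2D\Delta t} = 17.9$ nm $\le \sigma = 20$ nm, so
encounters cannot tunnel through the interaction radius undetected.
Bimolecular channels fire with probability $1-(1-\tilde g\Delta t)^n$
over the $n$ eligible partners within $\sigma$ (the Doi rule); states
update synchronously from the pre-step configuration, which makes the
update order-independent and reproducible.  Channels mirror the
toggle: autonomous ($R_i+R_i$), autocatalytic ($R_a+R_i\to 2R_a$,
logged for $R_0$), deactivation ($P_a+R_a$), phosphatase inhibition
($R_a+P_a$), plus unimolecular phosphatase flipping.

The published microscopic rates are stated in an ambiguous
typographical unit ("$\sigma$2$\pi$"); we implement the normalization
unit as the inverse interaction-disc area $u = 1/(\pi\sigma^2)$ and
treat only the *relative* sweep positions as meaningful.  With this
reading the published regime labels hold without calibration: at 4.55u
a high-state run is maintained for the whole horizon, at 4.95u
activity is prolonged and intermittent (local pockets deactivating and
re-igniting), at 6u it collapses within a couple of seconds -- though
with residual burstiness, because under this normalization the
microscopic fold sits slightly above 6u.  The
autocorrelation-time comparison of the near-critical bursts is
therefore made against the deep-monostable end of the published sweep
(9u), where basal fluctuations are fast.

$R_0$ -- the expected number of molecules a single active receptor
activates during its active lifetime -- is estimated from the event
log: each deactivation closes a lifetime and contributes its offspring
count, averaged inside a ~200 ms window.  When several active
receptors could have caused an activation the activator is drawn
uniformly among them; only the mean matters and it is unaffected.  The
analytic transmission potential
$R_0 = \alpha_2 R_T (1-R_a) / (\gamma P_T P_a)$ is exactly 1 at the
nonzero fixed point when autonomous activation is neglected, and the
basal state is linearly stable exactly when $R_0 < 1$; both identities
are asserted to $10^{-9}$.  The mean-field check runs the particle
system at 100x diffusion (with $\Delta t$ shrunk to preserve the
detection guarantee) on a 1 um domain, with the autonomous seeding rate
raised 20x so enough activation events occur inside the CPU budget --
the offspring statistics that define $R_0$ are not affected by the
seeding rate at basal occupancy.

Macrostates are estimated per the published recipe: a two-component
Gaussian mixture (a small local EM) iteratively pruned at the 90th
percentile of per-component Mahalanobis distance.  "Until convergence"
is read as: until pruning no longer moves the centroids (a fixed
percentile always removes points, so assignment-set stability alone
never terminates).

# Stochastic simulation and fluctuation sensing

Multiplicative noise is interpreted in the Stratonovich sense and
integrated with the Heun predictor-corrector scheme (the original
description names the interpretation, not the scheme).  The amplitude is
$\sigma\sqrt{x(1-x)}$ per noisy variable -- the inverse-square-root
relative scaling at small $x$ with boundary vanishing; the published
text gives only the scaling, not the function.  The toggle variant puts
noise on every variable ($\sigma = 0.05$); the compartment variant only
on $R_a^{PM}$ (intensity $\sigma_a^2 = 8\times10^{-4}$).  The adaptive
rule halves the step (with a fresh Wiener increment) when a step would
leave $[0,1]$ or move any state by more than the increment tolerance,
doubles it after ten accepted steps, and at the step floor accepts with
clamping (counted and reported).

Dominant frequencies come from a Morlet continuous wavelet transform
($\omega_0 = 6$, FFT convolution, 64 logarithmic scales): power is
averaged over time at each scale (cone-of-influence edges discarded)
and the dominant frequency is the argmax, after linear detrending.

## Known limitations: the fluctuation-sensing scan

The published claim that the dominant frequency of basal-activity
fluctuations is minimal near the saddle-node could **not** be
reproduced from the stated ingredients, and the corresponding
acceptance criterion is deliberately left failing rather than tuned:

* the basal fixed point's linearization is essentially independent of
  $R_T$ (slow eigenvalue $-0.01495$ at $R_T=1.0$ vs $-0.01487$ at
  $R_T=1.3499$), so no local spectral shift exists near the fold;
* with the published intensity the basal fluctuations (s.d.
  $\sim 6\times10^{-4}$, maximal excursions $\sim 5\times10^{-3}$)
  never reach the ghost region ($R_a^{PM} \sim 0.29$), so the
  nonlinear slow-excursion mechanism is out of reach as well;
* a 10x larger effective noise (the per-step reading of the noise
  convention) drives full stochastic switching instead, and an
  intermediate amplitude produces no trend either.

The scan (`frequency_vs_RT_scan()`) is implemented exactly as
specified -- $N = 50$ realizations per concentration, per-realization
dominant frequencies averaged -- and reports what it measures.

Basal runs of the compartment SDE sit within one noise increment of
the $R_a = 0$ boundary (the basal activity is $\sim 10^{-3}$), so
boundary contacts are persistent there; the clamp counter makes this
visible, and the sub-0.1% clamping bound is asserted where it is
meaningful, away from the boundary (toggle variant at the high state).

# Self-organized criticality run

`self_organized_run()` simulates the compartment model with
degradation active under a train of stimulus pulses twice: with the
dynamic recycling law and with fixed recycling.  With fixed recycling
the loss of membrane receptors shifts the system into the monostable
regime and the post-pulse prolongation shrinks pulse over pulse; the
dynamic law re-positions the system near the fold and retains the
prolongation until the multiplier cap binds.  With degradation off the
two runs coincide exactly (the multiplier is 1), which is the control
test.

# What a green test establishes -- and what it does not

The synthetic protocols emulate the published stimulation design
(random 12 x 5-min pulse trains over 480 min, steps, two-pulse probes)
exactly, but they are idealized square inputs with instantaneous
mixing; real growth-factor exposure has finite rise times,
receptor-level heterogeneity and spatial gradients that the
deterministic compartment model does not represent.  The particle
simulator runs at accelerated kinetics (the published choice) on
micrometre domains for seconds, not cell-scale minutes.  Green tests
therefore establish the *dynamical mechanism* -- fold geometry, ghost
transients, history-dependent integration, propagation thresholds --
not quantitative agreement with any experiment.
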