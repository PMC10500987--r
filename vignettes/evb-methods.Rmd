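---
title: "EVB free-energy profiles: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EVB free-energy profiles: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evbfep)
```

## The two-state EVB model

The empirical valence bond method represents an elementary reaction step by
two valence-bond states — the reactant and product bonding patterns — each
described by an ordinary classical force field.  Their energies $\epsilon_1$
and $\epsilon_2$ form the diagonal of a $2\times 2$ Hamiltonian,

$$H = \begin{pmatrix} \epsilon_1 & H_{12} \\ H_{12} & \epsilon_2 + \Delta\alpha \end{pmatrix},$$

whose lowest eigenvalue

$$E_g = \tfrac12 (H_{11}+H_{22}) - \tfrac12\sqrt{(H_{11}-H_{22})^2 + 4H_{12}^2}$$

is the adiabatic ground-state surface on which the free-energy profile is
computed (`ground_state_energy()`).  Two parameters are not supplied by the
force fields and must be calibrated on a reference reaction:

* the **coupling element** $H_{12}$, implemented as
  $A\,e^{-\mu (r-r_0) - \eta (r-r_0)^2}$ over a caller-chosen coordinate
  (an interatomic distance or the energy gap).  The exact printed form of
  this expression varies between EVB codes; the implementation here follows
  the standard description — an exponential, a Gaussian, or a flat constant
  when $\mu=\eta=0$ — and the constant form is the only one that is
  calibrated, since single constant $H_{ij}$ values are what reference
  calibrations report.  Both decay coefficients are evaluable for forward
  analysis of stored data.
* the **gas-phase shift** $\Delta\alpha$, a constant added to the product
  diabat only.  Keeping it off the reactant state means a recalibration
  never changes the forces that generated a stored trajectory, which is
  what makes pure-reanalysis calibration legitimate.

Both parameters are phase-independent: calibrated on the uncatalyzed
reference reaction they are reused unchanged in the enzyme.

Assumptions inherited from the method: exactly two states; $H_{12}$ real
and phase-independent; the diabats are valid force fields over the whole
sampled configuration space.  Bonds that break or form must be Morse rather
than harmonic (`morse_params()`) so the dissociated state has finite
energy, and 6–12 van der Waals terms between atoms whose bonding changes
are replaced by a soft exponential repulsion $C e^{-\beta r}$
(`soft_repulsion_params()`); the prefactor is exposed as a parameter with a
1 kcal/mol default.

## Sampling on the mapping potential

Sampling is driven by the mapping potential
$V(\lambda) = (1-\lambda)\epsilon_1 + \lambda(\epsilon_2+\Delta\alpha)$ in
a schedule of $\lambda$ windows (default 51 uniform windows, the common
choice for this kind of calculation; `lambda_schedule()`).  Because
$V(\lambda)$ is a *linear* combination, the difference between adjacent
mapping potentials per configuration is exactly
$\Delta\lambda\,\Delta\epsilon$ with
$\Delta\epsilon = (\epsilon_2+\Delta\alpha)-\epsilon_1$ — only the two
end-state energies per frame need to be stored.

### The free energy along the mapping path

`mapping_free_energies()` applies the exponential (Zwanzig) estimator
between adjacent windows in both directions,

$$\Delta G_{n\to n+1} = -\beta^{-1}\ln\langle e^{-\beta\Delta\lambda\,\Delta\epsilon}\rangle_n,$$

and averages the forward and the (negated) backward estimate
arithmetically; this is the plainest contract consistent with
"average over the forward and backward mapping directions", and cancels
the leading hysteresis.  Acceptance-ratio estimators are deliberately out
of scope.  All exponential averages are computed with a max-shifted
log-sum-exp, so finite input can never produce non-finite output.

### Projection onto the energy-gap coordinate

Configurations are binned on the generalized reaction coordinate
$X_s = \epsilon_1 - (\epsilon_2 + \Delta\alpha)$, so the reactant basin
sits at negative $X_s$ and the product basin at positive $X_s$ (the diabat
crossing is at $X_s = 0$).  For window $m$ and bin $s$ the umbrella
correction from $V_m$ to the ground state is

$$\Delta G(X_s) = \Delta G(\lambda_m) - \beta^{-1}
  \ln\Big\langle \delta(X - X_s)\, e^{-\beta(E_g - V_m)} \Big\rangle_m,$$

implemented as the sum of $e^{-\beta(E_g-V_m)}$ over the window's frames in
the bin divided by the window's **total** frame count
(`normalization = "window"`, the default in `umbrella_profile()`).  This
normalization matters: dividing by the *bin's* frame count instead (the
conditional average, available as `normalization = "bin"`) leaves a
spurious $+k_BT\ln P_m(s)$ term in every window's contribution, which we
measured as an $\approx 0.08$ kcal/mol systematic error against the exact
oracle on the default toy model.  With the window normalization every
window's contribution estimates the *same* bin free energy, and the final
profile is their average weighted by each window's share of the bin's
configurations (`combine_bins()`), with weights that sum to one per bin.

Binning defaults are 50 uniform bins over the observed gap range with a
minimum of 30 configurations for a bin to count as valid; the reference
implementations do not publish their settings, so both are plain
configuration parameters, flagged rather than silently dropped.  A
degenerate input in which every frame has the same gap falls back to a
single bin with a warning.

### Reading off the barriers

`extract_barriers()` locates the transition state as the most *prominent*
interior local maximum of the valid profile — the maximum of
min(drop to the left minimum, drop to the right minimum) — with ties broken
toward the smaller $|X_s|$, then takes the lowest valid bin on each side.
A plain global maximum is not usable here: on sampled profiles the global
maximum is usually a poorly-sampled tail bin.

Two extraction modes are provided.  `refine = "none"` reports the discrete
bin values (the natural contract for exact, densely-binned profiles).
`refine = "parabolic"` fits a quadratic through the bins around each
extremum (half-width 3) and reports the fitted vertex.  The refinement
exists because discrete extrema carry two biases that do not average away:
the argmin over several near-degenerate noisy bins selects the noise
(biasing minima low and maxima high), and bin averaging flattens curvature
by $O(w^2)$.  Comparing a sampled profile against the quadrature oracle at
matched binning, bin-level values agree to $<10^{-3}$ kcal/mol while raw
extracted extrema disagreed by $\sim 10^{-2}$; the parabolic vertex removes
this and is the recommended mode whenever profiles with different noise or
binning are compared.

## The built-in toy system

`default_toy_model()` is a one-dimensional stand-in for the MD layer: two
harmonic diabats with $k = 100$ kcal mol$^{-1}$ Å$^{-2}$ and minima at 0
and 1 Å, the product diabat offset by $+4.6$ kcal/mol, and a constant
coupling $A = 15$ kcal/mol.  The offset was chosen (by hand, from the
closed-form coupling lowerings of the two wells) so the ground-state
reaction free energy is about $+4$ kcal/mol with a low-kcal/mol barrier —
profile scales representative of a calibrated enzyme-style surface.  Morse
diabats and an optional soft repulsion on either diabat are available for
less symmetric tests.

Sampling is Metropolis Monte Carlo on $V(\lambda)(x)$ rather than any form
of dynamics: the estimators only need configurational Boltzmann sampling,
and a random walk needs no force code — the smallest correct stand-in for
MD.  Choices that matter:

* **proposal width** 0.18 Å by default, which is $\approx 2.4\sigma$ of the
  default wells at 300 K — the optimal-scaling rule for a one-dimensional
  random-walk proposal (acceptance near 45%).
* **thinning** keeps every 2nd post-burn-in step.  Aggressive thinning only
  discards information; the exponential averages downstream are noisy
  functionals and benefit from every sample.
* **window chaining**: window $m+1$ starts from the final coordinate of
  window $m$, mirroring consecutive FEP simulations; independent replicas
  differ only by a deterministically derived sub-seed, mirroring replicate
  simulations started from randomized velocities.  Identical seeds give
  bit-identical trajectories (the kernel draws from R's RNG).

What the toy model does *not* emulate: multidimensional coupling between
the reaction coordinate and an environment, the flat-bottom donor–acceptor
restraints used in real enzyme runs, long-range electrostatics, or any
kinetic observable.  Tests passing on the toy model therefore validate the
*analysis machinery* — the algebra from $(\epsilon_1,\epsilon_2)$ series to
$\Delta G^\ddagger/\Delta G^0$ — not the physics of any particular system.

`exact_gap_profile()` is the independent oracle: dense midpoint quadrature
of $e^{-\beta E_g(x)}$ over the coordinate range, binned on the gap exactly
like the estimator.  The grid is cell-centered so mirror-symmetric models
produce exactly symmetric profiles and grid points do not land on bin
edges; doubling the default grid density moves the extracted barrier by
less than $10^{-3}$ kcal/mol (asserted in the tests).  The test suite and
the acceptance script compare the sampled pipeline (51 windows ×
$10^5$ steps × 5 replicas) to this oracle at matched bin edges: the pooled
replicate profile with parabolic extraction agrees with the oracle to
within 3× the replicate standard error of the mean (typically a few
$10^{-3}$ kcal/mol deviation).

## Calibration

`calibrate_evb()` finds the constant coupling $A$ and shift $\Delta\alpha$
such that reanalysis of stored trajectories reproduces reference
$(\Delta G^\ddagger, \Delta G^0)$ within a tolerance (default 0.01
kcal/mol).  It is pure post-processing: for constant-coupling runs neither
parameter enters the mapping forces.  If an $r$-dependent coupling were
calibrated the same stored-trajectory reweighting would still be used, with
the usual caveat about overlap quality; that calibration is intentionally
not implemented.

The solver is a damped quasi-root iteration with numerical differences,
organised as alternating one-dimensional secant solves: $\Delta\alpha$
against the reaction free energy, then $A$ against the barrier, repeated
until the joint residual vector is inside the tolerance (iteration cap 50,
per-step move capped at 25 kcal/mol, negative-$A$ excursions clamped to
zero with a warning).  The alternating form was chosen over a joint
2×2 Newton step after the latter proved able to stall on a residual ridge
far from the solution, where the barrier and reaction values become
collinear.

Far-displaced starting points (e.g. $\Delta\alpha$ off by $\pm 20$
kcal/mol) can push the reanalyzed profile out of the barrier regime
entirely — a monotone profile has no interior maximum and strict extraction
correctly errors.  Inside the solver, `evaluate_targets(...,
on_no_barrier = "continue")` therefore falls back to a continuation
convention: split the profile at the diabat crossing $X_s = 0$, take the
side minima and the intervening maximum.  These continuation values have
the right monotone responses to steer the iteration back into the barrier
regime, and the two modes agree exactly whenever a genuine barrier exists;
the reported targets and the post-convergence audit always use strict
extraction.  Every successful calibration is re-verified by an independent
`evaluate_targets()` call before returning.

One physical point worth stating: the *mapping* free-energy difference
responds to $\Delta\alpha$ exactly one-to-one (an identity tested to
$10^{-10}$), but the *adiabatic* $\Delta G^0$ responds by
$c_2^2(\mathrm{PS}) - c_2^2(\mathrm{RS})$ — about 0.78 per unit shift on
the default toy model — because state mixing at finite coupling attenuates
the shift.  Calibration is unaffected (the solver measures the actual
response), but a shift of $\Delta\alpha$ by $\delta$ should not be expected
to move the profile's $\Delta G^0$ by exactly $\delta$.

Whether a reference calibration should be done on the replicate-averaged
profile or per replica and then averaged is not standardized; this package
calibrates on whatever frame set it is given, and the natural choice for
replicate data is to pool the replicas (the replicate-averaged profile),
which is what the acceptance workflow does.

## Replicate statistics and the Arrhenius decomposition

`replicate_summary()` reports mean, sample standard deviation ($n-1$
denominator) and SEM $= \mathrm{SD}/\sqrt{n}$ over independent replicas —
the error model appropriate when each replica is an independent estimate of
the same free energy.  The $n-1$ convention is what reproduces the SEM
columns of the reference replicate tables (20 and 30 replicas) at two
decimals.

`arrhenius_fit()` regresses $\Delta G^\ddagger/T$ on $1/T$ by ordinary
least squares: under $\Delta G^\ddagger(T) = \Delta H^\ddagger -
T\Delta S^\ddagger$ the slope is $\Delta H^\ddagger$ and the intercept
$-\Delta S^\ddagger$; $R^2$ is the squared Pearson correlation.  Results
are carried at full precision, with rounding left to the caller: note that
$T\Delta S^\ddagger$ at 283 K computed from the *unrounded* entropy
($-0.01844$) is $-5.22$ kcal/mol, whereas the two-step rounding through
$-0.018$ gives $-5.09$; the package reports the unrounded value.
Heat-capacity (temperature-dependent $\Delta H^\ddagger$) models are out of
scope.

## File-format boundary

Internally everything is kcal/mol and Ångström; files use the MD-engine
conventions (kJ/mol, nm, 1-based atom indices), converting with the factor
4.184 at read/write time (round trips are exact to 12 significant digits).
Energy series are XVG files (`#`/`@` metadata lines, whitespace-separated
rows) with `# lambda` / `# window` comments so synthetic and engine-derived
series are interchangeable.

Per-window topology emission (`write_lambda_topologies()`) follows two
conventions, both stated in the output: interactions present in *both*
states have their parameters interpolated linearly in $\lambda$ (matching
how the engine itself scales individual interaction parameters), while
bonds and soft repulsions present in only *one* state are emitted as
tabulated (type 9) bonds whose tables are pre-scaled by that state's weight
($1-\lambda$ or $\lambda$), so the bonded part of the mapping potential is
realized exactly per window; angles and dihedrals present in one state keep
their geometry with the force constant scaled by the state weight.  The
$\lambda = 0$ and $\lambda = 1$ topologies reproduce the inputs
interaction-for-interaction (asserted by re-parsing).  Only a constrained
dialect is supported — single molecule block, harmonic bonds/angles,
periodic dihedrals, Morse, tabulated bonds, pairs, exclusions, plus a
documented `[ soft_repulsion ]` extension section in state-description
files; anything else (macros, `#include`, virtual sites) is rejected
loudly.  Which per-window construction the original engine tooling uses is
not documented publicly; the convention above is declared, not
reverse-engineered.

## Problem sizes and determinism

The test suite runs the full study-scale check — 51 windows, $10^5$
Metropolis steps per window, 5 replicas — in well under two minutes on one
CPU; unit tests use 5–21 windows and $10^3$–$10^5$ steps.  Every stochastic
component is seeded: window sub-seeds and replica sub-seeds are derived
deterministically (modulo $2^{31}-1$) from one user seed, so whole
pipelines are bit-reproducible.  $k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹
throughout.

## Known limitations

* Two states only; no multi-state Hamiltonians, no analytic forces for real
  force fields, no periodic-boundary electrostatics.
* The toy sampler is configurational Monte Carlo; nothing kinetic can be
  inferred from it.
* No WHAM/MBAR-style global reweighting and no block-averaged error bars:
  replicate SD/SEM is the only error model.
* Calibration of $r$-dependent couplings ($\mu, \eta \neq 0$) is not
  implemented, only their evaluation.
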