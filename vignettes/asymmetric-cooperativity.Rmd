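---
title: "Asymmetric cooperativity and substrate inhibition: models, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric cooperativity and substrate inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymkin)
```

## The problem

Substrate inhibition (SI) — a declining reaction rate beyond an optimal
substrate concentration — is common among enzymes and classically attributed
to a second, inhibitory substrate-binding site. `asymkin` implements an
alternative kinetic model for monomeric bi-substrate enzymes such as the
UDP-glucose-dependent glucosyltransferases: substrates bind in **random
order**, but the two binding orders induce different conformational changes
and carry **unequal homotropic cooperativity**, so only the donor-first
ternary complex is catalytically productive. The inequality of the two Hill
coefficients alone produces SI; no second acceptor site is needed.

The package provides three layers:

1. **Closed-form rate laws** for acceptor and donor titrations, with the
   allosteric-descriptor algebra connecting Hill coefficients to conformer
   population shift.
2. A **mass-action simulator** of the two-branch mechanism, including a
   competitive "placeholder" effector that relieves SI, the donor
   glucohydrolase side activity, product inhibition, and timed
   pre-incubation (hysteresis) protocols.
3. A **matrix-kinetics fitting workflow** (global shared-parameter fits,
   donor-saturation analysis, Hill-coefficient profiling, Lineweaver–Burk
   classification, model selection, bootstrap uncertainty) plus a synthetic
   data generator emulating the 5 × 5 concentration-matrix assay design.

## Rate laws

### Acceptor titration (two Hill coefficients)

At a fixed donor level the acceptor (S) rate law is

$$v(S) = v_{max}\,\frac{(S/K_S)^n}{1 + (S/K_S)^n + (S/K_S)^x},$$

with a single half-saturation constant $K_S$ (µM) shared by the two binding
branches, $n$ the Hill coefficient of the productive (donor-first) order and
$x$ that of the non-productive (acceptor-first) order. Properties that
motivate this form:

* $n = x$ collapses the law to a saturating Hill curve — a hyperbola for
  $n = 1$: identical cooperativity in both branches gives
  Michaelis–Menten-like behaviour.
* $x > n$ gives a single interior maximum at
  $S^\ast = K_S\,(n/(x-n))^{1/x}$ (`optimum_acceptor()`), i.e. SI.
* For $n = 1,\ x = 2$ the law is *algebraically identical* to the classical
  single-site SI law $v = v_{max}S/(K_m + S + S^2/K_i)$ with
  $K_m = K_i = K_S$. This degeneracy matters for model selection (below).

The algebraic form is isolated in `acceptor_rate()`; any alternative
parameterization (e.g. branch-specific half-saturation constants) can be
substituted there without touching callers.

### Donor titration and donor saturation

The donor (U) titration is symmetric between the branches and follows a
plain Hill law $v(U) = v_{max} U^h/(K_U^h + U^h)$; at $h = 1$ it equals
Michaelis–Menten pointwise, which the suite verifies to $10^{-12}$ relative
error. The maximal rates of acceptor titrations at increasing donor levels
follow the hyperbola $v_{max}(U) = v_{max,\infty}\,U/(K_D + U)$, from which
the donor dissociation constant $K_D$ and the SI-free maximal rate
$v_{max,\infty}$ are read off.

### Allosteric descriptors

Assuming activity proportional to the activated-conformer fraction,
$v/v_{max} = \alpha L/(1+\alpha L)$ with $L = [E']/[E]$, comparison with the
Hill equation yields $\alpha L = (S/K_S)^n$ and $\alpha = (S/K_S)^{n-1}$
(`allosteric_descriptor()`). $\alpha = 1$ whenever $n = 1$ (no allosteric
effect) or $S = K_S$; the response is always the Hill binding isotherm.

## The mechanism simulator

Eight enzyme species evolve by mass action: free enzyme E, binary complexes
EA (acceptor-first) and ED (donor-first), ternary complexes Tnp
(non-productive) and Tp (productive), effector complexes EC and EDC, and the
product complex EP. Catalysis (`k_cat`) acts on Tp only; the glucohydrolase
side activity (`k_hyd`) acts on ED (donor bound, acceptor site empty,
transfer to water). Tnp connects to Tp only through a slow conformer
interconversion. The effector occupies the acceptor site of E, still admits
the donor (EC + D → EDC), and is displaced by the acceptor — modelled as
effector dissociation followed by acceptor association rather than a direct
ternary exchange, which has the same steady-state behaviour with fewer
elementary steps.

Design choices:

* **Open vs closed systems.** `steady_state_rate()` clamps free ligands
  (the initial-rate regime of 10–30 min assays, where substrate depletion is
  negligible); `simulate_progress()` can deplete them (`clamp` flags) for
  progress curves and conservation checks.
* **Steady-state detection.** The clamped enzyme subsystem is linear, so the
  trajectory converges to a unique fixed point; integration proceeds in
  doubling time chunks (stiff `lsoda`, default `rtol` $10^{-8}$) until the
  relative state change falls below $10^{-10}$ per minute.
* **Conservation.** Total enzyme is checked to $10^{-6} E_{tot}$ at every
  reported time; concentrations below $-10^{-9}$ µM abort, smaller negative
  round-off is clipped to zero for reporting.
* **The rapid-equilibrium oracle.** `rapid_equilibrium_rate()` solves the
  equilibrium partition of the binding network exactly and treats catalysis,
  hydrolysis *and* the slow interconversion as perturbations. Without the
  Tnp↔Tp edge the binding graph is almost a tree; the one cycle
  (E–EC–EDC–ED) must be thermodynamically consistent
  ($K_{EC} K_{EDC,D} = K_{ED} K_{EDC,C}$), and inconsistent parameter sets
  are rejected as singular. The suite verifies ODE/oracle agreement within
  1% when binding outpaces catalysis $10^4$-fold.

### The reference "trap" parameterization

No rate constants for this enzyme are published, so
`reference_mechanism()` ships a documented **fixture**: affinities in the
tens of µM, a tight dead-end ternary complex (2 µM), slow interconversion
(0.5 / 0.05 min⁻¹), `k_cat` = 200 min⁻¹, `k_hyd` = 5 min⁻¹, and a
fast-exchanging placeholder effector. It was chosen by forward simulation so
the phenomenology lands in the experimentally reported concentration
regimes: the acceptor optimum near 14 µM (donor 100 µM), pronounced
inhibition above it, effector reactivation of about 1.7-fold at five times
the optimal acceptor concentration with a dose–response maximum near
100 µM, monotone suppression of the hydrolase activity, and
pre-incubation-order-dependent initial rates that vanish when the
interconversion is made fast. It is a modelling fixture for tests and
demonstrations, not an estimate of the real enzyme's constants.

Two mechanistic points the simulator makes precise:

* **SI requires the acceptor-first branch.** Setting the acceptor's
  association to free enzyme to zero (an ordered mechanism) makes the rate
  monotone in acceptor concentration.
* **A competitive placeholder can relieve SI without violating detailed
  balance.** With a thermodynamically consistent cycle the effector cannot
  shift the E ⇌ ED equilibrium; it acts as a *kinetic catalyst* of donor
  loading, channelling free enzyme past the acceptor trap. Relief is
  therefore a steady-state (catalysis-driven) phenomenon — exactly why a
  purely equilibrium intuition would miss it.

## Fitting workflow

* **Loss.** Weighted least squares on rates. Default weights are
  1/variance from replicates when every concentration cell has ≥ 3
  replicates with positive spread, else unit weights (the assay papers do
  not state a regression scheme). Replicates enter as individual points, not
  means.
* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nls.lm`) in log10
  parameter space with box bounds — $v_{max} \in (0, 10^6]$,
  $K \in [10^{-3}, 10^5]$ µM, Hill coefficients $\in [0.1, 6]$ — from a
  data-driven start plus seeded log-uniform multi-starts (8 by default);
  convergence tolerances $10^{-10}$, at most $10^4$ residual evaluations per
  start. All fits are deterministic given (data, options, seed).
* **Global matrix fit.** Default mode shares $K_S, n, x$ across donor
  levels with a free $v_{max}$ per level (the matrix analyses find the
  acceptor parameters independent of donor); per-curve mode fits each level
  separately and reports the cross-level agreement (range and CV) of the
  shared parameters, covering both readings of a reported parameter range.
  The fit degrades gracefully below three donor levels: it proceeds with a
  flag and the donor-saturation stage records its failure reason, so partial
  analyses keep their completed stages.
* **Hill-coefficient profile.** `h(S)` is estimated by donor fits per
  acceptor level; the unit crossing is located by interpolating linearly in
  $(\log S, h)$ — concentrations span decades, so log spacing is the natural
  metric. An exact grid hit is returned as-is.
* **Lineweaver–Burk.** Straight lines in $(1/U, 1/v)$ per acceptor level;
  a common y-intercept (within 5% relative spread, a tolerance the source
  experiments do not specify) is competitive, a common x-intercept
  non-competitive, parallel slopes uncompetitive, otherwise mixed.
* **Model selection.** AICc with $k$ = free parameters + 1; models within
  ΔAICc < 2 are ties resolved toward fewer parameters. A relative floor of
  $10^{-10}$ (on the RMS rate scale) keeps noise-free interpolating fits
  comparable, so exact ties resolve by parsimony rather than floating-point
  noise. Because eq. 2 with $n=1, x=2$ *is* the classical SI law, the
  parsimonious selection for such data is the 3-parameter classical model;
  the asymmetric law wins only on data outside the classical family (e.g.
  $x = 3$), which the suite verifies at a ≥ 90/100 selection rate.
* **Bootstrap.** Residual resampling with percentile intervals; refits
  start from the base estimate (single start), the standard practice that
  keeps $B$ refits affordable. Coverage of the 95% intervals is checked at
  120 synthetic datasets × 99 resamples, the study size chosen for the
  default test run.

## Synthetic data

The generator emulates the matrix design: acceptor and donor grids of
{5, 10, 25, 50, 100} µM, five technical replicates, multiplicative normal
noise with cv = 8% truncated at zero — a visual match to the replicate SD
bars of the source assays; replicate error structure beyond a single i.i.d.
term (plate effects, systematic enzyme-preparation variability) is not
modelled. The default generating truth ($K_S = 20$ µM, $n = 1$, $x = 2$,
$v_{max,\infty} = 1157$ nmol/min/mg, $K_D = 19$ µM) takes the magnitudes of
the reported fits and is used for demonstrations and recovery tests only —
it is not a re-derivation of the assay data. Every dataset carries its
generating parameters and seed as a `truth` attribute, and generation never
touches the caller's RNG stream.

One structural caveat: the separable truth (acceptor law × donor
hyperbola) makes every donor titration exactly hyperbolic, so synthetic
$h(S)$ profiles sit at 1 with noise and the unit-h crossing is only
informative on data with real heterotropic coupling (as in the mechanism
simulator or real assays). Passing recovery tests therefore demonstrate the
pipeline's correctness on the stated generating process, not that real data
satisfy the sharing assumption.

## Numerical edge cases

* Zero substrate always returns rate 0 (including the $0^0$ guard for
  sub-unity Hill coefficients at $S = 0$).
* An unbounded $K_i$ is an explicit `Inf` marker for "no inhibition", not a
  large magic number.
* Degenerate inputs fail loudly: all-zero rates, rates constant across the
  titration ("unidentifiable"), fewer distinct concentrations than the model
  supports ("insufficient support"), < 3 points for the hyperbola; a fitted
  $K_D$ above the measured range or at the lower box bound is flagged
  rather than silently reported.
* Zero rates are rejected on reciprocal (Lineweaver–Burk) axes.

## Problem sizes of the shipped studies

The default test run uses 100 seeded repetitions for the matrix-recovery
and model-selection studies, 20 random parameterizations for the
ODE-vs-oracle comparison, 50 draws for the monotonicity properties, and
120 × 99 for bootstrap coverage; the acceptance script repeats the full
matrix pipeline 25 times. These sizes are the package's chosen
simulation-study design and are stated here so they can be scaled up for
more precise characterization.

## Limitations

* The mechanism's rate constants are a fixture; fitting them to data is out
  of scope (identifiability has not been established).
* No Bayesian inference, no stochastic (Gillespie) simulation, no
  luminescence-level modelling of the UDP-release readout.
* Xanthophyll-type pure inhibitors are representable as effectors with the
  donor-admission edge disabled, but this is a configuration option, not a
  mechanistic claim.
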