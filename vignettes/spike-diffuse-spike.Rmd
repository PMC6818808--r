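---
title: "The spike-diffuse-spike model of saltatory conduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spike-diffuse-spike model of saltatory conduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdspike)
```

## The model

A myelinated axon is treated as an infinite passive cable (the internodes)
studded with periodically spaced active point sites (the nodes of Ranvier).
Below threshold the membrane potential $V(x,t)$ obeys the cable equation

$$\tau \frac{\partial V}{\partial t} =
  \lambda^2 \frac{\partial^2 V}{\partial x^2} - V + R_m I_{chan}(t),$$

with time constant $\tau = C_m R_m$ and length constant
$\lambda = \sqrt{R_m/R_c}$ set by the myelin sheath.  When a node reaches
the firing threshold $V_{thr}$ it releases a *prescribed* channel current —
the spike-diffuse-spike simplification that replaces voltage-gated
Hodgkin–Huxley dynamics and makes the model analytically tractable.  Four
current shapes are supported: an instantaneous impulse (scenario A), a
delayed impulse (B), an exponential with instantaneous onset (C), and a
gated profile $(1-e^{-t/\tau_m})^\gamma e^{-t/\tau_h}$ that mimics measured
sodium currents (D, the default, with $\gamma = 1$).  A gated potassium
current of opposite sign ($(1-e^{-t/\tau_n})^4 e^{-t/\tau_k}$, peak density
7.5% of sodium, from the ratio of the maximal conductances 0.09/1.2 S/cm²)
can be added for action-potential shapes; it is excluded from velocity
computations, where only the depolarising sodium current matters.

Only the fraction
$\beta = 1/(1 + R_\lambda/2R_{node})$ of the nodal current enters the
axial cable; the rest leaks back across the nodal membrane
($R_\lambda = R_m/\lambda$, $R_{node} = R_n/\pi d l$).  A short node leaks
little ($\beta \to 1$ as $l \to 0$); a long one leaks almost everything.

The response of the cable to a single node is the convolution of the
entering current with the Green's function

$$G(x,t) = \frac{1}{\sqrt{4\pi\lambda^2\tau t}}
  \exp\!\Big({-\frac{x^2\tau}{4\lambda^2 t} - \frac{t}{\tau}}\Big),$$

which has closed forms for all four scenarios.  Superposing the responses
of all nodes (each firing $t_{sp}$ after its neighbour) and requiring the
reference node to sit exactly at threshold yields one implicit equation for
the internodal time-to-spike $t_{sp}$,

$$V_{thr} = \sum_{n=1}^{N} U\big(n(L + l\lambda/\lambda_n),\, n\,t_{sp}\big),$$

from which the conduction velocity follows as $v = (L+l)/t_{sp}$, corrected
for the finite transit speed $v_n$ within nodes via
$v = (L+l)/(L/v + l/v_n)$.

## Parameters

Two parameter columns are packaged (`parameter_set("standard")` and
`"fitted"`).  The standard column derives everything from first-principles
constants: $k_1 = 3.6$ pF/cm and $k_2 = 130\ \mathrm{M\Omega\,cm}$ for the
myelin capacitance and resistance (so $\tau = k_1 k_2 = 0.468$ ms
independent of geometry, and
$\lambda = 963.5\, d\sqrt{\ln(1/g)}$ µm per µm of diameter), axoplasm
resistivity 110 Ω cm, nodal membrane constants
$R_n = 33\ \Omega\,\mathrm{cm}^2$, $C_n = 1$ µF/cm²
($\tau_n = 33$ µs), peak current densities $i_{Na} = 50$,
$i_K = 3.75$ pA/µm², gating constants $\tau_m = 20$ µs, $\tau_h = 40$ µs,
threshold 15 mV, geometry $d = 1$ µm, $g = 0.6$, $L = 100d$, $l = 1$ µm.
The fitted column (calibrated against a biophysically detailed cortex
model) overrides $\tau = 1.45$ ms, $\lambda = 1200\,d\sqrt{\ln(1/g)}$,
$\lambda_n = 48.1\sqrt{d}$ µm, $\tau_n = 20$ µs, $\tau_m = 70$ µs,
$\tau_h = 160$ µs, $I_0 = 200$ pA/µm², $V_{thr} = 4$ mV, $d = 0.73$ µm,
$g = 0.81$.

All computation uses one internal unit system (µm, ms, mV, nA, MΩ, nF), in
which Ohm's law and $\tau = RC$ close without numerical factors; published
units are converted once at construction (`sds_units()`), and the
conversion factors are unit-tested.

Three conventions deserve explicit statement, because the model definition
leaves them open:

* **Impulse charge (scenarios A/B).**  A delta-shaped current needs a
  charge, not a density.  Dimensional analysis of the impulse-response
  prefactor fixes $Q = I_0 \cdot \pi d l \cdot \tau$; with the
  calibration $I_0 = 6.6$ pA/µm² this reproduces an action-potential
  amplitude of about 100 mV, which is the calibration the value was chosen
  to satisfy.
* **Nodal electrotonic penalty.**  A node of length $l$ adds electrotonic
  distance $l/\lambda_n$ (in units of its own, much shorter, length
  constant).  Expressed on the internodal cable this becomes a physical
  equivalent of $l\,\lambda/\lambda_n$, i.e. roughly $17.7\,l$ at standard
  parameters — nodes are electrically expensive.  The package uses the
  tabulated $\lambda_n = 38.9\sqrt{d/\mathrm{µm}}$ µm by default; the
  first-principles alternative $\sqrt{R_n d/4\rho_{ax}} \approx
  27.4\sqrt{d}$ µm is available via
  `derive_node_parameters(..., lam_node_method = "derived")`.
* **Within-node velocity.**  The node correction needs the conduction
  velocity inside a node, estimated as the velocity of an unmyelinated
  axon with nodal membrane properties at full channel density.  That
  estimate always uses the *gated sodium current*: the set's own $I_0$
  when the driving scenario is C or D (for the fitted column $I_0$ is
  itself a fitted current), and the constant $i_{Na}$ for the impulse
  scenarios A/B, whose $I_0$ is an impulse calibration rather than a
  sustained density.  It is computed once per $(d, l)$ and cached.

`parameter_set()` also fills scenario defaults: the scenario-B delay is
30 µs, and the scenario-C decay constant is *charge-matched* to the gated
sodium current at equal peak density
($\tau_c = \sum_s A_s\tau_s / C_{Na} \approx 69$ µs for standard
constants).  With an arbitrary shorter $\tau_c$ the exponential scenario
would carry less charge than the gated one and propagate more slowly,
inverting the natural ordering (instantaneous release fastest, gated rise
slowest) that the charge-matched default preserves.

## Numerical methods

**Stable complex error functions.**  The exponential-current responses
formally contain $\Im[e^{i\theta}(\mathrm{erf}(z)-1)]$ with exponentially
growing and decaying factors.  Everything is rewritten in terms of the
Faddeeva function $w(z) = e^{-z^2}\mathrm{erfc}(-iz)$, evaluated only in
the upper half-plane where $|w| \le 1$ (Weideman's 64-term rational
approximation for $|z| \le 7$, a Laplace continued fraction beyond, and
the reflection $w(-z) = 2e^{-z^2} - w(z)$), with all exponents combined
analytically before a single `exp`.  No intermediate can overflow; the
implementation agrees with a 50-digit arbitrary-precision oracle to better
than $10^{-12}$ relative error on the frozen test grids, and the composed
responses match direct adaptive quadrature of the convolution integral to
$10^{-8}$ — the master test of the module.

**Branches.**  For a current time constant $\tau_s < \tau$ the closed form
uses one Faddeeva term (the oscillatory phase cancels identically against
the cross term of $z^2$, so only real exponents remain); for
$\tau_s > \tau$ two real scaled-erfc terms
$e^{\mp 2\sqrt{ap}}\,\mathrm{erfc}(\sqrt{a/t} \mp \sqrt{pt})$ are used,
each folded with its Gaussian; the removable degeneracy $\tau_s = \tau$
(detected at $|1/\tau - 1/\tau_s| < 10^{-12}$ ms⁻¹) has an analytic limit
$2\sqrt{t}e^{-a/t} - 2\sqrt{\pi a}\,\mathrm{erfc}(\sqrt{a/t})$, all times
$e^{-t/\tau}$.

**Root finding.**  The threshold condition is solved for its smallest
positive root by a geometric bracketing scan over
$t_{sp} \in [10^{-6}, 10]$ ms followed by Newton iteration with a central
finite-difference derivative (step $\max(10^{-6}t, 10^{-9}\ \mathrm{ms})$),
safeguarded by bisection whenever a step leaves the bracket — scenario B's
causal cutoffs make the residual only piecewise smooth.  Convergence is
declared at $|$residual$| \le 10^{-9}$ mV.  A threshold that is never
reached returns an explicit propagation-failure result rather than an
error: conduction block is a physical outcome (it is how low-density
unmyelinated axons behave at the standard threshold).

**Trace resolution.**  The impulse scenarios have an integrable
$1/\sqrt{t}$ singularity at the firing instant of the local node, so "peak
amplitude" is only defined relative to a sampling resolution.  Voltage
traces default to 1 µs steps — physiological recording resolution, and
twenty times finer than the fastest gating constant — and peak amplitudes
are reported on that grid.

**Sums over nodes.**  The nodal sum is truncated at $N = 1000$ by default;
at standard parameters $N = 20$ already changes $t_{sp}$ by less than
0.5%, but short internodes genuinely need large $N$ (with $N = 10$ the
velocity at $L = 27$ µm, $l = 3.5$ µm drops measurably).  Nodes whose
spatial attenuation exceeds the double-precision floor are skipped.

## Unmyelinated axons

An unmyelinated axon is the $L = 0$ limit: firing sites spaced `l_disc`
apart on a cable with nodal membrane constants.  A relative channel
density $\rho$ scales the membrane conductance, hence
$\tilde\tau = \tau_n/\rho$, $\tilde\lambda = \lambda_n/\sqrt{\rho}$, and
the site current scales with $\rho$.  The resulting depolarisation scales
as $\sqrt{\rho}$, so at the standard 15 mV threshold densities of 10% or
less block conduction in physiological diameters — the limiting case of
the slowing that reduced density causes.  `l_disc` is a discretisation
choice, not a physical parameter; the solver re-solves at `l_disc/2` and
flags the result if the velocity moves by more than 2%.  Velocities follow
the classical square-root diameter law ($v(4d)/v(d) \approx 2$).

## Ephaptic coupling

Two axons sharing a restricted extracellular space couple through the
extracellular potential.  For the axial-current-conservation closure the
coupled pair diagonalises into two independent cable modes
$\tilde P_{1,2} = P_1 + c_{1,2} P_2$ with effective length constants
$\tilde\lambda_{1,2}$; for identical axons $c_{1,2} = \pm 1$ and, with a
fully restricted extracellular space, the common mode runs on a
$\sqrt{2}\lambda$ cable while the difference mode keeps the uncoupled
$\lambda$.  The implementation follows these closed-form decoupling formulas and is
verified end-to-end against a direct finite-difference solve of the
coupled PDE system.

One sign question deserves honesty.  Deriving the coupling term directly
from the conservation constraint yields the *opposite* sign, under which a
fully restricted extracellular space forbids common-mode propagation
entirely (the net axial current of a synchronous pair must vanish).  The
published formulas correspond to the $+$ sign and give finite, well-behaved
dynamics, so they are what the package implements.  Within that system the
pointwise pair response at internodal distances is weaker than the
single-axon response (the ordering seen when comparing depolarisation
curves at a node, reproduced by the PDE cross-check), offset action potentials
re-synchronise (an initial offset of 20 µs contracts in one internode),
and a passive neighbour is perturbed biphasically by a passing action
potential.  However, the full multi-node threshold solve makes the
synchronous pair cross threshold slightly *earlier* than a single action
potential — distant nodes reach further on the $\sqrt{2}\lambda$ mode —
so the pair's velocity ordering is opposite to what the curve comparison
suggests; and the biphasic passive perturbation runs
depolarisation-first.  Both behaviours are consequences of the published
equations, not numerical artefacts, and the corresponding acceptance
properties are left failing with this analysis rather than being adjusted.

Entrainment steps solve the two axons' threshold-crossing times at the
next node from the coupled potentials given the firing history (steady
near-synchronous propagation at the synchronous-pair $t_{sp}$, offset
`dt_in`), each by the same safeguarded bracketing solver.

## Linearised time-to-spike

The rising phase of the single-node depolarisation is nearly linear around
its inflection point $t_i$, giving the explicit estimate
$t_{sp} \approx t_i + (V_{thr} - V(t_i))/\dot V(t_i)$.  Closed forms for
$t_i$ are implemented per scenario: the quadratic root of the truncated
second-derivative condition for impulses (with small-distance limit
$\zeta x^2\tau/\lambda^2$, $\zeta = (1-\sqrt{2/3})/2 \approx 0.0918$),
branch-dependent roots for exponential currents, and the additive
approximation $t_i = \sqrt{2}x\tau/4\lambda + t_{i,chan}$ for gated
currents, where the channel inflection solves a quadratic in
$q/(1-q)$, $q = e^{-t/\tau_m}$ (for $\gamma = 1$,
$t_{i,chan} = 2\tau_m\ln(1+\tau_h/\tau_m)$; this closed form was
re-derived from $\ddot f = 0$ and verified against numerical second
derivatives).  The closed-form slope relation for impulses is
$\dot V(t_i) = \tfrac{2}{\sqrt 6}\,\lambda^2/(4\zeta^2x^2\tau)\,V(t_i)$ —
note the coefficient $2/\sqrt6 = 1-2\zeta$, verified numerically.  The
linearisation is a single-node analysis: it tracks the $N = 1$ Newton
solution to within roughly 15–20% at internodal distances and standard
parameters, degrades as $V_{thr}$ leaves the neighbourhood of $V(t_i)$
(results extrapolating to non-positive times are flagged unreachable), and
is never used as the production solver.

## What the tests do and do not show

The test suite validates the closed forms against independent quadrature,
arbitrary-precision special functions, finite-difference PDE solves, and
brute-force maximisation — i.e. the mathematics of the model, plus the
published quantitative anchors (0.47 ms time constant, 33 µs nodal
constant, ~6 m/s scenario-B velocity, ~100 mV amplitude, g-ratio exponent
0.68, linear and square-root diameter laws).  Problem sizes in the tests
are chosen for speed (grids of 4×4 geometry points, $N$ of a few hundred
for coupled solves) after checking that results are insensitive to them.
The model itself idealises: currents are voltage-independent and
identically shaped at every node, internodes are strictly periodic,
temperature and channel kinetics heterogeneity are absent, and ephaptic
coupling is distance-independent within the bundle.  Agreement with the
packaged anchors therefore demonstrates correctness of the implementation,
not biological completeness.

## Known limitations

* Aperiodic or heterogeneous axons (varying $d$, $g$, demyelinated
  segments) require per-node threshold times and are out of scope.
* The ephaptic sign issue above: the closed-form decoupling and the
  conservation constraint disagree; the package follows the decoupling.
* The velocity surface over node/internode length is more sensitive than
  its reputation for flatness (the minimum on the
  $l \in [0.5, 3.5]$ µm $\times$ $L \in [27, 152]$ µm grid is ~47% of the
  maximum, not $\ge$70%), plausibly because the large electrotonic node
  penalty $\lambda/\lambda_n \approx 17.7$ amplifies corner effects.
* Scenario C's decay constant and the impulse-charge convention are
  package choices (documented above), constrained but not uniquely fixed
  by the model definition.
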