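---
title: "Travelling waves under forward-backward nonlinear diffusion: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Travelling waves under forward-backward nonlinear diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbwave)
```

# The model

`fbwave` analyses the one-dimensional reaction-diffusion equation

$$U_t = \big(D(U)\,U_x\big)_x + R(U),$$

with the two-rate diffusivity
$D(U) = D_i(1-4U+3U^2) + D_g(4U-3U^2)$
and logistic kinetics $R(U) = \lambda U(1-U)$.  This pair arises as the
mean-field continuum limit of a lattice exclusion process in which agents
with both nearest neighbours vacant ("isolated") move, proliferate and die
with different probabilities than agents with an occupied neighbour
("grouped").  The limit identifies $D_{i,g} = P^{i,g}_m\Delta^2/(2\tau)$,
$\lambda_{i,g} = P^{i,g}_p/\tau$ and $K_{i,g} = P^{i,g}_d/\tau$; the package's
`lattice_from_continuum()` / `continuum_parameters()` implement this map
exactly at finite $\Delta, \tau$.

When $D_i > 4D_g$ the quadratic $D$ is convex and has two roots
$\alpha, \beta$ with $1/3 < \alpha < 2/3 < \beta < 1$: the equation is
backward-parabolic for densities in $(\alpha, \beta)$.  The benchmark
parameter set used throughout the package is $D_i = 0.25$, $D_g = 0.05$,
$\lambda = 0.75$, giving $\alpha = 0.5$, $\beta = 5/6$ and the minimum wave
speed $c^* = 2\sqrt{\lambda D_i} \approx 0.8660$.  A second, general
polynomial diffusivity $\hat D(U) = (U-0.1)(U-0.3)$ (same kinetics)
illustrates the case where the node conditions at the origin and at $\beta$
reverse order, so only shock-fronted waves exist in a window of speeds.

## Assumptions

* Monostable ("Fisher-KPP imprint") kinetics: $R > 0$ on $(0,1)$, $R'(0) > 0 > R'(1)$.
* $D > 0$ at both rest states $U = 0, 1$, so the far fields are forward-parabolic.
* At most two sign changes of $D$ on $[0, 1]$; evaluation outside $[0,1]$ is
  permitted (solvers overshoot) but no sign claims are made there.
* No explicit regularisation of the backward interval: the spatial grid is
  the regularisation, so `dx` is a physical-fidelity parameter and is
  recorded with every simulation result.

# Phase-plane construction of the wave

In the wave variable $z = x - ct$ with $p = D(u)\,du/dz$, travelling waves
solve the planar system $D(u) u' = p$, $D(u) p' = -cp - D(u)R(u)$, which is
singular on the walls $u = \alpha, \beta$.  The stretched variable $\xi$
with $D(u)\,d\xi = dz$ removes the walls at the price of reversing the
orientation where $D < 0$.  The desingularised system has equilibria
$(0,0)$, $(\alpha,0)$, $(\beta,0)$, $(1,0)$; with
$F(u) = (DR)'(u)$ the Jacobian eigenvalues are
$\lambda_\pm = (-c \pm \sqrt{c^2 - 4F})/2$: $(1,0)$ and $(\alpha,0)$ are
saddles; $(0,0)$ is a stable node iff $c \ge c^*$; $(\beta,0)$ is a stable
node iff $c \ge 2\sqrt{D'(\beta)R(\beta)}$ (a threshold that always lies
below $c^*$ for the two-rate family).  The wave is the concatenation of the
three heteroclinics $(1,0)\to(\beta,0)$, $(\alpha,0)\to(\beta,0)$ (traversed
backwards in $z$) and $(\alpha,0)\to(0,0)$, passing through the two holes in
the wall.

## Numerical choices

* **Shooting.**  Orbits start `eps = 1e-7` along the unit unstable
  eigenvector of a saddle and are integrated with `deSolve::lsodar`
  (`rtol = 1e-10`, `atol = 1e-12`), sampling every `dxi = 0.05`.  Integration
  stops by root-finding when the state enters a ball of radius `1e-8` around
  a node target (the approach is exponential, so this terminates) or `1e-6`
  around a spiral target (the orbit winds, so a tighter ball would waste
  effort), or when $u$ leaves $[-0.1, 1.1]$ (failure).  The $\xi$ budget is
  5000, generous because the slow stable eigenvalue at $(\beta, 0)$ is only
  about $-0.024$ at $c^*$.
* **Back to $z$.**  Along each orbit $z = \int D(u)\,d\xi$ by cumulative
  trapezoid over the orbit's own samples; this is equivalent to the
  $dz/du = D/p$ quadrature but needs no special treatment at turning points.
  The truncation gaps at the holes are bridged with the exact limiting slope
  there: along the eigendirection with eigenvalue $\lambda$,
  $du/dz = p/D \to \lambda / D'(u_{hole})$ (both numerator and denominator
  vanish linearly).  The middle segment is reversed by flipping sample
  order, never re-integrated: the two systems share trajectories as point
  sets.
* **Anchor.**  The assembled profile is translated so $u(0)$ equals
  $\alpha/2$ (or $1/2$ when $\alpha > 1/2$), a point always interior to the
  lower segment; the wave is translation-invariant so this is cosmetic but
  makes profiles comparable.
* **Validation.**  Passage through the holes is not proven here (that is the
  realm of canard theory); instead the assembled profile is validated a
  posteriori: the residual of
  $\tfrac{d}{dz}(D(u)u') + cu' + R(u)$ under centred differencing is below
  $10^{-4}$ away from the holes (measured: about $10^{-7}$), the profile is
  invariant to halving all integrator tolerances to within $10^{-5}$
  sup-norm, and it matches the late-time PDE front after optimal
  translation to within $2\times 10^{-2}$ (measured: about
  $1.4\times 10^{-3}$).
* **Vertical tangents.**  The Sturm-type point-spectrum count uses the
  number of interior crossings of $p$ through zero along an orbit;
  equilibrium-adjacent samples are trimmed (the holes are endpoints, not
  tangencies).  For the assembled monotone wave the count is zero; the
  spiral tail at $0.289 < c < 0.866$ gives at least one.

For speeds between $2\sqrt{D'(\beta)R(\beta)} \approx 0.289$ and $c^*$ the
construction still succeeds but the tail spirals: $u$ oscillates below zero
(minimum about $-0.02$ at $c = 0.4$), reproducing the biologically
irrelevant non-monotone waves.

# The PDE solver and the measured front speed

Both schemes discretise the conservative flux form with interface
diffusivities $(D(u_j) + D(u_{j+1}))/2$ and zero boundary fluxes, so mass is
conserved to rounding when $R = 0$.  Evaluating $D$ at the interface
*density* $(u_j + u_{j+1})/2$ instead looks natural but is degenerate here:
for the benchmark parameters the midpoint density of a sharp Heaviside step
is exactly $\alpha = 0.5$, every interface flux vanishes, and the step never
moves.  The node-averaged interface diffusivity has no such fixed point.

The default time stepping is backward Euler with the interface diffusivity
lagged one step and two Picard iterations on the reaction term, solved by
direct tridiagonal elimination (compiled).  It is unconditionally stable for
the forward-diffusion part, which matters for diffusivities like
$\hat D$ whose maximum on $[0,1]$ (0.63) would force a smaller explicit
step.  The explicit forward-Euler variant is kept for cross-checks and
enforces the diffusion-number budget $\max|D|\,\delta t/\delta x^2 \le 0.45$,
reducing $\delta t$ automatically (to 0.007 for $\hat D$ at
$\delta x = 0.1$) when violated.

With $\delta x = 0.1$, $\delta t = 0.01$, a Heaviside step at $x = 40$ on
$[0, 100]$ and the leading edge defined as the left-most point with
$U < 10^{-5}$, the least-squares slope of $L(t)$ over $t \in [30, 60]$ is
0.8638 for the implicit scheme (0.8512 for the explicit one).  Two effects
separate these numbers from $c^* = 0.8660$:

* the *discrete* linear-spreading speed of each scheme differs from $c^*$
  (about $+0.009$ for backward Euler and $-0.005$ for forward Euler at this
  resolution), and
* a pulled front relaxes to its asymptotic speed only algebraically, with a
  logarithmic-in-time shift of the front position; over a fixed window
  $[30, 60]$ this depresses the fitted slope by roughly $0.013$
  *independently of resolution*.

Consequently the windowed measurement converges, under joint refinement of
$\delta x$ and $\delta t$, to about $0.853$ — not to $c^*$ — and only later
windows approach $0.866$ (the implicit scheme gives $0.8661$ over
$[50, 100]$).  The refined-grid check in the test suite therefore asserts
agreement with $c^*$ within 1% ($0.8599$ at $(\delta x, \delta t)/2$, an
error of 0.7%) and refinement consistency within 0.5%, rather than monotone
approach to $0.866$ inside the fixed window, which the transient makes
impossible.  Problem sizes: 1001 nodes and 6000 steps at the benchmark
resolution, 2001 nodes and 12000 steps refined.

For $\hat D(U) = (U-0.1)(U-0.3)$ the same protocol run to $t = 50$ gives a
front speed of exactly $0.300$ (the node threshold $2\sqrt{\hat D(0)R'(0)}$)
and a persistent interior gradient about 13 times steeper than the smooth
benchmark wave — the shock-fronted regime.  No shock construction is
attempted in the phase plane (the equal-area/regularisation-limit rule is
not part of this package's scope); the simulation is the evidence.

# Spectral stability

Linearising about the wave and writing the eigenvalue problem as a first
order system in $(q, s)$ with $s = \tfrac{d}{dz}(D(\hat u)q)$, the essential
and absolute spectra are fixed by the far-field constant-coefficient
matrices at $U = 0$ and $U = 1$, where $D > 0$.  Everything needed is closed
form: spatial eigenvalues
$\mu^\pm = (-c \pm \sqrt{c^2 + 4D(\Lambda - R')})/2$ (principal branch),
dispersion parabolas $\Lambda = -Dk^2 + ick + R'$, and the rightmost points
of the absolute spectrum $K_+ = -c^2/(4D(0)) + \lambda$ and
$K_- = -c^2/(4D(1)) - \lambda$.  $K_-$ is always negative; $K_+$ crosses
zero exactly at $c = c^*$, so waves with $c < c^*$ are absolutely unstable
(no exponential weight can help) while for $c \ge c^*$ the weights
$\nu$ with $D(0)\nu^2 - c\nu + \lambda < 0$ shift the essential spectrum
into the closed left half plane.  The admissible interval is computed from
this quadratic directly — its roots are
$(c \pm \sqrt{c^2 - (c^*)^2})/(2D(0))$ — and the ideal weight
$\nu = c/(2D(0))$ attains $K_+^\nu = K_+$.  Verdicts at the boundary use a
relative tolerance of $10^{-12}$ on $K_+$ so that $c$ computed as
$2\sqrt{\lambda D_i}$ lands on the stabilisable side despite rounding; note
that the literal value $c = 0.866$ is *below* $c^*$ by $2.5\times10^{-5}$
and is treated as the rounding of $c^*$, not as a distinct speed.

Along the wave itself the package evaluates the variable-coefficient matrix
$A(\xi; \Lambda)$ with $\mathcal B = D'(\hat u)\,d\hat u/dz$ taken from the
orbit's $p$-component ($d\hat u/dz = p/D$, finite at the holes via the
limiting slopes above), and the winding rate of the $(q,s)$ line used in the
Sturm count; at a vertical crossing ($q = 0$) that rate is $+1$ for every
$\Lambda$, computed here as $(s\,q' - q\,s')/(q^2+s^2)$, the sign convention
that makes the crossing rate positive.  Full Evans-function root finding
over $\Lambda$ is out of scope; only the vertical-tangent counting argument
is implemented.

# The lattice generator: what it emulates, and what it does not

`meanfield_simulate()` iterates the discrete conservation statement for the
expected site occupancy: isolated-agent motility and proliferation terms
carry next-nearest-neighbour vacancy factors, grouped-agent terms are
total-minus-isolated corrections, and deaths split the same way.  Two
independent transcriptions are shipped deliberately — `meanfield_delta()`
follows the published bracket structure term by term, while the internal
stepper uses an edge-flux (pairwise transfer) form that telescopes exactly —
and a test pins them to each other at $10^{-14}$, guarding against
transcription slips in the nine-bracket expression.  Boundaries are
reflecting ghost sites copying the boundary value, consistent with the
PDE's no-flux condition.  Occupancies leaving $[0,1]$ raise an error rather
than being clamped: that is a symptom of inadmissible parameters.

`stochastic_simulate()` realises the process itself: per time step the
current agents are visited in uniformly shuffled order; each is classified
isolated/grouped *at its action time*, then attempts a move, a daughter
deposition, and death with its type's probabilities, all aborted on
exclusion conflicts.  The compiled core uses R's RNG, so runs are
bit-reproducible under `set.seed()`.  Validation: with all probabilities
zero the lattice is fixed; motility alone conserves agent number exactly; a
full lattice admits no births; a single agent's mean-square displacement
matches $2D_i t$; and for *equal* rates (pure symmetric exclusion) the
replicate-averaged density matches the mean-field recurrence within
Monte-Carlo error, an exactness property special to that limit.

Two honest discrepancies between the generator and the continuum model are
documented rather than hidden:

* **Pointwise convergence under refinement** of the mean-field recurrence to
  the PDE solver holds for positive-definite diffusivities (sup error
  0.019 at $\Delta = 0.2$, 0.010 at $\Delta = 0.1$ in the shipped test) but
  *not* on the sign-changing benchmark: on the backward interval every
  discretisation is its own grid-scale regularisation, and two different
  ones need not agree pointwise near the front.  Front *speeds* still agree
  within 2%.
* **The stochastic front is much slower than the mean-field front.**  At the
  benchmark mapping ($\Delta = 0.1$, $\tau = 0.01$, so $P^i_m = 0.5$,
  $P^g_m = 0.1$, $P_p = 0.0075$) the realised front advances at about
  $0.29$, a third of the PDE's $0.864$; even the equal-rate control gives
  about $0.62$.  The mean-field closure factorises neighbour occupancies,
  but one-dimensional nearest-neighbour birth creates parent-daughter pairs
  — instantly reclassified as slow grouped agents — exactly at the invasion
  tip, and per-site exclusion caps the tip occupancy at one agent, the
  growth-cutoff effect known to slow pulled fronts severely.  Passing tests
  on the mean-field recurrence therefore say nothing about stochastic front
  speeds, and the one acceptance check that equates them fails by design
  rather than being weakened.  A quantitative treatment of these pair
  correlations is beyond the package's scope.

# Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `eps` | `shoot_manifold()` | 1e-7 | saddle offset; small enough that the linearisation error is negligible, large enough to clear the equilibrium ball |
| `tol_eq`, `tol_spiral` | `shoot_manifold()` | 1e-8, 1e-6 | termination balls at node/spiral targets |
| `dxi` | `shoot_manifold()` | 0.05 | orbit sampling; halved in the invariance test |
| `dx`, `dt` | `pde_simulate()` | 0.1, 0.01 | benchmark resolution; `dx` doubles as the backward-diffusion regularisation scale |
| `threshold` | `front_position()` | 1e-5 | leading-edge detection level |
| fit window | `estimate_speed()` | last 50% | late-time linear regime; boundary contamination within 5`dx` raises an error |
| `delta`, `tau` | `lattice_params()` | 0.1, 0.01 | lattice scales; the continuum map is exact at any fixed pair |

# Known limitations

* No canard-theoretic justification of hole passage; validation is by ODE
  residual only.
* No shock construction in the phase plane and no regularised (higher-order
  or nonlocal) model variants.
* The admissible-weight interval is derived from the quadratic
  $K_+^\nu < 0$; no claim is made about weighted *point* spectrum.
* Minimality of $c^*$ is only asserted for the two-rate family; for general
  polynomial diffusivities the thresholds are reported without a minimality
  claim.
* One-dimensional lattices only; the stochastic/continuum speed gap above
  means the generator is a faithful realisation of the discrete model, not a
  cheap surrogate for the PDE.
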