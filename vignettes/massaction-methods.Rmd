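---
title: "Simulating mass-action reaction networks with automatic stiffness switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mass-action reaction networks with automatic stiffness switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massaction)
```

## The model class

`massaction` simulates reaction-based models: `M` chemical reactions over
`N` molecular species, each reaction of the form

$$\sum_j a_{ij} S_j \;\xrightarrow{k_i}\; \sum_j b_{ij} S_j,$$

with non-negative integer stoichiometric coefficients and a strictly
positive kinetic constant $k_i$. Only first- and second-order reactions are
admitted — a reactant side of one or two molecules — which covers
unimolecular conversion and decay, bimolecular binding, and dimerization
($2A \to \cdot$). This restriction is what most mechanistic pathway models
use in practice, and it keeps every rate law a monomial of degree at most
two. Zero-order source reactions are rejected by default; `parse_model()`
and `validate_model()` accept them under an explicit permissive flag, but
the random generator never produces them.

Under mass-action kinetics the deterministic dynamics are

$$\frac{d\mathbf X}{dt} = (\mathbf B - \mathbf A)^T\,
  [\mathbf K \circ \mathbf X^{\mathbf A}],$$

with $\mathbf X^{\mathbf A}$ the vector of reactant monomials. Every ODE is
a polynomial whose terms are indexed by the reactions that change the
species, which is what makes a sparse precomputed encoding natural.

A note on dimerization: a reactant `2A` contributes the plain mass-action
term $k\,X_A^2$. No combinatorial factor of $\tfrac12$ is applied — the
rate constant is understood to absorb it. Models calibrated under the
stochastic convention ($k\,X_A(X_A-1)/2$ propensities) should rescale their
constants accordingly.

## The compressed encoding

`build_encoding()` stores, per species, the list of monomials of its ODE
(signed net-stoichiometry coefficient $h_{ji}$ plus the index of $k_i$),
and per monomial the list of reactant factors (species index, exponent 1
or 2). Both lists are flat arrays addressed by per-owner inclusive
`(first, last)` offset spans; a span with `first > last` marks a species
whose derivative is identically zero (for instance a pure catalyst that
appears identically on both sides of every reaction it touches). Entries
are deterministically ordered — species-major, then ascending reaction
index — so a given model always produces the same encoding and regression
tests can be bit-exact. All stored indices are 0-based.

Derivatives and the Jacobian are evaluated directly from the spans. The
Jacobian is exact: each monomial is differentiated symbolically (an
exponent-1 factor is dropped; $X_r^2$ contributes $2X_r$), so implicit
integration never relies on finite differencing.

The `compact_mode` flag emulates 16-bit index storage and refuses systems
with 65,536 or more species or reactions. It is a validation mode for the
storage format's capacity, not a numerical setting — the default wide
indices compute identically.

## Explicit integration and the error controller

Between sampling instants the state advances by embedded
Runge-Kutta-Fehlberg 4(5) steps: six derivative stages per step, combined
into a fifth-order candidate $\mathbf u$ and a fourth-order companion
$\mathbf w$. The per-species error measure and step multiplier are

$$\mathbf{ER} = \frac{|\mathbf w - \mathbf u|}{dt}, \qquad
  \boldsymbol\delta = 0.84\left(\frac{\boldsymbol\varepsilon}
  {\mathbf{ER}}\right)^{1/4}.$$

The step is accepted — with $\mathbf u$, the higher-order member, as the
new state (local extrapolation) — iff $ER_j \le \varepsilon_j$ for every
species. On rejection the step is retried at $dt \cdot \min_j \delta_j$.

Two numerical choices matter here:

* **ER is computed from the stage combination**, i.e. as
  $|\sum_i (b^{(4)}_i - b^{(5)}_i)\, l_i|$, which is algebraically
  identical to $|\mathbf w - \mathbf u|/dt$ but avoids the catastrophic
  cancellation of forming two nearly equal states and subtracting. At the
  default tolerance $\varepsilon_j = 10^{-12}$ the naive form would bottom
  out on round-off ($\sim 10^{-16}|X|/dt$) and make the tolerance
  unreachable for small $dt$.
* **The step also grows on acceptance**, $dt \leftarrow \min(dt\cdot\min_j
  \delta_j,\ dt_{\max})$, with each $\delta_j$ capped at `delta_max = 4`
  (the cap also handles $ER_j = 0$ at equilibria). Without growth the
  solver would never recover from a transient that forced a small step;
  the factor-4 cap is standard controller practice and prevents runaway
  growth after a quiescent stretch.

Steps are clamped to land exactly on each sampling instant, so recorded
times are grid-exact and no interpolation is performed.

## Stiffness detection and implicit integration

If a rejected step's retry size falls below the threshold
$\varepsilon_s$ (default $10^{-6}$), the system is declared stiff and the
solver switches to backward differentiation formulae:

$$\sum_{i=0}^{q} \alpha_i\, \mathbf X(t - i\,dt) = dt\, \beta_0\,
  f(t, \mathbf X(t)), \qquad \alpha_0 = 1,$$

with the classical coefficient sets for $q = 1,\dots,6$ ($q = 1$ is
backward Euler; orders above 6 are refused because their
absolute-stability region is too small to be useful). The coefficients
satisfy $\sum_i \alpha_i = 0$ and $\beta_0 = -\sum_i i\,\alpha_i$ exactly;
the test suite re-derives them from these polynomial-exactness conditions
as an independent oracle. History states are kept at uniform spacing, and
when a configured order $q > 1$ lacks history the order ramps up from 1 —
one order per completed step — as multi-step methods require.

Each implicit step solves $G(\mathbf z) = \mathbf z + \sum_{i\ge1}
\alpha_i \mathbf X_{n+1-i} - dt\,\beta_0 f(\mathbf z) = 0$ by a modified
Newton-Raphson iteration: the iteration matrix $I - dt\,\beta_0 J$ is
factorized once (LU with partial pivoting) at the initial guess (the most
recent state) and the factors are reused across iterations. Convergence is
declared when the max-norm of the update drops below $\varepsilon_{NR}$;
if the update norm stagnates (successive ratio above 0.9 three times) the
Jacobian is re-evaluated and re-factorized once before failure is
declared. A hard failure aborts the simulation with a diagnostic rather
than silently continuing.

After each switch the solver takes one BDF macro-step of length `dt_bdf`
(configurable to more via `bdf_run_steps`) and then returns control to the
explicit method at `dt0`. On a genuinely stiff model this alternation
settles into a cheap rhythm — a couple of rejected explicit probes per
implicit macro-step — while on a model that was only transiently stiff the
explicit method simply resumes. The macro-step is clamped to the next
sampling instant; a clamped (shorter) step breaks the uniform-spacing
assumption, so the history is then reset and the order ramps up again.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `eps_rkf` | $10^{-12}$ per species | explicit error tolerance on $ER$ (concentration/time units) |
| `dt0` | $10^{-3}$ | initial explicit step |
| `eps_s` | $10^{-6}$ | step size below which the system is declared stiff |
| `bdf_order` | 1 | implicit order $q$ (backward Euler) |
| `dt_bdf` | 0.1 | implicit macro-step length |
| `eps_nr` | $10^{-6}$ | Newton update max-norm tolerance |
| `max_it` | $10^4$ | Newton iteration cap |
| `delta_max` | 4 | cap on the step multiplier |

The tolerances are absolute. Concentrations in the intended regime are
$O(1)$ (the generator samples $[0,1)$), so an absolute $10^{-12}$ behaves
like a very tight relative tolerance; models whose concentrations reach
very large magnitudes would need `eps_rkf` scaled up accordingly.

## The synthetic-model generator

`generate_random_model(M, N, seed)` emulates random benchmark networks:
each reaction draws one or two reactant molecules and one or two product
molecules uniformly with replacement; null reactions (identical sides) are
resampled; a post-pass attaches any species absent from every reaction as
a product of a randomly chosen reaction. Initial concentrations are
uniform on $[0,1)$ and kinetic constants log-uniform on $[10^{-8}, 1)$,
the wide spread of time scales being exactly what makes such networks a
meaningful stress test for a stiffness-switching solver. Horizon and grid
default to $t_{\max} = 50$ with 10 evenly spaced sampling instants. One
seeded Mersenne-Twister stream governs the whole draw, so models are
reproducible byte-for-byte once written out; the caller's RNG state is
left untouched.

Feasibility: a reaction touches at most four species slots, so `4 M >= N`
is required, and for tall, skinny systems near that bound the drawn
reactant/product counts may still leave too few slots — the generator then
raises an honest error rather than degrading its sampling law.

What the generated models do *not* emulate: scale-free or modular
topology, conservation-law structure, or thermodynamic consistency of the
constants. Passing the trajectory-agreement tests on these networks
demonstrates solver correctness on polynomial vector fields with widely
spread rate constants; it does not validate biological realism of any
particular pathway model.

## Verification strategy and problem sizes

The test suite checks every layer against an independent route:

* compressed derivative evaluation against a dense entry-by-entry
  evaluation of the matrix form, on twenty seeded 16×16 models (agreement
  to $10^{-12}$ relative);
* the analytic Jacobian against central finite differences on ten seeded
  32×32 models ($10^{-6}$ relative, floor $10^{-4}$);
* BDF coefficients against the Vandermonde solve of the exactness
  conditions;
* single-step and multi-step closed forms (exponential decay, the
  implicit-Euler and BDF2 scalar recurrences, equilibria as fixed points);
* order-of-accuracy ratios under step halving ($\sim dt^4$ for the
  embedded pair's $ER$, first order for backward Euler's global error);
* full trajectories against `deSolve::lsoda` driven by the dense
  right-hand side, on thirty seeded 64×64 networks over $[0, 50]$
  (maximum relative deviation below $10^{-4}$ with an absolute floor of
  $10^{-8}$; measured values sit near $10^{-7}$);
* physical properties: conservation on closed conversion chains
  ($10^{-9}$), the symmetric isomerization equilibrium, stiffness
  switching on a $k = 10^4$ / $k = 10^{-2}$ two-timescale model and its
  absence on a single-timescale one.

These sizes keep the whole suite under half a minute while exercising
every code path, including the implicit branch; the solver itself handles
1024×1024 networks in under a second per trajectory.

## Known limitations

* Rate laws beyond mass action (Michaelis-Menten, Hill) are out of scope;
  reduce them to elementary steps first.
* Tolerances are absolute, as discussed above.
* Negative concentrations are not clipped — the ODE flow defines the
  dynamics, and a warning is emitted below $-10^{-9}$. Models whose exact
  dynamics graze zero can dip slightly negative at tight-but-finite
  tolerances.
* The explicit/implicit alternation is heuristic in the same way the
  original step-collapse criterion is: a model that is stiff from $t = 0$
  pays a few rejected explicit probes per macro-step rather than being
  detected once and handed to the implicit method permanently
  (`bdf_run_steps` amortizes this if needed).
* Event handling (discrete perturbations mid-run) and trajectory
  interpolation between grid points are not provided.
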