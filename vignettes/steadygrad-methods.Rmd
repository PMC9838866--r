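---
title: "Gradients under steady-state constraints: models, methods, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradients under steady-state constraints: models, methods, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadygrad)
```

## The model class and its assumptions

`steadygrad` works with ODE models of biochemical reaction networks,

$$\dot x = f(x, \theta, u), \qquad x(t_0) = x_0(\theta, u), \qquad
y = h(x, \theta, u),$$

with nonnegative states $x$ (species concentrations), parameters $\theta$
(rate constants, possibly estimated on a log10 scale), and constant
experimental inputs $u$ (e.g. a stimulus level). Rate expressions may be any
differentiable closed form — mass action, Michaelis–Menten, arbitrary
algebraic rates — and for reaction-defined models the right-hand side is
assembled symbolically as $f = S\,v$ from the stoichiometric matrix. A
raw-ODE escape hatch exists for models without reaction structure; conserved
moiety detection then has no stoichiometry to work from and is skipped with
a warning. All derivatives ($\partial f/\partial x$,
$\partial f/\partial\theta$, $\partial h/\partial x$,
$\partial h/\partial\theta$, $\partial x_0/\partial\theta$) are generated
symbolically with `stats::D`; nothing is differentiated numerically inside
the model layer. States are kept in declaration order and every matrix in
the package uses that order.

Two standing assumptions matter:

* **Exponential stability.** For every initial condition used, the
  trajectory approaches a steady state $x^*(\theta, u)$ whose Jacobian
  $J(x^*)$ has eigenvalues with strictly negative real parts. This is both
  what makes equilibration meaningful and what the steady-state adjoint
  shortcut rests on.
* **Known, fixed noise.** Measurements carry independent Gaussian noise with
  a fixed standard deviation per row. Noise parameters that depend on
  $\theta$ are out of scope; the gradient formulas omit
  $\partial\sigma/\partial\theta$ terms accordingly.

Experiments combine three phases per condition: an optional
**pre-equilibration** (simulate to steady state under control inputs $u^e$;
that steady state is the initial state of the time course), the **time
course** under $u$ on $[t_0, t_{n_t}]$, and an optional
**post-equilibration** (simulate on from the last measured time until steady
state, because steady-state measurements exist; they are marked with an
infinite time in the measurement table).

## Objective and gradient

The negative log-likelihood is
$$J(\theta) = \tfrac12 \sum \Big[\log(2\pi\sigma^2) +
\big((\bar y - y)/\sigma\big)^2\Big]$$
over time-course and steady-state rows alike. The constant terms are kept so
objective values are comparable across runs and tools. The gradient is
assembled per condition from (i) direct observation-map terms
$-\sum r/\sigma^2\, \partial h/\partial\theta$, (ii) the adjoint quadrature
$-\int p^\top \partial f/\partial\theta\, dt$, and (iii) the initial-state
term $-p(t_0)^\top \partial x_0/\partial\theta$, which applies only when
$x_0$ is an explicit function of $\theta$ — under pre-equilibration it is
replaced by the pre-equilibration contribution below. The parameter-scale
chain rule (log10 entries multiplied by $\theta \ln 10$) is applied last.

## The steady-state adjoint shortcut

The adjoint state obeys $\dot p = -J(x(t))^\top p$ backward in time, with
jumps $(\partial h_i/\partial x)^\top r_i/\sigma_i^2$ at measured times and
$p \equiv 0$ beyond the last measurement. Over an equilibration interval the
trajectory sits at $x^*$, the Jacobian is constant, and — because $J(x^*)$
is Hurwitz — $p = 0$ is stable in reverse time. Integrating the adjoint ODE
over the interval therefore gives
$$J(x^*)^\top \int p\, dt = -\,p_{\text{boundary}},$$
so the entire quadrature collapses to one linear solve followed by a
matrix–vector product with $\partial f/\partial\theta|_{x^*}$:

* **Post-equilibration**: $p_{\text{boundary}}$ is the jump formed from the
  steady-state residuals. The adjoint handed on to the time-course backward
  pass is *exactly zero* — not the relaxed numerical value — since $p = 0$
  is reached and kept on the remainder of the interval.
* **Pre-equilibration**: the time-course backward pass ends at $t_0$ with
  some $p(t_0)$ (including a jump if a measurement sits exactly at $t_0$;
  the jump is applied before anything else uses $p(t_0)$). That vector seeds
  the solve in the Jacobian at the *pre-equilibration* steady state under
  $u^e$, and the contribution $-p_{\text{int}}^\top \partial f/\partial
  \theta|_{x^*(\theta,u^e),\,u^e}$ replaces the initial-state term: the
  adjoint has relaxed to zero at the far end of the interval, so its scalar
  product with the pre-equilibration initial-state sensitivities vanishes.

Both solves use dense LU with partial pivoting; every solve's scaled
residual and reciprocal condition estimate are recorded in the
`gradient_result` (`solves` field), and the test suite asserts
$\|J^\top p_{\text{int}} + p_{\text{boundary}}\| \le 10^{-10}
(1 + \|p_{\text{boundary}}\|)$ for every solve. At the model sizes targeted
here a sparse path is unnecessary; dense LU is exact enough and simplest.

**Applicability.** The solves need a nonsingular $J(x^*)$. The common
obstacle is conserved moieties: any left-null-space row $L$ of $S$ gives
$L f \equiv 0$, hence a singular Jacobian everywhere. The package computes
an exact integer basis of the left null space (fraction-free Gaussian
elimination over the rationals — exactness matters more than scalability at
desk scale, and the elimination is deterministic) and removes one state per
law, substituting $(T_c - \sum_{j} L_{cj} x_j)/L_{ce}$ symbolically with the
total $T_c = L_c\,x_0(\theta, u)$ kept symbolic so its $\theta$-dependence
propagates into the reduced derivatives. The eliminated state per law is the
one with the largest absolute coefficient (ties to the highest declaration
index — deterministic and avoids dividing by small coefficients); the chosen
column is then cleared from the remaining laws by exact row operations so
every replacement references only kept states. If the Jacobian is singular
for some other reason, the default is a hard classed error
(`steadygrad_singular_jacobian`); an opt-in fallback
(`allow_asa_fallback = TRUE`) silently integrates the adjoint backward over
that interval instead and tags the result, because silent method switching
can hide modeling problems and should be a deliberate choice.

## Reference methods

Three independent routes to the same gradient are first-class citizens:

* `asa` — the long-simulation adjoint: backward integration over the same
  equilibration span the forward equilibration used. This path deliberately
  evaluates everything at the raw simulation endpoints (that is what the
  long-simulation method observes), including the scalar product of the
  pre-equilibration initial-state sensitivities with $p(-t')$, which is
  evaluated rather than assumed zero. As the tail is stretched
  (`t_min_equil`), its gradient converges to the ssASA gradient — the test
  suite asserts the gap falls below $10^{-5}$.
* `forward` — forward sensitivities $\dot s = J s + \partial f/\partial
  \theta$ integrated with the states; at steady states $s^*$ comes from the
  per-parameter linear solves $J s^* = -\partial f/\partial\theta$, and
  pre-equilibration sensitivities seed the time course.
* `fd` — central finite differences on the estimation scale with relative
  step $10^{-5}$ (balancing truncation against integrator noise at the
  default forward tolerance).

The cross-validation surface is an eleven-problem seeded fixture suite
(`fixture_suite()`); on it, ssASA agrees with forward sensitivities to
better than $10^{-6}$ and with finite differences to better than $10^{-4}$
in relative infinity norm.

## Equilibration

Steady states are found by numerical integration until the weighted residual
$$\frac{1}{n_x}\sum_i (\dot x_i w_i)^2 < 1, \qquad
w_i = \frac{1}{\text{rtol}\,|x_i| + \text{atol}}$$
with defaults rtol $= 10^{-8}$, atol $= 10^{-16}$ (common practice for
equilibration runs). Two small choices are worth stating: the magnitude
$|x_i|$ enters the weight so that transient solver undershoots below zero
cannot flip weight signs (negative transients produce a warning, not an
error — stiff solvers legitimately undershoot); and the criterion is used in
its mean-of-squares form — "$<1$" is equivalent with or without the square
root. The integration proceeds over windows $[0, W], [W, 3W], \dots$ with
doubling lengths ($W = 10$ model time units, at most 30 windows), which
bounds total work at about twice the final window; the criterion is
evaluated at every checkpoint of every window, not only at window ends. A
**Newton polish** on $f(x) = 0$ runs by default after the simulation
converges, accepting each step only while the weighted residual decreases
(divergence or a singular Jacobian falls back to the simulation result with
a warning). Simulation-first-then-Newton is deliberately the default: pure
Newton from a poor initial guess can land multi-stable systems on the wrong
branch, whereas a converged simulation provides a refined starting point.
For multi-stable systems, post-equilibration always starts from the final
time-course state; selecting among multiple steady states is out of scope
and documented as such.

## Numerics

* **Integrators.** Forward passes use LSODA with the analytic model Jacobian
  at rtol $10^{-10}$/atol $10^{-12}$ — much tighter than the equilibration
  test, so method comparisons are not integrator-noise-limited. Backward
  passes use VODE (BDF) with the analytic adjoint Jacobian
  ($-J^\top$ plus the quadrature coupling block), which restarts cleanly at
  every measurement jump.
* **Quadratures.** The gradient integrals are augmented states integrated
  with the adjoint (so their error is controlled by the integrator), not
  post-hoc quadrature of stored $p(t)$.
* **Checkpointing.** The backward pass reads forward states from piecewise
  cubic Hermite interpolation of a checkpointed forward solution (states
  *and* exact derivatives at each checkpoint). Time-course grids place half
  the checkpoints geometrically near $t_0$ — equilibrating systems change on
  log time scales — and half uniformly (241 points by default).
* **Measurement bookkeeping.** A jump exactly at $t_{n_t}$ is applied before
  backward integration starts; a jump exactly at $t_0$ is applied before the
  initial-state term is formed. Multiple steady-state observables are folded
  into a single boundary jump — one steady state per condition.
* **Degenerate inputs.** $\sigma \le 0$, undeclared symbols, broken table
  references, and missing simulated values all raise classed errors naming
  the offending row/symbol; a zero weight denominator in the convergence
  test is a `steadygrad_degenerate_weight` error.

## Synthetic fixtures: what they emulate and what they do not

The generators produce the statistical structure the methods assume:
exponentially stable steady states (verified by an eigenvalue check at
generation; random linear networks are built strictly diagonally dominant so
they are Hurwitz by construction, and failed draws are regenerated from the
next sub-seed) and independent Gaussian noise. The four kinds are a
production–degradation unit (closed-form steady state $k_{in}/k_{out}$), a
conversion reaction (one conserved total — the moiety-reduction exercise,
including a $\theta$-dependent total through $x_0$), seeded stable linear
networks, and a three-state Michaelis–Menten chain (nonlinear, saturable
conversions with small fixed linear leaks so a steady state exists for every
positive parameter vector, which keeps multi-start optimization
well-behaved across the whole bounded box). Time-course sampling is
log-spaced across a window matched to each kind's relaxation time; noise
defaults to $\sigma = 0.05$ for cross-validation suites and $\sigma = 0.01$
for the recovery study; $\sigma = 0$ yields exact values recorded with unit
weights. One deliberately unreduced conversion problem exercises the
singular-Jacobian error path.

What passing tests on these fixtures does **not** show about real data:
there are no misspecified models, no outliers or non-Gaussian noise, no
unknown noise parameters, no events/delays/time-dependent inputs, and the
dimensions are desk-scale (3–5 states) rather than the hundreds-to-thousands
of states where the backward-integration savings matter most. The
work-count diagnostics (backward RHS evaluations over equilibration spans:
exactly zero under ssASA, hundreds under the reference adjoint) are the
directional, hardware-independent analogue of wall-clock speedups.

## Estimation

`estimate()` draws start points uniformly within the bounds on the
estimation scale (log10 bounds sampled in log10 space), seeded and
reproducible, and runs bounded `L-BFGS-B` from each with the selected
gradient method; objective and gradient share one simulation per parameter
vector. The optimizer is a contract — bounded, gradient-based, deterministic
given a start — not a contribution; any optimizer with those properties
would do. Failed starts are reported, never silently dropped, and results
are sorted by final negative log-likelihood.

Problem sizes used by the shipped studies: the cross-validation suite runs
eleven problems with 4–6 log-spaced time points and up to five states; the
recovery study fits the six-parameter Michaelis–Menten chain to two
conditions × eight time points × three observables plus steady-state rows
($\sigma = 0.01$), 20 starts, 150 iterations cap, with slightly relaxed
integration tolerances (rtol $10^{-6}$, atol $10^{-8}$, 41 checkpoints) —
comfortably sufficient for an optimizer driven to $\sim 10^{-9}$ relative
objective improvement, and a sensible default for fitting where individual
gradients need not be reproducible to $10^{-6}$.

## Known limitations

Events, delays, time-dependent inputs, SBML import, full PEtab compliance,
$\theta$-dependent noise, second-order adjoints, and steady-state parametric
sensitivities as adjoint outputs are all out of scope. Moiety detection
needs a stoichiometric matrix; raw-ODE models skip it. The steady-state
shortcut is only as good as the equilibration: a system that plateaus
slowly enough to pass the residual test away from its true steady state will
bias every method that trusts $x^*$ (the Newton polish mitigates this). For
multi-stable systems the package always equilibrates from the final
time-course state and does not attempt branch selection.
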