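# steadygrad

Objective-function gradients for maximum-likelihood parameter estimation in
ODE models of biochemical reaction networks whose experiments involve
**steady-state constraints** — pre-equilibration (the experiment starts from
a steady state reached under a control condition) and post-equilibration
(measurements of the steady state itself, taken after the time course).

## The problem and the method

Models are of the form

    dx/dt = f(x, θ, u),   x(t0) = x0(θ, u),   y = h(x, θ, u)

with states `x`, parameters `θ`, constant experimental inputs `u`, and
Gaussian measurement noise. The negative log-likelihood is

    J(θ) = ½ Σ [ log(2πσ²) + ((ȳ − y)/σ)² ]

summed over time-course and steady-state measurements. Gradient-based
multi-start optimization needs `∂J/∂θ` cheaply; adjoint sensitivity analysis
(ASA) provides it by integrating the adjoint state backward,

    dp/dt = −J(x(t), θ, u)ᵀ p,

with jumps `p += (∂h/∂x)ᵀ (ȳ − y)/σ²` at measurement times, and assembling

    ∂J/∂θ = − Σ r/σ² ∂h/∂θ − ∫ pᵀ ∂f/∂θ dt − p(t0)ᵀ ∂x0/∂θ.

The standard treatment of equilibration phases integrates the adjoint
backward over the entire (long) equilibration span. `steadygrad` implements
the **steady-state adjoint (ssASA)** shortcut: at an exponentially stable
steady state `x*` the Jacobian is constant, `p = 0` is stable in backward
time, and the quadrature over the equilibration interval collapses to a
single linear solve in the transposed steady-state Jacobian,

    J(x*)ᵀ p_int = −p_boundary,     contribution = −p_intᵀ ∂f/∂θ|x*,

for the post-equilibration interval (with `p_boundary` formed from the
steady-state residuals) and likewise for the pre-equilibration interval
(with `p_boundary = p(t0)` handed over from the time-course backward pass).
No backward numerical integration is performed over equilibration spans at
all — the package counts backward right-hand-side evaluations so the saving
is measurable.

The solves require a nonsingular steady-state Jacobian. The usual obstacle —
conserved moieties (left null space of the stoichiometric matrix) — is
removed by exact rational null-space detection and symbolic elimination of
one state per conserved total (`find_conserved_quantities()`,
`reduce_model()`).

Also included, behind the same interface: the reference long-simulation
adjoint (`asa`), forward sensitivities with steady-state sensitivities by
per-parameter linear solves (`forward`), and central finite differences
(`fd`) — used to cross-validate every gradient; steady-state equilibration
with the weighted-residual convergence test
`(1/n) Σ (ẋᵢ wᵢ)² < 1, wᵢ = 1/(rtol |xᵢ| + atol)` and an optional Newton
polish; seeded synthetic fixtures; a PEtab-subset problem format; and
multi-start bounded (`L-BFGS-B`) estimation.

## Worked example

A production–degradation model `dx/dt = k_in·w − k_out·x` at
`(k_in, k_out) = (2, 1)` has the steady state `x* = k_in/k_out = 2`. With a
single steady-state measurement `ȳ* = 3` (σ = 1) the hand-derived gradient
is `∂J/∂θ = −(ȳ* − x*)·∂x*/∂θ = (−1, +2)` on the linear scale:

```r
library(steadygrad)
fx <- make_fixture("production_degradation", sigma = 0, n_timepoints = 0,
                   equilibration = "post")
fx$problem$measurements$measurement <- 3   # the steady-state datum
g <- ssasa_gradient(fx$problem, fx$theta_true_est)
print(g)
#> <gradient_result> method = ssasa, nll = 1.41894
#>   gradient (estimation scale):
#>     k_in    k_out
#> -4.60517  4.60517
#>   RHS evals: forward 418, backward (time course) 0, backward (equilibration) 0
g$gradient_linear
#>  k_in k_out
#>    -1     2
```

The fixture's parameters are estimated on a log10 scale, so the printed
gradient is the linear-scale `(−1, +2)` times `θ ln 10`; `nll = 1.41894` is
`½ log(2π) + ½·1²` for the unit residual. Zero backward RHS evaluations were
spent on the equilibration interval: the posteq contribution came from one
1×1 linear solve. The long-simulation reference
(`asa_gradient_longsim(fx$problem, fx$theta_true_est)`) returns the same
gradient with several hundred backward evaluations.

A command-line launcher is installed under `inst/cli/steadygrad`
(subcommands `simulate`, `gradient`, `check-gradients`, `estimate`,
`make-fixture`, `reduce`).

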