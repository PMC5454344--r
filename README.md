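# porocyl

Steady-state solvers for the radial deformation of a **soft poroelastic
cylinder under fluid injection** — the annular cross-section of an artery
wall, a tissue layer around a needle or catheter, a cylindrical filter, or a
borehole wall. Fluid injected at the centre flows radially outward through
the solid skeleton; when the driving pressure is comparable to the stiffness
of the skeleton, the flow and the deformation are strongly coupled and the
response departs from classical linear poroelasticity.

The package is aimed at researchers in tissue biomechanics and poromechanics
who need reference steady states — e.g. as benchmarks for finite-element
poroelasticity codes — and at anyone studying how kinematic nonlinearity,
nonlinear elasticity and deformation-dependent permeability interact in
radial geometries.

## The model

In plane strain with incompressible constituents, a steady state satisfies
(dimensionless: lengths in units of the outer radius b₀, stresses in units
of the oedometric modulus M)

    dσ′_r/dr + (σ′_r − σ′_θ)/r = dp/dr = −q / (r·k̃(φ_f)),

which combines with an elasticity law into a second-order ODE for the radial
displacement u_s(r); for linear elasticity

    u_s″ + u_s′/r − u_s/r² = −q / (r·k̃[φ_f(u_s)]).

Six model variants combine the treatment of the kinematics (linearized vs
rigorous, with φ_f = 1 − (1−φ_f,0)/J exactly), the elasticity law (linear vs
Hencky logarithmic-strain) and the permeability law (constant vs normalized
Kozeny–Carman k̃ = (1−φ_f,0)²/φ_f,0³ · φ_f³/(1−φ_f)²); they carry the labels
`L-k0`, `L-kKC`, `Q-k0`, `Q-kKC`, `N-k0`, `N-kKC`. The outer boundary is
either fixed (`constrained`) or free under an applied radial effective
stress (`unconstrained`); flow is driven by an imposed flow rate `q` or
pressure drop `dp`. `L-k0` and `Q-k0` have (semi-)closed forms; the general
case is solved by Chebyshev spectral collocation with Newton iteration on an
unknown deformed domain. Continuation utilities expose the hallmark
nonlinear structure: an unconstrained annulus supports only a finite maximum
pressure drop Δp^max(a₀), below which **two** steady states coexist (a less-
and a more-deformed branch), while a constrained annulus is single-valued in
Δp but conducts at most a finite maximum flow rate.

## Worked example

```r
library(porocyl)

prob <- problem("Q-kKC", a0 = 0.3, bc = "constrained", dp = 0.08)
st <- solve_steady(prob, numerics_config(n_nodes = 65))
st
#> <porocyl steady state: Q-kKC, constrained BC, a0 = 0.3>
#>   a = 0.3198798, b = 1, q = 0.069912122, dp = 0.08
#>   converged = TRUE (residual 9.18e-12, 24 iters, 65 nodes, spectral)

summarize_state(st)
#> <porocyl summary Q-kKC (constrained), a0 = 0.3>
#>   delta_a = 0.0198798, delta_wall = -0.0198798
#>   phi in [0.478644, 0.519417];  |sig_r|max = 0.0427114, |sig_th|max = 0.0522041
#>   q = 0.0699121 (rigid reference q0 = 0.0664467), dp = 0.08

force_balance(st)
#> <porocyl force balance: Fp = 0.0991241, Fth = 0.0137014, Fr = 0.0854227, closure = 8.55e-14>
```

Reading the numbers: a pressure drop of 0.08·M pushes the inner radius out
by Δa ≈ 0.02·b₀ and, because the outer wall is held fixed, thins the wall by
exactly the same amount. The porosity rises above its reference value 0.5
near the injection surface and is squeezed below it at the outer wall. The
flow rate exceeds the rigid-cylinder reference q₀ (thick-ish walls dilate
near the inlet, where resistance is concentrated), and the fluid load Fp is
carried almost entirely by the outer support (Fr) rather than by hoop
stress — the force balance closes to 9e-14.

The same problem without the outer support is double-valued:

```r
bp <- solve_both_branches(0.3, "Q-kKC", "unconstrained", target_dp = 0.08)
bp
#> <porocyl branch pair at dp = 0.08: q_less = 0.10926036, q_more = 118.7099 (fold q = 2.25015)>
```

A command-line front end is shipped at
`system.file("cli", "porocyl.R", package = "porocyl")` with `solve` and
`sweep` subcommands writing CSV profiles and JSON summaries; see the script
header for flags.

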