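---
title: "Methods: steady injection into a soft poroelastic annulus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady injection into a soft poroelastic annulus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porocyl)
```

## The physical problem

`porocyl` computes steady states of a fluid-saturated, soft poroelastic
cylinder — an idealization of an artery wall, a tissue annulus around a
catheter, or a borehole wall — when fluid is injected at its centre and flows
radially outward through the solid skeleton. The cross-section is an annulus
of initial inner radius $a_0$ and outer radius $b_0$, in plane strain, with
both constituents incompressible. The inner surface is a free, material
boundary; the outer boundary is either held fixed ("constrained") or free
with an applied radial effective stress $\sigma_r^\star$ ("unconstrained").
Flow is driven by an imposed volumetric flow rate per unit length or by an
imposed pressure drop across the wall.

When the driving pressure is comparable to the stiffness of the skeleton the
deformation is large, and three distinct nonlinearities matter:

* **kinematics** — the exact porosity–displacement relation and the motion of
  the domain boundaries, versus their small-strain linearization;
* **elasticity** — a Hencky (logarithmic-strain) hyperelastic law, which
  stiffens in compression and softens in tension, versus linear elasticity;
* **permeability** — a normalized Kozeny–Carman law
  $\tilde k(\phi_f) = \frac{(1-\phi_{f,0})^2}{\phi_{f,0}^3}
  \frac{\phi_f^3}{(1-\phi_f)^2}$, which vanishes with the porosity and
  diverges as $\phi_f \to 1$, versus constant permeability.

The package implements all six legal combinations, labelled
`L-k0`, `L-kKC` (linearized kinematics + linear elasticity),
`Q-k0`, `Q-kKC` (rigorous kinematics + linear elasticity) and
`N-k0`, `N-kKC` (rigorous kinematics + Hencky elasticity). Linearized
kinematics is never combined with Hencky elasticity: wherever the
linearization is valid, the Hencky law reduces to linear elasticity, so the
combination adds nothing but inconsistency.

## Governing equations at steady state

Working in dimensionless variables (lengths in units of $b_0$, stresses and
pressures in units of the oedometric modulus $M$, permeability in units of
its reference value), a steady state has a stationary solid and a purely
radial Darcy flux, so momentum balance and Darcy's law combine into

$$\frac{d\sigma_r'}{dr} + \frac{\sigma_r' - \sigma_\theta'}{r}
  = \frac{dp}{dr} = -\frac{q}{r\,\tilde k(\phi_f)},$$

with $q$ the dimensionless flow rate. Substituting the elasticity law yields
a second-order ODE for the radial displacement $u_s(r)$: for linear
elasticity

$$u_s'' + \frac{u_s'}{r} - \frac{u_s}{r^2}
  = -\frac{q}{r\,\tilde k[\phi_f(u_s)]},$$

and for Hencky elasticity the analogous quotient form in the principal
stretches $\lambda_r = (1 - u_s')^{-1}$, $\lambda_\theta = (1 - u_s/r)^{-1}$,
whose denominator $\lambda_r r\,[1 - (\ln\lambda_r +
\Gamma\ln\lambda_\theta)]$ can vanish at extreme compression (the solver
signals this rather than stepping over it). The porosity follows from the
volume change, $\phi_f = 1 - (1-\phi_{f,0})/J$ with
$J = \lambda_r\lambda_\theta$, or from its linearization
$\phi_f = \phi_{f,0} + (1-\phi_{f,0})(u_s' + u_s/r)$ for the L models. The
material enters through two numbers: $\Gamma = \Lambda/M \in [-\tfrac12, 1]$
and the reference porosity $\phi_{f,0}$.

The boundary conditions are $\sigma_r'(a) = 0$ and $u_s(a) = a - a_0$ at the
(unknown) inner radius, plus either $u_s(b) = 0$ with $b = 1$ (constrained)
or $\sigma_r'(b) = \sigma_r^\star$ and $u_s(b) = b - 1$ with $b$ unknown
(unconstrained). For the L models all conditions are applied on the reference
annulus $[a_0, 1]$. The pressure is gauged to zero at the outer boundary, and
an imposed pressure drop is enforced through the quadrature identity
$\Delta p = q \int_a^b \frac{dr}{r \tilde k(\phi_f)}$.

## Closed forms and the spectral solver

With constant permeability the linear-elasticity ODE is linear, with general
solution $u_s = c_1 r + c_2/r - \tfrac{q}{2} r \ln r$. For `L-k0`
(classical linear poroelasticity) the two boundary conditions are linear in
$(c_1, c_2)$ and the problem is fully closed-form (`solve_L_k0()`), with
$q = \Delta p / \ln(1/a_0)$ independent of the outer boundary condition —
identical to a rigid cylinder. For `Q-k0` the same displacement family lives
on the unknown deformed annulus and $(c_1, c_2, a[, b][, q])$ satisfy a small
nonlinear algebraic system (`solve_Q_k0()`), solved by damped Newton
iteration seeded from the linearized solution. We derived the closed form by
substitution into the ODE rather than copying coefficients from anywhere;
the test suite validates it by residual substitution.

All six models are handled uniformly by `solve_steady()`: Chebyshev spectral
collocation on Gauss–Lobatto nodes mapped to $[a, b]$, with the nodal
displacement plus the scalars $\{a, b, q\}$ (as applicable) as one unknown
vector, boundary rows replacing the ODE rows at the endpoints, and dedicated
rows for the kinematic closures and the pressure-drop quadrature constraint.
Newton iteration uses an analytically assembled Jacobian for the
displacement block — the residual depends on $u_s$ only through pointwise
functions of $(u_s, u_s', u_s'')$, so the chain rule gives the exact block at
the cost of a few matrix products — and central finite differences only for
the few scalar columns. We originally finite-differenced the whole matrix;
that proved unreliable at fine resolution because the boundary stress rows
carry differentiation-matrix entries of order $2n^2/(b-a)$, so a nodal
perturbation $h$ incurs an $O(h^2 (n^2/(b-a))^3)$ truncation error that the
conditioning of the system amplifies into a stalled line search. The hybrid
Jacobian restored quadratic convergence everywhere we tested.

Numerical parameters (`numerics_config()`), with defaults chosen so single
solves complete in well under a second:

* `n_nodes = 129` collocation nodes. The fields are analytic, so thin-wall
  solutions are fully resolved by ~10 nodes and thick-wall solutions by
  ~65; the default leaves a wide margin.
* `mapping = "auto"`: an affine map of the computational interval, switched
  to a logarithmic-radius map when $a_0 \le 10^{-2}$ because injection
  gradients then concentrate near the inner radius.
* `tol = 1e-9` on the residual infinity norm (ODE rows scaled by $r$, which
  removes the $1/r$ roundoff amplification near a small inner radius), with
  a step-norm tolerance of $10^{-9}$. We initially targeted $10^{-10}$, but
  at 129 nodes with displacements of order 0.2–0.5 the double-differentiation
  roundoff floor of the residual sits near $3\times10^{-10}$, so the extra
  decade is unreachable in double precision; truncation error is orders of
  magnitude below either value. A line search that stalls within a factor 30
  of `tol` is accepted as converged-at-the-roundoff-floor, with the achieved
  residual reported.
* `ramp_steps = 10` geometric load-ramping steps from 1% of the target load,
  warm-starting each solve; a failed step is bisected, and a step that
  collapses below $10^{-6}$ of the target is reported as the end of the
  branch (this is how an above-fold pressure drop manifests).
* porosity is clamped to $[10^{-6}, 1-10^{-6}]$ *only* inside permeability
  evaluations during Newton iterates, because intermediate iterates may
  transiently overshoot; a converged state must satisfy the open-interval
  invariant or the solve is reported failed. The clamp floor is our choice —
  there is no physically distinguished porosity floor short of collapse.

## Folds and the two solution branches

For an unconstrained annulus the map $q \mapsto \Delta p$ at fixed geometry
rises to a finite maximum $\Delta p^{\max}(a_0)$ and then falls: above it no
steady state exists, below it two coexist (a less- and a more-deformed
state). All branch structure is therefore resolved by sweeping $q$, which
parametrizes the curve single-valuedly, rather than by pseudo-arclength
continuation: `trace_load_curve()` warm-starts along an increasing $q$ grid,
`find_fold()` refines the discrete maximum of $\Delta p(q)$ by
golden-section/parabolic search (tolerance $10^{-6}$ in $\Delta p$), and
`solve_both_branches()` root-finds in $q$ on each side of the fold
(tolerance $10^{-8}$). The default grid spans $[10^{-3} q_0, 10^2 q_0]$
around the rigid reference $q_0 = \Delta p / \ln(1/a_0)$ in 60 geometric
points and is extended automatically when the falling side has not yet
dropped to the target — the tail of $\Delta p(q)$ can decay slowly, so a
fixed two-decade window does not always bracket the more-deformed branch.
Non-convergence at extreme deformation truncates a curve and is recorded as
the physical end of the branch. For a constrained annulus $\Delta p(q)$ is
monotone but $q$ saturates at a finite maximum; `find_fold()` then reports
the largest achieved flow rate.

```{r branches, eval = FALSE}
bp <- solve_both_branches(a0 = 0.3, "Q-kKC", "unconstrained", target_dp = 0.1)
summarize_state(bp$less)
summarize_state(bp$more)
```

## Diagnostics

From a converged state the package derives the pressure profile (spectral
antiderivative of $-q/(r\tilde k)$ gauged to zero at the outer boundary; the
pressure-drop constraint itself uses Clenshaw–Curtis quadrature, and the two
agree to spectral accuracy), the fluid velocity $v_f = q/(r\phi_f)$ with its
constant-flux invariant, the Lagrangian coordinate $R = r - u_s$, porosity
and stress extrema (evaluated on a 10x-oversampled barycentric interpolant,
because nodal extrema under-resolve the steep inner region of thick-walled
solutions), the solid-volume conservation integral (identically satisfied by
rigorous kinematics, and a genuine model defect of the linearized
kinematics), and the macroscopic force balance $F_p = F_\theta + F_r$
between pressure loading, hoop stress and outer traction. For the L models
the force balance is evaluated on the reference domain, consistently with
where their boundary conditions are imposed; the closure identity then holds
discretely there too.

## What the tests do and do not show

The suite checks the implementation against independent oracles: the
closed-form `L-k0`/`Q-k0` family, second-order agreement of the Hencky and
linear laws at small strain, grid-refinement and spectral-convergence
behaviour, conservation identities, and the documented qualitative structure
(sign patterns, fold existence, branch ordering, boundary-condition
dichotomies). Problem sizes in the tests (13–65 nodes, 25–50-point load
curves) are chosen so the whole suite runs in seconds while truncation error
stays far below every asserted tolerance. None of this validates the
*constitutive choices* against any particular tissue or soil: Hencky
elasticity and Kozeny–Carman permeability are generic laws chosen for their
qualitative behaviour, the material is assumed isotropic and elastic at
arbitrary strain, and plasticity, fracture, permeability anisotropy and
transient consolidation are out of scope.
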