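# Derived fields and scalar diagnostics from a converged steady state.

#' Nodal pore-pressure profile
#'
#' The steady pressure satisfies `dp/dr = -q / (r * ktilde)` with gauge
#' `p(b) = 0`; it is computed spectrally on the state's grid (and stored on
#' the state at construction). The value at the inner node equals the
#' pressure drop.
#'
#' @param state A converged `porocyl_state`.
#' @return Nodal pressure values (decreasing in r for q > 0).
#' @export
pressure_profile <- function(state) {
  stopifnot(inherits(state, "porocyl_state"))
  state$p
}

#' Nodal fluid velocity
#'
#' At steady state the solid is stationary and the total flux is carried by
#' the fluid alone: `v_f = q / (r * phi_f)`, so that `r * phi_f * v_f = q` at
#' every radius.
#'
#' @param state A converged `porocyl_state`.
#' @export
fluid_velocity <- function(state) {
  state$q / (state$grid$r * state$phi)
}

#' Lagrangian (reference) coordinate of the deformed material
#'
#' `R(r) = r - u_s(r)`, the reference position of the material currently at
#' radius r. Must be strictly increasing (no interpenetration); for rigorous
#' kinematics `R(a) = a0` and `R(b) = 1` by the kinematic boundary
#' conditions.
#'
#' @param state A converged `porocyl_state`.
#' @return Nodal reference positions.
#' @export
lagrangian_coordinate <- function(state) {
  R <- state$grid$r - state$us
  fine <- oversample(state)
  if (any(diff(fine$r - fine$us) <= 0))
    porocyl_stop("interpenetration",
                 "Lagrangian coordinate non-monotone: material interpenetration")
  R
}

# evaluate the interpolants of us and dus on a 10x-oversampled Chebyshev grid
oversample <- function(state, factor = 10L) {
  grid <- state$grid
  nf <- factor * grid$n
  xi_f <- -cos(pi * (0:(nf - 1L)) / (nf - 1L))
  r_f <- if (grid$mapping == "affine") {
    grid$a + (grid$b - grid$a) * (xi_f + 1) / 2
  } else {
    exp(log(grid$a) + (log(grid$b) - log(grid$a)) * (xi_f + 1) / 2)
  }
  list(r = r_f,
       us = grid_interp(grid, state$us, r_f),
       dus = grid_interp(grid, state$dus, r_f))
}

#' Scalar summary of a converged steady state
#'
#' Reports the change in inner radius, the change in wall thickness, porosity
#' extrema, effective-stress magnitude extrema, the flow rate and pressure
#' drop, and the rigid-cylinder reference flow rate `q0 = dp / log(1/a0)`.
#' Extrema are evaluated on a 10x-oversampled barycentric interpolant of the
#' displacement field (nodal extrema under-resolve the steep inner-radius
#' region of thick-walled solutions) with the constitutive relations applied
#' pointwise.
#'
#' @param state A converged `porocyl_state`.
#' @return Object of class `porocyl_summary` (a named list).
#' @export
summarize_state <- function(state) {
  stopifnot(inherits(state, "porocyl_state"))
  prob <- state$problem
  fine <- oversample(state)
  mat <- prob$material
  phi_f <- porosity_field(fine$us, fine$dus, fine$r, mat$phi0,
                          prob$model$kinematics, strict = FALSE)
  sig_f <- stress_field(fine$us, fine$dus, fine$r, mat$gamma,
                        prob$model$elasticity)
  structure(list(
    model = prob$model$label, bc = prob$bc, a0 = prob$a0,
    delta_a = state$a - prob$a0,
    delta_wall = (state$b - state$a) - (1 - prob$a0),
    phi_min = min(phi_f), phi_max = max(phi_f),
    abs_sig_r_max = max(abs(sig_f$sig_r)),
    abs_sig_th_max = max(abs(sig_f$sig_th)),
    us_max = max(abs(fine$us)),
    q = state$q, dp = state$dp,
    q0 = rigid_flow_rate(state$dp, prob$a0)),
    class = "porocyl_summary")
}

#' @export
print.porocyl_summary <- function(x, ...) {
  cat(sprintf("<porocyl summary %s (%s), a0 = %g>\n", x$model, x$bc, x$a0))
  cat(sprintf("  delta_a = %.6g, delta_wall = %.6g\n", x$delta_a, x$delta_wall))
  cat(sprintf("  phi in [%.6g, %.6g];  |sig_r|max = %.6g, |sig_th|max = %.6g\n",
              x$phi_min, x$phi_max, x$abs_sig_r_max, x$abs_sig_th_max))
  cat(sprintf("  q = %.6g (rigid reference q0 = %.6g), dp = %.6g\n",
              x$q, x$q0, x$dp))
  invisible(x)
}

#' Macroscopic force balance on half the annulus
#'
#' The net 'vertical' force components acting on one half of the annular
#' cross-section: pressure loading `Fp = 2 a dp + 2 integral_a^b p dr`,
#' internal azimuthal stress `Fth = 2 integral_a^b sig_th dr` and external
#' radial traction `Fr = -2 b sig_r(b)`. Mechanical equilibrium requires
#' `Fp = Fth + Fr`; the residual is reported as `closure`. For
#' linearized-kinematics models, forces are evaluated on the reference
#' domain, consistently with the linearized boundary conditions.
#'
#' @param state A converged `porocyl_state`.
#' @return Object of class `porocyl_forces` with fields `Fp`, `Fth`, `Fr`,
#'   `closure`.
#' @export
force_balance <- function(state) {
  grid <- state$grid
  n <- grid$n
  dp <- state$p[1]
  Fp <- 2 * grid$a * dp + 2 * grid_quad(grid, state$p)
  Fth <- 2 * grid_quad(grid, state$sig$sig_th)
  Fr <- -2 * grid$b * state$sig$sig_r[n]
  structure(list(Fp = Fp, Fth = Fth, Fr = Fr, closure = Fp - (Fth + Fr)),
            class = "porocyl_forces")
}

#' @export
print.porocyl_forces <- function(x, ...) {
  cat(sprintf("<porocyl force balance: Fp = %.6g, Fth = %.6g, Fr = %.6g, closure = %.3g>\n",
              x$Fp, x$Fth, x$Fr, x$closure))
  invisible(x)
}

#' Solid-volume conservation defect
#'
#' Returns `integral_a^b 2 r (1 - phi_f) dr - (1 - a0^2)(1 - phi0)` (the
#' factor pi cancels). Rigorous-kinematics states satisfy this identically
#' (up to quadrature roundoff); linearized-kinematics states generally carry
#' a nonzero defect because the linearized porosity-displacement relation is
#' not rigorously mass conservative.
#'
#' @param state A converged `porocyl_state`.
#' @export
mass_conservation_defect <- function(state) {
  grid <- state$grid
  phi0 <- state$problem$material$phi0
  grid_quad(grid, 2 * grid$r * (1 - state$phi)) -
    (1 - state$problem$a0^2) * (1 - phi0)
}
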