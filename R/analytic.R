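# Closed-form and semi-analytic steady states for constant permeability.
#
# With constant (dimensionless) permeability the steady displacement ODE
#   u'' + u'/r - u/r^2 = -q/r
# is linear, with general solution
#   u(r) = c1*r + c2/r - (q/2) * r * log(r).
# For linearized kinematics (L-k0) the domain is the reference annulus
# [a0, 1] and the boundary conditions are linear in (c1, c2): the solution is
# fully closed-form. For rigorous kinematics (Q-k0) the same family holds on
# the unknown deformed annulus [a, b], and (c1, c2, a[, b][, q]) satisfy a
# small nonlinear algebraic system solved by damped Newton iteration seeded
# from the linearized solution.

analytic_u <- function(r, c1, c2, q) c1 * r + c2 / r - (q / 2) * r * log(r)
analytic_du <- function(r, c1, c2, q) c1 - c2 / r^2 - (q / 2) * (log(r) + 1)
analytic_sig_r <- function(r, c1, c2, q, gamma) {
  analytic_du(r, c1, c2, q) + gamma * analytic_u(r, c1, c2, q) / r
}

#' Flow rate through a rigid cylinder
#'
#' The reference flow rate `q0 = dp / log(1/a0)` driven by a pressure drop
#' `dp` across a rigid annulus of inner radius `a0` (outer radius 1). This is
#' also the prediction of classical linear poroelasticity (L-k0) for any
#' outer boundary condition.
#'
#' @param dp Pressure drop (>= 0).
#' @param a0 Inner radius, in (0, 1).
#' @examples
#' rigid_flow_rate(0.025, 0.85)
#' @export
rigid_flow_rate <- function(dp, a0) {
  stopifnot(all(dp >= 0))
  if (any(a0 <= 0) || any(a0 >= 1))
    porocyl_stop("singular_geometry",
                 "rigid flow rate requires 0 < a0 < 1 (diverges as a0 -> 1)")
  dp / log(1 / a0)
}

#' Pressure drop across an annulus at constant permeability
#'
#' `dp = q * log(b/a)`; the constant-permeability form of the general
#' quadrature relation between flow rate and pressure drop.
#'
#' @param q Flow rate.
#' @param a,b Deformed inner and outer radii, `0 < a < b`.
#' @export
dp_q_constant_k <- function(q, a, b) {
  stopifnot(all(a > 0), all(a < b))
  q * log(b / a)
}

#' Closed-form steady state of the classical linear-poroelastic model (L-k0)
#'
#' @param prob A [problem()] with model `"L-k0"`.
#' @param n_nodes Number of collocation nodes on which to tabulate the
#'   closed-form fields (for uniform post-processing).
#' @param mapping Node mapping, as in [numerics_config()].
#' @return A `porocyl_state`.
#' @export
solve_L_k0 <- function(prob, n_nodes = 129L, mapping = "auto") {
  if (prob$model$label != "L-k0")
    porocyl_stop("illegal_model", "solve_L_k0 requires the L-k0 model")
  a0 <- prob$a0
  gamma <- prob$material$gamma
  if (prob$drive$kind == "pressure_drop") {
    dp <- prob$drive$value
    q <- rigid_flow_rate(dp, a0)
  } else {
    q <- prob$drive$value
    dp <- dp_q_constant_k(q, a0, 1)
  }
  cc <- L_k0_constants(a0, gamma, q, prob$bc, prob$sig_star)
  grid <- build_grid(n_nodes, a0, 1, resolve_mapping(mapping, a0))
  us <- analytic_u(grid$r, cc[1], cc[2], q)
  # reported deformed radii follow the linearized convention
  st <- make_state(prob, grid, us,
                   a = a0 + analytic_u(a0, cc[1], cc[2], q),
                   b = 1 + analytic_u(1, cc[1], cc[2], q),
                   q = q, dp = dp, converged = TRUE, residual_norm = 0,
                   newton_iters = 0L, method = "analytic")
  st$constants <- list(c1 = cc[1], c2 = cc[2])
  st
}

# (c1, c2) from the two linear boundary conditions
L_k0_constants <- function(a0, gamma, q, bc, sig_star) {
  # sig_r(r) = (1+g) c1 - (1-g) c2 / r^2 - (q/2) [(1+g) log r + 1]
  A <- matrix(0, 2, 2)
  rhs <- numeric(2)
  A[1, ] <- c(1 + gamma, -(1 - gamma) / a0^2)
  rhs[1] <- (q / 2) * ((1 + gamma) * log(a0) + 1)
  if (bc == "unconstrained") {
    A[2, ] <- c(1 + gamma, -(1 - gamma))
    rhs[2] <- sig_star + q / 2
  } else {
    A[2, ] <- c(1, 1)   # u(1) = 0
    rhs[2] <- 0
  }
  as.numeric(solve(A, rhs))
}

#' Semi-analytic steady state of the quasi-linear constant-permeability model
#' (Q-k0)
#'
#' The displacement retains the constant-permeability closed form but lives on
#' the unknown deformed annulus `[a, b]`; the integration constants, deformed
#' radii and (for an imposed pressure drop) the flow rate satisfy a small
#' nonlinear algebraic system closed by the kinematic conditions
#' `u(a) = a - a0`, `u(b) = b - 1` and the drive relation `dp = q log(b/a)`.
#'
#' @param prob A [problem()] with model `"Q-k0"`.
#' @param numerics A [numerics_config()] (tolerances, node count for the
#'   tabulated output grid).
#' @param branch `"less"` (default) seeds Newton from the linearized solution;
#'   `"more"` seeds a strongly deformed iterate to aim for the more-deformed
#'   branch where the imposed pressure drop admits two solutions.
#' @return A `porocyl_state`.
#' @export
solve_Q_k0 <- function(prob, numerics = numerics_config(), branch = c("less", "more")) {
  if (prob$model$label != "Q-k0")
    porocyl_stop("illegal_model", "solve_Q_k0 requires the Q-k0 model")
  branch <- match.arg(branch)
  a0 <- prob$a0
  gamma <- prob$material$gamma
  bc <- prob$bc
  dp_driven <- prob$drive$kind == "pressure_drop"
  drv <- prob$drive$value

  if (drv == 0) return(zero_state(prob, numerics))

  # seed from the linearized solution
  probL <- problem("L-k0", a0 = a0, bc = bc, gamma = gamma,
                   phi0 = prob$material$phi0, sig_star = prob$sig_star,
                   q = if (dp_driven) NULL else drv,
                   dp = if (dp_driven) drv else NULL)
  stL <- solve_L_k0(probL, n_nodes = 17L)
  c0 <- c(stL$constants$c1, stL$constants$c2)
  a_g <- max(stL$a, a0 * 0.2)
  b_g <- if (bc == "unconstrained") max(stL$b, a_g * 1.01) else 1
  q_g <- stL$q
  if (branch == "more") {
    # aim beyond the fold: strongly expanded inner radius, larger flow rate
    a_g <- a0 + 0.6 * (1 - a0)
    q_g <- 8 * q_g
  }

  x0 <- c(c0, a_g)
  if (bc == "unconstrained") x0 <- c(x0, b_g)
  if (dp_driven) x0 <- c(x0, q_g)

  fn <- function(x) {
    c1 <- x[1]; c2 <- x[2]; a <- x[3]
    b <- if (bc == "unconstrained") x[4] else 1
    q <- if (dp_driven) x[length(x)] else drv
    if (!is.finite(a) || !is.finite(b) || a <= 0 || a >= b)
      return(rep(NaN, length(x)))
    g <- c(analytic_sig_r(a, c1, c2, q, gamma),
           analytic_u(a, c1, c2, q) - (a - a0))
    if (bc == "unconstrained") {
      g <- c(g, analytic_sig_r(b, c1, c2, q, gamma) - prob$sig_star,
             analytic_u(b, c1, c2, q) - (b - 1))
    } else {
      g <- c(g, analytic_u(1, c1, c2, q))
    }
    if (dp_driven) g <- c(g, q * log(b / a) - drv)
    g
  }

  ns <- newton_solve(x0, fn, tol = numerics$tol, step_tol = numerics$step_tol,
                     max_iter = 100L, fd_step = numerics$fd_step)
  if (!ns$converged)
    porocyl_stop("no_convergence",
                 sprintf("Q-k0 algebraic system did not converge (best residual %.3g)",
                         ns$residual_norm))
  x <- ns$x
  c1 <- x[1]; c2 <- x[2]; a <- x[3]
  b <- if (bc == "unconstrained") x[4] else 1
  q <- if (dp_driven) x[length(x)] else drv
  dp <- if (dp_driven) drv else dp_q_constant_k(q, a, b)
  grid <- build_grid(numerics$n_nodes, a, b,
                     resolve_mapping(numerics$mapping, a0))
  us <- analytic_u(grid$r, c1, c2, q)
  st <- make_state(prob, grid, us, a = a, b = b, q = q, dp = dp,
                   converged = TRUE, residual_norm = ns$residual_norm,
                   newton_iters = ns$iters, method = "semi-analytic")
  st$constants <- list(c1 = c1, c2 = c2)
  st
}
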