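# Chebyshev spectral-collocation + Newton solver for all six model variants.
#
# The steady displacement ODE (linear elasticity)
#   u'' + u'/r - u/r^2 = -q / (r * ktilde[phi(u)])
# or its Hencky counterpart is collocated on Gauss-Lobatto nodes mapped to
# the (possibly unknown) deformed annulus [a, b]. The unknown vector is the
# nodal displacement plus, depending on model and drive, the deformed radii
# and the flow rate; boundary rows replace the ODE residual at the endpoint
# nodes and the extra scalars get their own closure rows (kinematic
# conditions and the imposed-pressure-drop quadrature constraint). Inside the
# solver the ODE rows are scaled by r, which removes the 1/r amplification of
# roundoff near a small inner radius without changing the solution.

#' Collocated ODE residual for linear-elasticity models (L and Q)
#'
#' Evaluates `u'' + u'/r - u/r^2 + q/(r * ktilde(phi))` at the grid nodes,
#' with the porosity computed from the linearized or rigorous
#' displacement-porosity relation according to `model$kinematics` and the
#' permeability law according to `model$permeability`. Vanishes at a steady
#' state of any L or Q model.
#'
#' @param us Nodal displacement on `grid`.
#' @param grid A [build_grid()] grid.
#' @param q Dimensionless flow rate.
#' @param model A `porocyl_model` with `elasticity = "linear"`.
#' @param mat A [material()].
#' @return Nodal residual vector.
#' @export
ode_residual_linear <- function(us, grid, q, model, mat) {
  stopifnot(model$elasticity == "linear")
  r <- grid$r
  dus <- grid_deriv(grid, us)
  d2us <- grid_deriv(grid, dus)
  phi <- porosity_field(us, dus, r, mat$phi0, model$kinematics)
  ktil <- permeability(phi, model$permeability, mat$phi0)
  d2us + dus / r - us / r^2 + q / (r * ktil)
}

#' Collocated ODE residual for Hencky-elasticity models (N)
#'
#' Evaluates `u''` minus the Hencky right-hand side
#' \deqn{\frac{(1-\lambda_\theta/\lambda_r)[\ln\lambda_r +
#'   \Gamma\ln\lambda_\theta - \Gamma] + (1-\Gamma)\ln(\lambda_\theta/\lambda_r)
#'   - q\lambda_r\lambda_\theta / \tilde k}{\lambda_r r
#'   \{1 - [\ln\lambda_r + \Gamma\ln\lambda_\theta]\}}}
#' at the grid nodes. Signals a `porocyl_hencky_singularity` error when the
#' denominator factor `1 - (ln lam_r + gamma ln lam_th)` falls below 1e-8 in
#' magnitude at any node.
#'
#' @inheritParams ode_residual_linear
#' @param model A `porocyl_model` with `elasticity = "hencky"` (rigorous
#'   kinematics).
#' @export
ode_residual_hencky <- function(us, grid, q, model, mat) {
  stopifnot(model$elasticity == "hencky", model$kinematics == "rigorous")
  r <- grid$r
  dus <- grid_deriv(grid, us)
  d2us <- grid_deriv(grid, dus)
  st <- stretches(us, dus, r)
  gamma <- mat$gamma
  lr <- log(st$lam_r); lt <- log(st$lam_th)
  den_fac <- 1 - (lr + gamma * lt)
  if (any(abs(den_fac) < 1e-8))
    porocyl_stop("hencky_singularity",
                 "Hencky ODE denominator vanishes: 1 - (ln lam_r + gamma ln lam_th) ~ 0")
  phi <- porosity_exact(st$J, mat$phi0)
  ktil <- permeability(phi, model$permeability, mat$phi0)
  num <- (1 - st$lam_th / st$lam_r) * (lr + gamma * lt - gamma) +
    (1 - gamma) * (lt - lr) - q * st$lam_r * st$lam_th / ktil
  d2us - num / (st$lam_r * r * den_fac)
}

#' Imposed-pressure-drop constraint residual
#'
#' The steady pressure drop obeys `dp = q * integral_a^b dr / (r * ktilde)`;
#' this returns `q * integral - target_dp` by Clenshaw-Curtis quadrature on
#' the state's grid, the scalar constraint row used when the drive is an
#' imposed pressure drop.
#'
#' @param state A `porocyl_state` (or any list with `grid`, `q`, `ktilde`).
#' @param grid Optional grid override (defaults to `state$grid`).
#' @param target_dp Imposed pressure drop.
#' @export
enforce_pressure_drop <- function(state, grid = state$grid, target_dp) {
  state$q * grid_quad(grid, 1 / (grid$r * state$ktilde)) - target_dp
}

# --- internal residual assembly -------------------------------------------

# layout of the unknown vector for a given problem/drive
unknown_layout <- function(prob, n) {
  rigorous <- prob$model$kinematics == "rigorous"
  idx <- list(us = seq_len(n), a = NULL, b = NULL, q = NULL)
  k <- n
  if (rigorous) { k <- k + 1L; idx$a <- k }
  if (rigorous && prob$bc == "unconstrained") { k <- k + 1L; idx$b <- k }
  if (prob$drive$kind == "pressure_drop") { k <- k + 1L; idx$q <- k }
  idx$total <- k
  idx
}

# full residual vector at drive value `v` (q or dp per prob$drive$kind);
# returns NaNs on kinematically inadmissible iterates so the line search
# backtracks. ODE rows are scaled by r.
assemble_residual <- function(x, prob, layout, base, mapping, v) {
  n <- length(layout$us)
  us <- x[layout$us]
  model <- prob$model
  mat <- prob$material
  a0 <- prob$a0
  a <- if (is.null(layout$a)) a0 else x[layout$a]
  b <- if (is.null(layout$b)) {
    if (model$kinematics == "rigorous") 1 else 1
  } else x[layout$b]
  q <- if (is.null(layout$q)) v else x[layout$q]
  if (model$kinematics == "linearized") { a <- a0; b <- 1 }
  if (!is.finite(a) || !is.finite(b) || a <= 0 || a >= b)
    return(rep(NaN, layout$total))

  grid <- build_grid(n, a, b, mapping, base = base)
  r <- grid$r
  dus <- grid_deriv(grid, us)

  rigorous <- model$kinematics == "rigorous"
  if ((rigorous || model$elasticity == "hencky") &&
      (any(dus >= 1 - 1e-12) || any(us >= r * (1 - 1e-12))))
    return(rep(NaN, layout$total))

  phi <- porosity_field(us, dus, r, mat$phi0, model$kinematics, strict = FALSE)
  ktil <- permeability_clamped(phi, model$permeability, mat$phi0)

  d2us <- grid_deriv(grid, dus)
  if (model$elasticity == "linear") {
    core <- r * d2us + dus - us / r + q / ktil
  } else {
    lam_r <- 1 / (1 - dus)
    lam_th <- 1 / (1 - us / r)
    gamma <- mat$gamma
    lr <- log(lam_r); lt <- log(lam_th)
    den_fac <- 1 - (lr + gamma * lt)
    if (any(abs(den_fac) < 1e-8)) return(rep(NaN, layout$total))
    num <- (1 - lam_th / lam_r) * (lr + gamma * lt - gamma) +
      (1 - gamma) * (lt - lr) - q * lam_r * lam_th / ktil
    core <- r * d2us - num / (lam_r * den_fac)
  }

  sig <- stress_field(us, dus, r, mat$gamma, model$elasticity)
  res <- core
  res[1] <- sig$sig_r[1]                       # inner boundary: free surface
  res[n] <- if (prob$bc == "unconstrained") {
    sig$sig_r[n] - prob$sig_star               # applied outer traction
  } else {
    us[n]                                      # fixed outer boundary
  }
  extras <- numeric(0)
  if (!is.null(layout$a)) extras <- c(extras, us[1] - (a - a0))
  if (!is.null(layout$b)) extras <- c(extras, us[n] - (b - 1))
  if (!is.null(layout$q))
    extras <- c(extras, q * grid_quad(grid, 1 / (r * ktil)) - v)
  c(res, extras)
}

# --- analytic Jacobian -----------------------------------------------------
#
# The residual depends on the nodal displacement only through pointwise
# functions of (u, u' = A u, u'' = A A u) with A the mapped differentiation
# matrix, so the displacement block of the Jacobian is assembled exactly from
# chain-rule diagonals; only the few scalar columns (a, b, q), whose
# perturbations move the grid smoothly, are finite-differenced. A purely
# finite-difference Jacobian is unreliable here: the boundary stress rows
# carry D-matrix entries of order 2 n^2 / (b - a), so a nodal perturbation h
# incurs an O(h^2 (n^2/(b-a))^3) truncation error that the system's
# conditioning then amplifies into a stalled line search on fine grids.

# derivative of the clamped permeability w.r.t. porosity (zero when clamped
# or for the constant law)
dktilde_dphi <- function(phi, law, phi0, floor = 1e-6, ceil = 1 - 1e-6) {
  if (law == "constant") return(rep(0, length(phi)))
  out <- numeric(length(phi))
  inside <- phi > floor & phi < ceil
  k <- permeability(phi[inside], law, phi0)
  out[inside] <- k * (3 / phi[inside] + 2 / (1 - phi[inside]))
  out
}

assemble_jacobian <- function(x, prob, layout, base, mapping, v) {
  n <- length(layout$us)
  us <- x[layout$us]
  model <- prob$model
  mat <- prob$material
  a0 <- prob$a0
  a <- if (is.null(layout$a)) a0 else x[layout$a]
  b <- if (is.null(layout$b)) 1 else x[layout$b]
  q <- if (is.null(layout$q)) v else x[layout$q]
  if (model$kinematics == "linearized") { a <- a0; b <- 1 }
  grid <- build_grid(n, a, b, mapping, base = base)
  r <- grid$r
  A <- grid$D / grid$drdxi
  dus <- as.numeric(A %*% us)
  gamma <- mat$gamma
  phi0 <- mat$phi0
  law <- model$permeability

  phi <- porosity_field(us, dus, r, phi0, model$kinematics, strict = FALSE)
  ktil <- permeability_clamped(phi, law, phi0)
  dkdphi <- dktilde_dphi(phi, law, phi0)

  rA2 <- (r * A) %*% A
  if (model$elasticity == "linear") {
    if (model$kinematics == "linearized") {
      dphi_ds <- rep(1 - phi0, n)
      dphi_dw <- rep(1 - phi0, n)
    } else {
      lam_r <- 1 / (1 - dus)
      lam_th <- 1 / (1 - us / r)
      dphi_ds <- (1 - phi0) / lam_th
      dphi_dw <- (1 - phi0) / lam_r
    }
    t_perm <- -q * dkdphi / ktil^2
    Jus <- rA2 + A - diag(1 / r, n) +
      (t_perm * dphi_ds) * A + diag(t_perm * dphi_dw / r, n)
    # boundary stress rows: sig_r = u' + gamma u/r
    row_in <- A[1, ]; row_in[1] <- row_in[1] + gamma / r[1]
    row_out <- A[n, ]; row_out[n] <- row_out[n] + gamma / r[n]
  } else {
    lam_r <- 1 / (1 - dus)
    lam_th <- 1 / (1 - us / r)
    lr <- log(lam_r); lt <- log(lam_th)
    den_fac <- 1 - (lr + gamma * lt)
    P <- lr + gamma * lt - gamma
    num <- (1 - lam_th / lam_r) * P + (1 - gamma) * (lt - lr) -
      q * lam_r * lam_th / ktil
    den <- lam_r * den_fac
    dphi_ds <- (1 - phi0) / lam_th
    dphi_dw <- (1 - phi0) / lam_r
    dnum_ds <- lam_th * P + (1 - lam_th / lam_r) * lam_r - (1 - gamma) * lam_r -
      q * lam_th * lam_r^2 / ktil +
      q * lam_r * lam_th / ktil^2 * dkdphi * dphi_ds
    dnum_dw <- -lam_th^2 * P / lam_r + gamma * lam_th * (1 - lam_th / lam_r) +
      (1 - gamma) * lam_th - q * lam_r * lam_th^2 / ktil +
      q * lam_r * lam_th / ktil^2 * dkdphi * dphi_dw
    dden_ds <- lam_r^2 * (den_fac - 1)
    dden_dw <- -gamma * lam_r * lam_th
    dG_ds <- -(dnum_ds * den - num * dden_ds) / den^2
    dG_dw <- -(dnum_dw * den - num * dden_dw) / den^2
    Jus <- rA2 + dG_ds * A + diag(dG_dw / r, n)
    # Hencky stress row: sig_r = (ln lam_r + gamma ln lam_th) / J
    Jdet <- lam_r * lam_th
    sig_r <- (lr + gamma * lt) / Jdet
    ds_ds <- lam_r / Jdet - sig_r * lam_r
    ds_dw <- gamma * lam_th / Jdet - sig_r * lam_th
    row_in <- ds_ds[1] * A[1, ]; row_in[1] <- row_in[1] + ds_dw[1] / r[1]
    row_out <- ds_ds[n] * A[n, ]; row_out[n] <- row_out[n] + ds_dw[n] / r[n]
  }

  Jus[1, ] <- row_in
  if (prob$bc == "unconstrained") {
    Jus[n, ] <- row_out
  } else {
    Jus[n, ] <- 0; Jus[n, n] <- 1
  }

  J <- matrix(0, layout$total, layout$total)
  J[seq_len(n), seq_len(n)] <- Jus
  k <- n
  if (!is.null(layout$a)) { k <- k + 1L; J[k, 1] <- 1 }
  if (!is.null(layout$b)) { k <- k + 1L; J[k, n] <- 1 }
  if (!is.null(layout$q)) {
    k <- k + 1L
    if (law != "constant") {
      if (model$kinematics == "linearized") {
        dphi_ds <- rep(1 - phi0, n); dphi_dw <- rep(1 - phi0, n)
      }
      cvec <- -q * grid$w * grid$drdxi * dkdphi / (r * ktil^2)
      J[k, seq_len(n)] <- as.numeric((cvec * dphi_ds) %*% A)
      J[k, seq_len(n)] <- J[k, seq_len(n)] + cvec * dphi_dw / r
    }
  }

  # scalar columns (a, b, q) by central differences: grid perturbations are
  # smooth, without the D-matrix step amplification of the nodal columns
  scalars <- c(layout$a, layout$b, layout$q)
  for (j in scalars) {
    h <- 1e-7 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (assemble_residual(xp, prob, layout, base, mapping, v) -
                 assemble_residual(xm, prob, layout, base, mapping, v)) / (2 * h)
  }
  J
}

#' Solve a steady state by Chebyshev collocation and Newton iteration
#'
#' General solver for all six model variants, both outer boundary conditions
#' and both drive modes. The load (flow rate or pressure drop) is ramped
#' geometrically from 1% of its target over `numerics$ramp_steps`
#' warm-started Newton solves, with adaptive bisection of a load step that
#' fails to converge; imposed-pressure-drop problems above the fold therefore
#' terminate with a non-converged diagnostic state rather than jumping
#' branches.
#'
#' @param prob A [problem()].
#' @param numerics A [numerics_config()].
#' @return A `porocyl_state`; inspect `$converged` (a non-converged return
#'   carries the best iterate and `$residual_norm`).
#' @examples
#' st <- solve_steady(problem("Q-kKC", a0 = 0.85, bc = "constrained", dp = 0.025),
#'                    numerics_config(n_nodes = 33, ramp_steps = 4))
#' st$q
#' @export
solve_steady <- function(prob, numerics = numerics_config()) {
  v_target <- prob$drive$value
  if (v_target == 0) return(zero_state(prob, numerics))
  n <- numerics$n_nodes
  mapping <- resolve_mapping(numerics$mapping, prob$a0)
  cd <- cheb_diff(n)
  base <- list(xi = cd$xi, D = cd$D, w = clenshaw_curtis(n))
  layout <- unknown_layout(prob, n)
  dp_driven <- prob$drive$kind == "pressure_drop"

  x <- numeric(layout$total)
  if (!is.null(layout$a)) x[layout$a] <- prob$a0
  if (!is.null(layout$b)) x[layout$b] <- 1
  if (!is.null(layout$q)) x[layout$q] <- rigid_flow_rate(v_target, prob$a0)

  m <- numerics$ramp_steps
  loads <- if (m == 1L) v_target else v_target * 0.01^((m - seq_len(m)) / (m - 1))
  total_iters <- 0L
  v_done <- 0
  best <- NULL
  i <- 1L
  attempts <- 0L
  while (i <= length(loads)) {
    v <- loads[i]
    if (!is.null(layout$q) && v_done == 0)
      x[layout$q] <- rigid_flow_rate(v, prob$a0)
    fn <- function(z) assemble_residual(z, prob, layout, base, mapping, v)
    jac <- function(z) assemble_jacobian(z, prob, layout, base, mapping, v)
    ns <- newton_solve(x, fn, tol = numerics$tol, step_tol = numerics$step_tol,
                       max_iter = numerics$max_iter, fd_step = numerics$fd_step,
                       jac = jac)
    total_iters <- total_iters + ns$iters
    attempts <- attempts + 1L
    if (ns$converged) {
      x <- ns$x
      v_done <- v
      best <- ns
      i <- i + 1L
    } else {
      # bisect the failed load step (physical end of branch if steps collapse)
      v_mid <- (v_done + v) / 2
      if (attempts > 12L * m || (v - v_done) / v_target < 1e-6) {
        st <- spectral_state(prob, ns$x, layout, base, mapping,
                             v, dp_driven, converged = FALSE,
                             residual_norm = ns$residual_norm,
                             iters = total_iters)
        st$diagnostics <- list(reason = ns$reason, load_reached = v_done,
                               load_target = v_target, history = ns$history)
        return(st)
      }
      loads <- c(loads[seq_len(i - 1L)], v_mid, loads[i:length(loads)])
    }
  }
  spectral_state(prob, x, layout, base, mapping, v_target, dp_driven,
                 converged = TRUE, residual_norm = best$residual_norm,
                 iters = total_iters)
}

spectral_state <- function(prob, x, layout, base, mapping, v, dp_driven,
                           converged, residual_norm, iters) {
  n <- length(layout$us)
  us <- x[layout$us]
  a <- if (is.null(layout$a)) prob$a0 else x[layout$a]
  b <- if (is.null(layout$b)) 1 else x[layout$b]
  q <- if (is.null(layout$q)) v else x[layout$q]
  dp <- if (dp_driven) v else NULL
  if (prob$model$kinematics == "linearized") {
    grid <- build_grid(n, prob$a0, 1, mapping, base = base)
    # reported deformed radii follow the linearized convention
    st <- make_state(prob, grid, us, a = prob$a0 + us[1], b = 1 + us[n],
                     q = q, dp = dp, converged = converged,
                     residual_norm = residual_norm, newton_iters = iters,
                     method = "spectral")
  } else {
    grid <- build_grid(n, a, b, mapping, base = base)
    st <- make_state(prob, grid, us, a = a, b = b, q = q, dp = dp,
                     converged = converged, residual_norm = residual_norm,
                     newton_iters = iters, method = "spectral")
  }
  st
}
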