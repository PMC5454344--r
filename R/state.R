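# Construction of converged steady-state objects shared by the analytic and
# spectral solvers. A porocyl_state stores the nodal displacement field on its
# collocation grid together with the deformed geometry, drive scalars, derived
# porosity/stress/pressure fields and convergence diagnostics.

make_state <- function(prob, grid, us, a, b, q, dp = NULL,
                       converged = TRUE, residual_norm = NA_real_,
                       newton_iters = NA_integer_, method = "analytic") {
  model <- prob$model
  mat <- prob$material
  dus <- grid_deriv(grid, us)
  r <- grid$r

  kin_ok <- all(dus < 1) && all(us < r)
  phi <- porosity_field(us, dus, r, mat$phi0,
                        kinematics = model$kinematics, strict = FALSE)
  phi_ok <- all(phi > 0) && all(phi < 1)
  law <- model$permeability
  ktil <- permeability_clamped(phi, law, mat$phi0)
  sig <- if (model$elasticity == "hencky" && !kin_ok) {
    list(sig_r = rep(NA_real_, grid$n), sig_th = rep(NA_real_, grid$n),
         sig_z = rep(NA_real_, grid$n))
  } else {
    stress_field(us, dus, r, mat$gamma, model$elasticity)
  }

  if (is.null(dp)) dp <- q * grid_quad(grid, 1 / (r * ktil))

  # pressure by spectral antiderivative of dp/dr = -q/(r k), gauged p(b) = 0
  A <- grid$D / grid$drdxi
  A[grid$n, ] <- 0
  A[grid$n, grid$n] <- 1
  rhs <- -q / (r * ktil)
  rhs[grid$n] <- 0
  p <- tryCatch(as.numeric(solve(A, rhs)),
                error = function(e) rep(NA_real_, grid$n))

  ok <- converged && kin_ok && (phi_ok || law == "constant" &&
                                  model$kinematics == "linearized")
  # linearized-kinematics states may leave (0,1) porosity at extreme loads
  # without invalidating the (linear) solve; rigorous states must not.
  if (model$kinematics == "rigorous") ok <- converged && kin_ok && phi_ok

  structure(list(problem = prob, model = model, grid = grid,
                 us = us, dus = dus, a = a, b = b, q = q, dp = dp,
                 phi = phi, ktilde = ktil, sig = sig, p = p,
                 converged = ok, physical = kin_ok && phi_ok,
                 residual_norm = residual_norm, newton_iters = newton_iters,
                 method = method),
            class = "porocyl_state")
}

#' @export
print.porocyl_state <- function(x, ...) {
  cat(sprintf("<porocyl steady state: %s, %s BC, a0 = %g>\n",
              x$model$label, x$problem$bc, x$problem$a0))
  cat(sprintf("  a = %.8g, b = %.8g, q = %.8g, dp = %.8g\n",
              x$a, x$b, x$q, x$dp))
  cat(sprintf("  converged = %s (residual %.3g, %s iters, %d nodes, %s)\n",
              x$converged, x$residual_norm,
              ifelse(is.na(x$newton_iters), "-", x$newton_iters),
              x$grid$n, x$method))
  invisible(x)
}

# zero-load state: the reference configuration is an exact solution
zero_state <- function(prob, numerics) {
  mapping <- resolve_mapping(numerics$mapping, prob$a0)
  grid <- build_grid(numerics$n_nodes, prob$a0, 1, mapping)
  make_state(prob, grid, us = rep(0, grid$n), a = prob$a0, b = 1,
             q = 0, dp = 0, converged = TRUE, residual_norm = 0,
             newton_iters = 0L, method = "trivial")
}

resolve_mapping <- function(mapping, a0) {
  if (mapping != "auto") return(mapping)
  if (a0 <= 1e-2) "log_radius" else "affine"
}
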