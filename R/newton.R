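# Damped Newton iteration with dense finite-difference Jacobian.
#
# The systems solved here are small (a handful of scalars for the analytic
# constant-permeability family, ~n_nodes + 3 for the collocation BVP), so a
# dense central-difference Jacobian with direct solve is both simple and fast.
# A backtracking line search (halving, up to 8 times) guards against residual
# increase or non-finite trial residuals from transient kinematic overshoot.

fd_jacobian <- function(fn, x, fd_step) {
  m <- length(x)
  J <- matrix(NA_real_, m, m)
  for (j in seq_len(m)) {
    h <- fd_step * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# fn(x) must return a residual vector of the same length as x; non-finite
# entries are tolerated (treated as line-search rejection). Large-displacement
# fine-grid solves can hit a roundoff floor slightly above tol: a line search
# that stalls within one decade of tol is accepted as converged-at-floor,
# with the achieved residual reported.
newton_solve <- function(x0, fn, tol = 1e-10, step_tol = 1e-9,
                         max_iter = 30L, fd_step = 1e-7, stall_factor = 30,
                         jac = NULL) {
  x <- x0
  Fx <- suppressWarnings(fn(x))
  if (!all(is.finite(Fx))) {
    return(list(x = x, converged = FALSE, residual_norm = Inf, iters = 0L,
                history = Inf, reason = "non-finite residual at start"))
  }
  nrm <- max(abs(Fx))
  history <- nrm
  iters <- 0L
  reason <- "max_iter"
  while (iters < max_iter) {
    if (nrm <= tol) { reason <- "converged"; break }
    J <- if (is.null(jac)) fd_jacobian(fn, x, fd_step) else jac(x)
    if (!all(is.finite(J))) { reason <- "non-finite Jacobian"; break }
    dx <- tryCatch(solve(J, -Fx), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) { reason <- "singular Jacobian"; break }
    t <- 1
    accepted <- FALSE
    for (ls in 0:8) {
      xt <- x + t * dx
      Ft <- suppressWarnings(fn(xt))
      if (all(is.finite(Ft)) && max(abs(Ft)) < nrm) {
        x <- xt; Fx <- Ft; nrm <- max(abs(Ft)); accepted <- TRUE
        break
      }
      t <- t / 2
    }
    iters <- iters + 1L
    history <- c(history, nrm)
    if (!accepted) { reason <- "line search stalled"; break }
    if (max(abs(t * dx)) <= step_tol && nrm <= tol) { reason <- "converged"; break }
  }
  converged <- nrm <= tol
  if (converged) reason <- "converged"
  if (!converged && reason == "line search stalled" && nrm <= stall_factor * tol) {
    converged <- TRUE
    reason <- "stalled at roundoff floor"
  }
  list(x = x, converged = converged, residual_norm = nrm, iters = iters,
       history = history, reason = reason)
}
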