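# Parameter sweeps and branch structure.
#
# At fixed geometry the map q -> dp is single-valued while its inverse is
# double-valued below the fold (an unconstrained annulus supports at most a
# finite pressure drop dp_max). All branch structure is therefore resolved by
# sweeping the imposed flow rate q with warm-started Newton solves, and the
# two solutions at an imposed pressure drop are recovered by root-finding on
# the rising and falling sides of the dp(q) curve. This avoids
# pseudo-arclength continuation entirely.

#' Trace a pressure-drop/flow-rate load curve at fixed geometry
#'
#' Solves a sequence of imposed-flow-rate problems along an increasing
#' `q_grid`, warm-starting each solve from the previous solution, and records
#' the resulting pressure drop of each converged state. The curve is
#' truncated (and flagged) at the first non-convergent point, which is
#' treated as the physical end of the branch.
#'
#' @param a0 Initial inner radius.
#' @param model Model label or `porocyl_model`.
#' @param bc `"unconstrained"` or `"constrained"`.
#' @param q_grid Increasing flow rates, starting near zero.
#' @param numerics A [numerics_config()] (use a moderate node count; curves
#'   involve many solves).
#' @param gamma,phi0,sig_star Passed to [problem()].
#' @param keep_states Keep the full states (default) or summaries only.
#' @return Object of class `porocyl_load_curve` with fields `q`, `dp`,
#'   `states`, `truncated`.
#' @export
trace_load_curve <- function(a0, model, bc, q_grid,
                             numerics = numerics_config(n_nodes = 41L, ramp_steps = 1L),
                             gamma = 0.4, phi0 = 0.5, sig_star = 0,
                             keep_states = TRUE) {
  stopifnot(length(q_grid) >= 1, all(diff(q_grid) > 0), all(q_grid > 0))
  model <- parse_model(model)
  qs <- dps <- numeric(0)
  states <- list()
  truncated <- FALSE
  warm <- NULL
  for (q in q_grid) {
    st <- solve_q_warm(a0, model, bc, q, numerics, gamma, phi0, sig_star, warm)
    if (is.null(st) || !st$converged) { truncated <- TRUE; break }
    warm <- st
    qs <- c(qs, q)
    dps <- c(dps, st$dp)
    states[[length(states) + 1L]] <- if (keep_states) st else summarize_state(st)
  }
  if (!length(qs))
    porocyl_stop("no_convergence", "no point of the load curve converged")
  structure(list(a0 = a0, model = model, bc = bc, q = qs, dp = dps,
                 states = states, truncated = truncated),
            class = "porocyl_load_curve")
}

#' @export
print.porocyl_load_curve <- function(x, ...) {
  cat(sprintf("<porocyl load curve: %s (%s), a0 = %g, %d points%s>\n",
              x$model$label, x$bc, x$a0, length(x$q),
              if (x$truncated) ", truncated" else ""))
  cat(sprintf("  q in [%.4g, %.4g], dp in [%.4g, %.4g]\n",
              min(x$q), max(x$q), min(x$dp), max(x$dp)))
  invisible(x)
}

# one imposed-q solve, warm-started from a previous state when available
solve_q_warm <- function(a0, model, bc, q, numerics, gamma, phi0, sig_star,
                         warm = NULL) {
  prob <- problem(model, a0 = a0, bc = bc, q = q, gamma = gamma, phi0 = phi0,
                  sig_star = if (bc == "unconstrained") sig_star else 0)
  n <- numerics$n_nodes
  mapping <- resolve_mapping(numerics$mapping, a0)
  cd <- cheb_diff(n)
  base <- list(xi = cd$xi, D = cd$D, w = clenshaw_curtis(n))
  layout <- unknown_layout(prob, n)
  x <- numeric(layout$total)
  if (!is.null(layout$a)) x[layout$a] <- a0
  if (!is.null(layout$b)) x[layout$b] <- 1
  if (!is.null(warm) && warm$grid$n == n) {
    x[layout$us] <- warm$us
    if (!is.null(layout$a)) x[layout$a] <- warm$a
    if (!is.null(layout$b)) x[layout$b] <- warm$b
  }
  fn <- function(z) assemble_residual(z, prob, layout, base, mapping, q)
  jac <- function(z) assemble_jacobian(z, prob, layout, base, mapping, q)
  ns <- newton_solve(x, fn, tol = numerics$tol, step_tol = numerics$step_tol,
                     max_iter = numerics$max_iter, fd_step = numerics$fd_step,
                     jac = jac)
  if (!ns$converged && is.null(warm)) {
    # cold start at finite q: fall back to the ramped solver
    st <- solve_steady(prob, numerics_config(
      n_nodes = n, tol = numerics$tol, step_tol = numerics$step_tol,
      max_iter = numerics$max_iter, mapping = numerics$mapping,
      ramp_steps = 8L, fd_step = numerics$fd_step))
    return(if (st$converged) st else NULL)
  }
  if (!ns$converged) return(NULL)
  spectral_state(prob, ns$x, layout, base, mapping, q, dp_driven = FALSE,
                 converged = TRUE, residual_norm = ns$residual_norm,
                 iters = ns$iters)
}

#' Locate the fold (limit point) of a load curve
#'
#' For an unconstrained annulus the dp(q) curve rises to a maximum
#' supportable pressure drop `dp_max` and falls; the fold is located by
#' golden-section/parabolic refinement of the discrete maximum, re-solving
#' the BVP at each probe. For a constrained annulus dp(q) is monotone but q
#' saturates: the maximal achieved flow rate is reported instead. Signals a
#' `porocyl_no_fold` error when the unconstrained curve is monotone over the
#' grid (grid too short, or a genuinely fold-free model such as L-k0).
#'
#' @param curve A `porocyl_load_curve`.
#' @param dp_tol Refinement tolerance on dp (unconstrained).
#' @return Object of class `porocyl_fold`: unconstrained, fields `dp_max` and
#'   `q_at_fold`; constrained, fields `q_max` and `dp_at_qmax`.
#' @export
find_fold <- function(curve, dp_tol = 1e-6) {
  stopifnot(inherits(curve, "porocyl_load_curve"))
  if (curve$bc == "constrained") {
    return(structure(list(q_max = max(curve$q), dp_at_qmax = max(curve$dp),
                          bc = "constrained", truncated = curve$truncated),
                     class = "porocyl_fold"))
  }
  dp <- curve$dp
  i_max <- which.max(dp)
  if (i_max == length(dp) || all(diff(dp) > 0))
    porocyl_stop("no_fold",
                 "dp(q) is monotone over the grid: no fold bracketed")
  if (i_max == 1L)
    porocyl_stop("no_fold", "dp(q) decreasing from the first grid point")
  numerics <- numerics_config(n_nodes = curve$states[[1]]$grid$n, ramp_steps = 1L)
  env <- new.env()
  env$warm <- curve$states[[i_max]]
  dp_of_q <- function(q) {
    st <- solve_q_warm(curve$a0, curve$model, curve$bc, q, numerics,
                       curve$states[[1]]$problem$material$gamma,
                       curve$states[[1]]$problem$material$phi0,
                       curve$states[[1]]$problem$sig_star, env$warm)
    if (is.null(st)) return(NA_real_)
    env$warm <- st
    st$dp
  }
  opt <- stats::optimize(function(q) -dp_of_q(q),
                         interval = c(curve$q[i_max - 1L], curve$q[i_max + 1L]),
                         tol = dp_tol)
  dp_max <- max(-opt$objective, dp[i_max])   # refinement never loses the grid max
  structure(list(dp_max = dp_max, q_at_fold = opt$minimum, bc = "unconstrained"),
            class = "porocyl_fold")
}

#' @export
print.porocyl_fold <- function(x, ...) {
  if (x$bc == "unconstrained") {
    cat(sprintf("<porocyl fold: dp_max = %.8g at q = %.8g>\n", x$dp_max, x$q_at_fold))
  } else {
    cat(sprintf("<porocyl fold (constrained): q_max = %.8g reached at dp = %.8g%s>\n",
                x$q_max, x$dp_at_qmax,
                if (isTRUE(x$truncated)) " (branch end by non-convergence)" else ""))
  }
  invisible(x)
}

#' Both coexisting solutions at an imposed pressure drop
#'
#' Below the fold, an unconstrained annulus admits a less-deformed solution
#' (lower flow rate) and a more-deformed solution (higher flow rate) at the
#' same pressure drop. Both are recovered by root-finding in q on the rising
#' and falling sides of the dp(q) curve.
#'
#' @inheritParams trace_load_curve
#' @param target_dp Imposed pressure drop (must be below the fold).
#' @param q_grid Optional flow-rate grid for the underlying load curve;
#'   default 60 points geometric in `[1e-3 q0, 1e2 q0]` with
#'   `q0 = target_dp / log(1/a0)`.
#' @param q_tol Root-finding tolerance in q.
#' @return Object of class `porocyl_branch_pair` with fields `less`, `more`
#'   (states), `dp`, `fold`.
#' @export
solve_both_branches <- function(a0, model, bc = "unconstrained", target_dp,
                                numerics = numerics_config(n_nodes = 41L, ramp_steps = 1L),
                                q_grid = NULL, q_tol = 1e-8,
                                gamma = 0.4, phi0 = 0.5, sig_star = 0) {
  if (bc != "unconstrained")
    porocyl_stop("invalid_bc", "branch pairs exist only for the unconstrained BC")
  q0 <- rigid_flow_rate(target_dp, a0)
  if (is.null(q_grid))
    q_grid <- exp(seq(log(1e-3 * q0), log(1e2 * q0), length.out = 60L))
  curve <- trace_load_curve(a0, model, bc, q_grid, numerics,
                            gamma = gamma, phi0 = phi0, sig_star = sig_star)
  # extend the curve geometrically until the falling side drops below the
  # target (the tail of dp(q) can decay slowly), the branch ends by
  # non-convergence, or a generous flow-rate cap is reached
  while (!curve$truncated && utils::tail(curve$dp, 1) >= target_dp &&
         utils::tail(curve$q, 1) < 1e6 * q0) {
    q_ext <- utils::tail(curve$q, 1) * 10^(seq_len(12L) / 12L)
    ext <- tryCatch(
      trace_load_curve(a0, model, bc, q_ext, numerics, gamma = gamma,
                       phi0 = phi0, sig_star = sig_star),
      porocyl_no_convergence = function(e) NULL)
    if (is.null(ext)) break
    curve$q <- c(curve$q, ext$q)
    curve$dp <- c(curve$dp, ext$dp)
    curve$states <- c(curve$states, ext$states)
    curve$truncated <- ext$truncated
  }
  fold <- find_fold(curve)
  if (target_dp > fold$dp_max)
    porocyl_stop("above_fold",
                 sprintf("target dp = %g exceeds dp_max = %g", target_dp, fold$dp_max))
  env <- new.env(); env$warm <- NULL
  g <- function(q) {
    st <- solve_q_warm(a0, curve$model, bc, q, numerics, gamma, phi0,
                       sig_star, env$warm)
    if (is.null(st)) return(NA_real_)
    env$warm <- st
    env$last <- st
    st$dp - target_dp
  }
  # rising side
  i_lo <- which(curve$dp >= target_dp)[1]
  env$warm <- curve$states[[max(1L, i_lo - 1L)]]
  lo <- if (i_lo == 1L) min(q_grid) * 1e-3 else curve$q[i_lo - 1L]
  root_less <- stats::uniroot(g, interval = c(lo, fold$q_at_fold),
                              tol = q_tol, extendInt = "no")
  less <- env$last
  # falling side: bracket between the fold and a curve point below target
  after <- which(curve$q > fold$q_at_fold & curve$dp < target_dp)
  if (!length(after))
    porocyl_stop("single_solution",
                 "falling side of dp(q) not bracketed within the flow-rate range")
  env$warm <- curve$states[[after[1]]]
  root_more <- stats::uniroot(g, interval = c(fold$q_at_fold, curve$q[after[1]]),
                              tol = q_tol, extendInt = "no")
  more <- env$last
  if (less$q > more$q) { tmp <- less; less <- more; more <- tmp }
  structure(list(less = less, more = more, dp = target_dp, fold = fold),
            class = "porocyl_branch_pair")
}

#' @export
print.porocyl_branch_pair <- function(x, ...) {
  cat(sprintf("<porocyl branch pair at dp = %g: q_less = %.8g, q_more = %.8g (fold q = %.6g)>\n",
              x$dp, x$less$q, x$more$q, x$fold$q_at_fold))
  invisible(x)
}

#' Sweep the initial inner radius at fixed pressure drop
#'
#' Tabulates summary and force-balance diagnostics over a grid of initial
#' inner radii at an imposed pressure drop: one row per geometry for the
#' constrained boundary (a single solution always exists), and one row per
#' branch for the unconstrained boundary where the pair exists, with
#' above-fold geometries marked.
#'
#' @inheritParams solve_both_branches
#' @param a0_grid Initial inner radii within (0, 1).
#' @return A data.frame, one row per (a0, branch), with summary and force
#'   columns plus a `status` column (`"ok"`, `"above_fold"`, `"failed"`).
#' @export
sweep_a0 <- function(model, bc, target_dp, a0_grid,
                     numerics = numerics_config(n_nodes = 41L, ramp_steps = 6L),
                     gamma = 0.4, phi0 = 0.5, sig_star = 0) {
  if (!length(a0_grid))
    porocyl_stop("invalid_drive", "empty a0 grid")
  stopifnot(all(a0_grid > 0), all(a0_grid < 1))
  rows <- list()
  add_row <- function(a0, branch, status, st = NULL) {
    base <- list(a0 = a0, branch = branch, status = status)
    if (!is.null(st)) {
      sm <- summarize_state(st)
      fb <- force_balance(st)
      base <- c(base, sm[c("delta_a", "delta_wall", "phi_min", "phi_max",
                           "abs_sig_r_max", "abs_sig_th_max", "q", "dp", "q0")],
                list(Fp = fb$Fp, Fth = fb$Fth, Fr = fb$Fr, closure = fb$closure))
    } else {
      base <- c(base, stats::setNames(as.list(rep(NA_real_, 13L)),
                                      c("delta_a", "delta_wall", "phi_min", "phi_max",
                                        "abs_sig_r_max", "abs_sig_th_max", "q", "dp",
                                        "q0", "Fp", "Fth", "Fr", "closure")))
    }
    rows[[length(rows) + 1L]] <<- as.data.frame(base)
  }
  for (a0 in a0_grid) {
    if (bc == "constrained") {
      st <- tryCatch(solve_steady(problem(model, a0 = a0, bc = bc, dp = target_dp,
                                          gamma = gamma, phi0 = phi0), numerics),
                     porocyl_error = function(e) NULL)
      if (!is.null(st) && st$converged) add_row(a0, "single", "ok", st)
      else add_row(a0, "single", "failed")
    } else {
      bp <- tryCatch(
        solve_both_branches(a0, model, bc, target_dp, numerics,
                            gamma = gamma, phi0 = phi0, sig_star = sig_star),
        porocyl_above_fold = function(e) "above_fold",
        porocyl_error = function(e) NULL)
      if (inherits(bp, "porocyl_branch_pair")) {
        add_row(a0, "less", "ok", bp$less)
        add_row(a0, "more", "ok", bp$more)
      } else if (identical(bp, "above_fold")) {
        add_row(a0, "none", "above_fold")
      } else {
        add_row(a0, "none", "failed")
      }
    }
  }
  do.call(rbind, rows)
}
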