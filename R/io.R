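# Dimensional conversion, configuration, tabular writers, CLI backends and
# benchmark fixture generation.

#' Dimensional scales of a physical problem
#'
#' @param b0 Initial outer radius (length).
#' @param mu Fluid dynamic viscosity.
#' @param k0 Reference permeability.
#' @param M Oedometric (p-wave) modulus.
#' @return Object of class `porocyl_scales`, including the poroelastic
#'   timescale `Tpe = b0^2 mu / (k0 M)`.
#' @export
dimensional_scales <- function(b0, mu, k0, M) {
  vals <- c(b0 = b0, mu = mu, k0 = k0, M = M)
  if (any(!is.finite(vals)) || any(vals <= 0))
    porocyl_stop("invalid_scales", "all dimensional scales must be positive")
  structure(list(b0 = b0, mu = mu, k0 = k0, M = M,
                 Tpe = b0^2 * mu / (k0 * M)),
            class = "porocyl_scales")
}

#' Convert a dimensional drive to its dimensionless counterpart
#'
#' An injection rate per unit length `Qhat` maps to the dimensionless flow
#' rate `q = mu Qhat / (2 pi k0 M)`; a dimensional pressure drop maps to
#' `dp / M`. Both compare the injection pressure scale with the elastic
#' stiffness.
#'
#' @param scales A [dimensional_scales()].
#' @param Qhat Injection rate per unit length (supply exactly one of `Qhat`,
#'   `dp`).
#' @param dp Dimensional pressure drop.
#' @return A list with the dimensionless drive (`q` or `dp`) and `Tpe`.
#' @export
nondimensionalize <- function(scales, Qhat = NULL, dp = NULL) {
  stopifnot(inherits(scales, "porocyl_scales"))
  if (is.null(Qhat) == is.null(dp))
    porocyl_stop("invalid_drive", "supply exactly one of Qhat or dp")
  if (!is.null(Qhat)) {
    list(q = scales$mu * Qhat / (2 * pi * scales$k0 * scales$M),
         Tpe = scales$Tpe)
  } else {
    list(dp = dp / scales$M, Tpe = scales$Tpe)
  }
}

#' @rdname nondimensionalize
#' @param q Dimensionless flow rate to convert back (one of `q`, `dp`).
#' @export
dimensionalize <- function(scales, q = NULL, dp = NULL) {
  stopifnot(inherits(scales, "porocyl_scales"))
  if (is.null(q) == is.null(dp))
    porocyl_stop("invalid_drive", "supply exactly one of q or dp")
  if (!is.null(q)) {
    list(Qhat = q * 2 * pi * scales$k0 * scales$M / scales$mu)
  } else {
    list(dp = dp * scales$M)
  }
}

#' Build a problem from a flat configuration file
#'
#' Reads a YAML key/value document mirroring the CLI flags (`model`, `bc`,
#' `a0`, `gamma`, `phi0`, `sigstar`, and one of `q`/`dp`).
#'
#' @param path Path to a YAML file.
#' @return A `porocyl_problem`.
#' @export
problem_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  problem_from_opts(cfg)
}

problem_from_opts <- function(opts) {
  get <- function(k, default = NULL) if (!is.null(opts[[k]])) opts[[k]] else default
  problem(model = get("model"),
          a0 = as.numeric(get("a0")),
          bc = get("bc", "unconstrained"),
          q = if (!is.null(get("q"))) as.numeric(get("q")) else NULL,
          dp = if (!is.null(get("dp"))) as.numeric(get("dp")) else NULL,
          gamma = as.numeric(get("gamma", 0.4)),
          phi0 = as.numeric(get("phi0", 0.5)),
          sig_star = as.numeric(get("sigstar", 0)))
}

# 17 significant digits: enough for bit-stable round-trips of doubles
fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a radial-profile table
#'
#' CSV with columns `r`, `R_lagrangian`, `us`, `phi`, `sig_r`, `sig_th`,
#' `sig_z`, `p`, `vf`, written with 17 significant digits so re-reading
#' reproduces the nodal values exactly.
#'
#' @param state A converged `porocyl_state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(state, path) {
  df <- profile_frame(state)
  txt <- vapply(df, fmt17, character(nrow(df)))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1L)
  out <- rbind(colnames(df), txt)
  writeLines(apply(out, 1L, paste, collapse = ","), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

profile_frame <- function(state) {
  data.frame(r = state$grid$r,
             R_lagrangian = state$grid$r - state$us,
             us = state$us,
             phi = state$phi,
             sig_r = state$sig$sig_r,
             sig_th = state$sig$sig_th,
             sig_z = state$sig$sig_z,
             p = state$p,
             vf = fluid_velocity(state))
}

#' Write a JSON summary record for a converged state
#'
#' Keys match the summary and force-balance field names, plus convergence
#' metadata.
#'
#' @param state A converged `porocyl_state`.
#' @param path Output JSON path.
#' @export
write_summary <- function(state, path) {
  sm <- summarize_state(state)
  fb <- force_balance(state)
  rec <- c(unclass(sm),
           list(Fp = fb$Fp, Fth = fb$Fth, Fr = fb$Fr, closure = fb$closure,
                a = state$a, b = state$b,
                mass_defect = mass_conservation_defect(state),
                converged = state$converged,
                residual_norm = state$residual_norm,
                n_nodes = state$grid$n, method = state$method))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Solve one problem and write its artifacts (CLI backend)
#'
#' Backend of the `solve` subcommand of the shipped command-line script
#' (`system.file("cli", "porocyl.R", package = "porocyl")`). Solves the
#' problem described by `opts` (a named list mirroring the CLI flags,
#' or a config file via `opts$config`), writes `<out>_profile.csv` and
#' `<out>_summary.json`, and returns the state.
#'
#' @param opts Named list: `model`, `bc`, `a0`, one of `q`/`dp`, optional
#'   `gamma`, `phi0`, `sigstar`, `nodes`, `tol`, `out`, `config`.
#' @return The `porocyl_state`, invisibly. Signals an error (for a CLI,
#'   nonzero exit) on non-convergence.
#' @export
run_solve <- function(opts) {
  prob <- if (!is.null(opts$config)) problem_from_config(opts$config)
          else problem_from_opts(opts)
  num <- numerics_config(
    n_nodes = if (!is.null(opts$nodes)) as.integer(opts$nodes) else 129L,
    tol = if (!is.null(opts$tol)) as.numeric(opts$tol) else 1e-9)
  st <- if (prob$model$label == "L-k0") {
    solve_L_k0(prob, n_nodes = num$n_nodes)
  } else if (prob$model$label == "Q-k0") {
    solve_Q_k0(prob, num)
  } else {
    solve_steady(prob, num)
  }
  if (!st$converged)
    porocyl_stop("no_convergence",
                 sprintf("solve did not converge (residual %.3g, load reached %.3g)",
                         st$residual_norm,
                         if (!is.null(st$diagnostics)) st$diagnostics$load_reached else NA))
  out <- if (!is.null(opts$out)) opts$out else "porocyl"
  write_profile(st, paste0(out, "_profile.csv"))
  write_summary(st, paste0(out, "_summary.json"))
  invisible(st)
}

#' Sweep geometries and write a tabulated summary (CLI backend)
#'
#' Backend of the `sweep` subcommand: runs [sweep_a0()] over a geometry grid
#' at an imposed pressure drop and writes one CSV row per (a0, branch),
#' above-fold geometries marked in the `status` column.
#'
#' @param opts Named list: `model`, `bc`, `dp`, `a0_min`, `a0_max`, `a0_n`
#'   (or an explicit `a0_grid` vector), optional `gamma`, `phi0`, `sigstar`,
#'   `nodes`, `out`.
#' @return The sweep data.frame, invisibly.
#' @export
run_sweep <- function(opts) {
  a0_grid <- if (!is.null(opts$a0_grid)) as.numeric(opts$a0_grid) else {
    if (is.null(opts$a0_min) || is.null(opts$a0_max) || is.null(opts$a0_n))
      porocyl_stop("invalid_drive", "sweep requires a0_grid or a0_min/a0_max/a0_n")
    seq(as.numeric(opts$a0_min), as.numeric(opts$a0_max),
        length.out = as.integer(opts$a0_n))
  }
  if (!length(a0_grid)) porocyl_stop("invalid_drive", "empty a0 grid")
  model <- parse_model(opts$model)
  bc <- if (!is.null(opts$bc)) opts$bc else "unconstrained"
  num <- numerics_config(
    n_nodes = if (!is.null(opts$nodes)) as.integer(opts$nodes) else 41L,
    ramp_steps = 6L)
  tab <- sweep_a0(model, bc, as.numeric(opts$dp), a0_grid, num,
                  gamma = if (!is.null(opts$gamma)) as.numeric(opts$gamma) else 0.4,
                  phi0 = if (!is.null(opts$phi0)) as.numeric(opts$phi0) else 0.5,
                  sig_star = if (!is.null(opts$sigstar)) as.numeric(opts$sigstar) else 0)
  if (all(tab$status == "failed"))
    porocyl_stop("no_convergence", "all sweep points failed")
  if (!is.null(opts$out)) utils::write.csv(tab, opts$out, row.names = FALSE)
  invisible(tab)
}

#' Benchmark fixture matrix
#'
#' The reference case matrix: both headline geometries (thick wall
#' `a0 = 1e-3`, `dp = 0.33`; thin wall `a0 = 0.85`, `dp = 0.025`) crossed
#' with the six model variants and both outer boundary conditions (24 cases),
#' at `gamma = 0.4`, `phi0 = 0.5`, `sig_star = 0`.
#'
#' @return A data.frame with columns `case`, `model`, `bc`, `a0`, `dp`.
#' @export
fixture_cases <- function() {
  geoms <- data.frame(a0 = c(1e-3, 0.85), dp = c(0.33, 0.025))
  models <- c("L-k0", "L-kKC", "Q-k0", "Q-kKC", "N-k0", "N-kKC")
  bcs <- c("unconstrained", "constrained")
  out <- expand.grid(model = models, bc = bcs, geom = 1:2,
                     stringsAsFactors = FALSE)
  out$a0 <- geoms$a0[out$geom]
  out$dp <- geoms$dp[out$geom]
  out$geom <- NULL
  out$case <- sprintf("%s_%s_a0=%g_dp=%g", out$model, out$bc, out$a0, out$dp)
  out[c("case", "model", "bc", "a0", "dp")]
}

#' Generate regression fixtures for external benchmarking
#'
#' Writes a reference radial profile (CSV) and summary (JSON) per case of
#' [fixture_cases()], generated from the closed-form solutions where
#' available (L-k0, Q-k0) and spectral solves otherwise, plus a
#' `metadata.json` recording models, node counts and tolerances. The solver
#' is deterministic, so re-running reproduces the files bit-identically.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param cases Subset of [fixture_cases()] rows (default: all 24).
#' @param n_nodes Node count for the generating solves.
#' @return The metadata list, invisibly. Aborts if any generating solve
#'   fails.
#' @export
make_fixtures <- function(out_dir, cases = fixture_cases(), n_nodes = 65L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- numerics_config(n_nodes = n_nodes, ramp_steps = 10L)
  meta <- list(n_nodes = n_nodes, tol = num$tol, gamma = 0.4, phi0 = 0.5,
               sig_star = 0, cases = list())
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    prob <- problem(cs$model, a0 = cs$a0, bc = cs$bc, dp = cs$dp)
    st <- if (cs$model == "L-k0") solve_L_k0(prob, n_nodes = n_nodes)
          else if (cs$model == "Q-k0") solve_Q_k0(prob, num)
          else solve_steady(prob, num)
    if (!st$converged)
      porocyl_stop("no_convergence",
                   sprintf("fixture case %s failed to converge", cs$case))
    write_profile(st, file.path(out_dir, paste0(cs$case, "_profile.csv")))
    write_summary(st, file.path(out_dir, paste0(cs$case, "_summary.json")))
    meta$cases[[cs$case]] <- list(model = cs$model, bc = cs$bc, a0 = cs$a0,
                                  dp = cs$dp, method = st$method,
                                  residual_norm = st$residual_norm)
  }
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}
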