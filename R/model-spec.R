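#' Model variants for the poroelastic cylinder
#'
#' A model variant combines a treatment of the kinematics (linearized or
#' rigorous), an elasticity law (linear or Hencky logarithmic-strain), and a
#' permeability law (constant or Kozeny-Carman). Linearized kinematics is never
#' combined with Hencky elasticity, since Hencky elasticity reduces to linear
#' elasticity exactly in the regime where linearization is valid. The six legal
#' combinations carry the conventional labels L-k0, L-kKC, Q-k0, Q-kKC, N-k0
#' and N-kKC, where L = linearized kinematics + linear elasticity (classical
#' linear poroelasticity when paired with k0), Q = rigorous kinematics + linear
#' elasticity ("quasi-linear"), and N = rigorous kinematics + Hencky elasticity
#' (fully nonlinear when paired with kKC).
#'
#' @param kinematics `"linearized"` or `"rigorous"`.
#' @param elasticity `"linear"` or `"hencky"`.
#' @param permeability `"constant"` or `"kozeny_carman"`.
#' @return An object of class `porocyl_model` with fields `kinematics`,
#'   `elasticity`, `permeability` and `label`.
#' @examples
#' model_spec("rigorous", "hencky", "kozeny_carman")  # N-kKC
#' parse_model("Q-k0")
#' @export
model_spec <- function(kinematics = c("rigorous", "linearized"),
                       elasticity = c("linear", "hencky"),
                       permeability = c("constant", "kozeny_carman")) {
  kinematics <- match.arg(kinematics)
  elasticity <- match.arg(elasticity)
  permeability <- match.arg(permeability)
  if (kinematics == "linearized" && elasticity == "hencky") {
    porocyl_stop("illegal_model",
                 "linearized kinematics cannot be combined with Hencky elasticity")
  }
  fam <- if (kinematics == "linearized") "L" else if (elasticity == "linear") "Q" else "N"
  perm <- if (permeability == "constant") "k0" else "kKC"
  structure(list(kinematics = kinematics, elasticity = elasticity,
                 permeability = permeability,
                 label = paste0(fam, "-", perm)),
            class = "porocyl_model")
}

#' @rdname model_spec
#' @param label One of `"L-k0"`, `"L-kKC"`, `"Q-k0"`, `"Q-kKC"`, `"N-k0"`,
#'   `"N-kKC"`.
#' @export
parse_model <- function(label) {
  if (inherits(label, "porocyl_model")) return(label)
  tab <- list(
    "L-k0"  = c("linearized", "linear", "constant"),
    "L-kKC" = c("linearized", "linear", "kozeny_carman"),
    "Q-k0"  = c("rigorous", "linear", "constant"),
    "Q-kKC" = c("rigorous", "linear", "kozeny_carman"),
    "N-k0"  = c("rigorous", "hencky", "constant"),
    "N-kKC" = c("rigorous", "hencky", "kozeny_carman"))
  if (!is.character(label) || length(label) != 1L || !label %in% names(tab)) {
    porocyl_stop("illegal_model",
                 sprintf("unknown model label %s; use one of %s",
                         deparse(label), paste(names(tab), collapse = ", ")))
  }
  v <- tab[[label]]
  model_spec(v[1], v[2], v[3])
}

#' @export
print.porocyl_model <- function(x, ...) {
  cat(sprintf("<porocyl model %s: %s kinematics, %s elasticity, %s permeability>\n",
              x$label, x$kinematics, x$elasticity, x$permeability))
  invisible(x)
}

#' Material parameters
#'
#' The dimensionless material description: stresses are measured in units of
#' the oedometric (p-wave) modulus M, so the only elastic parameter is
#' `gamma` = Lambda/M, the ratio of Lame's first parameter to M
#' (gamma in [-1/2, 1]; gamma = 1 is incompressible), together with the
#' uniform reference porosity `phi0`.
#'
#' @param gamma Ratio Lambda/M, in `[-0.5, 1]`.
#' @param phi0 Reference porosity, in `(0, 1)`.
#' @return Object of class `porocyl_material`.
#' @export
material <- function(gamma = 0.4, phi0 = 0.5) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(phi0), length(phi0) == 1L, is.finite(phi0))
  if (gamma < -0.5 || gamma > 1)
    porocyl_stop("invalid_material", "gamma must lie in [-0.5, 1]")
  if (phi0 <= 0 || phi0 >= 1)
    porocyl_stop("invalid_material", "phi0 must lie in (0, 1)")
  structure(list(gamma = gamma, phi0 = phi0), class = "porocyl_material")
}

#' Define an injection problem
#'
#' Dimensionless problem definition: lengths are in units of the initial outer
#' radius (so the initial outer radius is 1 and the initial inner radius is
#' `a0`), stresses and pressures in units of the oedometric modulus M. Flow is
#' driven either by an imposed dimensionless flow rate `q` or an imposed
#' pressure drop `dp` (exactly one must be given). The outer boundary is either
#' `"constrained"` (fixed in place) or `"unconstrained"` (free, subject to an
#' applied radial effective stress `sig_star`, zero by default).
#'
#' @param model A `porocyl_model` or a label accepted by [parse_model()].
#' @param a0 Initial inner radius, in `(0, 1)`.
#' @param bc `"unconstrained"` or `"constrained"`.
#' @param q,dp Imposed flow rate or pressure drop (exactly one, nonnegative).
#' @param gamma,phi0 Material parameters, see [material()].
#' @param sig_star Applied outer radial effective stress (unconstrained only).
#' @return Object of class `porocyl_problem`.
#' @examples
#' problem("Q-kKC", a0 = 0.3, bc = "unconstrained", dp = 0.1)
#' @export
problem <- function(model, a0, bc = c("unconstrained", "constrained"),
                    q = NULL, dp = NULL, gamma = 0.4, phi0 = 0.5,
                    sig_star = 0) {
  model <- parse_model(model)
  bc <- match.arg(bc)
  stopifnot(is.numeric(a0), length(a0) == 1L)
  if (!is.finite(a0) || a0 <= 0 || a0 >= 1)
    porocyl_stop("singular_geometry", "a0 must lie strictly between 0 and 1")
  if (is.null(q) == is.null(dp))
    porocyl_stop("invalid_drive", "supply exactly one of q or dp")
  drive <- if (!is.null(q)) list(kind = "flow_rate", value = q)
           else list(kind = "pressure_drop", value = dp)
  stopifnot(is.numeric(drive$value), length(drive$value) == 1L,
            is.finite(drive$value))
  if (drive$value < 0)
    porocyl_stop("invalid_drive", "drive value must be nonnegative")
  if (bc == "constrained" && !identical(sig_star, 0) && sig_star != 0)
    porocyl_stop("invalid_bc", "a constrained outer boundary carries no sig_star")
  structure(list(model = model, a0 = a0, bc = bc,
                 material = material(gamma, phi0),
                 sig_star = sig_star, drive = drive),
            class = "porocyl_problem")
}

#' @export
print.porocyl_problem <- function(x, ...) {
  cat(sprintf("<porocyl problem: %s, a0 = %g, %s outer boundary, %s = %g,",
              x$model$label, x$a0, x$bc, x$drive$kind, x$drive$value),
      sprintf("gamma = %g, phi0 = %g, sig_star = %g>\n",
              x$material$gamma, x$material$phi0, x$sig_star))
  invisible(x)
}

#' Numerical parameters for the spectral solver
#'
#' @param n_nodes Number of Chebyshev-Gauss-Lobatto collocation nodes (>= 8).
#' @param tol Residual infinity-norm convergence tolerance.
#' @param step_tol Newton step infinity-norm tolerance.
#' @param max_iter Newton iteration cap per load step.
#' @param mapping `"auto"`, `"affine"` or `"log_radius"` node mapping. `"auto"`
#'   uses the affine map unless `a0 <= 1e-2`, where gradients concentrate near
#'   the inner radius and a logarithmic map resolves them.
#' @param ramp_steps Number of geometric load-ramping steps (>= 1).
#' @param fd_step Relative finite-difference step for the Newton Jacobian.
#' @return Object of class `porocyl_numerics`.
#' @export
numerics_config <- function(n_nodes = 129L, tol = 1e-9, step_tol = 1e-9,
                            max_iter = 30L, mapping = c("auto", "affine", "log_radius"),
                            ramp_steps = 10L, fd_step = 1e-7) {
  mapping <- match.arg(mapping)
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 8L, tol > 0, step_tol > 0, max_iter >= 1L,
            ramp_steps >= 1L, fd_step > 0)
  structure(list(n_nodes = n_nodes, tol = tol, step_tol = step_tol,
                 max_iter = as.integer(max_iter), mapping = mapping,
                 ramp_steps = as.integer(ramp_steps), fd_step = fd_step),
            class = "porocyl_numerics")
}

# classed conditions so callers can distinguish failure modes
porocyl_stop <- function(class, message, ...) {
  stop(structure(class = c(paste0("porocyl_", class), "porocyl_error",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
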