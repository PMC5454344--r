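#' Principal stretches of the axisymmetric plane-strain deformation
#'
#' In plane strain the deformation gradient is diagonal with radial stretch
#' `lam_r = 1/(1 - dus_dr)`, azimuthal stretch `lam_th = 1/(1 - us/r)` and
#' `lam_z = 1`. The Jacobian determinant `J = lam_r * lam_th` measures the
#' local volume change. All arguments are vectorized.
#'
#' @param us Radial displacement (units of the initial outer radius).
#' @param dus_dr Radial displacement gradient.
#' @param r Radial coordinate (> 0).
#' @return A list with components `r`, `us`, `dus_dr`, `lam_r`, `lam_th`, `J`.
#' @examples
#' stretches(0.25, 0.5, 0.5)  # lam_r = 2, lam_th = 2, J = 4
#' @export
stretches <- function(us, dus_dr, r) {
  stopifnot(all(r > 0))
  if (any(dus_dr >= 1) || any(us >= r)) {
    porocyl_stop("invalid_kinematics",
                 "non-positive stretch: requires dus_dr < 1 and us < r")
  }
  lam_r <- 1 / (1 - dus_dr)
  lam_th <- 1 / (1 - us / r)
  list(r = r, us = us, dus_dr = dus_dr,
       lam_r = lam_r, lam_th = lam_th, J = lam_r * lam_th)
}

#' Porosity from the local volume change
#'
#' With incompressible constituents, deformation occurs only through
#' rearrangement of the solid skeleton, so `J = (1 - phi0) / (1 - phi_f)` and
#' hence `phi_f = 1 - (1 - phi0)/J`. Values outside the physical range (0, 1)
#' arise when the skeleton is compressed past close packing (`J <= 1 - phi0`).
#'
#' @param J Jacobian determinant (> 0), vectorized.
#' @param phi0 Reference porosity, in (0, 1).
#' @param strict If `TRUE` (default), signal a `porocyl_porosity_collapse`
#'   error when any value falls at or below zero; if `FALSE`, return the raw
#'   values (useful for diagnosing intermediate Newton iterates).
#' @return Porosity values in (-Inf, 1).
#' @examples
#' porosity_exact(2, 0.5)  # 0.75
#' @export
porosity_exact <- function(J, phi0, strict = TRUE) {
  stopifnot(all(J > 0), phi0 > 0, phi0 < 1)
  phi <- 1 - (1 - phi0) / J
  if (strict && any(phi <= 0)) {
    porocyl_stop("porosity_collapse",
                 "porosity collapsed to zero or below (J <= 1 - phi0)")
  }
  phi
}

#' Linearized porosity-displacement relation
#'
#' The small-deformation limit of [porosity_exact()]:
#' `phi_f = phi0 + (1 - phi0) * (dus_dr + us/r)`. Unconditionally evaluable;
#' results outside (0, 1) are returned as-is (the linearized theory carries no
#' hard kinematic barrier).
#'
#' @inheritParams stretches
#' @param phi0 Reference porosity.
#' @export
porosity_linearized <- function(us, dus_dr, r, phi0) {
  stopifnot(all(r > 0))
  phi0 + (1 - phi0) * (dus_dr + us / r)
}

#' Dimensionless permeability laws
#'
#' Permeability normalized by its reference value: `"constant"` returns 1;
#' `"kozeny_carman"` returns the normalized Kozeny-Carman form
#' `(1 - phi0)^2 / phi0^3 * phi^3 / (1 - phi)^2`, which equals 1 at
#' `phi = phi0`, vanishes as the porosity vanishes and diverges as the
#' porosity tends to one.
#'
#' @param phi Porosity, in (0, 1) for the Kozeny-Carman law.
#' @param law `"constant"` or `"kozeny_carman"`.
#' @param phi0 Reference porosity.
#' @examples
#' permeability(0.75, "kozeny_carman", 0.5)  # 13.5
#' @export
permeability <- function(phi, law = c("constant", "kozeny_carman"), phi0 = 0.5) {
  law <- match.arg(law)
  if (law == "constant") return(rep(1, length(phi)))
  if (any(phi <= 0) || any(phi >= 1)) {
    porocyl_stop("permeability_domain",
                 "Kozeny-Carman permeability requires porosity in (0, 1)")
  }
  (1 - phi0)^2 / phi0^3 * phi^3 / (1 - phi)^2
}

# clamped evaluation for intermediate Newton iterates: porosity transiently
# outside (0,1) must not abort the iteration; the converged solution is
# re-checked against the open-interval invariant.
permeability_clamped <- function(phi, law, phi0,
                                 floor = 1e-6, ceil = 1 - 1e-6) {
  if (law == "constant") return(rep(1, length(phi)))
  permeability(pmin(pmax(phi, floor), ceil), law, phi0)
}

#' Linear-elastic effective stress
#'
#' Dimensionless (stresses in units of M, so Lambda becomes `gamma`):
#' `sig_r = dus_dr + gamma*us/r`, `sig_th = gamma*dus_dr + us/r`,
#' `sig_z = gamma*(dus_dr + us/r)`. Tension is positive.
#'
#' @inheritParams stretches
#' @param gamma Ratio Lambda/M.
#' @return List with components `sig_r`, `sig_th`, `sig_z`.
#' @export
stress_linear <- function(us, dus_dr, r, gamma) {
  stopifnot(all(r > 0))
  e_r <- dus_dr
  e_th <- us / r
  list(sig_r = e_r + gamma * e_th,
       sig_th = gamma * e_r + e_th,
       sig_z = gamma * (e_r + e_th))
}

#' Hencky (logarithmic-strain) effective stress
#'
#' Cauchy effective stress of the Hencky hyperelastic law in plane strain,
#' dimensionless: with `J = lam_r*lam_th`,
#' `sig_r = (ln lam_r + gamma ln lam_th)/J`,
#' `sig_th = (gamma ln lam_r + ln lam_th)/J`,
#' `sig_z = gamma (ln lam_r + ln lam_th)/J`.
#' Reduces to [stress_linear()] to second order in the strain.
#'
#' @param lam_r,lam_th Principal stretches (> 0).
#' @param gamma Ratio Lambda/M.
#' @return List with components `sig_r`, `sig_th`, `sig_z`.
#' @export
stress_hencky <- function(lam_r, lam_th, gamma) {
  stopifnot(all(lam_r > 0), all(lam_th > 0))
  J <- lam_r * lam_th
  lr <- log(lam_r)
  lt <- log(lam_th)
  list(sig_r = (lr + gamma * lt) / J,
       sig_th = (gamma * lr + lt) / J,
       sig_z = gamma * (lr + lt) / J)
}

# stress at nodal fields for a given elasticity law
stress_field <- function(us, dus_dr, r, gamma, elasticity) {
  if (elasticity == "linear") {
    stress_linear(us, dus_dr, r, gamma)
  } else {
    st <- stretches(us, dus_dr, r)
    stress_hencky(st$lam_r, st$lam_th, gamma)
  }
}

# porosity at nodal fields for a given kinematic treatment
porosity_field <- function(us, dus_dr, r, phi0, kinematics, strict = TRUE) {
  if (kinematics == "linearized") {
    porosity_linearized(us, dus_dr, r, phi0)
  } else {
    st <- stretches(us, dus_dr, r)
    porosity_exact(st$J, phi0, strict = strict)
  }
}
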