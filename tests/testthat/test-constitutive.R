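test_that("stretches follow the plane-strain kinematic relations", {
  st <- stretches(0, 0, 0.5)
  expect_equal(c(st$lam_r, st$lam_th, st$J), c(1, 1, 1))

  st <- stretches(us = 0.25, dus_dr = 0.5, r = 0.5)   # us/r = 0.5
  expect_equal(st$lam_r, 2)
  expect_equal(st$lam_th, 2)
  expect_equal(st$J, 4)

  expect_error(stretches(us = 0, dus_dr = 1, r = 0.5),
               class = "porocyl_invalid_kinematics")
  expect_error(stretches(us = 0.6, dus_dr = 0, r = 0.5),
               class = "porocyl_invalid_kinematics")
})

test_that("exact porosity tracks the volume change and flags collapse", {
  expect_equal(porosity_exact(1, 0.5), 0.5)
  expect_equal(porosity_exact(2, 0.5), 0.75)
  expect_error(porosity_exact(0.5, 0.5), class = "porocyl_porosity_collapse")
  expect_equal(porosity_exact(0.5, 0.5, strict = FALSE), 0)
})

test_that("linearized porosity matches its small-strain definition and limit", {
  expect_equal(porosity_linearized(0, 0, 1, 0.37), 0.37)
  expect_equal(porosity_linearized(us = 0.1, dus_dr = 0.05, r = 1, phi0 = 0.5),
               0.575)
  # agreement with the exact relation is second order in the strain
  eps <- c(1e-2, 1e-3, 1e-4)
  gap <- vapply(eps, function(e) {
    st <- stretches(us = e, dus_dr = e, r = 1)
    abs(porosity_exact(st$J, 0.5) - porosity_linearized(e, e, 1, 0.5))
  }, numeric(1))
  expect_equal(loglog_slope(eps, gap), 2, tolerance = 0.05)
})

test_that("permeability laws are normalized at the reference porosity", {
  expect_equal(permeability(0.5, "constant", 0.5), 1)
  expect_equal(permeability(0.5, "kozeny_carman", 0.5), 1)
  expect_equal(permeability(0.3, "kozeny_carman", 0.3), 1)
  expect_equal(permeability(0.75, "kozeny_carman", 0.5), 13.5)
  # vanishes with the porosity, diverges toward full porosity, monotone
  expect_lt(permeability(1e-4, "kozeny_carman", 0.5), 1e-10)
  phis <- seq(0.01, 0.99, length.out = 200)
  expect_true(all(diff(permeability(phis, "kozeny_carman", 0.5)) > 0))
  expect_error(permeability(0, "kozeny_carman", 0.5),
               class = "porocyl_permeability_domain")
  expect_error(permeability(1, "kozeny_carman", 0.5),
               class = "porocyl_permeability_domain")
})

test_that("linear stress matches its definition and symmetries", {
  s0 <- stress_linear(0, 0, 1, 0.4)
  expect_equal(unlist(s0), c(sig_r = 0, sig_th = 0, sig_z = 0))
  s <- stress_linear(us = 0.1, dus_dr = 0.05, r = 1, gamma = 0.4)
  expect_equal(s$sig_r, 0.09)
  expect_equal(s$sig_th, 0.12)
  expect_equal(s$sig_z, 0.06)
  # isotropic deformation: sig_r = sig_th = (1 + gamma) * eps
  si <- stress_linear(us = 0.02, dus_dr = 0.02, r = 1, gamma = 0.4)
  expect_equal(si$sig_r, si$sig_th)
  expect_equal(si$sig_r, 1.4 * 0.02)
})

test_that("Hencky stress matches its definition and is linear in gamma", {
  s0 <- stress_hencky(1, 1, 0.4)
  expect_equal(unlist(s0), c(sig_r = 0, sig_th = 0, sig_z = 0))
  s <- stress_hencky(2, 1, 0.4)
  expect_equal(s$sig_r, log(2) / 2)
  expect_equal(s$sig_th, 0.4 * log(2) / 2)
  expect_equal(s$sig_z, 0.4 * log(2) / 2)
  # both laws are linear in gamma at fixed kinematics
  g <- c(-0.3, 0.1, 0.8)
  hr <- vapply(g, function(gm) stress_hencky(1.3, 0.9, gm)$sig_r, numeric(1))
  lr <- vapply(g, function(gm) stress_linear(0.1, 0.2, 1, gm)$sig_r, numeric(1))
  expect_equal(diff(hr, lag = 2) / diff(g, lag = 2),
               (hr[2] - hr[1]) / (g[2] - g[1]))
  expect_equal(diff(lr, lag = 2) / diff(g, lag = 2),
               (lr[2] - lr[1]) / (g[2] - g[1]))
})

test_that("Hencky elasticity reduces to linear elasticity at rate eps^2", {
  eps <- c(1e-2, 1e-3, 1e-4)
  gap <- vapply(eps, function(e) {
    sh <- stress_hencky(1 + e, 1 + 0.7 * e, 0.4)
    sl <- stress_linear(us = 0.7 * e, dus_dr = e, r = 1, gamma = 0.4)
    max(abs(c(sh$sig_r - sl$sig_r, sh$sig_th - sl$sig_th, sh$sig_z - sl$sig_z)))
  }, numeric(1))
  expect_equal(loglog_slope(eps, gap), 2, tolerance = 0.1)
})

test_that("exact porosity agrees with the displacement-divergence form", {
  # (phi - phi0)/(1 - phi0) = (1/r) d/dr (r u - u^2/2) for smooth fields
  phi0 <- 0.5
  r <- seq(1.2, 2, length.out = 7)
  for (fld in list(list(u = function(r) 0.15 * r, du = function(r) rep(0.15, length(r))),
                   list(u = function(r) 0.2 / r, du = function(r) -0.2 / r^2))) {
    u <- fld$u(r); du <- fld$du(r)
    st <- stretches(u, du, r)
    lhs <- (porosity_exact(st$J, phi0) - phi0) / (1 - phi0)
    # (1/r) d/dr (r u - u^2/2) = u/r + du - u du / r
    rhs <- u / r + du - u * du / r
    expect_equal(lhs, rhs, tolerance = 1e-13)
  }
})

test_that("model taxonomy enforces the six legal variants", {
  labels <- c("L-k0", "L-kKC", "Q-k0", "Q-kKC", "N-k0", "N-kKC")
  for (lb in labels) expect_identical(parse_model(lb)$label, lb)
  expect_error(model_spec("linearized", "hencky", "constant"),
               class = "porocyl_illegal_model")
  expect_error(parse_model("L-hencky"), class = "porocyl_illegal_model")
  expect_error(material(gamma = 1.2), class = "porocyl_invalid_material")
  expect_error(material(phi0 = 0), class = "porocyl_invalid_material")
  expect_error(problem("Q-k0", a0 = 1.2, dp = 0.1),
               class = "porocyl_singular_geometry")
  expect_error(problem("Q-k0", a0 = 0.5, dp = 0.1, q = 0.1),
               class = "porocyl_invalid_drive")
})
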