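test_that("linear ODE residual is zero at rest and small on the closed form", {
  p <- problem("L-kKC", a0 = 0.5, bc = "unconstrained", q = 0.1)
  g <- build_grid(33L, 0.5, 1, "affine")
  res0 <- ode_residual_linear(rep(0, g$n), g, 0, p$model, p$material)
  expect_equal(max(abs(res0)), 0)
})

test_that("Hencky ODE residual vanishes at rest and detects its singularity", {
  p <- problem("N-k0", a0 = 0.5, bc = "unconstrained", q = 0.1)
  g <- build_grid(25L, 0.5, 1, "affine")
  res0 <- ode_residual_hencky(rep(0, g$n), g, 0, p$model, p$material)
  expect_equal(max(abs(res0)), 0)
  # a uniform-slope field with ln(lam_r) = 1 (gamma = 0) hits the singular
  # denominator of the Hencky right-hand side
  p0 <- problem("N-k0", a0 = 0.5, bc = "unconstrained", q = 0.1, gamma = 0)
  us_sing <- (1 - exp(-1)) * (g$r - 0.5)
  expect_error(ode_residual_hencky(us_sing, g, 0.1, p0$model, p0$material),
               class = "porocyl_hencky_singularity")
})

test_that("Hencky and linear residuals agree at second order in amplitude", {
  p_lin <- problem("Q-k0", a0 = 0.5, bc = "unconstrained", q = 0)
  p_hen <- problem("N-k0", a0 = 0.5, bc = "unconstrained", q = 0)
  g <- build_grid(25L, 0.5, 1, "affine")
  shape <- sin(pi * (g$r - 0.5) / 0.5) * g$r
  eps <- c(1e-2, 1e-3, 1e-4)
  gap <- vapply(eps, function(e) {
    us <- e * shape
    max(abs(ode_residual_hencky(us, g, 0, p_hen$model, p_hen$material) -
              ode_residual_linear(us, g, 0, p_lin$model, p_lin$material)))
  }, numeric(1))
  expect_equal(loglog_slope(eps, gap), 2, tolerance = 0.1)
})

test_that("a converged Hencky solution has small residual on a refined grid", {
  st <- cached_state("N-k0", "unconstrained", 0.5, 0.05)
  g2 <- build_grid(2L * st$grid$n, st$grid$a, st$grid$b, st$grid$mapping)
  us2 <- grid_interp(st$grid, st$us, g2$r)
  res <- ode_residual_hencky(us2, g2, st$q, st$model, st$problem$material)
  # endpoints carry boundary rows in the solve; check interior nodes
  expect_lt(max(abs(res[2:(g2$n - 1L)])), 1e-6)
})

test_that("spectral solver reproduces the L-k0 closed form for both BCs", {
  for (cfg in list(thin, thick)) {
    for (bc in c("unconstrained", "constrained")) {
      p <- problem("L-k0", a0 = cfg$a0, bc = bc, dp = cfg$dp)
      sa <- solve_L_k0(p, n_nodes = 49L)
      ss <- solve_steady(p, numerics_config(n_nodes = 49L, ramp_steps = 2L))
      expect_true(ss$converged)
      expect_lt(max(abs(ss$us - sa$us)), 1e-8)
      expect_equal(ss$q, sa$q, tolerance = 1e-10)
    }
  }
})

test_that("zero drive returns the reference state without iteration", {
  st <- solve_steady(problem("N-kKC", a0 = 0.3, bc = "unconstrained", dp = 0),
                     test_numerics())
  expect_true(st$converged)
  expect_identical(st$newton_iters, 0L)
  expect_equal(max(abs(st$us)), 0)
  expect_equal(st$q, 0)
})

test_that("imposed dp and imposed q produce the same steady state", {
  num <- test_numerics(n_nodes = 41L, ramp_steps = 6L)
  for (bc in c("unconstrained", "constrained")) {
    s1 <- solve_steady(problem("Q-kKC", a0 = 0.3, bc = bc, dp = 0.08), num)
    expect_true(s1$converged)
    s2 <- solve_steady(problem("Q-kKC", a0 = 0.3, bc = bc, q = s1$q), num)
    expect_true(s2$converged)
    expect_lt(max(abs(s1$us - s2$us)), 1e-8)
    expect_lt(abs(s1$a - s2$a), 1e-8)
    expect_lt(abs(s1$dp - s2$dp), 1e-8)
  }
})

test_that("imposed-pressure-drop constraint matches the constant-k closed form", {
  st <- cached_state("Q-k0", "unconstrained", 0.85, 0.025)
  # residual zero iff q = dp / log(b/a)
  expect_lt(abs(enforce_pressure_drop(st, target_dp = 0.025)), 1e-9)
  st_wrong <- st
  st_wrong$q <- st$q * 1.1
  expect_gt(abs(enforce_pressure_drop(st_wrong, target_dp = 0.025)), 1e-3)
  # quadrature of 1/(r ktilde) with ktilde = 1 equals log(b/a)
  expect_equal(grid_quad(st$grid, 1 / (st$grid$r * st$ktilde)),
               log(st$b / st$a), tolerance = 1e-10)
  # trivial zero case
  st0 <- solve_steady(problem("Q-k0", a0 = 0.5, bc = "constrained", q = 0),
                      test_numerics())
  expect_equal(enforce_pressure_drop(st0, target_dp = 0), 0)
})

test_that("solutions converge spectrally with the node count", {
  # fully nonlinear thick-wall case: successive grid doublings shrink the
  # field difference at least geometrically until roundoff
  p <- problem("N-kKC", a0 = 1e-3, bc = "unconstrained", dp = 0.33)
  sts <- lapply(c(17L, 33L, 65L), function(n)
    solve_steady(p, numerics_config(n_nodes = n, ramp_steps = 6L)))
  expect_true(all(vapply(sts, function(s) s$converged, logical(1))))
  d1 <- us_max_diff(sts[[1]], sts[[2]])
  d2 <- us_max_diff(sts[[2]], sts[[3]])
  expect_lt(d2, 0.05 * d1)
  expect_lt(d2, 1e-4)

  # thin-wall counterpart resolves fully on very few nodes: the difference
  # sequence collapses to the solver floor immediately
  p2 <- problem("N-kKC", a0 = 0.85, bc = "unconstrained", dp = 0.025)
  sts2 <- lapply(c(8L, 9L, 11L), function(n)
    solve_steady(p2, numerics_config(n_nodes = n, ramp_steps = 6L)))
  e1 <- us_max_diff(sts2[[1]], sts2[[2]])
  e2 <- us_max_diff(sts2[[2]], sts2[[3]])
  expect_lt(e2, 0.1 * e1)
  expect_lt(e2, 1e-8)
})

test_that("converged states satisfy free-surface and monotone-pressure laws", {
  for (key in list(c("Q-kKC", "unconstrained"), c("N-kKC", "unconstrained"))) {
    st <- cached_state(key[1], key[2], 0.3, 0.08)
    n <- st$grid$n
    expect_lt(abs(st$sig$sig_r[1]), 3e-8)
    expect_lt(abs(st$sig$sig_r[n]), 3e-8)       # sig_star = 0
    expect_true(all(diff(st$p) < 0))            # p strictly decreasing
    expect_equal(st$p[n], 0)
  }
})

test_that("above-fold pressure drops are reported as non-converged", {
  # dp_max at a0 = 0.3 for unconstrained Q-kKC is ~0.2; demand far more
  st <- solve_steady(problem("Q-kKC", a0 = 0.3, bc = "unconstrained", dp = 1.5),
                     test_numerics(n_nodes = 25L, ramp_steps = 4L))
  expect_false(st$converged)
  expect_true(st$diagnostics$load_reached < 1.5)
})
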