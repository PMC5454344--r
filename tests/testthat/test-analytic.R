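test_that("rigid reference flow rate matches its closed form", {
  expect_equal(rigid_flow_rate(0.025, 0.85), 0.025 / log(1 / 0.85))
  expect_equal(rigid_flow_rate(0.025, 0.85), 0.153828, tolerance = 1e-5)
  expect_equal(rigid_flow_rate(0.33, 1e-3), 0.33 / log(1000))
  expect_equal(rigid_flow_rate(0.33, 1e-3), 0.0477724, tolerance = 1e-5)
  expect_equal(rigid_flow_rate(0, 0.4), 0)
  expect_error(rigid_flow_rate(0.1, 1), class = "porocyl_singular_geometry")
})

test_that("constant-permeability drive relation inverts exactly", {
  expect_equal(dp_q_constant_k(1, 1 / exp(1), 1), 1)
  expect_equal(dp_q_constant_k(rigid_flow_rate(0.33, 1e-3), 1e-3, 1), 0.33)
  q <- 0.173
  expect_equal(rigid_flow_rate(dp_q_constant_k(q, 0.42, 1), 0.42), q,
               tolerance = 1e-15)
})

test_that("the particular solution satisfies the constant-permeability ODE", {
  # u_p = -(q/2) r log r inserted into u'' + u'/r - u/r^2 gives -q/r exactly
  q <- 0.37
  r <- seq(0.3, 1, length.out = 11)
  u <- -(q / 2) * r * log(r)
  du <- -(q / 2) * (log(r) + 1)
  d2u <- -(q / 2) / r
  expect_equal(d2u + du / r - u / r^2, -q / r, tolerance = 1e-14)
})

test_that("L-k0 closed form satisfies its boundary conditions and pressure law", {
  # zero drive: undeformed
  st0 <- solve_L_k0(problem("L-k0", a0 = 0.5, bc = "unconstrained", dp = 0),
                    n_nodes = 17L)
  expect_equal(max(abs(st0$us)), 0)
  expect_equal(max(abs(st0$sig$sig_r)), 0)

  for (cfg in list(thin, thick)) {
    stu <- solve_L_k0(problem("L-k0", a0 = cfg$a0, bc = "unconstrained",
                              dp = cfg$dp), n_nodes = 41L)
    stc <- solve_L_k0(problem("L-k0", a0 = cfg$a0, bc = "constrained",
                              dp = cfg$dp), n_nodes = 41L)
    # q is independent of the outer boundary condition for L-k0
    expect_equal(stu$q, stc$q)
    expect_equal(stu$q, rigid_flow_rate(cfg$dp, cfg$a0))
    # free surfaces: sig_r vanishes at both ends (sig_star = 0)
    expect_lt(abs(stu$sig$sig_r[1]), 1e-12)
    expect_lt(abs(stu$sig$sig_r[stu$grid$n]), 1e-12)
    # constrained: no outer displacement
    expect_lt(abs(stc$us[stc$grid$n]), 1e-14)
    # pressure p = q log(1/r)
    expect_equal(stu$p, stu$q * log(1 / stu$grid$r), tolerance = 1e-10)
  }
})

test_that("L-k0 closed form annihilates the collocated ODE residual", {
  p <- problem("L-k0", a0 = 0.85, bc = "unconstrained", dp = 0.025)
  st <- solve_L_k0(p, n_nodes = 41L)
  res <- ode_residual_linear(st$us, st$grid, st$q, p$model, p$material)
  expect_lt(max(abs(res)), 1e-8)
  # constant permeability: residual is independent of phi0
  res2 <- ode_residual_linear(st$us, st$grid, st$q, p$model, material(0.4, 0.21))
  expect_identical(res, res2)
})

test_that("Q-k0 approaches L-k0 quadratically as the load vanishes", {
  qs <- c(2e-2, 2e-3)
  gaps <- vapply(qs, function(q) {
    num <- numerics_config(n_nodes = 33L)
    sQ <- solve_Q_k0(problem("Q-k0", a0 = 0.5, bc = "unconstrained", q = q), num)
    sL <- solve_L_k0(problem("L-k0", a0 = 0.5, bc = "unconstrained", q = q),
                     n_nodes = 33L)
    us_max_diff(sQ, sL)
  }, numeric(1))
  expect_equal(loglog_slope(qs, gaps), 2, tolerance = 0.2)
})

test_that("Q-k0 satisfies its kinematic closures by construction", {
  num <- numerics_config(n_nodes = 41L)
  for (bc in c("unconstrained", "constrained")) {
    st <- solve_Q_k0(problem("Q-k0", a0 = 0.85, bc = bc, dp = 0.025), num)
    expect_lt(abs(st$us[1] - (st$a - 0.85)), 1e-9)
    if (bc == "unconstrained") {
      expect_lt(abs(st$us[st$grid$n] - (st$b - 1)), 1e-9)
    } else {
      expect_identical(st$b, 1)
      expect_lt(abs(st$us[st$grid$n]), 1e-9)
    }
    expect_equal(st$dp, 0.025)
    expect_equal(st$q * log(st$b / st$a), 0.025, tolerance = 1e-9)
  }
})

test_that("Q-k0 semi-analytic and spectral solutions coincide", {
  p <- problem("Q-k0", a0 = 0.85, bc = "unconstrained", dp = 0.025)
  sa <- solve_Q_k0(p, numerics_config(n_nodes = 49L))
  ss <- cached_state("Q-k0", "unconstrained", 0.85, 0.025)
  expect_lt(abs(sa$a - ss$a), 1e-8)
  expect_lt(abs(sa$b - ss$b), 1e-8)
  expect_lt(abs(sa$q - ss$q), 1e-8)
  expect_lt(us_max_diff(sa, ss), 1e-8)
})

test_that("with frozen reference radii the Q-k0 system reduces to L-k0", {
  # the L-k0 constants satisfy the Q-k0 stress/displacement equations posed
  # on the frozen domain [a0, 1]
  a0 <- 0.6; gamma <- 0.4; q <- 0.05
  for (bc in c("unconstrained", "constrained")) {
    st <- solve_L_k0(problem("L-k0", a0 = a0, bc = bc, q = q), n_nodes = 17L)
    c1 <- st$constants$c1; c2 <- st$constants$c2
    sig_in <- porocyl:::analytic_sig_r(a0, c1, c2, q, gamma)
    expect_lt(abs(sig_in), 1e-14)
    if (bc == "unconstrained") {
      expect_lt(abs(porocyl:::analytic_sig_r(1, c1, c2, q, gamma)), 1e-14)
    } else {
      expect_lt(abs(porocyl:::analytic_u(1, c1, c2, q)), 1e-14)
    }
  }
})
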