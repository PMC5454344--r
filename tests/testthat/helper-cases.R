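# Shared numerics and memoized solves for the test suite. Node counts are
# modest: the fields are smooth, so truncation error is far below the
# tolerances being asserted, and the whole suite stays fast.

test_numerics <- function(n_nodes = 33L, ramp_steps = 4L, ...) {
  numerics_config(n_nodes = n_nodes, ramp_steps = ramp_steps, ...)
}

# headline configurations: thick wall (a0 = 1e-3, dp = 0.33) and thin wall
# (a0 = 0.85, dp = 0.025)
thick <- list(a0 = 1e-3, dp = 0.33)
thin <- list(a0 = 0.85, dp = 0.025)

.state_cache <- new.env(parent = emptyenv())

cached_state <- function(model, bc, a0, dp, n_nodes = 65L, ramp_steps = 6L) {
  key <- paste(model, bc, a0, dp, n_nodes, sep = "|")
  if (is.null(.state_cache[[key]])) {
    st <- solve_steady(problem(model, a0 = a0, bc = bc, dp = dp),
                       numerics_config(n_nodes = n_nodes,
                                       ramp_steps = ramp_steps))
    stopifnot(st$converged)
    .state_cache[[key]] <- st
  }
  .state_cache[[key]]
}

# max |u_s| difference between two states compared on the overlap of their
# physical domains (the deformed annuli generally differ slightly)
us_max_diff <- function(s1, s2, n_probe = 200L) {
  lo <- max(s1$grid$a, s2$grid$a)
  hi <- min(s1$grid$b, s2$grid$b)
  rg <- seq(lo, hi, length.out = n_probe)
  max(abs(grid_interp(s1$grid, s1$us, rg) - grid_interp(s2$grid, s2$us, rg)))
}

# least-squares slope of log(y) against log(x)
loglog_slope <- function(x, y) {
  unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])
}
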