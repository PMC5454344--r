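#' Chebyshev differentiation matrix on [-1, 1]
#'
#' Gauss-Lobatto nodes and the dense pseudospectral first-derivative matrix
#' (standard barycentric/trigonometric construction). Nodes are returned in
#' ascending order. The matrix differentiates polynomials of degree up to
#' `n - 1` exactly (to roundoff) and annihilates constants.
#'
#' @param n Number of nodes (>= 2).
#' @return List with `xi` (ascending nodes) and `D` (n x n derivative matrix).
#' @export
cheb_diff <- function(n) {
  stopifnot(n >= 2)
  N <- n - 1L
  # descending Trefethen ordering, then flip to ascending
  x <- cos(pi * (0:N) / N)
  c_coef <- c(2, rep(1, N - 1L), 2) * (-1)^(0:N)
  X <- matrix(x, n, n)
  dX <- X - t(X)
  D <- (c_coef %o% (1 / c_coef)) / (dX + diag(n))
  diag(D) <- diag(D) - rowSums(D)
  idx <- n:1
  list(xi = x[idx], D = D[idx, idx])
}

#' Clenshaw-Curtis quadrature weights on [-1, 1]
#'
#' Weights matching the Gauss-Lobatto nodes of [cheb_diff()] (ascending
#' order); exact for polynomials of degree up to `n - 1`.
#'
#' @param n Number of nodes (>= 2).
#' @return Numeric vector of weights.
#' @export
clenshaw_curtis <- function(n) {
  stopifnot(n >= 2)
  N <- n - 1L
  if (N == 1L) return(c(1, 1))
  theta <- pi * (0:N) / N
  w <- numeric(n)
  v <- rep(1, N - 1L)
  inner <- theta[2:N]
  if (N %% 2L == 0L) {
    w[1] <- w[n] <- 1 / (N^2 - 1)
    for (k in seq_len(N / 2 - 1L)) {
      v <- v - 2 * cos(2 * k * inner) / (4 * k^2 - 1)
    }
    v <- v - cos(N * inner) / (N^2 - 1)
  } else {
    w[1] <- w[n] <- 1 / N^2
    for (k in seq_len((N - 1L) / 2L)) {
      v <- v - 2 * cos(2 * k * inner) / (4 * k^2 - 1)
    }
  }
  w[2:N] <- 2 * v / N
  rev(w)  # ascending node order (weights are symmetric, rev for clarity)
}

#' Collocation grid on a physical interval
#'
#' Maps the Chebyshev-Gauss-Lobatto nodes to `[a, b]` either affinely or
#' through a logarithmic-radius map (`ln r` affine in the computational
#' coordinate), which clusters resolution near the inner radius where
#' injection-driven gradients concentrate for thick-walled geometries.
#' Differentiation and quadrature are transformed by the chain rule.
#'
#' @param n_nodes Number of nodes (>= 8 recommended).
#' @param a,b Interval endpoints, `0 < a < b`.
#' @param mapping `"affine"` or `"log_radius"`.
#' @param base Optional precomputed `cheb_diff`/`clenshaw_curtis` pair (reused
#'   across repeated remappings during Newton iteration).
#' @return Object of class `porocyl_grid`: `xi`, `D` (computational), `w`
#'   (computational weights), `r` (ascending physical nodes), `drdxi` (metric),
#'   plus `a`, `b`, `mapping`, `n`.
#' @export
build_grid <- function(n_nodes, a, b, mapping = c("affine", "log_radius"),
                       base = NULL) {
  mapping <- match.arg(mapping)
  if (!(is.finite(a) && is.finite(b)) || a <= 0 || a >= b)
    porocyl_stop("invalid_interval", "grid requires 0 < a < b")
  if (is.null(base)) {
    cd <- cheb_diff(n_nodes)
    base <- list(xi = cd$xi, D = cd$D, w = clenshaw_curtis(n_nodes))
  }
  xi <- base$xi
  if (mapping == "affine") {
    r <- a + (b - a) * (xi + 1) / 2
    drdxi <- rep((b - a) / 2, length(xi))
  } else {
    la <- log(a); lb <- log(b)
    r <- exp(la + (lb - la) * (xi + 1) / 2)
    drdxi <- r * (lb - la) / 2
  }
  structure(list(xi = xi, D = base$D, w = base$w, r = r, drdxi = drdxi,
                 a = a, b = b, mapping = mapping, n = length(xi)),
            class = "porocyl_grid")
}

#' Differentiate a nodal field with respect to the physical coordinate
#' @param grid A `porocyl_grid`.
#' @param f Nodal values.
#' @return Nodal values of df/dr.
#' @export
grid_deriv <- function(grid, f) {
  as.numeric(grid$D %*% f) / grid$drdxi
}

#' Integrate a nodal field over the physical interval
#'
#' Clenshaw-Curtis quadrature transformed to `[a, b]`; spectrally accurate for
#' smooth integrands.
#' @inheritParams grid_deriv
#' @return The scalar integral of `f` over `[a, b]`.
#' @export
grid_quad <- function(grid, f) {
  sum(grid$w * f * grid$drdxi)
}

#' Barycentric interpolation of a nodal field
#'
#' Evaluates the degree-(n-1) Chebyshev interpolant of nodal values at
#' arbitrary points of `[a, b]`, interpolating in the computational
#' coordinate.
#'
#' @inheritParams grid_deriv
#' @param r_new Evaluation points within `[a, b]`.
#' @return Interpolated values at `r_new`.
#' @export
grid_interp <- function(grid, f, r_new) {
  if (any(r_new < grid$a - 1e-12) || any(r_new > grid$b + 1e-12))
    porocyl_stop("invalid_interval", "interpolation points outside [a, b]")
  xi_new <- if (grid$mapping == "affine") {
    2 * (r_new - grid$a) / (grid$b - grid$a) - 1
  } else {
    2 * (log(r_new) - log(grid$a)) / (log(grid$b) - log(grid$a)) - 1
  }
  n <- grid$n
  # barycentric weights for Gauss-Lobatto nodes (ascending order)
  wb <- (-1)^(seq_len(n) - 1)
  wb[c(1, n)] <- wb[c(1, n)] / 2
  out <- numeric(length(xi_new))
  for (i in seq_along(xi_new)) {
    d <- xi_new[i] - grid$xi
    hit <- which(abs(d) < 1e-14)
    if (length(hit)) {
      out[i] <- f[hit[1]]
    } else {
      t <- wb / d
      out[i] <- sum(t * f) / sum(t)
    }
  }
  out
}
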