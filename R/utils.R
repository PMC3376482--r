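#' @importFrom stats plogis setNames approx optim
#' @importFrom utils head tail modifyList
NULL

# numerically stable log(1 + exp(z))
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

#' Composite Simpson quadrature on a uniform grid
#'
#' @param y values on the grid (vector, or matrix with one row per node)
#' @param h uniform spacing
#' @return the integral approximation (scalar for a vector `y`)
#' @keywords internal
#' @noRd
simpson <- function(y, h) {
  n <- if (is.matrix(y)) nrow(y) else length(y)
  if (n < 3L || n %% 2L == 0L)
    stop("Simpson quadrature needs an odd number of nodes (even interval count), got ", n)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  if (is.matrix(y)) drop(crossprod(w, y)) * h / 3 else sum(w * y) * h / 3
}

# symmetric positive-definite matrix square root via eigendecomposition
spd_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("matrix is not positive definite (min eigenvalue ", min(e$values), ")")
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

# finite-difference first derivative on a uniform grid, 4th order interior,
# 2nd-order one-sided at the ends; y may be a matrix (nodes x components)
fd_derivative <- function(y, h) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 5L) stop("need at least 5 grid points for finite differences")
  d <- matrix(0, n, ncol(y))
  i <- 3:(n - 2)
  d[i, ] <- (y[i - 2, ] - 8 * y[i - 1, ] + 8 * y[i + 1, ] - y[i + 2, ]) / (12 * h)
  d[2, ] <- (y[3, ] - y[1, ]) / (2 * h)
  d[n - 1, ] <- (y[n, ] - y[n - 2, ]) / (2 * h)
  d[1, ] <- (-3 * y[1, ] + 4 * y[2, ] - y[3, ]) / (2 * h)
  d[n, ] <- (3 * y[n, ] - 4 * y[n - 1, ] + y[n - 2, ]) / (2 * h)
  d
}

# first derivative on an arbitrary strictly increasing grid: degree-4
# polynomial through the 5 nearest nodes, differentiated at each node
fd_derivative_nonuniform <- function(y, t) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 5L) stop("need at least 5 grid points for finite differences")
  d <- matrix(0, n, ncol(y))
  for (k in seq_len(n)) {
    i0 <- min(max(k - 2L, 1L), n - 4L)
    idx <- i0:(i0 + 4L)
    dt <- t[idx] - t[k]
    hl <- max(abs(dt))  # scale for conditioning
    V <- outer(0:4, dt / hl, function(p, s) s^p)
    w <- solve(V, c(0, 1, 0, 0, 0)) / hl
    d[k, ] <- crossprod(w, y[idx, , drop = FALSE])
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
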