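# Internal numeric and RNG helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so generator functions are pure in their `seed`
#' argument and never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range. Distinct labels give effectively independent streams.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629) + 1L
}

# Numerically stable log(sum(exp(x))) by row of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for Gauss-Hermite quadrature with weight function
#' `exp(-x^2)` (physicists' convention), computed by the Golub-Welsch
#' algorithm: eigendecomposition of the symmetric tridiagonal Jacobi matrix
#' with off-diagonals `sqrt(k/2)`.
#'
#' @param k number of nodes (>= 1).
#' @return list with `nodes` and `weights`, each length `k`.
#' @examples
#' gh <- gauss_hermite(5)
#' sum(gh$weights) # integral of exp(-x^2) = sqrt(pi)
#' @export
gauss_hermite <- function(k) {
  stopifnot(k >= 1)
  if (k == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(k - 1L) / 2)
  jac <- matrix(0, k, k)
  jac[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- off
  jac[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- off
  e <- eigen(jac, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * (e$vectors[1L, ord])^2)
}

# Bilinear interpolation of a matrix-valued field. `grid` is a list with
# `x`, `y` (ascending cell-centre coordinates) and `z` (matrix, z[i, j] at
# x[i], y[j]). Points outside the grid are clamped to the border.
bilinear <- function(grid, px, py) {
  x <- grid$x; y <- grid$y; z <- grid$z
  px <- pmin(pmax(px, x[1L]), x[length(x)])
  py <- pmin(pmax(py, y[1L]), y[length(y)])
  ix <- pmin(pmax(findInterval(px, x), 1L), length(x) - 1L)
  iy <- pmin(pmax(findInterval(py, y), 1L), length(y) - 1L)
  tx <- (px - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (py - y[iy]) / (y[iy + 1L] - y[iy])
  z00 <- z[cbind(ix, iy)]
  z10 <- z[cbind(ix + 1L, iy)]
  z01 <- z[cbind(ix, iy + 1L)]
  z11 <- z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# Euclidean distance from each point in (px, py) to the nearest point in
# (qx, qy), chunked to bound memory.
nearest_dist <- function(px, py, qx, qy, chunk = 2000L) {
  n <- length(px)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(px[idx], qx, "-")^2 + outer(py[idx], qy, "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}
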