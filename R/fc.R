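#' Parameters of the cell-to-cell contributor adjustment
#'
#' Bundles the quantities that parameterize the adjustment term
#' [fc_full()]: the number of direct neighbours per cell `k`, the
#' connection-window width `z` over which the constant small-focus branch is
#' smoothly joined to the ring-growth branch, the irregularity scaling
#' `theta` (`theta = 1` corresponds to perfectly circular focus growth),
#' and the number of initially infected cells (foci) `psi`. The total
#' number of infected cells is divided by `phi = psi * theta` before the
#' piecewise curve is evaluated, so that a culture with several irregular
#' foci is mapped onto an equivalent single circular focus.
#'
#' @param k integer, neighbours per interior cell (>= 3); 6 for a hexagonal
#'   monolayer.
#' @param z positive real, connection-window width in cells.
#' @param theta irregularity scaling, >= 1.
#' @param psi integer >= 1, number of foci at the start of the dynamics.
#' @return An object of class `"adjustment_params"`, a list with elements
#'   `k`, `z`, `theta`, `psi`, `phi` and the connection coefficients
#'   `a`, `b` (see [solve_connection()]).
#' @examples
#' ap <- adjustment_params(k = 6, z = 10)
#' fc_full(1, ap)   # 1: a lone infected cell always contributes
#' fc_full(50, ap)  # < 1: part of the focus is enclosed
#' @export
adjustment_params <- function(k = 6L, z = 10, theta = 1, psi = 1L) {
  stopifnot(length(k) == 1L, length(z) == 1L, length(theta) == 1L,
            length(psi) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop("`k` must be an integer >= 3")
  if (!is.finite(z) || z <= 0) stop("`z` must be > 0")
  if (!is.finite(theta) || theta < 1) stop("`theta` must be >= 1")
  psi <- as.integer(psi)
  if (is.na(psi) || psi < 1L) stop("`psi` must be an integer >= 1")
  cc <- solve_connection(k, z)
  structure(list(k = k, z = z, theta = theta, psi = psi,
                 phi = psi * theta, a = cc$a, b = cc$b),
            class = "adjustment_params")
}

#' Proportion of focus-perimeter cells after n complete expansion phases
#'
#' For a single focus growing radially on a lattice with `k` neighbours per
#' cell, the fraction of infected cells lying in the perimeter (and hence
#' still able to transmit to an uninfected neighbour) after the n-th
#' complete ring is `2kn / (kn^2 + kn + 2)`.
#'
#' @param n expansion phase, integer >= 1 (vectorised).
#' @param k neighbours per cell.
#' @return Fraction in (0, 1].
#' @examples
#' ring_fraction(1, 6)  # 6/7
#' ring_fraction(2, 6)  # 12/19
#' @export
ring_fraction <- function(n, k = 6) {
  if (any(n < 1 | n != floor(n))) stop("`n` must be an integer >= 1")
  2 * k * n / (k * n^2 + k * n + 2)
}

#' Size of a radially grown focus after n complete expansion phases
#'
#' `I(n, k) = (k/2) n^2 + (k/2) n + 1`. For `k = 6` these are the centred
#' hexagonal numbers 1, 7, 19, 37, ...
#'
#' @param n expansion phase, >= 0 (vectorised).
#' @param k neighbours per cell.
#' @return Focus size (number of cells).
#' @examples
#' focus_size(0:3, 6)  # 1 7 19 37
#' @export
focus_size <- function(n, k = 6) {
  if (any(n < 0)) stop("`n` must be >= 0")
  (k / 2) * n^2 + (k / 2) * n + 1
}

#' Continuous perimeter fraction of a radially grown focus
#'
#' Inverts [focus_size()] for the expansion phase `n` and substitutes into
#' the perimeter count `k n`, giving the perimeter fraction as a continuous
#' function of the focus size:
#' `fc(I) = (sqrt(k^2 + 8 k I - 8 k) - k) / (2 I)`.
#' Exact whenever `I` is a complete-ring size.
#'
#' @param I focus size, `I >= k` (vectorised).
#' @param k neighbours per cell.
#' @return Fraction in (0, 1].
#' @examples
#' fc_ring(7, 6)   # 6/7, identical to ring_fraction(1, 6)
#' fc_ring(19, 6)  # 12/19
#' @export
fc_ring <- function(I, k = 6) {
  if (any(I < k)) stop("`fc_ring` requires I >= k; use fc_full() for small foci")
  (sqrt(k^2 + 8 * k * I - 8 * k) - k) / (2 * I)
}

# analytic d/dI of fc_ring; used for the C^1 connection solve
fc_ring_deriv <- function(I, k = 6) {
  s <- sqrt(k^2 + 8 * k * I - 8 * k)
  (4 * k * I / s - (s - k)) / (2 * I^2)
}

#' Coefficients of the smooth connection polynomial
#'
#' On `k < I < k + z` the adjustment term is the cubic
#' `f2(I) = a (I - k)^3 + b (I - k)^2 + 1`, which by construction satisfies
#' `f2(k) = 1` and `f2'(k) = 0`. The coefficients `a`, `b` are obtained from
#' the two remaining smoothness conditions at the upper end of the window,
#' `f2(k + z) = fc_ring(k + z)` and `f2'(k + z) = fc_ring'(k + z)`,
#' a 2x2 linear system solved exactly.
#'
#' @param k neighbours per cell.
#' @param z connection-window width, > 0.
#' @return list with elements `a` and `b`.
#' @examples
#' solve_connection(6, 10)
#' @export
solve_connection <- function(k = 6, z = 10) {
  if (!is.finite(z) || z <= 0) stop("`z` must be > 0")
  f  <- fc_ring(k + z, k)
  fp <- fc_ring_deriv(k + z, k)
  # a z^3 + b z^2 = f - 1 ; 3 a z^2 + 2 b z = fp
  A <- matrix(c(z^3, z^2, 3 * z^2, 2 * z), nrow = 2, byrow = TRUE)
  ab <- solve(A, c(f - 1, fp))
  list(a = ab[[1]], b = ab[[2]])
}

#' Adjustment term fc(I): proportion of infected cells contributing to
#' cell-to-cell transmission
#'
#' Piecewise-smooth correction applied to the mass-action cell-to-cell
#' infection term `beta_c I T`. With effective focus size
#' `Ieff = I / (psi * theta)`:
#' \itemize{
#'   \item `Ieff <= k`: all infected cells still border uninfected cells,
#'     `fc = 1`;
#'   \item `k < Ieff < k + z`: cubic connection polynomial
#'     (see [solve_connection()]);
#'   \item `Ieff >= k + z`: continuous ring-growth fraction [fc_ring()].
#' }
#' The function is continuous with a continuous first derivative and
#' non-increasing in `I`.
#'
#' @param I number of infected cells, >= 0 (continuous; vectorised).
#' @param params an [adjustment_params()] object.
#' @return Values in (0, 1].
#' @examples
#' ap <- adjustment_params(k = 6, z = 10)
#' fc_full(c(1, 6, 16, 100), ap)
#' @export
fc_full <- function(I, params = adjustment_params()) {
  stopifnot(inherits(params, "adjustment_params"))
  if (any(I < 0)) stop("`I` must be >= 0")
  k <- params$k; z <- params$z
  Ieff <- I / params$phi
  out <- numeric(length(I))
  lo  <- Ieff <= k
  mid <- Ieff > k & Ieff < k + z
  hi  <- Ieff >= k + z
  out[lo] <- 1
  if (any(mid)) {
    d <- Ieff[mid] - k
    out[mid] <- params$a * d^3 + params$b * d^2 + 1
  }
  if (any(hi)) out[hi] <- fc_ring(Ieff[hi], k)
  out
}
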