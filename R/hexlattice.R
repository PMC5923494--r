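#' Hexagon-shaped hexagonal lattice of cells
#'
#' Builds the monolayer geometry used by the agent-based simulator: cells sit
#' on a triangular grid (each interior cell has `k = 6` direct neighbours)
#' and the overall culture is hexagon-shaped with `side` cells per edge, for
#' a total of `3 side^2 - 3 side + 1` cells. Sites are addressed in axial
#' coordinates `(q, r)` with `|q|, |r|, |q + r| <= side - 1`.
#'
#' @param side cells per edge of the hexagonal culture, integer >= 1.
#' @return An object of class `"hex_lattice"`: a list with
#'   \describe{
#'     \item{side}{cells per edge}
#'     \item{n_sites}{total number of cells}
#'     \item{k}{nominal neighbours per interior cell (6)}
#'     \item{coords}{integer matrix `n_sites x 2` of axial `(q, r)`}
#'     \item{adjacency}{list of integer neighbour indices per site (1-based);
#'       boundary sites have fewer than 6 entries}
#'     \item{nbr_matrix}{integer matrix `n_sites x 6` of neighbour indices,
#'       padded with `NA` (0 in the C++ engine) on the boundary}
#'   }
#' @examples
#' lat <- hex_lattice(2)
#' lat$n_sites                      # 7
#' lengths(lat$adjacency)           # centre has 6 neighbours, corners 3
#' hex_lattice(90)$n_sites          # 24031
#' @export
hex_lattice <- function(side) {
  stopifnot(length(side) == 1L)
  side <- as.integer(side)
  if (is.na(side) || side < 1L) stop("`side` must be an integer >= 1")
  s <- side - 1L
  q <- rep.int(seq.int(-s, s), 2L * s + 1L)
  r <- rep(seq.int(-s, s), each = 2L * s + 1L)
  keep <- abs(q + r) <= s
  q <- q[keep]; r <- r[keep]
  n <- length(q)
  stopifnot(n == 3L * side^2 - 3L * side + 1L)
  key <- paste(q, r)
  idx <- stats::setNames(seq_len(n), key)
  dirs <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                c(1L, -1L), c(-1L, 1L))
  nbr <- matrix(NA_integer_, nrow = n, ncol = 6L)
  for (d in seq_len(6L)) {
    nq <- q + dirs[d, 1L]; nr <- r + dirs[d, 2L]
    ok <- abs(nq) <= s & abs(nr) <= s & abs(nq + nr) <= s
    nbr[ok, d] <- idx[paste(nq[ok], nr[ok])]
  }
  adjacency <- apply(nbr, 1L, function(x) as.integer(x[!is.na(x)]),
                     simplify = FALSE)
  structure(list(side = side, n_sites = n, k = 6L,
                 coords = cbind(q = q, r = r),
                 adjacency = adjacency, nbr_matrix = nbr),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("hex_lattice: side %d, %d sites, k = %d\n",
              x$side, x$n_sites, x$k))
  invisible(x)
}

# index of the central site (q = r = 0)
hex_center <- function(lattice) {
  which(lattice$coords[, "q"] == 0L & lattice$coords[, "r"] == 0L)
}

# neighbour matrix in 0-based form with 0 padding, as consumed by the C++ core
hex_nbr0 <- function(lattice) {
  m <- lattice$nbr_matrix
  m[is.na(m)] <- 0L
  m
}
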