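#' Uniform computational grid
#'
#' The nutrient field lives on a uniform `I x I x I` node grid spanning the
#' closed cube `[-L/2, L/2]^3`; node spacing is `h = L / (I - 1)` and the
#' outermost node layer lies exactly on the domain boundary, where the
#' far-field Dirichlet condition `c = 1` applies.
#'
#' @param I nodes per axis (integer >= 3).
#' @param L domain side length, um.
#' @return A list of class `spheroid_grid` with fields `I`, `L`, `h` and
#'   the per-axis node coordinates `nodes`.
#' @export
spheroid_grid <- function(I, L) {
  I <- as.integer(I)
  stopifnot(I >= 3, L > 0)
  h <- L / (I - 1)
  structure(list(I = I, L = L, h = h,
                 nodes = seq(-L / 2, L / 2, length.out = I)),
            class = "spheroid_grid")
}

#' @rdname spheroid_grid
#' @param p a [spheroid_params()] object.
#' @export
grid_from_params <- function(p) spheroid_grid(p$I, p$L)

#' Control-volume agent density
#'
#' Counts living agents into the `h`-cube control volume around each grid
#' node (nearest-node assignment) and divides by the control volume, giving
#' the local cell density in cells per cubic micrometre. Total mass is
#' conserved: the densities times `h^3` sum to the number of agents.
#'
#' @param agents an [agent_table()] (or any data frame with `x`, `y`, `z`).
#' @param grid a [spheroid_grid()].
#' @return An `I x I x I` numeric array of densities.
#' @export
bin_density <- function(agents, grid) {
  cpp_bin_density(agents$x, agents$y, agents$z, grid$I, grid$L)
}

#' Quasi-steady nutrient field
#'
#' Solves the steady reaction--diffusion balance `0 = lap(c) - alpha * v * c`
#' for the non-dimensional nutrient concentration `c` on the grid, with
#' `c = 1` on the domain boundary. The diffusion operator is the standard
#' seven-point finite-volume stencil; after eliminating the Dirichlet nodes
#' the system is symmetric positive definite and is solved with
#' Jacobi-preconditioned conjugate gradients, warm-started from a previous
#' field when one is supplied. The discrete maximum principle guarantees
#' `0 < c <= 1`; round-off excursions beyond the interval of more than ten
#' times the solver tolerance are treated as an error rather than silently
#' clipped.
#'
#' @param v density array from [bin_density()].
#' @param alpha consumption-to-diffusion ratio, um per cell.
#' @param grid a [spheroid_grid()].
#' @param warm_start optional previous concentration array.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return An `I x I x I` array of concentrations in \[0, 1\] with
#'   attributes `iterations` and `relres`.
#' @export
solve_nutrient <- function(v, alpha, grid, warm_start = NULL,
                           tol = 1e-8, maxit = 20000) {
  stopifnot(alpha >= 0, length(v) == grid$I^3)
  sol <- cpp_solve_nutrient(v, grid$I, grid$h, alpha, warm_start, tol, maxit)
  if (!sol$converged)
    stop(sprintf(
      "nutrient solver failed to converge: relative residual %.3e after %d iterations",
      sol$relres, sol$iterations))
  cc <- sol$c
  lo <- min(cc); hi <- max(cc)
  slack <- 10 * tol
  if (lo < -slack || hi > 1 + slack)
    stop(sprintf(
      "nutrient solution violates the maximum principle (range [%.3e, %.3e])",
      lo, hi))
  cc[cc < 0] <- 0
  cc[cc > 1] <- 1
  attr(cc, "iterations") <- sol$iterations
  attr(cc, "relres") <- sol$relres
  cc
}

#' Sample a nodal field at agent positions
#'
#' Trilinear interpolation of the eight surrounding node values.
#'
#' @param positions a data frame with `x`, `y`, `z` columns (um) or an
#'   `n x 3` matrix.
#' @param field an `I x I x I` nodal array.
#' @param grid a [spheroid_grid()].
#' @return Numeric vector of interpolated values.
#' @export
sample_field <- function(positions, field, grid) {
  if (is.matrix(positions))
    positions <- tibble::tibble(x = positions[, 1], y = positions[, 2],
                                z = positions[, 3])
  cpp_trilinear(positions$x, positions$y, positions$z, field, grid$I, grid$L)
}

#' Export the equatorial plane of a nutrient field as CSV
#'
#' Writes the `z = 0` plane of a nodal field (node coordinates in um plus
#' the concentration) to a CSV file for external plotting.
#'
#' @param field an `I x I x I` nodal array.
#' @param grid the matching [spheroid_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_equatorial_plane <- function(field, grid, path) {
  kz <- which.min(abs(grid$nodes))  # node layer nearest z = 0
  plane <- field[, , kz]
  df <- expand.grid(x_um = grid$nodes, y_um = grid$nodes)
  df$c <- as.vector(plane)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
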