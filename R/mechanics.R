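# Two-particle adhesion/repulsion mechanics and overdamped displacement.
#
# The force between two cells acts along their center line and depends only
# on the center distance d. With Rp the sum of the two physical radii and
# RA the sum of the two action radii, the implemented law is
#
#   f(d) = c_repulsion * ((Rp - d) / Rp)^2 * [d < Rp]
#          - c_adhesion * ((RA - d) / RA)^2 * [d < RA]
#
# (positive = repulsive, along the line from j to i). It is continuous in d,
# identically zero for d >= RA, strongly repulsive once the physical radii
# overlap, and purely adhesive in the action-radius shell. The equilibrium
# separation solves f(d) = 0 and is independent of the viscosity and of the
# time step.

#' Force-model parameters
#'
#' @param c_repulsion,c_adhesion Nonnegative force scales of the repulsive
#'   and adhesive branches.
#' @param eta Viscosity: micrometers of displacement per unit force per
#'   hour in the overdamped update `x(t+dt) = x(t) + eta * F * dt`.
#' @return A list of class `force_params`.
#' @export
force_params <- function(c_repulsion = 30, c_adhesion = 2, eta = 1) {
  if (c_repulsion < 0 || c_adhesion < 0 || eta < 0) {
    abort("force_params: all parameters must be nonnegative")
  }
  structure(list(c_repulsion = c_repulsion, c_adhesion = c_adhesion,
                 eta = eta), class = "force_params")
}

#' Pairwise force between two cells
#'
#' Evaluates the documented piecewise-polynomial force law for a single
#' pair. Zero whenever the center distance is at least the sum of the two
#' action radii; antisymmetric by construction. Coincident centers repel
#' with magnitude `c_repulsion` along a uniformly random direction
#' (documented tie-break).
#'
#' @param cell_i,cell_j One-row slices of a cell population tibble.
#' @param params A [force_params()].
#' @return Numeric 3-vector: the force on `cell_i`.
#' @export
pairwise_force <- function(cell_i, cell_j, params = force_params()) {
  dvec <- c(cell_i$x - cell_j$x, cell_i$y - cell_j$y, cell_i$z - cell_j$z)
  d <- sqrt(sum(dvec^2))
  RA <- cell_i$r_action + cell_j$r_action
  if (d >= RA) return(c(0, 0, 0))
  if (d < 1e-9) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    return(params$c_repulsion * u)
  }
  Rp <- cell_i$r_physical + cell_j$r_physical
  f <- cpp_force_magnitude(d, Rp, RA, params$c_repulsion, params$c_adhesion)
  f * dvec / d
}

#' Total force on every cell
#'
#' Sums the pairwise forces over a uniform bucket grid with spacing twice
#' the largest action radius currently in the population (rebuilt on every
#' call), which visits exactly the pairs whose action radii can overlap.
#' The result equals the brute-force all-pairs sum. Dead cells keep their
#' mechanical presence and participate fully.
#'
#' @param cells Cell population tibble.
#' @param params A [force_params()].
#' @return Numeric matrix (n x 3) of forces.
#' @export
total_forces <- function(cells, params = force_params()) {
  n <- nrow(cells)
  if (n == 0) return(matrix(0, 0, 3))
  pos <- cbind(cells$x, cells$y, cells$z)
  zero <- matrix(0, n, 3)
  res <- cpp_total_forces(pos, cells$r_physical, cells$r_action,
                          params$c_repulsion, params$c_adhesion, zero)
  if (length(res$coincident) > 0) {
    # redraw: coincident pairs repel along random unit directions, one draw
    # per affected lower-index cell in ascending row order
    dirs <- zero
    rows <- sort(unique(res$coincident))
    dd <- matrix(rnorm(3 * length(rows)), ncol = 3)
    dirs[rows, ] <- dd / sqrt(rowSums(dd^2))
    res <- cpp_total_forces(pos, cells$r_physical, cells$r_action,
                            params$c_repulsion, params$c_adhesion, dirs)
  }
  res$forces
}

#' Overdamped displacement update
#'
#' `x(t + dt) = x(t) + eta * F * dt` for every cell.
#'
#' @param cells Cell population tibble.
#' @param forces Matrix (n x 3) of forces, as from [total_forces()].
#' @param eta Viscosity (displacement per force per hour).
#' @param dt Step length, hours.
#' @return The population with updated positions.
#' @export
apply_displacements <- function(cells, forces, eta, dt) {
  if (nrow(cells) == 0) return(cells)
  cells$x <- cells$x + eta * forces[, 1] * dt
  cells$y <- cells$y + eta * forces[, 2] * dt
  cells$z <- cells$z + eta * forces[, 3] * dt
  cells
}

#' Reflect cells into the simulation cube
#'
#' Agents must stay inside the continuum domain so concentration lookups are
#' defined; positions beyond a face are mirrored back across it.
#'
#' @param cells Cell population tibble.
#' @param lower,upper Numeric 3-vectors bounding the cube.
#' @return The population with reflected positions.
#' @export
reflect_into_domain <- function(cells, lower, upper) {
  refl <- function(v, lo, hi) {
    hi - abs(hi - (lo + abs(v - lo)))
  }
  cells$x <- refl(cells$x, lower[1], upper[1])
  cells$y <- refl(cells$y, lower[2], upper[2])
  cells$z <- refl(cells$z, lower[3], upper[3])
  cells
}
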