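# Assembly of the agent source/sink fields A+ / A- and the
# parameter-derivation utilities (mass-scaled diffusion, half-life to decay
# constant, homogenized effective decay).
#
# Tumor cells deposit their coefficient onto the single nearest lattice node
# (a discrete delta). Vessel segments are discretized into m points along
# the center line, each carrying an equal share of the cylinder's lateral
# surface 2*pi*r*l (a discrete line-delta).

#' Coupling coefficients between agents and fields
#'
#' `alpha_*` are per-cell sink (or, for VEGF, source) strengths; `beta_*`
#' are vessel source/sink strengths per unit lateral surface. All enter the
#' FTCS update as rates (1/h) on the node they are deposited on. `beta_d`
#' and `beta_t` contribute only while the respective drug window is active.
#'
#' @param alpha_n,alpha_d,alpha_t Tumor sink strengths (nutrients, DOX,
#'   TRA), 1/h per cell.
#' @param alpha_v VEGF secretion strength per hypoxic cell, 1/h.
#' @param beta_n,beta_v,beta_d,beta_t Vessel strengths per um^2 of lateral
#'   surface, 1/h.
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(alpha_n = 0.6, alpha_v = 1,
                            alpha_d = 0.01, alpha_t = 0.01,
                            beta_n = 2e-4, beta_v = 2e-4,
                            beta_d = 4e-4, beta_t = 4e-4) {
  p <- list(alpha_n = alpha_n, alpha_v = alpha_v, alpha_d = alpha_d,
            alpha_t = alpha_t, beta_n = beta_n, beta_v = beta_v,
            beta_d = beta_d, beta_t = beta_t)
  if (any(vapply(p, function(x) x < 0, logical(1)))) {
    abort("coupling_params: all coefficients must be nonnegative")
  }
  structure(p, class = "coupling_params")
}

# accumulate weights onto flattened lattice nodes
deposit <- function(idx3, weights, n) {
  storage.mode(idx3) <- "integer"
  cpp_deposit(idx3, weights, as.integer(n))
}

#' Tumor-cell source and sink fields
#'
#' Every living cell deposits its coefficient onto the nearest lattice node:
#' all non-dead cells act as sinks for nutrients, DOX and TRA; only hypoxic
#' cells act as VEGF sources. Dead cells contribute nothing. Lattice sums
#' equal the analytic totals exactly (deposition conserves totals).
#'
#' @param cells Cell population tibble.
#' @param grid A [substance_grid()] supplying the shared lattice geometry.
#' @param params A [coupling_params()].
#' @return Named list of `n^3` arrays: `A_minus_n`, `A_minus_d`,
#'   `A_minus_t` (sinks) and `A_plus_v` (VEGF source).
#' @export
tumor_source_sink_fields <- function(cells, grid, params) {
  n <- grid$n
  zero <- array(0, dim = c(n, n, n))
  live <- cells$state != "D"
  if (!any(live)) {
    return(list(A_minus_n = zero, A_minus_d = zero, A_minus_t = zero,
                A_plus_v = zero))
  }
  pos <- cbind(cells$x, cells$y, cells$z)[live, , drop = FALSE]
  idx <- node_indices(grid, pos)
  ones <- rep(1, nrow(idx))
  counts <- deposit(idx, ones, n)
  hyp <- cells$state[live] == "H"
  A_plus_v <- if (any(hyp)) {
    params$alpha_v * deposit(idx[hyp, , drop = FALSE], ones[hyp], n)
  } else zero
  list(A_minus_n = params$alpha_n * counts,
       A_minus_d = params$alpha_d * counts,
       A_minus_t = params$alpha_t * counts,
       A_plus_v = A_plus_v)
}

#' Discrete line-delta of a vessel segment
#'
#' Discretizes the lateral surface of one cylindrical vessel agent into
#' `m = max(3, ceiling(2 l / h_min + 1))` sample points placed at the
#' midpoints of `m` equal sub-intervals of the center line. Each point
#' carries the weight `2 pi r l / m`, so the weights sum to the lateral
#' surface exactly.
#'
#' @param agent One-row slice of a vessel tree tibble.
#' @param h_min Smallest lattice spacing among the coupled fields,
#'   micrometers.
#' @param grid Optional [substance_grid()]; when given, nearest-node lattice
#'   indices are attached.
#' @return A tibble with columns `x`, `y`, `z`, `weight` (and `ix`, `iy`,
#'   `iz` when `grid` is supplied). Zero-length agents yield zero rows.
#' @export
vessel_line_delta <- function(agent, h_min, grid = NULL) {
  s <- c(agent$x0, agent$y0, agent$z0)
  e <- c(agent$x1, agent$y1, agent$z1)
  l <- sqrt(sum((e - s)^2))
  if (l <= 0) {
    message("vessel_line_delta: skipping zero-length agent ", agent$id)
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          weight = numeric(0)))
  }
  m <- max(3, ceiling(2 * l / h_min + 1))
  t <- (seq_len(m) - 0.5) / m
  pts <- tibble::tibble(
    x = s[1] + t * (e[1] - s[1]),
    y = s[2] + t * (e[2] - s[2]),
    z = s[3] + t * (e[3] - s[3]),
    weight = 2 * pi * (agent$diameter / 2) * l / m
  )
  if (!is.null(grid)) {
    idx <- node_indices(grid, as.matrix(pts[, c("x", "y", "z")]))
    pts$ix <- idx[, 1]; pts$iy <- idx[, 2]; pts$iz <- idx[, 3]
  }
  pts
}

#' Vessel source and sink fields
#'
#' Vessels source nutrients always, DOX only during the DOX window (scaled
#' by the supply factor `phi`), TRA only during the TRA window; they sink
#' VEGF always. Contributions are line-deltas weighted by the lateral
#' surface of each segment.
#'
#' @param vessels Vessel tree tibble (see [new_vessel_tree()]).
#' @param grid A [substance_grid()] supplying the lattice geometry.
#' @param params A [coupling_params()].
#' @param phi DOX supply factor, `>= 1` (see [phi()]).
#' @param dox_active,tra_active Logical: is the drug's delivery window
#'   open?
#' @return Named list of arrays `A_plus_n`, `A_plus_d`, `A_plus_t`
#'   (sources) and `A_minus_v` (VEGF sink).
#' @export
vessel_source_sink_fields <- function(vessels, grid, params, phi = 1,
                                      dox_active = FALSE,
                                      tra_active = FALSE) {
  n <- grid$n
  zero <- array(0, dim = c(n, n, n))
  if (is.null(vessels) || nrow(vessels) == 0) {
    return(list(A_plus_n = zero, A_plus_d = zero, A_plus_t = zero,
                A_minus_v = zero))
  }
  surf <- vessel_surface_deposit(vessels, grid)
  list(A_plus_n = params$beta_n * surf,
       A_plus_d = if (dox_active) phi * params$beta_d * surf else zero,
       A_plus_t = if (tra_active) params$beta_t * surf else zero,
       A_minus_v = params$beta_v * surf)
}

# deposit all vessel lateral surface onto the lattice (um^2 per node),
# vectorized over segments
vessel_surface_deposit <- function(vessels, grid) {
  s <- cbind(vessels$x0, vessels$y0, vessels$z0)
  e <- cbind(vessels$x1, vessels$y1, vessels$z1)
  l <- sqrt(rowSums((e - s)^2))
  keep <- l > 0
  if (!any(keep)) return(array(0, dim = c(grid$n, grid$n, grid$n)))
  s <- s[keep, , drop = FALSE]; e <- e[keep, , drop = FALSE]
  l <- l[keep]
  r <- vessels$diameter[keep] / 2
  m <- pmax(3, ceiling(2 * l / grid$h + 1))
  seg <- rep.int(seq_along(l), m)
  tloc <- (unlist(lapply(m, seq_len)) - 0.5) / m[seg]
  pts <- s[seg, , drop = FALSE] + tloc * (e[seg, , drop = FALSE] -
                                            s[seg, , drop = FALSE])
  w <- (2 * pi * r * l / m)[seg]
  deposit(node_indices(grid, pts), w, grid$n)
}

#' Mass-scaled diffusion coefficient
#'
#' Diffusion slows with molecular size; assuming the mass grows with the
#' cube of the effective radius, `D` scales as the inverse cube root of the
#' mass. Given a reference molecule (glucose: 180 g/mol, 50 um^2/h), the
#' mass ratio `alpha = mass / ref_mass` yields
#' `D = ref_D * alpha^(-1/3)`.
#'
#' @param mass Molecular mass, g/mol.
#' @param ref_mass,ref_D Reference mass (g/mol) and diffusion coefficient
#'   (um^2/h).
#' @return A list with elements `alpha` (mass ratio) and `D` (um^2/h).
#' @examples
#' scaled_diffusion(19.3e3) # VEGF monomer
#' @export
scaled_diffusion <- function(mass, ref_mass = 180, ref_D = 50) {
  if (any(mass <= 0) || ref_mass <= 0) {
    abort("scaled_diffusion: masses must be positive")
  }
  alpha <- mass / ref_mass
  list(alpha = alpha, D = ref_D * alpha^(-1 / 3))
}

#' Decay constant from a half-life
#'
#' @param half_life Half-life in hours, `> 0`.
#' @return Decay constant `log(2) / half_life` in 1/h.
#' @examples
#' halflife_to_decay(20) # fast bound for Doxorubicin
#' @export
halflife_to_decay <- function(half_life) {
  if (any(half_life <= 0)) abort("halflife_to_decay: half_life must be > 0")
  log(2) / half_life
}

#' Homogenized effective decay
#'
#' A substance decaying at rate `lam` and consumed at `r` per cell by cells
#' at number density `density` effectively decays at `lam + r * density`,
#' the quantity to compare against exponential surrogate fits.
#'
#' @param lam Intrinsic decay constant, 1/h.
#' @param r Consumption per cell (concentration x volume per hour).
#' @param density Cells per unit volume.
#' @return Effective decay constant, 1/h.
#' @export
effective_decay <- function(lam, r, density) {
  if (any(lam < 0) || any(r < 0) || any(density < 0)) {
    abort("effective_decay: all arguments must be nonnegative")
  }
  lam + r * density
}

# round half away from zero at a given number of decimals
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mass-scaled diffusion coefficients for the modeled substances
#'
#' Derives the diffusion coefficients of VEGF (monomer and dimer), DOX and
#' TRA from their molecular masses by inverse-cube-root scaling against
#' glucose, and reports the mass ratios and scale factors rounded to the
#' conventional printed precision (half away from zero).
#'
#' @return A tibble with columns `substance`, `mass`, `alpha`, `scale`, `D`
#'   (exact values) and their rounded counterparts `alpha_r` (integer),
#'   `scale_r` (2 decimals), `D_r` (1 decimal).
#' @export
diffusion_table <- function() {
  masses <- c(glucose = 180, vegf_monomer = 19.3e3, vegf_dimer = 38.6e3,
              dox = 543, tra = 145e3)
  sd <- scaled_diffusion(masses)
  tibble::tibble(
    substance = names(masses),
    mass = unname(masses),
    alpha = unname(sd$alpha),
    scale = unname(sd$alpha^(-1 / 3)),
    D = unname(sd$D),
    alpha_r = round_half_away(unname(sd$alpha)),
    scale_r = round_half_away(unname(sd$alpha^(-1 / 3)), 2),
    D_r = round_half_away(unname(sd$D), 1)
  )
}
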