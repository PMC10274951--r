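# Five-state stochastic cell cycle for tumor agents.
#
# States: Q (quiescent), SG2 (DNA duplication + mitosis preparation),
# G1 (post-division growth), H (hypoxic), D (dead, absorbing).
# Deterministic transitions: SG2->G1 (timer), G1->Q (timer), Q<->H
# (hypoxic-threshold switch). Stochastic transitions: Q->SG2, Q->D,
# SG2->SG2 (clock reset), SG2->D, H->D.

CELL_STATES <- c("Q", "SG2", "G1", "H", "D")

#' Cell-cycle parameters
#'
#' The stochastic cell cycle is parametrized by exactly 20 scalars: the two
#' deterministic phase durations, the hypoxic threshold, and the rate /
#' threshold / drug-modulation constants of the five stochastic transitions.
#' Drug effects enter through an exponential suppression of proliferation by
#' Trastuzumab (`lambda_QSG2`), a Doxorubicin-triggered clock reset in SG2,
#' and linear plus cross terms (`xi_*`) that scale the death probabilities
#' with the local drug concentrations.
#'
#' Defaults describe a BT-474-like cell line at desk scale: a cell divides
#' roughly every two to three days under half-saturated nutrients, hypoxic
#' cells die with a mean lifetime of `1 / r_HD` = 25 hours, and the
#' drug-free death probabilities are negligible above the hypoxic threshold.
#'
#' @param T_SG2,T_G1 Phase durations in hours.
#' @param u_n_H Hypoxic threshold on the (dimensionless) nutrient
#'   concentration: below it quiescent cells switch to `H`.
#' @param c_QSG2,u_n_QSG2,lambda_QSG2 Q to SG2: linear-ramp slope (1/h),
#'   ramp onset, and TRA suppression constant.
#' @param a_QD,b_QD,u_n_QD,xi_d_QD,xi_t_QD,xi_dt_QD Q to D: smoothed
#'   Heaviside offset (1/h), sharpness, transition point, and DOX / TRA /
#'   cross modulation factors.
#' @param c_SG2SG2,u_d_SG2SG2 SG2 clock reset: ramp slope (1/h) and onset on
#'   the DOX concentration.
#' @param c_SG2D,u_n_SG2D SG2 to D: ramp slope (1/h) and onset.
#' @param r_HD H to D rate (1/h).
#' @param xi_d_HD,xi_t_HD,xi_dt_HD Drug modulation of the hypoxic death
#'   rate.
#' @return A list of class `cell_cycle_params`.
#' @examples
#' p <- cell_cycle_params()
#' length(unclass(p)) # 20 scalars
#' @export
cell_cycle_params <- function(T_SG2 = 12,
                              T_G1 = 10,
                              u_n_H = 0.15,
                              c_QSG2 = 0.3,
                              u_n_QSG2 = 0.05,
                              lambda_QSG2 = 4,
                              a_QD = 0.001,
                              b_QD = 50,
                              u_n_QD = 0.05,
                              xi_d_QD = 5,
                              xi_t_QD = 2,
                              xi_dt_QD = 500,
                              c_SG2SG2 = 0.5,
                              u_d_SG2SG2 = 0.1,
                              c_SG2D = 0.01,
                              u_n_SG2D = 0.5,
                              r_HD = 0.04,
                              xi_d_HD = 5,
                              xi_t_HD = 2,
                              xi_dt_HD = 500) {
  p <- list(
    T_SG2 = T_SG2, T_G1 = T_G1, u_n_H = u_n_H,
    c_QSG2 = c_QSG2, u_n_QSG2 = u_n_QSG2, lambda_QSG2 = lambda_QSG2,
    a_QD = a_QD, b_QD = b_QD, u_n_QD = u_n_QD,
    xi_d_QD = xi_d_QD, xi_t_QD = xi_t_QD, xi_dt_QD = xi_dt_QD,
    c_SG2SG2 = c_SG2SG2, u_d_SG2SG2 = u_d_SG2SG2,
    c_SG2D = c_SG2D, u_n_SG2D = u_n_SG2D,
    r_HD = r_HD, xi_d_HD = xi_d_HD, xi_t_HD = xi_t_HD, xi_dt_HD = xi_dt_HD
  )
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 ||
                  is.na(x) || x < 0, logical(1))
  if (any(bad)) {
    abort(paste0("cell_cycle_params: all parameters must be nonnegative ",
                 "scalars; offending: ", paste(names(p)[bad], collapse = ", ")))
  }
  thr <- c("u_n_H", "u_n_QSG2", "u_n_QD", "u_d_SG2SG2", "u_n_SG2D")
  over <- vapply(p[thr], function(x) x > 1, logical(1))
  if (any(over)) {
    abort(paste0("cell_cycle_params: thresholds must lie in [0, 1]; ",
                 "offending: ", paste(thr[over], collapse = ", ")))
  }
  structure(p, class = "cell_cycle_params")
}

#' Cell geometry: nuclear, physical and action radii
#'
#' The natural radii of a fully grown cell, in micrometers. The radii must
#' satisfy `0 < r_nuclear <= r_physical <= r_action`. Defaults follow the
#' BT-474 literature values with physical radius 9.953, nuclear 5.296 and
#' action 12.083 (some sources print the first two transposed, which would
#' put the nucleus outside the cell; we keep the physically consistent
#' ordering and expose all three as free parameters).
#'
#' @param r_nuclear,r_physical,r_action Radii in micrometers.
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(r_nuclear = 5.296, r_physical = 9.953,
                          r_action = 12.083) {
  if (!(r_nuclear > 0 && r_nuclear <= r_physical && r_physical <= r_action)) {
    abort("cell_geometry: need 0 < r_nuclear <= r_physical <= r_action")
  }
  structure(list(r_nuclear = r_nuclear, r_physical = r_physical,
                 r_action = r_action), class = "cell_geometry")
}

#' Smoothed Heaviside transition probability
#'
#' Converts a concentration into a per-step probability through
#' `1 - exp(-(a + 1 / (1 + exp(2 b (x - xbar)))) dt)`: a logistic switch
#' centered at `xbar` (sharpness `b`), offset by a baseline rate `a`, turned
#' into a probability over a step of length `dt`. Monotonically
#' non-increasing in `x` for `b > 0`; used for death transitions that fire
#' when a concentration is LOW.
#'
#' @param x Concentration(s) in `[0, 1]`.
#' @param a Baseline rate offset (1/h), `>= 0`.
#' @param b Sharpness of the switch, `>= 0`.
#' @param xbar Transition point in `[0, 1]`.
#' @param dt Step length in hours, `>= 0`.
#' @return Probabilities in `[0, 1)`, same length as `x`.
#' @examples
#' smoothed_heaviside(0.5, a = 0, b = 10, xbar = 0.5, dt = 1) # 1 - exp(-1/2)
#' @export
smoothed_heaviside <- function(x, a, b, xbar, dt) {
  if (any(x < 0 | x > 1) || any(xbar < 0 | xbar > 1)) {
    abort("smoothed_heaviside: x and xbar must lie in [0, 1]")
  }
  if (any(a < 0) || any(b < 0) || any(dt < 0)) {
    abort("smoothed_heaviside: a, b, dt must be nonnegative")
  }
  1 - exp(-(a + 1 / (1 + exp(2 * b * (x - xbar)))) * dt)
}

#' Linear-ramp transition probability
#'
#' Converts a concentration into a per-step probability through
#' `1 - exp(-max(c (x - xbar) / (1 - xbar), 0) dt)`: zero up to the onset
#' `xbar`, then a rate rising linearly to `c` at `x = 1`. Monotonically
#' non-decreasing in `x`; used for transitions that fire when a
#' concentration is HIGH.
#'
#' @param x Concentration(s) in `[0, 1]`.
#' @param c Slope (1/h), `>= 0`.
#' @param xbar Ramp onset in `[0, 1)`.
#' @param dt Step length in hours, `>= 0`.
#' @return Probabilities in `[0, 1)`, same length as `x`.
#' @examples
#' linear_ramp(1, c = 1, xbar = 0, dt = 1) # 1 - exp(-1)
#' @export
linear_ramp <- function(x, c, xbar, dt) {
  if (any(x < 0 | x > 1)) abort("linear_ramp: x must lie in [0, 1]")
  if (any(xbar < 0 | xbar >= 1)) abort("linear_ramp: xbar must lie in [0, 1)")
  if (any(c < 0) || any(dt < 0)) abort("linear_ramp: c, dt must be nonnegative")
  1 - exp(-pmax(c * (x - xbar) / (1 - xbar), 0) * dt)
}

#' Stochastic transition probabilities of the cell cycle
#'
#' Evaluates the five stochastic transition probabilities at given local
#' concentrations. Each probability is clamped to `[0, 1]` (the drug
#' modulation factors can formally push the death probabilities above one).
#'
#' @param u_n,u_v,u_d,u_t Local concentrations in `[0, 1]` (nutrients, VEGF,
#'   DOX, TRA); vectors of common length are accepted. `u_v` does not enter
#'   any transition but is accepted for interface symmetry.
#' @param params A [cell_cycle_params()] object.
#' @param dt Step length in hours.
#' @return A tibble with columns `p_Q_SG2`, `p_Q_D`, `p_SG2_SG2`,
#'   `p_SG2_D`, `p_H_D`.
#' @examples
#' transition_probabilities(0.5, 0, 0, 0, cell_cycle_params(), dt = 0.1)
#' @export
transition_probabilities <- function(u_n, u_v = 0, u_d = 0, u_t = 0,
                                     params = cell_cycle_params(), dt) {
  stopifnot(inherits(params, "cell_cycle_params"))
  concs <- list(u_n = u_n, u_v = u_v, u_d = u_d, u_t = u_t)
  for (nm in names(concs)) {
    if (any(concs[[nm]] < 0 | concs[[nm]] > 1)) {
      abort(paste0("transition_probabilities: ", nm, " must lie in [0, 1]"))
    }
  }
  p <- params
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  tibble::tibble(
    p_Q_SG2 = clamp01(
      linear_ramp(u_n, p$c_QSG2, p$u_n_QSG2, dt) * exp(-p$lambda_QSG2 * u_t)),
    p_Q_D = clamp01(
      smoothed_heaviside(u_n, p$a_QD, p$b_QD, p$u_n_QD, dt) *
        (1 + p$xi_d_QD * u_d + p$xi_t_QD * u_t + p$xi_dt_QD * u_d * u_t)),
    p_SG2_SG2 = clamp01(linear_ramp(u_d, p$c_SG2SG2, p$u_d_SG2SG2, dt)),
    p_SG2_D = clamp01(linear_ramp(u_n, p$c_SG2D, p$u_n_SG2D, dt)),
    p_H_D = clamp01(
      p$r_HD * dt *
        (1 + p$xi_d_HD * u_d + p$xi_t_HD * u_t + p$xi_dt_HD * u_d * u_t))
  )
}

# allocation-light internal version of transition_probabilities (no tibble,
# no input re-validation: concentrations come from bounded grids)
transition_probs_list <- function(u_n, u_d, u_t, p, dt) {
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  list(
    p_Q_SG2 = clamp01(
      (1 - exp(-pmax(p$c_QSG2 * (u_n - p$u_n_QSG2) / (1 - p$u_n_QSG2), 0) *
                 dt)) * exp(-p$lambda_QSG2 * u_t)),
    p_Q_D = clamp01(
      (1 - exp(-(p$a_QD + 1 / (1 + exp(2 * p$b_QD * (u_n - p$u_n_QD)))) *
                 dt)) *
        (1 + p$xi_d_QD * u_d + p$xi_t_QD * u_t + p$xi_dt_QD * u_d * u_t)),
    p_SG2_SG2 = clamp01(
      1 - exp(-pmax(p$c_SG2SG2 * (u_d - p$u_d_SG2SG2) /
                      (1 - p$u_d_SG2SG2), 0) * dt)),
    p_SG2_D = clamp01(
      1 - exp(-pmax(p$c_SG2D * (u_n - p$u_n_SG2D) / (1 - p$u_n_SG2D), 0) *
                dt)),
    p_H_D = clamp01(
      p$r_HD * dt *
        (1 + p$xi_d_HD * u_d + p$xi_t_HD * u_t + p$xi_dt_HD * u_d * u_t))
  )
}

#' Construct a tumor cell population
#'
#' Builds the canonical cell table: one row per cell with its position,
#' current radii, categorical state and state-entry clock.
#'
#' @param position Numeric matrix (n x 3) of cell centers, micrometers.
#' @param state Initial state for every cell (single string or vector),
#'   one of `Q`, `SG2`, `G1`, `H`, `D`.
#' @param geometry A [cell_geometry()] with the natural radii.
#' @param clock Initial state-entry clocks in hours.
#' @param id Integer ids; defaults to `1:n`.
#' @return A tibble with columns `id`, `x`, `y`, `z`, `r_nuclear`,
#'   `r_physical`, `r_action`, `state`, `clock`.
#' @export
new_cell_population <- function(position, state = "Q",
                                geometry = cell_geometry(), clock = 0,
                                id = NULL) {
  position <- as.matrix(position)
  if (ncol(position) != 3) abort("new_cell_population: position must be n x 3")
  n <- nrow(position)
  if (!all(state %in% CELL_STATES)) {
    abort(paste("new_cell_population: states must be one of",
                paste(CELL_STATES, collapse = ", ")))
  }
  tibble::tibble(
    id = if (is.null(id)) seq_len(n) else as.integer(id),
    x = position[, 1], y = position[, 2], z = position[, 3],
    r_nuclear = geometry$r_nuclear,
    r_physical = geometry$r_physical,
    r_action = geometry$r_action,
    state = rep_len(as.character(state), n),
    clock = rep_len(as.numeric(clock), n)
  )
}

# Linear radius regrowth during G1: a cell leaves division with half its
# natural volume (radii scaled by 2^(-1/3)) and regrows linearly over T_G1.
g1_radius_factor <- function(clock, T_G1) {
  f0 <- 2^(-1 / 3)
  pmin(f0 + (1 - f0) * clock / T_G1, 1)
}

#' Advance every tumor cell by one time step
#'
#' Applies, in a fixed order: (1) the deterministic timer rules SG2->G1
#' (with volume-preserving division) and G1->Q; (2) the hypoxia switch
#' Q->H / H->Q; (3) at most one stochastic transition drawn from
#' [transition_probabilities()]. A cell changes state at most once per step;
#' any state change (including the SG2 clock reset) zeroes the clock. Dead
#' cells are returned unchanged and never leave `D`.
#'
#' Random draws are consumed in a documented order so runs are reproducible:
#' first one division direction (three standard normals) per dividing mother
#' in ascending id, then one uniform per stochastically eligible cell in
#' ascending id.
#'
#' Division places the daughter at the mother's post-division physical
#' radius along a uniformly random direction; both keep half the mother's
#' volume and regrow to natural size linearly during G1.
#'
#' @param cells Cell population tibble (see [new_cell_population()]),
#'   ordered by ascending id.
#' @param concs List with per-cell concentration vectors `u_n`, `u_d`,
#'   `u_t` (and optionally `u_v`, unused) evaluated at the cell centers.
#' @param params A [cell_cycle_params()].
#' @param geometry A [cell_geometry()] (natural radii).
#' @param dt Step length, hours.
#' @return The updated population (daughters appended with fresh ids).
#' @export
step_cells <- function(cells, concs, params, geometry = cell_geometry(),
                       dt) {
  stopifnot(inherits(params, "cell_cycle_params"))
  n <- nrow(cells)
  if (n == 0) return(cells)
  if (!all(cells$state %in% CELL_STATES)) {
    abort("step_cells: unknown cell state")
  }
  state <- cells$state
  clock <- cells$clock
  alive <- state != "D"
  clock[alive] <- clock[alive] + dt
  changed <- !alive  # D never changes nor draws

  u_n <- rep_len(concs$u_n, n)
  u_d <- rep_len(if (is.null(concs$u_d)) 0 else concs$u_d, n)
  u_t <- rep_len(if (is.null(concs$u_t)) 0 else concs$u_t, n)

  # (1) deterministic timers
  div <- !changed & state == "SG2" & clock >= params$T_SG2
  g1q <- !changed & state == "G1" & clock >= params$T_G1
  # (2) hypoxia switch
  qh <- !changed & state == "Q" & u_n < params$u_n_H
  hq <- !changed & state == "H" & u_n >= params$u_n_H

  state[div] <- "G1"
  state[g1q] <- "Q"
  state[qh] <- "H"
  state[hq] <- "Q"
  det_changed <- div | g1q | qh | hq
  clock[det_changed] <- 0
  changed <- changed | det_changed

  # division geometry: mother shrinks to half volume, daughter is placed at
  # the post-division physical radius along a random unit direction
  f_div <- 2^(-1 / 3)
  daughters <- NULL
  if (any(div)) {
    idx <- which(div)  # ascending id by construction
    dirs <- matrix(rnorm(3 * length(idx)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    rn <- geometry$r_nuclear * f_div
    rp <- geometry$r_physical * f_div
    ra <- geometry$r_action * f_div
    cells$r_nuclear[idx] <- rn
    cells$r_physical[idx] <- rp
    cells$r_action[idx] <- ra
    daughters <- tibble::tibble(
      id = max(cells$id) + seq_along(idx),
      x = cells$x[idx] + rp * dirs[, 1],
      y = cells$y[idx] + rp * dirs[, 2],
      z = cells$z[idx] + rp * dirs[, 3],
      r_nuclear = rn, r_physical = rp, r_action = ra,
      state = "G1", clock = 0
    )
  }

  # (3) at most one stochastic transition for untouched cells
  eligible <- !changed & state %in% c("Q", "SG2", "H")
  if (any(eligible)) {
    idx <- which(eligible)
    pr <- transition_probs_list(u_n[idx], u_d[idx], u_t[idx], params, dt)
    u <- runif(length(idx))
    st <- state[idx]
    new_st <- st
    reset <- logical(length(idx))

    isQ <- st == "Q"
    new_st[isQ & u < pr$p_Q_SG2] <- "SG2"
    new_st[isQ & u >= pr$p_Q_SG2 &
             u < pmin(pr$p_Q_SG2 + pr$p_Q_D, 1)] <- "D"

    isS <- st == "SG2"
    rs <- isS & u < pr$p_SG2_SG2
    reset[rs] <- TRUE
    new_st[isS & !rs & u < pmin(pr$p_SG2_SG2 + pr$p_SG2_D, 1)] <- "D"

    isH <- st == "H"
    new_st[isH & u < pr$p_H_D] <- "D"

    moved <- new_st != st | reset
    state[idx] <- new_st
    clock[idx[moved]] <- 0
  }

  cells$state <- state
  cells$clock <- clock

  # radii: G1 cells follow the regrowth schedule, all other living cells are
  # at natural size (dead cells keep the radii they died with)
  g1 <- cells$state == "G1"
  if (any(g1)) {
    f <- g1_radius_factor(cells$clock[g1], params$T_G1)
    cells$r_nuclear[g1] <- geometry$r_nuclear * f
    cells$r_physical[g1] <- geometry$r_physical * f
    cells$r_action[g1] <- geometry$r_action * f
  }
  grown <- cells$state %in% c("Q", "SG2", "H")
  cells$r_nuclear[grown] <- geometry$r_nuclear
  cells$r_physical[grown] <- geometry$r_physical
  cells$r_action[grown] <- geometry$r_action

  if (!is.null(daughters)) cells <- dplyr::bind_rows(cells, daughters)
  cells
}

#' Count cells per state
#'
#' @param cells Cell population tibble.
#' @return Named integer vector over `Q`, `SG2`, `G1`, `H`, `D` plus
#'   `living` and `total`.
#' @export
count_states <- function(cells) {
  counts <- vapply(CELL_STATES, function(s) sum(cells$state == s), integer(1))
  c(counts, living = sum(counts[c("Q", "SG2", "G1", "H")]),
    total = nrow(cells))
}

#' Write / read a cell population snapshot
#'
#' Tab-separated text, one row per cell, full double precision; the
#' round trip is exact.
#'
#' @param cells Cell population tibble.
#' @param path File path.
#' @return `read_cells` returns the population tibble; `write_cells`
#'   invisibly returns `path`.
#' @export
write_cells <- function(cells, path) {
  df <- as.data.frame(cells)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "id"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$id <- as.integer(df$id)
  tibble::as_tibble(df)
}
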