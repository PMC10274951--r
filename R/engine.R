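# Time-stepping orchestration. Per agent step, in fixed order:
#   (1) assemble the source/sink fields from the current agents,
#   (2) advance each substance by enough stable FTCS substeps,
#   (3) advance the treatment supply state and window flags,
#   (4) cell-cycle updates for all cells,
#   (5) vessel branching/growth (unless past the shutoff day),
#   (6) force computation, displacement, reflection into the domain,
#   (7) record outputs per cadence.
# Identical config + seed implies identical outputs.

default_substances <- function() {
  list(
    nutrients = list(D = 50, lam = 0, bc = "neumann", bc_value = 0,
                     init = 0, enabled = TRUE),
    vegf = list(D = 10.5, lam = 0.002, bc = "neumann", bc_value = 0,
                init = 0, enabled = TRUE),
    dox = list(D = scaled_diffusion(543)$D, lam = halflife_to_decay(24),
               bc = "neumann", bc_value = 0, init = 0, enabled = TRUE),
    tra = list(D = scaled_diffusion(145e3)$D, lam = 2e-3, bc = "neumann",
               bc_value = 0, init = 0, enabled = TRUE)
  )
}

#' Simulation configuration
#'
#' Collects every tunable of a run: domain and lattice geometry, time step,
#' duration, substance blocks (diffusion, decay, boundary condition, initial
#' value, enabled flag), the module parameter sets, the initial agents and
#' the treatment schedule. Unknown substance names or missing fields are
#' errors.
#'
#' @param domain_length Edge length of the cubic domain, micrometers.
#' @param n_grid Lattice nodes per axis (shared by all substances).
#' @param dt Agent time step, hours.
#' @param days Total simulated days.
#' @param seed Default RNG seed used by [run_simulation()] when none is
#'   passed explicitly.
#' @param output_every Record the state-count series every this many steps.
#' @param vessel_shutoff_day Day after which the vessel growth algorithm is
#'   turned off (`Inf` = never).
#' @param substances Named list (`nutrients`, `vegf`, `dox`, `tra`) of
#'   blocks with fields `D`, `lam`, `bc`, `bc_value`, `init`, `enabled`;
#'   see `default_substances` in the package source for the defaults.
#' @param cell_params A [cell_cycle_params()].
#' @param geometry A [cell_geometry()].
#' @param force A [force_params()].
#' @param angio An [angiogenesis_params()].
#' @param coupling A [coupling_params()].
#' @param treatment A [treatment_state()], or `NULL` for no treatment.
#' @param initial_cells List with `n` (count), `state` (`"Q"` or `"H"`),
#'   optionally `center`, and optionally `placement` (`"spheroid"`, the
#'   densely packed default, or `"uniform"`: positions uniform over the
#'   central 70% of the domain, as when engrafted cells scatter through a
#'   vascularized tissue); or a ready-made cell population tibble.
#' @param vessels `NULL` (avascular), the string `"generate"`, or a vessel
#'   tree tibble.
#' @param vasc_spec A [vasculature_gen_spec()] used when
#'   `vessels = "generate"`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(domain_length = 600,
                              n_grid = 25,
                              dt = 0.1,
                              days = 10,
                              seed = 1L,
                              output_every = 1L,
                              vessel_shutoff_day = Inf,
                              substances = default_substances(),
                              cell_params = cell_cycle_params(),
                              geometry = cell_geometry(),
                              force = force_params(),
                              angio = angiogenesis_params(),
                              coupling = coupling_params(),
                              treatment = NULL,
                              initial_cells = list(n = 200, state = "Q"),
                              vessels = NULL,
                              vasc_spec = NULL) {
  if (dt <= 0) abort("simulation_config: dt must be positive")
  if (days <= 0) abort("simulation_config: days must be positive")
  if (vessel_shutoff_day > days && is.finite(vessel_shutoff_day)) {
    abort("simulation_config: vessel_shutoff_day must not exceed days")
  }
  base <- default_substances()
  if (!setequal(names(substances), names(base))) {
    abort(paste("simulation_config: substances must be exactly",
                paste(names(base), collapse = ", ")))
  }
  for (nm in names(base)) {
    extra <- setdiff(names(substances[[nm]]), names(base[[nm]]))
    if (length(extra)) {
      abort(paste0("simulation_config: unknown field(s) in substance '", nm,
                   "': ", paste(extra, collapse = ", ")))
    }
    substances[[nm]] <- utils::modifyList(base[[nm]], substances[[nm]])
  }
  stopifnot(inherits(cell_params, "cell_cycle_params"),
            inherits(geometry, "cell_geometry"),
            inherits(force, "force_params"),
            inherits(angio, "angiogenesis_params"),
            inherits(coupling, "coupling_params"))
  if (!is.null(treatment)) stopifnot(inherits(treatment, "treatment_state"))
  structure(list(
    domain_length = domain_length, n_grid = as.integer(n_grid), dt = dt,
    days = days, seed = seed, output_every = as.integer(output_every),
    vessel_shutoff_day = vessel_shutoff_day, substances = substances,
    cell_params = cell_params, geometry = geometry, force = force,
    angio = angio, coupling = coupling, treatment = treatment,
    initial_cells = initial_cells, vessels = vessels,
    vasc_spec = vasc_spec
  ), class = "simulation_config")
}

#' Validate a simulation configuration
#'
#' Re-runs the constructor checks plus derived invariants (lattice spacing,
#' per-substance stability substeps at the configured dt).
#'
#' @param config A [simulation_config()].
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  h <- config$domain_length / (config$n_grid - 1)
  for (nm in names(config$substances)) {
    s <- config$substances[[nm]]
    if (!s$bc %in% c("neumann", "dirichlet")) {
      abort(paste0("validate_config: bad bc for ", nm))
    }
    # substep count must be finite and sane
    m <- ceiling(config$dt / max_stable_dt(s$D, s$lam, h))
    if (m > 1e4) {
      abort(paste0("validate_config: substance ", nm,
                   " would need > 10000 substeps; refine dt or h"))
    }
  }
  invisible(config)
}

# positivity-preserving substep count: (lam + 6 D/h^2 + maxA+ + maxA-) dt <= 1
# guarantees u stays in [0,1]; it implies the von-Neumann bound.
n_substeps <- function(D, lam, h, maxA, dt) {
  rate <- lam + 6 * D / h^2 + maxA
  max(1L, as.integer(ceiling(dt * rate / 1)),
      as.integer(ceiling(dt / max_stable_dt(D, lam, h))))
}

# engine-internal FTCS substepping: inputs are already validated (A fields
# are built as nonnegative scalar multiples of deposits), so skip the
# per-call checks of ftcs_step and avoid intermediate copies
ftcs_advance <- function(g, ap, am, dt, m, bc_code) {
  sub <- dt / m
  u <- g$u
  for (k in seq_len(m)) {
    u <- cpp_ftcs_step(u, dim(u), g$h, g$D, g$lam, sub, ap, am, bc_code,
                       g$bc_value)
  }
  g$u <- u
  g
}

#' Run a simulation
#'
#' Executes the full hybrid model for the configured duration and returns
#' the per-step state-count series together with the final agent
#' populations and fields. Identical `(config, seed)` pairs give identical
#' outputs.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param quiet Suppress the per-day progress line?
#' @return An object of class `tumor_sim`: a list with `series` (tibble),
#'   `cells`, `vessels`, `grids`, `config`, `seed`.
#' @export
run_simulation <- function(config, seed = config$seed, quiet = TRUE) {
  validate_config(config)
  set.seed(seed)
  L <- config$domain_length
  n <- config$n_grid
  h <- L / (n - 1)
  ctr <- rep(L / 2, 3)

  grids <- lapply(names(config$substances), function(nm) {
    s <- config$substances[[nm]]
    substance_grid(nm, n, h, s$D, s$lam, bc = s$bc, bc_value = s$bc_value,
                   init = s$init)
  })
  names(grids) <- names(config$substances)

  cells <- if (is.data.frame(config$initial_cells)) {
    config$initial_cells
  } else {
    ic <- config$initial_cells
    center <- if (is.null(ic$center)) ctr else ic$center
    if (identical(ic$placement, "uniform")) {
      pos <- matrix(runif(3 * ic$n, 0.15 * L, 0.85 * L), ncol = 3)
      new_cell_population(pos, state = ic$state,
                          geometry = config$geometry)
    } else {
      place_spheroid(ic$n, config$geometry$r_physical, center = center,
                     state = ic$state, geometry = config$geometry)
    }
  }

  vessels <- config$vessels
  if (is.character(vessels) && identical(vessels, "generate")) {
    spec <- config$vasc_spec
    if (is.null(spec)) {
      spec <- vasculature_gen_spec(
        domain_lower = c(0, 0, 0), domain_upper = rep(L, 3),
        exclusion_center = ctr,
        exclusion_radius = 2 * spheroid_radius(
          max(1, nrow(cells)), config$geometry$r_physical))
    }
    vessels <- generate_vasculature(spec)
  }
  has_vessels <- !is.null(vessels) && nrow(vessels) > 0

  trt <- config$treatment
  chi <- if (is.null(trt)) 0 else trt$chi

  dt <- config$dt
  n_steps <- as.integer(round(config$days * 24 / dt))
  shutoff_h <- config$vessel_shutoff_day * 24
  v_cell <- 4 / 3 * pi * config$geometry$r_physical^3
  enabled <- vapply(config$substances, `[[`, logical(1), "enabled")

  vessels_static <- !is.finite(shutoff_h) || shutoff_h <= 0
  vsurf_cache <- NULL
  max_vsurf_cache <- 0
  zero <- array(0, dim = c(n, n, n))
  empty <- numeric(0)
  bc_code <- vapply(grids, function(g)
    if (g$bc == "dirichlet") 1L else 0L, integer(1))
  field_live <- vapply(grids, function(g) max(g$u) > 0, logical(1))

  rec_steps <- unique(c(seq(0L, n_steps, by = config$output_every), n_steps))
  out <- matrix(NA_real_, length(rec_steps), 15L)
  colnames(out) <- c("step", "time_h", "day", "n_Q", "n_SG2", "n_G1",
                     "n_H", "n_D", "living", "total", "volume",
                     "n_vessels", "vessel_length", "chi", "phi")
  ri <- 1L
  record <- function(step, t) {
    st <- cells$state
    nQ <- sum(st == "Q"); nS <- sum(st == "SG2"); nG <- sum(st == "G1")
    nH <- sum(st == "H"); nD <- sum(st == "D")
    vt <- if (has_vessels) vessel_totals(vessels) else
      c(n_agents = 0, length = 0, surface = 0)
    out[ri, ] <<- c(step, t, t / 24, nQ, nS, nG, nH, nD,
                    nQ + nS + nG + nH, length(st),
                    length(st) * v_cell / 0.64,
                    vt[["n_agents"]], vt[["length"]], chi, phi(chi))
    ri <<- ri + 1L
  }
  record(0L, 0)

  for (step in seq_len(n_steps)) {
    t <- (step - 1L) * dt

    # (1) assemble source/sink fields (only for enabled substances; the
    # lattice deposition of a static vessel forest is cached)
    act <- if (is.null(trt)) c(dox = FALSE, tra = FALSE) else
      windows_active(t, trt)
    live <- cells$state != "D"
    counts <- if (any(live)) {
      deposit(node_indices(grids$nutrients,
                           cbind(cells$x, cells$y, cells$z)[live, ,
                                                            drop = FALSE]),
              rep(1, sum(live)), n)
    } else zero
    max_counts <- max(counts)
    hyp <- live & cells$state == "H"
    vsurf <- if (!has_vessels) zero else if (vessels_static) {
      if (is.null(vsurf_cache)) {
        vsurf_cache <- vessel_surface_deposit(vessels, grids$nutrients)
        max_vsurf_cache <- max(vsurf_cache)
      }
      vsurf_cache
    } else vessel_surface_deposit(vessels, grids$nutrients)
    max_vsurf <- if (!has_vessels) 0 else if (vessels_static)
      max_vsurf_cache else max(vsurf)
    cp <- config$coupling
    Ap <- list(
      nutrients = cp$beta_n * vsurf,
      vegf = if (any(hyp)) {
        cp$alpha_v * deposit(
          node_indices(grids$nutrients,
                       cbind(cells$x, cells$y, cells$z)[hyp, , drop = FALSE]),
          rep(1, sum(hyp)), n)
      } else zero,
      dox = if (act[["dox"]]) phi(chi) * cp$beta_d * vsurf else zero,
      tra = if (act[["tra"]]) cp$beta_t * vsurf else zero)
    Am <- list(nutrients = cp$alpha_n * counts, vegf = cp$beta_v * vsurf,
               dox = cp$alpha_d * counts, tra = cp$alpha_t * counts)

    # (2) advance the continua with positivity-preserving substeps
    max_ap <- c(nutrients = cp$beta_n * max_vsurf,
                vegf = if (any(hyp)) max(Ap$vegf) else 0,
                dox = if (act[["dox"]]) phi(chi) * cp$beta_d * max_vsurf
                  else 0,
                tra = if (act[["tra"]]) cp$beta_t * max_vsurf else 0)
    max_am <- c(nutrients = cp$alpha_n * max_counts,
                vegf = cp$beta_v * max_vsurf,
                dox = cp$alpha_d * max_counts,
                tra = cp$alpha_t * max_counts)
    for (nm in names(grids)) {
      if (!enabled[[nm]]) next
      g <- grids[[nm]]
      if (!field_live[[nm]]) {
        if (max_ap[[nm]] == 0 && !(bc_code[[nm]] == 1L && g$bc_value > 0)) {
          next
        }
        field_live[[nm]] <- TRUE
      }
      m <- n_substeps(g$D, g$lam, g$h, max_ap[[nm]] + max_am[[nm]], dt)
      ap <- if (max_ap[[nm]] > 0) Ap[[nm]] else empty
      am <- if (max_am[[nm]] > 0) Am[[nm]] else empty
      grids[[nm]] <- ftcs_advance(g, ap, am, dt, m, bc_code[[nm]])
    }

    # (3) treatment supply state
    if (!is.null(trt)) {
      chi <- chi_step(chi, act[["tra"]], trt$tau_up, trt$tau_down,
                      trt$chi_max, dt)
    }

    # (4) cell-cycle updates
    if (nrow(cells) > 0) {
      pos <- cbind(cells$x, cells$y, cells$z)
      concs <- list(u_n = sample_at(grids$nutrients, pos),
                    u_d = sample_at(grids$dox, pos),
                    u_t = sample_at(grids$tra, pos))
      cells <- step_cells(cells, concs, config$cell_params,
                          config$geometry, dt)
    }

    # (5) angiogenesis
    if (has_vessels && enabled[["vegf"]] && t < shutoff_h) {
      vessels <- step_vasculature(vessels, grids$vegf, config$angio, dt)
    }

    # (6) mechanics
    if (nrow(cells) > 1) {
      forces <- total_forces(cells, config$force)
      cells <- apply_displacements(cells, forces, config$force$eta, dt)
      cells <- reflect_into_domain(cells, c(0, 0, 0), rep(L, 3))
    }

    # (7) outputs
    if (step == rec_steps[min(ri, length(rec_steps))]) record(step, t + dt)
    if (step %% 240L == 0L) {
      if (!all(vapply(grids, function(g) all(is.finite(g$u)), logical(1)))) {
        abort("run_simulation: non-finite field values detected")
      }
      if (!quiet) {
        message(sprintf("day %.1f: %d cells (%d living), %d vessel agents",
                        t / 24, nrow(cells),
                        sum(cells$state != "D"),
                        if (has_vessels) nrow(vessels) else 0L))
      }
    }
  }

  series <- tibble::as_tibble(as.data.frame(out[seq_len(ri - 1L), ,
                                                 drop = FALSE]))
  for (col in c("step", "n_Q", "n_SG2", "n_G1", "n_H", "n_D", "living",
                "total", "n_vessels")) {
    series[[col]] <- as.integer(series[[col]])
  }
  structure(list(series = series, cells = cells, vessels = vessels,
                 grids = grids, config = config, seed = seed),
            class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  s <- tail(x$series, 1)
  cat(sprintf("<tumor_sim> %g days, seed %s\n", x$config$days,
              format(x$seed)))
  cat(sprintf("  final: %d cells (%d living: Q %d, SG2 %d, G1 %d, H %d; D %d)\n",
              s$total, s$living, s$n_Q, s$n_SG2, s$n_G1, s$n_H, s$n_D))
  if (!is.null(x$vessels)) {
    cat(sprintf("  vasculature: %d agents, %.0f um total length\n",
                s$n_vessels, s$vessel_length))
  }
  cat(sprintf("  tumor volume: %.3g mm^3\n", s$volume * 1e-9))
  invisible(x)
}

#' Tidy the state-count series of a run
#'
#' @param x A `tumor_sim` object.
#' @param ... Unused.
#' @return A long tibble with columns `time_h`, `day`, `quantity`, `value`,
#'   one row per recorded quantity per time point.
#' @method tidy tumor_sim
#' @export
tidy.tumor_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, -c("step", "time_h", "day"),
                      names_to = "quantity", values_to = "value")
}

#' One-row summary of a run
#'
#' @param x A `tumor_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: final counts, peak living count and its day,
#'   final volume, vessel totals, seed.
#' @method glance tumor_sim
#' @export
glance.tumor_sim <- function(x, ...) {
  s <- x$series
  fin <- tail(s, 1)
  ipk <- which.max(s$living)
  tibble::tibble(
    days = x$config$days, seed = x$seed,
    final_living = fin$living, final_total = fin$total,
    final_dead = fin$n_D, final_volume_mm3 = fin$volume * 1e-9,
    peak_living = s$living[ipk], peak_living_day = s$day[ipk],
    final_vessel_agents = fin$n_vessels,
    final_vessel_length = fin$vessel_length
  )
}

#' Plot the state-count series of a run
#'
#' Cell counts per state plus the living and total aggregates over time.
#'
#' @param object A `tumor_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tumor_sim
#' @export
autoplot.tumor_sim <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$quantity %in% c("n_Q", "n_SG2", "n_G1", "n_H", "n_D",
                           "living", "total"), ]
  labels <- c(n_Q = "Q", n_SG2 = "SG2", n_G1 = "G1", n_H = "H", n_D = "D",
              living = "living", total = "total")
  d$quantity <- factor(labels[d$quantity], levels = labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value,
                                  color = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [days]", y = "cells", color = "state") +
    ggplot2::theme_minimal()
}
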