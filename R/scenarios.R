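# Scenario presets at desk scale. The three families mirror the model's
# canonical computational experiments: avascular spheroid growth under a
# nutrient bath (hypoxic-threshold sweep), sprouting angiogenesis around a
# hypoxic spheroid (with or without the vessel VEGF sink), and the fully
# coupled treatment comparison across four drug protocols.

#' Avascular tumor spheroid scenario
#'
#' 200 quiescent cells seeded at the center of a cube, nutrients held at
#' 0.5 on the boundary (Dirichlet bath) and initialized to 0.5 everywhere;
#' VEGF and both drugs are switched off. The hypoxic threshold `u_n_H`
#' selects the growth regime: at high thresholds the hypoxic region
#' eventually engulfs the spheroid and the population dies off, at low
#' thresholds a proliferative surface hull persists.
#'
#' @param u_n_H Hypoxic threshold.
#' @param n_cells Seeded cell count.
#' @param days Simulated days.
#' @param n_grid Lattice nodes per axis.
#' @param domain_length Domain edge, micrometers.
#' @param dt Time step, hours (default 6 minutes).
#' @param seed Default seed.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A [simulation_config()].
#' @export
scenario_spheroid <- function(u_n_H = 0.15, n_cells = 200, days = 30,
                              n_grid = 40, domain_length = 780, dt = 0.1,
                              seed = 1L, ...) {
  subs <- default_substances()
  subs$nutrients$bc <- "dirichlet"
  subs$nutrients$bc_value <- 0.5
  subs$nutrients$init <- 0.5
  subs$vegf$enabled <- FALSE
  subs$dox$enabled <- FALSE
  subs$tra$enabled <- FALSE
  simulation_config(
    domain_length = domain_length, n_grid = n_grid, dt = dt, days = days,
    seed = seed, substances = subs,
    cell_params = cell_cycle_params(u_n_H = u_n_H),
    initial_cells = list(n = n_cells, state = "Q"),
    vessels = NULL, ...
  )
}

#' Sprouting angiogenesis scenario
#'
#' A hypoxic spheroid secretes VEGF inside a synthetic vasculature; sprouts
#' form above the VEGF threshold and tips grow along the gradient. To
#' isolate the network morphology, the spheroid acts as a steady VEGF
#' source: the nutrient and drug fields are disabled, cells stay hypoxic
#' and the hypoxic death rate is zeroed, so the signal persists for the
#' whole run. With the vessel VEGF sink enabled, vessels locally deplete
#' VEGF, which pushes new sprouts apart and produces a more diffuse,
#' tumor-surrounding network; the dispersion of new tip positions is the
#' contrast to the sink-free run.
#'
#' @param vegf_sink Couple the vessels to the VEGF field as sinks?
#' @param n_cells Seeded (hypoxic) cell count.
#' @param days Simulated days.
#' @param n_grid Lattice nodes per axis.
#' @param domain_length Domain edge, micrometers.
#' @param dt Time step, hours.
#' @param seed Default seed.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A [simulation_config()].
#' @export
scenario_angiogenesis <- function(vegf_sink = TRUE, n_cells = 800,
                                  days = 10, n_grid = 24,
                                  domain_length = 575, dt = 0.2,
                                  seed = 1L, ...) {
  subs <- default_substances()
  subs$nutrients$enabled <- FALSE
  subs$dox$enabled <- FALSE
  subs$tra$enabled <- FALSE
  cpl <- coupling_params(beta_v = if (vegf_sink) 2e-3 else 0)
  ctr <- rep(domain_length / 2, 3)
  spec <- vasculature_gen_spec(
    domain_lower = c(0, 0, 0), domain_upper = rep(domain_length, 3),
    exclusion_center = ctr,
    exclusion_radius = 120, target_length_density = 5e-5
  )
  simulation_config(
    domain_length = domain_length, n_grid = n_grid, dt = dt, days = days,
    seed = seed, substances = subs, coupling = cpl,
    cell_params = cell_cycle_params(r_HD = 0),  # steady hypoxic source
    initial_cells = list(n = n_cells, state = "H"),
    vessels = "generate", vasc_spec = spec, ...
  )
}

#' Treatment-comparison scenario
#'
#' Fully coupled run at a compact scale: a quiescent population inside a
#' static synthetic vasculature that supplies nutrients and, during the
#' scheduled windows, the drugs. The avascular core of the seeded spheroid
#' collapses in the first days; the population then re-establishes along
#' the vasculature and grows, and treatment starts on day 8. Three delivery
#' slots are allocated (days 8-9, 10-11 and 12-12.5); the four protocols
#' fill them as DOX-DOX-DOX, TRA-TRA-TRA, TRA-TRA-DOX, and DOX-DOX-TRA,
#' alongside an untreated control. The supply factor charges during TRA
#' delivery, so DOX arriving after TRA enters at an enhanced rate while the
#' reverse order gains nothing — the in-silico form of giving the
#' anti-angiogenic agent first.
#'
#' @param protocol One of `"untreated"`, `"DOX"`, `"TRA"`, `"TRA_DOX"`,
#'   `"DOX_TRA"`.
#' @param n_cells Seeded (quiescent) cell count.
#' @param days Simulated days.
#' @param n_grid Lattice nodes per axis.
#' @param domain_length Domain edge, micrometers.
#' @param dt Time step, hours.
#' @param seed Default seed.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A [simulation_config()].
#' @export
scenario_treatment <- function(protocol = c("untreated", "DOX", "TRA",
                                            "TRA_DOX", "DOX_TRA"),
                               n_cells = 150, days = 14, n_grid = 20,
                               domain_length = 475, dt = 0.2, seed = 1L,
                               ...) {
  protocol <- match.arg(protocol)
  subs <- default_substances()
  subs$nutrients$init <- 0.5
  slots <- list(c(8, 9), c(10, 11), c(12, 12.5))  # days
  to_h <- function(s) do.call(rbind, lapply(s, function(w) w * 24))
  assign_drug <- switch(protocol,
    untreated = list(dox = NULL, tra = NULL),
    DOX = list(dox = slots, tra = NULL),
    TRA = list(dox = NULL, tra = slots),
    TRA_DOX = list(dox = slots[3], tra = slots[1:2]),
    DOX_TRA = list(dox = slots[1:2], tra = slots[3])
  )
  trt <- treatment_state(
    dox_windows = if (is.null(assign_drug$dox)) NULL else
      to_h(assign_drug$dox),
    tra_windows = if (is.null(assign_drug$tra)) NULL else
      to_h(assign_drug$tra),
    chi_max = 1, tau_up = 12, tau_down = 48
  )
  ctr <- rep(domain_length / 2, 3)
  spec <- vasculature_gen_spec(
    domain_lower = c(0, 0, 0), domain_upper = rep(domain_length, 3),
    exclusion_center = ctr, exclusion_radius = 70,
    target_length_density = 6e-5
  )
  simulation_config(
    domain_length = domain_length, n_grid = n_grid, dt = dt, days = days,
    seed = seed, substances = subs, treatment = trt,
    coupling = coupling_params(beta_n = 1.5e-3),
    vessel_shutoff_day = 0,  # static vasculature: treatment phase only
    initial_cells = list(n = n_cells, state = "Q",
                         placement = "uniform"),
    vessels = "generate", vasc_spec = spec, ...
  )
}
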