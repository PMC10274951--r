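# Cell cycle: transition functions, probabilities, and the state machine.

test_that("smoothed Heaviside matches closed-form values and rejects bad input", {
  # logistic term is exactly 1/2 at x = xbar
  expect_equal(smoothed_heaviside(0.5, a = 0, b = 7, xbar = 0.5, dt = 1),
               1 - exp(-0.5), tolerance = 1e-12)
  # sharp switch far above the transition point: rate ~ 0
  expect_equal(smoothed_heaviside(1, a = 0, b = 500, xbar = 0.5, dt = 1), 0,
               tolerance = 1e-12)
  # frozen extended-precision evaluation of the closed form
  expect_equal(smoothed_heaviside(0.2, a = 0.1, b = 10, xbar = 0.5, dt = 0.5),
               0.42233645878289279, tolerance = 1e-14)
  expect_error(smoothed_heaviside(1.2, 0, 1, 0.5, 1), "\\[0, 1\\]")
  expect_error(smoothed_heaviside(0.5, 0, 1, -0.1, 1), "\\[0, 1\\]")
})

test_that("linear ramp is zero below onset and matches closed form above", {
  expect_equal(linear_ramp(c(0, 0.2, 0.4), c = 5, xbar = 0.4, dt = 2),
               c(0, 0, 0))
  expect_equal(linear_ramp(1, c = 1, xbar = 0, dt = 1), 1 - exp(-1),
               tolerance = 1e-12)
  # frozen extended-precision evaluation
  expect_equal(linear_ramp(0.7, c = 2, xbar = 0.4, dt = 0.25),
               0.22119921692859513, tolerance = 1e-14)
  expect_error(linear_ramp(0.5, 1, 1, 1), "\\[0, 1\\)")
})

test_that("transition functions are monotone in the concentration", {
  x <- seq(0, 1, by = 0.01)
  s <- smoothed_heaviside(x, a = 0.2, b = 8, xbar = 0.4, dt = 0.5)
  expect_true(all(diff(s) <= 1e-14))
  r <- linear_ramp(x, c = 1.5, xbar = 0.3, dt = 0.5)
  expect_true(all(diff(r) >= -1e-14))
})

test_that("transition probabilities obey the closed forms and stay in [0,1]", {
  p <- cell_cycle_params()
  dt <- 0.5
  # no TRA: Q->SG2 equals the bare ramp
  pr <- transition_probabilities(0.8, 0, 0, 0, p, dt)
  expect_equal(pr$p_Q_SG2,
               linear_ramp(0.8, p$c_QSG2, p$u_n_QSG2, dt))
  # drug-free: Q->D is the bare switch, H->D is r_HD * dt
  expect_equal(pr$p_Q_D,
               smoothed_heaviside(0.8, p$a_QD, p$b_QD, p$u_n_QD, dt))
  expect_equal(pr$p_H_D, p$r_HD * dt)
  # strong TRA suppression sends Q->SG2 to zero
  psup <- cell_cycle_params(lambda_QSG2 = 200)
  prs <- transition_probabilities(0.8, 0, 0, 1, psup, dt)
  expect_lt(prs$p_Q_SG2, 1e-10)
  # property: clamped to [0,1] over a box of parameters and inputs
  set.seed(42)
  for (rep in 1:200) {
    pp <- cell_cycle_params(
      c_QSG2 = runif(1, 0, 5), u_n_QSG2 = runif(1, 0, 0.9),
      lambda_QSG2 = runif(1, 0, 10), a_QD = runif(1, 0, 2),
      b_QD = runif(1, 0, 100), u_n_QD = runif(1),
      xi_d_QD = runif(1, 0, 1e3), xi_t_QD = runif(1, 0, 1e3),
      xi_dt_QD = runif(1, 0, 1e4), c_SG2SG2 = runif(1, 0, 5),
      u_d_SG2SG2 = runif(1, 0, 0.9), c_SG2D = runif(1, 0, 5),
      u_n_SG2D = runif(1, 0, 0.9), r_HD = runif(1, 0, 2),
      xi_d_HD = runif(1, 0, 1e3), xi_t_HD = runif(1, 0, 1e3),
      xi_dt_HD = runif(1, 0, 1e4))
    pr <- transition_probabilities(runif(1), runif(1), runif(1), runif(1),
                                   pp, dt = runif(1, 0, 2))
    vals <- unlist(pr)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("cell-cycle parameter set has exactly 20 scalars and validates", {
  p <- cell_cycle_params()
  expect_length(unclass(p), 20L)
  expect_error(cell_cycle_params(u_n_H = 1.5), "\\[0, 1\\]")
  expect_error(cell_cycle_params(r_HD = -1), "nonnegative")
})

test_that("deterministic timers: SG2 divides at T_SG2, G1 matures at T_G1", {
  p <- cell_cycle_params()
  geo <- cell_geometry()
  cells <- new_cell_population(matrix(c(0, 0, 0), 1), state = "SG2",
                               clock = p$T_SG2 - 0.05)
  set.seed(1)
  out <- step_cells(cells, list(u_n = 1), p, geo, dt = 0.1)
  expect_equal(nrow(out), 2L)                 # daughter created
  expect_equal(out$state, c("G1", "G1"))
  expect_equal(out$clock, c(0, 0))
  # both at half the mother's volume
  expect_equal(out$r_physical, rep(geo$r_physical * 2^(-1 / 3), 2))
  # daughter placed at the post-division physical radius from the mother
  d <- sqrt(sum((out[2, c("x", "y", "z")] - out[1, c("x", "y", "z")])^2))
  expect_equal(d, geo$r_physical * 2^(-1 / 3), tolerance = 1e-12)

  g1 <- new_cell_population(matrix(0, 1, 3), state = "G1",
                            clock = p$T_G1 - 0.05)
  out2 <- step_cells(g1, list(u_n = 1), p, geo, dt = 0.1)
  expect_equal(out2$state, "Q")
  expect_equal(out2$r_physical, geo$r_physical)  # back to natural size
})

test_that("hypoxia switch is a threshold on the nutrient level", {
  p <- cell_cycle_params()
  q <- new_cell_population(matrix(0, 1, 3), state = "Q")
  set.seed(1)
  expect_equal(step_cells(q, list(u_n = p$u_n_H - 1e-9), p,
                          cell_geometry(), 0.1)$state, "H")
  h <- new_cell_population(matrix(0, 1, 3), state = "H")
  expect_equal(step_cells(h, list(u_n = p$u_n_H), p,
                          cell_geometry(), 0.1)$state, "Q")
})

test_that("dead cells are absorbing and unknown states are fatal", {
  p <- cell_cycle_params()
  d <- new_cell_population(matrix(0, 1, 3), state = "D", clock = 3)
  out <- step_cells(d, list(u_n = 1), p, cell_geometry(), 0.1)
  expect_equal(out$state, "D")
  expect_equal(out$clock, 3)  # clock frozen too
  bad <- d
  bad$state <- "X"
  expect_error(step_cells(bad, list(u_n = 1), p, cell_geometry(), 0.1),
               "unknown")
})

test_that("only the allowed transitions are reachable from each state", {
  # drive many single cells from each state across concentration corners and
  # record the observed one-step targets
  p <- cell_cycle_params(r_HD = 0.5, c_QSG2 = 2, a_QD = 0.5, c_SG2D = 2,
                         c_SG2SG2 = 2, u_n_SG2D = 0.1)
  allowed <- list(Q = c("Q", "SG2", "H", "D"),
                  SG2 = c("SG2", "G1", "D"),
                  G1 = c("G1", "Q"),
                  H = c("H", "Q", "D"),
                  D = "D")
  set.seed(99)
  for (st in names(allowed)) {
    seen <- character(0)
    for (rep in 1:300) {
      cells <- new_cell_population(matrix(0, 1, 3), state = st,
                                   clock = runif(1, 0, 15))
      out <- step_cells(cells,
                        list(u_n = sample(c(0, 0.1, 0.5, 1), 1),
                             u_d = sample(c(0, 1), 1),
                             u_t = sample(c(0, 1), 1)),
                        p, cell_geometry(), dt = 0.5)
      seen <- union(seen, out$state[1])
    }
    expect_true(all(seen %in% allowed[[st]]),
                info = paste("from", st, ":", paste(seen, collapse = ",")))
  }
})

test_that("Monte-Carlo transition frequencies match the closed form", {
  p <- cell_cycle_params()
  dt <- 1
  n <- 10000
  u_n <- 0.6
  set.seed(7)
  cells <- new_cell_population(matrix(0, n, 3), state = "Q")
  out <- step_cells(cells, list(u_n = rep(u_n, n)), p, cell_geometry(), dt)
  pr <- transition_probabilities(u_n, 0, 0, 0, p, dt)
  expect_true(within_3se(mean(out$state == "SG2"), pr$p_Q_SG2, n))
})

test_that("hypoxic cells die at rate r_HD: mean lifetime is 1/r_HD", {
  p <- cell_cycle_params(r_HD = 0.05)
  n <- 2000
  dt <- 1
  set.seed(11)
  cells <- new_cell_population(matrix(0, n, 3), state = "H")
  death_time <- rep(NA_real_, n)
  for (step in 1:160) {
    cells <- step_cells(cells, list(u_n = rep(0, n)), p, cell_geometry(), dt)
    died <- is.na(death_time) & cells$state == "D"
    death_time[died] <- step * dt
  }
  # discrete geometric lifetime: mean = dt / p_step with p = 1 - exp(-r dt)
  p_step <- p$r_HD * dt  # probability as implemented (clamped product)
  expected <- dt / p_step
  se <- expected / sqrt(sum(!is.na(death_time)))
  expect_lt(abs(mean(death_time, na.rm = TRUE) - expected), 4 * se)
})

test_that("population grows under saturating nutrients, dies without", {
  p <- cell_cycle_params()
  set.seed(5)
  cells <- place_spheroid(50, 9.953, center = c(0, 0, 0))
  rich <- cells
  for (step in 1:160) {
    rich <- step_cells(rich, list(u_n = rep(1, nrow(rich))), p,
                       cell_geometry(), dt = 0.5)
  }
  expect_gt(sum(rich$state != "D"), 50)

  poor <- cells
  for (step in 1:160) {
    poor <- step_cells(poor, list(u_n = rep(0, nrow(poor))), p,
                       cell_geometry(), dt = 0.5)
  }
  expect_equal(sum(poor$state %in% c("Q", "SG2", "G1")), 0)
  expect_gt(sum(poor$state == "D"), 40)  # 80 h >> 1/r_HD
})

test_that("cell snapshots round-trip exactly through the text format", {
  set.seed(3)
  cells <- place_spheroid(20, 9.953, center = c(50, 50, 50))
  cells$state[3] <- "H"
  path <- tempfile(fileext = ".tsv")
  write_cells(cells, path)
  back <- read_cells(path)
  expect_equal(as.data.frame(back), as.data.frame(cells))
})
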