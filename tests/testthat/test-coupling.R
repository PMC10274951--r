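# Agent -> field coupling and the parameter-derivation utilities.

test_that("tumor deposition conserves totals and respects state gating", {
  prm <- coupling_params(alpha_n = 0.3, alpha_v = 0.2, alpha_d = 0.05,
                         alpha_t = 0.02)
  g <- substance_grid("nutrients", 9, 20, D = 50)
  set.seed(41)
  n <- 100
  cells <- new_cell_population(matrix(runif(3 * n, 0, 160), ncol = 3))
  cells$state[1:30] <- "H"
  cells$state[31:40] <- "D"
  f <- tumor_source_sink_fields(cells, g, prm)
  live <- sum(cells$state != "D")
  hyp <- sum(cells$state == "H")
  expect_equal(sum(f$A_minus_n), prm$alpha_n * live)
  expect_equal(sum(f$A_minus_d), prm$alpha_d * live)
  expect_equal(sum(f$A_minus_t), prm$alpha_t * live)
  expect_equal(sum(f$A_plus_v), prm$alpha_v * hyp)

  # toggling one cell H -> Q changes only the VEGF source
  cells2 <- cells
  cells2$state[1] <- "Q"
  f2 <- tumor_source_sink_fields(cells2, g, prm)
  expect_equal(f2$A_minus_n, f$A_minus_n)
  expect_equal(sum(f2$A_plus_v), prm$alpha_v * (hyp - 1))

  # toggling to D removes the cell from every field
  cells3 <- cells
  cells3$state[41] <- "D"
  f3 <- tumor_source_sink_fields(cells3, g, prm)
  expect_equal(sum(f3$A_minus_n), prm$alpha_n * (live - 1))

  # an all-dead population contributes nothing
  cells$state <- "D"
  f0 <- tumor_source_sink_fields(cells, g, prm)
  expect_true(all(vapply(f0, function(a) sum(a) == 0, logical(1))))
})

test_that("a single cell deposits on exactly one node", {
  prm <- coupling_params()
  g <- substance_grid("nutrients", 7, 25, D = 50)
  cells <- new_cell_population(matrix(c(74, 51, 149), 1), state = "Q")
  f <- tumor_source_sink_fields(cells, g, prm)
  expect_equal(sum(f$A_minus_n > 0), 1L)
  expect_equal(max(f$A_minus_n), prm$alpha_n)
  expect_equal(sum(f$A_plus_v), 0)  # Q cells do not secrete VEGF
  # node is the nearest one: (74,51,149)/25 -> indices (4, 3, 7)
  expect_equal(f$A_minus_n[4, 3, 7], prm$alpha_n)
})

test_that("vessel line-delta places the printed point counts and conserves surface", {
  v <- straight_chain(1, len = 10, diameter = 8)
  pts <- vessel_line_delta(v[1, ], h_min = 22.5)
  expect_equal(nrow(pts), 3L)               # m = max(3, ceil(2*10/22.5+1))
  expect_equal(sum(pts$weight), 2 * pi * 4 * 10, tolerance = 1e-12)

  v2 <- straight_chain(1, len = 100, diameter = 8)
  pts2 <- vessel_line_delta(v2[1, ], h_min = 22.5)
  expect_equal(nrow(pts2), 10L)             # ceil(2*100/22.5 + 1) = 10
  expect_equal(sum(pts2$weight), 2 * pi * 4 * 100, tolerance = 1e-12)
  # sample points lie on the center line, inside the segment
  expect_true(all(pts2$x > 0 & pts2$x < 100))
  expect_equal(pts2$y, rep(0, 10))
})

test_that("vessel fields: sources, sinks, windows and supply factor", {
  g <- substance_grid("nutrients", 9, 20, D = 50, origin = c(-80, -80, -80))
  prm <- coupling_params(beta_n = 1e-3, beta_v = 2e-3, beta_d = 5e-4,
                         beta_t = 5e-4)
  set.seed(43)
  v <- straight_chain(5, len = 10, start = c(-40, 0, 0), diameter = 10)
  surf <- sum(2 * pi * 5 * rep(10, 5))

  # outside every window: no drug source at all
  f <- vessel_source_sink_fields(v, g, prm, phi = 1,
                                 dox_active = FALSE, tra_active = FALSE)
  expect_equal(sum(f$A_plus_d), 0)
  expect_equal(sum(f$A_plus_t), 0)
  expect_equal(sum(f$A_plus_n), prm$beta_n * surf, tolerance = 1e-12)
  expect_equal(sum(f$A_minus_v), prm$beta_v * surf, tolerance = 1e-12)

  # doubling phi doubles the DOX source node-wise
  f1 <- vessel_source_sink_fields(v, g, prm, phi = 1, dox_active = TRUE)
  f2 <- vessel_source_sink_fields(v, g, prm, phi = 2, dox_active = TRUE)
  expect_equal(f2$A_plus_d, 2 * f1$A_plus_d)
  expect_equal(sum(f1$A_plus_d), prm$beta_d * surf, tolerance = 1e-12)
})

test_that("mass-scaled diffusion reproduces the printed derivations", {
  expect_equal(scaled_diffusion(180), list(alpha = 1, D = 50))
  vm <- scaled_diffusion(19.3e3)
  expect_equal(round(vm$alpha), 107)
  expect_equal(vm$D, 10.524667954034835, tolerance = 1e-12)
  tr <- scaled_diffusion(145e3)
  expect_equal(round(tr$alpha), 806)
  expect_equal(tr$alpha^(-1 / 3), 0.10747352686054839, tolerance = 1e-12)
  tab <- diffusion_table()
  expect_equal(tab$alpha_r, c(1, 107, 214, 3, 806))
  expect_equal(tab$scale_r[tab$substance == "vegf_monomer"], 0.21)
  expect_equal(tab$D_r[tab$substance == "vegf_monomer"], 10.5)
  expect_error(scaled_diffusion(-1), "positive")
})

test_that("half-life conversion and homogenized decay", {
  expect_equal(halflife_to_decay(48), 0.014440566261665527, tolerance = 1e-14)
  expect_equal(halflife_to_decay(20), 0.034657359027997266, tolerance = 1e-14)
  expect_equal(halflife_to_decay(28 * 24), 0.0010314690186903948,
               tolerance = 1e-14)
  expect_error(halflife_to_decay(0), "> 0")

  expect_equal(effective_decay(0.3, 0.5, 0), 0.3)
  expect_equal(effective_decay(0, 0.01, 100), 1)
  # linearity in the density
  lam <- 0.1; r <- 0.02; rho <- 7
  expect_equal(effective_decay(lam, r, 2 * rho) - effective_decay(lam, r, rho),
               r * rho)
})

test_that("one hypoxic cell + one vessel reach the dense-solve VEGF steady state", {
  skip_if_not_installed("Matrix")
  n <- 13; h <- 20
  g <- substance_grid("vegf", n, h, D = 10.5, lam = 0.02)
  prm <- coupling_params(alpha_v = 0.4, beta_v = 1e-3)
  cells <- new_cell_population(matrix(c(120, 120, 120), 1), state = "H")
  L <- (n - 1) * h
  v <- straight_chain(4, len = 10, start = c(40, 180, 120), diameter = 10)
  tum <- tumor_source_sink_fields(cells, g, prm)
  ves <- vessel_source_sink_fields(v, g, prm)
  Ap <- tum$A_plus_v
  Am <- ves$A_minus_v

  # iterate the FTCS map to (near) stationarity
  dt <- 0.8 / (g$lam + 6 * g$D / h^2 + max(Ap) + max(Am))
  for (i in 1:4000) g <- ftcs_step(g, Ap, Am, dt)

  # independent steady state: (lam - D Lap + diag(A+ + A-)) u = A+
  N <- n^3
  idx <- function(i, j, k) i + (j - 1) * n + (k - 1) * n * n
  clampi <- function(i) min(max(i, 1), n)
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(r, c, x) {
    trip$i <<- c(trip$i, r); trip$j <<- c(trip$j, c); trip$x <<- c(trip$x, x)
  }
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    r <- idx(i, j, k)
    add(r, r, g$lam + 6 * g$D / h^2 + Ap[i, j, k] + Am[i, j, k])
    for (nb in list(c(clampi(i + 1), j, k), c(clampi(i - 1), j, k),
                    c(i, clampi(j + 1), k), c(i, clampi(j - 1), k),
                    c(i, j, clampi(k + 1)), c(i, j, clampi(k - 1)))) {
      add(r, idx(nb[1], nb[2], nb[3]), -g$D / h^2)
    }
  }
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(N, N))
  u_star <- as.numeric(Matrix::solve(A, as.numeric(Ap)))
  expect_equal(as.numeric(g$u), u_star, tolerance = 1e-6)
})
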