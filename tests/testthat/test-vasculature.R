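# Vessel tree structure, diameters, branching criteria, sprouting and
# tip growth.

test_that("diameter rules: floor 5, cap 20, factors 0.8 and 0.98", {
  expect_equal(branch_diameter(30), 20)
  expect_equal(branch_diameter(4), 5)
  expect_equal(branch_diameter(10), 8)
  expect_equal(taper_diameter(25), 20)
  expect_equal(taper_diameter(5), 5)
  expect_equal(taper_diameter(10), 9.8)
  expect_error(branch_diameter(0), "positive")
})

test_that("tree audit accepts chains and rejects broken structures", {
  v <- straight_chain(6)
  expect_silent(validate_vessel_tree(v))
  expect_equal(vessel_tips(v)$id, 6L)

  disconnected <- v
  disconnected$x0[3] <- disconnected$x0[3] + 1
  expect_error(validate_vessel_tree(disconnected), "start")

  triple <- dplyr::bind_rows(v, v[4:6, ] |>
    dplyr::mutate(id = id + 10L,
                  mother = c(3L, 14L, 15L)))
  # agent 3 now has daughters 4 and 14: still legal (2 daughters)
  expect_silent(validate_vessel_tree(triple))
  quad <- dplyr::bind_rows(triple,
                           dplyr::mutate(v[4, ], id = 30L, mother = 3L))
  expect_error(validate_vessel_tree(quad), "more than two")

  thin <- v
  thin$diameter[2] <- 3
  expect_error(validate_vessel_tree(thin), "at least 5")
})

test_that("nearest tip distance is the exact minimum (brute-force oracle)", {
  expect_equal(nearest_tip_distance(c(0, 0, 0), NULL), Inf)
  expect_equal(nearest_tip_distance(c(0, 0, 0),
                                    matrix(c(100, 0, 0), 1)), 100)
  set.seed(47)
  tips <- matrix(runif(600, -50, 50), ncol = 3)
  pt <- c(5, -3, 12)
  expect_equal(nearest_tip_distance(pt, tips),
               min(sqrt(colSums((t(tips) - pt)^2))))
})

test_that("branching needs VEGF, tip clearance, and branch spacing", {
  prm <- angiogenesis_params(u_v_thres = 0.1, d_tip = 20, d_branch = 45)
  g <- substance_grid("vegf", 11, 30, D = 10, origin = c(-150, -150, -150))
  v <- straight_chain(10, len = 10, start = c(-50, 0, 0))

  # (i) below the VEGF threshold: never
  expect_false(can_branch(v, 5L, u_v = 0.05, tip_points = NULL, prm))
  # tips and roots are never candidates
  expect_false(can_branch(v, 1L, u_v = 1, tip_points = NULL, prm))
  expect_false(can_branch(v, 10L, u_v = 1, tip_points = NULL, prm))
  # (ii) a tip too close blocks branching (midpoint of agent 5 is (-5,0,0))
  expect_false(can_branch(v, 5L, u_v = 1,
                          tip_points = matrix(c(-5, 10, 0), 1), prm))
  # empty tip registry counts as infinitely far
  expect_true(can_branch(v, 5L, u_v = 1, tip_points = NULL, prm))
})

test_that("branch spacing follows hand-counted arc lengths along a chain", {
  prm <- angiogenesis_params(u_v_thres = 0, d_tip = 0, d_branch = 45)
  # chain of 10 segments of 10 um; give agent 1 a second daughter so that it
  # becomes a branching point at the chain's head
  v <- straight_chain(10, len = 10)
  stub <- tibble::tibble(id = 99L, mother = 1L, x0 = 10, y0 = 0, z0 = 0,
                         x1 = 10, y1 = 1, z1 = 0, diameter = 8,
                         stopped = FALSE)
  v2 <- dplyr::bind_rows(v, stub)
  # arc length from agent q (q >= 2) back to the branching point at agent 1
  # walks q-2 intermediate segments: length = (q - 2) * 10
  expected_arc <- (2:9 - 2) * 10
  eligible <- vapply(2:9, function(q) {
    can_branch(v2, q, u_v = 1, tip_points = NULL, prm)
  }, logical(1))
  expect_equal(eligible, expected_arc > 45)
})

test_that("sprouting is Bernoulli at rate p_s_rate * dt on a cone", {
  v <- straight_chain(3)
  # p_s_rate = 0: never sprouts
  prm0 <- angiogenesis_params(p_s_rate = 0)
  set.seed(53)
  expect_null(try_sprout(v, 2L, c(0, 0, 1), prm0, dt = 1))

  # Monte-Carlo rate within 3 binomial SE
  prm <- angiogenesis_params(p_s_rate = 0.02)
  set.seed(59)
  hits <- 0L
  for (i in 1:10000) {
    if (!is.null(try_sprout(v, 2L, c(0, 0, 1), prm, dt = 1))) hits <- hits + 1L
  }
  expect_true(within_3se(hits / 10000, 0.02, 10000))

  # degenerate cone: axis exactly along the gradient, unit length, attached
  prm1 <- angiogenesis_params(p_s_rate = 1e9, cone_half_angle = 0)
  set.seed(61)
  s <- try_sprout(v, 2L, c(0, 0, 2), prm1, dt = 1)
  axis <- c(s$x1 - s$x0, s$y1 - s$y0, s$z1 - s$z0)
  expect_equal(axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(c(s$x0, s$y0, s$z0), c(20, 0, 0))  # mother's end point
  expect_equal(s$diameter, branch_diameter(10))

  # sampled axes lie on the cone at the requested half-angle
  prm2 <- angiogenesis_params(p_s_rate = 1e9, cone_half_angle = pi / 7)
  for (i in 1:20) {
    s2 <- try_sprout(v, 2L, c(1, 2, -0.5), prm2, dt = 1)
    ax <- c(s2$x1 - s2$x0, s2$y1 - s2$y0, s2$z1 - s2$z0)
    gu <- c(1, 2, -0.5) / sqrt(sum(c(1, 2, -0.5)^2))
    expect_equal(acos(sum(ax * gu) / sqrt(sum(ax^2))), pi / 7,
                 tolerance = 1e-10)
  }
})

test_that("tip growth: gradient gating, inertial limit, and the 9+1 split", {
  # inertial limit w2 = 1: straight continuation at speed * dt
  prm <- angiogenesis_params(w1 = 0, w2 = 1, w3 = 0, speed = 2,
                             g_min = 0, g_stop = 10)
  v <- straight_chain(1, len = 5)
  set.seed(67)
  out <- grow_tip(v, 1L, c(1e-4, 0, 0), prm, dt = 0.5)
  expect_equal(out$x1, 6)                     # 5 + 2 * 0.5
  expect_equal(c(out$y1, out$z1), c(0, 0))

  # below g_min: no-op; above g_stop: permanently stopped
  prm2 <- angiogenesis_params(g_min = 1e-3, g_stop = 0.1)
  expect_equal(grow_tip(v, 1L, c(1e-4, 0, 0), prm2, dt = 1), v)
  stopped <- grow_tip(v, 1L, c(0.2, 0, 0), prm2, dt = 1)
  expect_true(stopped$stopped[1])
  expect_equal(stopped$x1, v$x1)
  # a stopped tip never grows again
  expect_equal(grow_tip(stopped, 1L, c(1e-2, 0, 0), prm2, dt = 1), stopped)

  # split rule: length 9.5 + 1 um of growth -> 9 um proximal, 1 um distal tip
  prm3 <- angiogenesis_params(w1 = 0, w2 = 1, w3 = 0, speed = 1,
                              g_min = 0, g_stop = 10)
  v95 <- straight_chain(1, len = 9.5, diameter = 10)
  out3 <- grow_tip(v95, 1L, c(1e-4, 0, 0), prm3, dt = 1)
  expect_equal(nrow(out3), 2L)
  len <- sqrt((out3$x1 - out3$x0)^2 + (out3$y1 - out3$y0)^2 +
                (out3$z1 - out3$z0)^2)
  expect_equal(unname(len), c(9, 1), tolerance = 1e-12)
  expect_equal(out3$mother[2], out3$id[1])
  expect_equal(out3$diameter[2], taper_diameter(10))
  expect_silent(validate_vessel_tree(out3))
})

test_that("a growth step in a uniform gradient follows the gradient line", {
  prm <- angiogenesis_params(w1 = 1, w2 = 0, w3 = 0, speed = 2,
                             g_min = 0, g_stop = 10)
  v <- straight_chain(1, len = 2)
  for (i in 1:3) v <- grow_tip(v, max(v$id), c(0, 1e-3, 0), prm, dt = 1)
  tip <- vessel_tips(v)
  expect_equal(nrow(v), 1L)           # no split below 10 um
  expect_equal(tip$x1, 2)             # end point moved only along +y
  expect_equal(tip$y1, 6)             # 3 steps of 2 um along the gradient
})

test_that("whole-forest stepping keeps the tree invariants", {
  set.seed(71)
  g <- substance_grid("vegf", 13, 25, D = 10.5, lam = 0.01)
  # VEGF blob in the center drives growth
  ctr <- array(0, c(13, 13, 13)); ctr[7, 7, 7] <- 0.9
  for (i in 1:400) g <- ftcs_step(g, A_plus = ctr * 0.5, dt = 0.5)
  prm <- angiogenesis_params(u_v_thres = 1e-4, d_tip = 15, d_branch = 20,
                             p_s_rate = 0.5, g_min = 1e-8, g_stop = 1,
                             w3 = 0.1)
  v <- straight_chain(12, len = 10, start = c(30, 150, 150))
  n0 <- nrow(v)
  for (s in 1:60) v <- step_vasculature(v, g, prm, dt = 0.5)
  expect_gt(nrow(v), n0)      # it actually grew
  expect_silent(validate_vessel_tree(v))
  nd <- tabulate(match(v$mother, v$id), nbins = nrow(v))
  expect_true(all(nd <= 2))
  expect_true(all(v$diameter >= 5))
  expect_true(all(v$diameter[is.na(v$mother)] <= 10))
  # new branches never exceed 20 um
  expect_true(all(v$diameter[!is.na(v$mother)] <= 20))
})

test_that("vessel trees round-trip exactly through the text format", {
  set.seed(73)
  spec <- vasculature_gen_spec(domain_upper = c(400, 400, 400),
                               exclusion_center = c(200, 200, 200),
                               exclusion_radius = 80,
                               target_length_density = 1e-5)
  v <- generate_vasculature(spec)
  path <- tempfile(fileext = ".tsv")
  write_vessel_tree(v, path)
  back <- read_vessel_tree(path)
  expect_equal(as.data.frame(back), as.data.frame(v))
})
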