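# Linked tree of cylindrical vessel agents and sprouting angiogenesis.
#
# Each agent is a cylinder segment with a start point, an end point and a
# diameter, one mother (NA for roots) and zero, one or two daughters:
# 0 daughters = tip cell, 1 = regular segment, 2 = branching point. A
# daughter starts where its mother ends, so the structure is a forest of
# connected trees. Tips elongate along the VEGF gradient; regular segments
# may sprout a second daughter on a random cone around the gradient.

#' Construct a vessel tree (or forest)
#'
#' @param id Integer agent ids (unique).
#' @param mother Integer id of each agent's mother, `NA` for roots.
#' @param start,end Numeric n x 3 matrices of segment endpoints,
#'   micrometers; every non-root agent must start where its mother ends.
#' @param diameter Segment diameters, micrometers (at least 5).
#' @param stopped Logical: has this tip permanently stopped growing?
#' @return A tibble with columns `id`, `mother`, `x0`, `y0`, `z0`, `x1`,
#'   `y1`, `z1`, `diameter`, `stopped`.
#' @export
new_vessel_tree <- function(id, mother, start, end, diameter,
                            stopped = FALSE) {
  start <- rbind(start); end <- rbind(end)
  v <- tibble::tibble(
    id = as.integer(id), mother = as.integer(mother),
    x0 = start[, 1], y0 = start[, 2], z0 = start[, 3],
    x1 = end[, 1], y1 = end[, 2], z1 = end[, 3],
    diameter = as.numeric(diameter),
    stopped = rep_len(as.logical(stopped), length(id))
  )
  validate_vessel_tree(v)
  v
}

#' Audit the vessel-tree invariants
#'
#' Checks id uniqueness, mother references, the at-most-two-daughters rule,
#' endpoint connectivity (each daughter starts at its mother's end point),
#' acyclicity, and the 5-micrometer diameter floor. Fatal on violation.
#'
#' @param vessels Vessel tree tibble.
#' @param tol Endpoint-connectivity tolerance, micrometers.
#' @return The tree, invisibly, if valid.
#' @export
validate_vessel_tree <- function(vessels, tol = 1e-6) {
  v <- vessels
  if (nrow(v) == 0) return(invisible(v))
  if (anyDuplicated(v$id)) abort("vessel tree: duplicate ids")
  has_mother <- !is.na(v$mother)
  mi <- match(v$mother[has_mother], v$id)
  if (anyNA(mi)) abort("vessel tree: mother reference to a missing id")
  nd <- tabulate(mi, nbins = nrow(v))
  if (any(nd > 2)) abort("vessel tree: an agent has more than two daughters")
  gap <- cbind(v$x0[has_mother] - v$x1[mi],
               v$y0[has_mother] - v$y1[mi],
               v$z0[has_mother] - v$z1[mi])
  if (nrow(gap) > 0 && max(abs(gap)) > tol) {
    abort("vessel tree: a daughter does not start at its mother's end point")
  }
  if (any(v$diameter < 5 - 1e-9)) {
    abort("vessel tree: diameters must be at least 5 um")
  }
  # acyclicity: walking mothers from any agent must terminate
  idx_of <- setNames(seq_len(nrow(v)), v$id)
  for (i in seq_len(nrow(v))) {
    seen <- 0L
    j <- i
    while (!is.na(v$mother[j])) {
      j <- idx_of[[as.character(v$mother[j])]]
      seen <- seen + 1L
      if (seen > nrow(v)) abort("vessel tree: cycle detected")
    }
  }
  invisible(v)
}

# number of daughters per agent (aligned with rows)
n_daughters <- function(vessels) {
  mi <- match(vessels$mother, vessels$id)
  tabulate(mi[!is.na(mi)], nbins = nrow(vessels))
}

#' Tip agents of a vessel forest
#'
#' @param vessels Vessel tree tibble.
#' @return The rows with zero daughters (terminal ends).
#' @export
vessel_tips <- function(vessels) {
  vessels[n_daughters(vessels) == 0L, , drop = FALSE]
}

segment_lengths <- function(vessels) {
  sqrt((vessels$x1 - vessels$x0)^2 + (vessels$y1 - vessels$y0)^2 +
         (vessels$z1 - vessels$z0)^2)
}

#' Diameter of a new branch
#'
#' A sprout branching off a cylinder of diameter `d0` takes
#' `max(5, min(0.8 d0, 20))` micrometers: new microvasculature never falls
#' below the capillary floor of 5 um nor exceeds 20 um.
#'
#' @param d0 Mother diameter, micrometers (positive).
#' @return Branch diameter, micrometers.
#' @examples
#' branch_diameter(10) # 8
#' @export
branch_diameter <- function(d0) {
  if (any(d0 <= 0)) abort("branch_diameter: d0 must be positive")
  pmax(5, pmin(0.8 * d0, 20))
}

#' Tapered diameter along a growing vessel
#'
#' When a tip splits, the distal segment takes
#' `max(5, min(0.98 d0, 20))` micrometers, gently narrowing the new vessel
#' towards the capillary floor.
#'
#' @param d0 Proximal diameter, micrometers (positive).
#' @return Distal diameter, micrometers.
#' @examples
#' taper_diameter(10) # 9.8
#' @export
taper_diameter <- function(d0) {
  if (any(d0 <= 0)) abort("taper_diameter: d0 must be positive")
  pmax(5, pmin(0.98 * d0, 20))
}

#' Distance to the nearest tip
#'
#' Exact minimum Euclidean distance from a point to any tip end point;
#' `Inf` for an empty registry (so the vicinity criterion passes).
#'
#' @param point Numeric 3-vector.
#' @param tip_points Numeric m x 3 matrix of tip end points.
#' @return Distance in micrometers.
#' @export
nearest_tip_distance <- function(point, tip_points) {
  if (is.null(tip_points) || NROW(tip_points) == 0) return(Inf)
  tip_points <- rbind(tip_points)
  sqrt(min((tip_points[, 1] - point[1])^2 + (tip_points[, 2] - point[2])^2 +
             (tip_points[, 3] - point[3])^2))
}

# arc length from agent `row` to the nearest branching point walking
# motherward (direction = "up") or daughterward ("down"); Inf when the walk
# ends at a root or tip (tree ends satisfy the criterion)
arc_length_to_branch <- function(vessels, row, nd, direction) {
  len <- segment_lengths(vessels)
  total <- 0
  j <- row
  repeat {
    if (direction == "up") {
      if (is.na(vessels$mother[j])) return(Inf)
      j <- match(vessels$mother[j], vessels$id)
      if (nd[j] >= 2L) return(total)
      total <- total + len[j]
    } else {
      ds <- which(!is.na(vessels$mother) & vessels$mother == vessels$id[j])
      if (length(ds) == 0) return(Inf)   # tip
      if (length(ds) >= 2) return(total) # branching point reached
      j <- ds
      total <- total + len[j]
    }
  }
}

#' Angiogenesis parameters
#'
#' @param u_v_thres VEGF concentration an agent must sense to branch.
#' @param d_tip Minimum Euclidean distance to the nearest tip, um.
#' @param d_branch Minimum arc length between branching points, um.
#' @param p_s_rate Sprouting rate, 1/h (`p_s = p_s_rate * dt` must be
#'   small).
#' @param w1,w2,w3 Growth-direction weights: gradient following, axis
#'   inertia, and randomness.
#' @param g_min Minimum gradient magnitude for tip growth (per um).
#' @param g_stop Gradient magnitude at which a tip permanently stops.
#' @param speed Tip extension rate, um/h.
#' @param split_length Tip length at which it splits into a 9 + 1 um pair,
#'   um.
#' @param cone_half_angle Half-angle of the sprouting cone around the VEGF
#'   gradient, radians.
#' @return A list of class `angiogenesis_params`.
#' @export
angiogenesis_params <- function(u_v_thres = 0.02, d_tip = 60, d_branch = 40,
                                p_s_rate = 0.05, w1 = 10, w2 = 1,
                                w3 = 0.2, g_min = 1e-5, g_stop = 1.5e-3,
                                speed = 2, split_length = 10,
                                cone_half_angle = pi / 6) {
  p <- list(u_v_thres = u_v_thres, d_tip = d_tip, d_branch = d_branch,
            p_s_rate = p_s_rate, w1 = w1, w2 = w2, w3 = w3, g_min = g_min,
            g_stop = g_stop, speed = speed, split_length = split_length,
            cone_half_angle = cone_half_angle)
  if (any(vapply(p, function(x) x < 0, logical(1)))) {
    abort("angiogenesis_params: all parameters must be nonnegative")
  }
  if (w1 + w2 + w3 <= 0) abort("angiogenesis_params: need w1 + w2 + w3 > 0")
  structure(p, class = "angiogenesis_params")
}

#' May this agent sprout a new branch?
#'
#' A regular segment (exactly one mother and one daughter) may branch iff
#' (i) the VEGF concentration at its midpoint reaches `u_v_thres`, (ii) the
#' nearest tip is farther than `d_tip`, and (iii) the arc length along the
#' vessel to both the preceding and the succeeding branching point exceeds
#' `d_branch` (tree ends count as infinitely far). Tips and branching
#' points are never candidates.
#'
#' @param vessels Vessel tree tibble.
#' @param id Agent id to test.
#' @param u_v VEGF concentration at the agent midpoint.
#' @param tip_points Matrix of current tip end points (m x 3).
#' @param params An [angiogenesis_params()].
#' @return `TRUE` or `FALSE`.
#' @export
can_branch <- function(vessels, id, u_v, tip_points, params) {
  row <- match(id, vessels$id)
  nd <- n_daughters(vessels)
  if (is.na(vessels$mother[row]) || nd[row] != 1L) return(FALSE)
  if (u_v < params$u_v_thres) return(FALSE)
  mid <- c((vessels$x0[row] + vessels$x1[row]) / 2,
           (vessels$y0[row] + vessels$y1[row]) / 2,
           (vessels$z0[row] + vessels$z1[row]) / 2)
  if (nearest_tip_distance(mid, tip_points) <= params$d_tip) return(FALSE)
  if (arc_length_to_branch(vessels, row, nd, "up") <= params$d_branch) {
    return(FALSE)
  }
  if (arc_length_to_branch(vessels, row, nd, "down") <= params$d_branch) {
    return(FALSE)
  }
  TRUE
}

# unit vector on a cone of given half-angle around axis g (unit vector);
# azimuth uniform. Draws exactly one uniform.
cone_sample <- function(g, half_angle) {
  az <- runif(1, 0, 2 * pi)
  # orthonormal basis around g
  ref <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * g) * g
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(g[2] * e1[3] - g[3] * e1[2],
          g[3] * e1[1] - g[1] * e1[3],
          g[1] * e1[2] - g[2] * e1[1])
  cos(half_angle) * g + sin(half_angle) * (cos(az) * e1 + sin(az) * e2)
}

#' Attempt to sprout a new tip from a branching candidate
#'
#' With probability `p_s = p_s_rate * dt` creates a second daughter of
#' length about one micrometer whose axis lies on a cone of half-angle
#' `cone_half_angle` around the VEGF gradient (azimuth uniform); its
#' diameter is [branch_diameter()] of the mother's. A vanishing gradient
#' falls back to a uniformly random direction on the unit sphere.
#' [can_branch()] must have returned `TRUE` for the agent.
#'
#' Draw order: one uniform for the Bernoulli trial, then (on success) one
#' uniform for the cone azimuth, or three standard normals for the
#' zero-gradient fallback.
#'
#' @param vessels Vessel tree tibble.
#' @param id Id of the sprouting agent.
#' @param grad_uv Numeric 3-vector, VEGF gradient at the agent.
#' @param params An [angiogenesis_params()].
#' @param dt Step length, hours.
#' @return A one-row tibble for the new tip agent, or `NULL`.
#' @export
try_sprout <- function(vessels, id, grad_uv, params, dt) {
  if (runif(1) >= params$p_s_rate * dt) return(NULL)
  gn <- sqrt(sum(grad_uv^2))
  axis <- if (gn < .Machine$double.eps) {
    u <- rnorm(3)
    u / sqrt(sum(u^2))
  } else {
    cone_sample(grad_uv / gn, params$cone_half_angle)
  }
  row <- match(id, vessels$id)
  start <- c(vessels$x1[row], vessels$y1[row], vessels$z1[row])
  tibble::tibble(
    id = max(vessels$id) + 1L,
    mother = vessels$id[row],
    x0 = start[1], y0 = start[2], z0 = start[3],
    x1 = start[1] + axis[1], y1 = start[2] + axis[2],
    z1 = start[3] + axis[3],
    diameter = branch_diameter(vessels$diameter[row]),
    stopped = FALSE
  )
}

#' Elongate one tip cell along the VEGF gradient
#'
#' Moves the tip end point by `speed * dt` along the normalized direction
#' `w1 * grad + w2 * axis + w3 * X3` (with `X3` uniform on `(-1, 1)^3`).
#' No growth below `g_min`; at `g_stop` the tip permanently stops (vessels
#' halt once they reach high gradients). When the tip reaches
#' `split_length` (10 um) it is split into a 9 um proximal segment and a
#' 1 um distal tip whose diameter is [taper_diameter()] of the proximal
#' one; any overshoot beyond 10 um is discarded.
#'
#' @param vessels Vessel tree tibble.
#' @param id Tip agent id (must have no daughters).
#' @param grad_uv VEGF gradient at the tip end point (3-vector).
#' @param params An [angiogenesis_params()].
#' @param dt Step length, hours.
#' @return The updated vessel tree (possibly with one new agent).
#' @export
grow_tip <- function(vessels, id, grad_uv, params, dt) {
  row <- match(id, vessels$id)
  if (vessels$stopped[row]) return(vessels)
  gn <- sqrt(sum(grad_uv^2))
  if (gn < params$g_min) return(vessels)
  if (gn >= params$g_stop) {
    vessels$stopped[row] <- TRUE
    return(vessels)
  }
  s <- c(vessels$x0[row], vessels$y0[row], vessels$z0[row])
  e <- c(vessels$x1[row], vessels$y1[row], vessels$z1[row])
  axis <- e - s
  al <- sqrt(sum(axis^2))
  if (al > 0) axis <- axis / al
  X3 <- runif(3, -1, 1)
  dir <- params$w1 * grad_uv + params$w2 * axis + params$w3 * X3
  dn <- sqrt(sum(dir^2))
  if (dn < .Machine$double.eps) return(vessels)
  dir <- dir / dn
  e_new <- e + params$speed * dt * dir
  len <- sqrt(sum((e_new - s)^2))
  if (len < params$split_length) {
    vessels$x1[row] <- e_new[1]
    vessels$y1[row] <- e_new[2]
    vessels$z1[row] <- e_new[3]
    return(vessels)
  }
  # split: proximal 9 um, distal 1 um along the new axis, no residual
  u <- (e_new - s) / len
  mid <- s + 9 * u
  tip_end <- s + 10 * u
  d_prox <- vessels$diameter[row]
  vessels$x1[row] <- mid[1]; vessels$y1[row] <- mid[2]
  vessels$z1[row] <- mid[3]
  new_tip <- tibble::tibble(
    id = max(vessels$id) + 1L, mother = vessels$id[row],
    x0 = mid[1], y0 = mid[2], z0 = mid[3],
    x1 = tip_end[1], y1 = tip_end[2], z1 = tip_end[3],
    diameter = taper_diameter(d_prox),
    stopped = FALSE
  )
  dplyr::bind_rows(vessels, new_tip)
}

#' One angiogenesis step for the whole forest
#'
#' First every branching candidate (in ascending id) is tested with
#' [can_branch()] against the tip registry frozen at the start of the step
#' and, if eligible, attempts [try_sprout()]; then every tip (ascending id,
#' including tips created this step) is elongated with [grow_tip()]. VEGF
#' values and gradients are read from `uv_grid` at agent midpoints and tip
#' end points respectively.
#'
#' @param vessels Vessel tree tibble.
#' @param uv_grid VEGF [substance_grid()].
#' @param params An [angiogenesis_params()].
#' @param dt Step length, hours.
#' @return The updated vessel tree.
#' @export
step_vasculature <- function(vessels, uv_grid, params, dt) {
  if (nrow(vessels) == 0) return(vessels)
  nd <- n_daughters(vessels)
  tipsm <- vessels[nd == 0L, , drop = FALSE]
  tip_points <- cbind(tipsm$x1, tipsm$y1, tipsm$z1)

  # branching pass over regular segments in ascending id
  cand <- which(!is.na(vessels$mother) & nd == 1L)
  cand <- cand[order(vessels$id[cand])]
  if (length(cand) > 0) {
    mids <- cbind((vessels$x0[cand] + vessels$x1[cand]) / 2,
                  (vessels$y0[cand] + vessels$y1[cand]) / 2,
                  (vessels$z0[cand] + vessels$z1[cand]) / 2)
    uv <- sample_at(uv_grid, mids)
    grads <- gradient_at(uv_grid, mids)
    for (q in seq_along(cand)) {
      i <- cand[q]
      if (uv[q] < params$u_v_thres) next  # cheap test before geometry
      if (!can_branch(vessels, vessels$id[i], uv[q], tip_points, params)) next
      sprout <- try_sprout(vessels, vessels$id[i], grads[q, ], params, dt)
      if (!is.null(sprout)) vessels <- dplyr::bind_rows(vessels, sprout)
    }
  }

  # growth pass over tips in ascending id
  repeat_ids <- vessel_tips(vessels)$id
  for (id in sort(repeat_ids)) {
    row <- match(id, vessels$id)
    if (vessels$stopped[row]) next
    ep <- c(vessels$x1[row], vessels$y1[row], vessels$z1[row])
    g <- tryCatch(gradient_at(uv_grid, ep)[1, ], error = function(e) NULL)
    if (is.null(g)) { vessels$stopped[row] <- TRUE; next }  # left the domain
    vessels <- grow_tip(vessels, id, g, params, dt)
  }
  vessels
}

#' Write / read a vessel tree
#'
#' Tab-separated text, one record per agent (id, mother id, start, end,
#' diameter, stopped flag), full double precision; the round trip is exact.
#'
#' @param vessels Vessel tree tibble.
#' @param path File path.
#' @return `read_vessel_tree` returns the tree; `write_vessel_tree`
#'   invisibly returns `path`.
#' @export
write_vessel_tree <- function(vessels, path) {
  df <- as.data.frame(vessels)
  for (col in c("x0", "y0", "z0", "x1", "y1", "z1", "diameter")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vessel_tree
#' @export
read_vessel_tree <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$id <- as.integer(df$id)
  df$mother <- as.integer(df$mother)
  df$stopped <- as.logical(df$stopped)
  v <- tibble::as_tibble(df)
  validate_vessel_tree(v)
  v
}

#' Total vessel length and surface of a forest
#'
#' @param vessels Vessel tree tibble.
#' @return Named numeric vector with `n_agents`, `length` (um) and
#'   `surface` (um^2).
#' @export
vessel_totals <- function(vessels) {
  len <- segment_lengths(vessels)
  c(n_agents = nrow(vessels), length = sum(len),
    surface = sum(2 * pi * (vessels$diameter / 2) * len))
}
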