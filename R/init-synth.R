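# Initial-state construction: densely packed tumor spheroids and a
# synthetic initial vasculature. The vasculature generator is an original
# stand-in for data-derived networks: a sparse forest of connected
# cylindrical chains (5-20+ um diameter) traced as bounded random walks
# through the domain, leaving an exclusion ball around the tumor seed
# empty, calibrated to a target vessel length per unit volume.

#' Radius of a randomly close-packed spheroid
#'
#' `N` spheres of radius `r_cell` packed at the random-close-packing
#' fraction 0.64 fill a ball of radius `r_cell * (N / 0.64)^(1/3)`.
#'
#' @param N Cell count, `>= 1`.
#' @param r_cell Cell radius, micrometers.
#' @return Spheroid radius, micrometers.
#' @examples
#' spheroid_radius(500, 9.953)
#' @export
spheroid_radius <- function(N, r_cell) {
  if (any(N < 1) || any(r_cell <= 0)) {
    abort("spheroid_radius: need N >= 1 and r_cell > 0")
  }
  r_cell * (N / 0.64)^(1 / 3)
}

#' Seed a tumor spheroid
#'
#' Places `N` cells uniformly at random inside the ball of radius
#' [spheroid_radius()] around `center`. Runs that start with vasculature
#' and no nutrients begin in the hypoxic state `H`; spheroid-only runs with
#' a nutrient bath begin in `Q`.
#'
#' Draw order: `3 N` standard normals (directions) then `N` uniforms
#' (radii).
#'
#' @param N Cell count.
#' @param r_cell Cell radius used for the packing, micrometers.
#' @param center Numeric 3-vector, micrometers.
#' @param state Initial state for all cells (`"Q"` or `"H"`).
#' @param geometry A [cell_geometry()].
#' @return A cell population tibble.
#' @export
place_spheroid <- function(N, r_cell, center = c(0, 0, 0), state = "Q",
                           geometry = cell_geometry()) {
  R <- spheroid_radius(N, r_cell)
  dirs <- matrix(rnorm(3 * N), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- R * runif(N)^(1 / 3)
  pos <- sweep(dirs * rad, 2, center, `+`)
  new_cell_population(pos, state = state, geometry = geometry)
}

#' Specification of the synthetic vasculature generator
#'
#' @param domain_lower,domain_upper Numeric 3-vectors bounding the cube,
#'   micrometers.
#' @param n_parents Number of parent vessels to trace (walks are added
#'   until the target density is met, up to this count; 0 yields an empty
#'   forest).
#' @param diameter_range Range of parent starting diameters, micrometers.
#' @param waviness Angular random-walk step: the direction is perturbed by
#'   `waviness` times a standard-normal 3-vector each segment.
#' @param exclusion_center,exclusion_radius Ball kept free of vessels
#'   (where the tumor is seeded), micrometers.
#' @param target_length_density Target total vessel length per volume,
#'   um/um^3.
#' @param segment_length Agent length, micrometers.
#' @return A list of class `vasculature_gen_spec`.
#' @export
vasculature_gen_spec <- function(domain_lower = c(0, 0, 0),
                                 domain_upper = c(600, 600, 600),
                                 n_parents = 200,
                                 diameter_range = c(8, 25),
                                 waviness = 0.25,
                                 exclusion_center = c(300, 300, 300),
                                 exclusion_radius = 120,
                                 target_length_density = 3e-5,
                                 segment_length = 10) {
  spec <- list(domain_lower = domain_lower, domain_upper = domain_upper,
               n_parents = n_parents, diameter_range = diameter_range,
               waviness = waviness, exclusion_center = exclusion_center,
               exclusion_radius = exclusion_radius,
               target_length_density = target_length_density,
               segment_length = segment_length)
  ext <- domain_upper - domain_lower
  if (any(ext <= 0)) abort("vasculature_gen_spec: empty domain")
  if (exclusion_radius >= min(ext) / 2) {
    abort("vasculature_gen_spec: exclusion ball must fit inside the domain")
  }
  structure(spec, class = "vasculature_gen_spec")
}

# start point on a random face of the domain, outside the exclusion ball
random_face_point <- function(lo, hi, exc_c, exc_r) {
  repeat {
    face <- sample.int(6, 1)
    ax <- (face + 1) %/% 2
    p <- lo + runif(3) * (hi - lo)
    p[ax] <- if (face %% 2 == 1) lo[ax] else hi[ax]
    if (sqrt(sum((p - exc_c)^2)) > exc_r) return(p)
  }
}

#' Generate a synthetic initial vasculature
#'
#' Traces parent vessels as bounded random walks of `segment_length`
#' cylinders through the domain: each walk starts on a random face heading
#' inward, perturbs its direction by the waviness each step, is deflected
#' off the exclusion ball, and stops when it leaves the domain. Diameters
#' start uniformly in `diameter_range` and taper gently (factor 0.99 per
#' segment, floored at 5 um). Walks are added until the total length per
#' volume reaches the target density (or `n_parents` walks have been
#' traced).
#'
#' @param spec A [vasculature_gen_spec()].
#' @return A vessel forest tibble (see [new_vessel_tree()]); passes
#'   [validate_vessel_tree()] and leaves the exclusion ball empty.
#' @export
generate_vasculature <- function(spec) {
  stopifnot(inherits(spec, "vasculature_gen_spec"))
  lo <- spec$domain_lower; hi <- spec$domain_upper
  vol <- prod(hi - lo)
  target_len <- spec$target_length_density * vol
  rows <- list()
  next_id <- 1L
  total_len <- 0
  n_walks <- 0L
  max_steps <- ceiling(1.5 * sqrt(sum((hi - lo)^2)) / spec$segment_length)

  while (n_walks < spec$n_parents && total_len < target_len) {
    p <- random_face_point(lo, hi, spec$exclusion_center,
                           spec$exclusion_radius)
    # head inward with a random tilt
    center <- (lo + hi) / 2
    dir <- center - p + 0.3 * sqrt(sum((hi - lo)^2)) * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    d <- runif(1, spec$diameter_range[1], spec$diameter_range[2])
    mother <- NA_integer_
    for (s in seq_len(max_steps)) {
      q <- p + spec$segment_length * dir
      # deflect away from the exclusion ball
      if (sqrt(sum((q - spec$exclusion_center)^2)) <= spec$exclusion_radius) {
        away <- p - spec$exclusion_center
        away <- away / sqrt(sum(away^2))
        dir <- dir + 2 * away
        dir <- dir / sqrt(sum(dir^2))
        q <- p + spec$segment_length * dir
      }
      if (any(q < lo) || any(q > hi)) break
      rows[[length(rows) + 1L]] <- c(next_id, mother, p, q, d)
      mother <- next_id
      next_id <- next_id + 1L
      total_len <- total_len + spec$segment_length
      if (total_len >= target_len) break  # truncate once calibrated
      p <- q
      dir <- dir + spec$waviness * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      d <- max(5, 0.99 * d)
    }
    n_walks <- n_walks + 1L
  }
  if (length(rows) == 0) {
    return(tibble::tibble(id = integer(0), mother = integer(0),
                          x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                          x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                          diameter = numeric(0), stopped = logical(0)))
  }
  m <- do.call(rbind, rows)
  v <- new_vessel_tree(id = m[, 1], mother = m[, 2], start = m[, 3:5],
                       end = m[, 6:8], diameter = m[, 9])
  v
}
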