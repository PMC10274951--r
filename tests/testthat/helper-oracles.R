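# Independent oracles used across the suite. These deliberately re-derive
# quantities through a different code path than the implementation.

# Brute-force all-pairs force sum, straight from the documented force law,
# in plain R. Oracle for the bucket-grid kernel.
brute_force_forces <- function(cells, params) {
  n <- nrow(cells)
  F <- matrix(0, n, 3)
  if (n < 2) return(F)
  pos <- cbind(cells$x, cells$y, cells$z)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dvec <- pos[i, ] - pos[j, ]
      d <- sqrt(sum(dvec^2))
      RA <- cells$r_action[i] + cells$r_action[j]
      if (d >= RA || d < 1e-9) next
      Rp <- cells$r_physical[i] + cells$r_physical[j]
      f <- 0
      if (d < Rp) f <- f + params$c_repulsion * ((Rp - d) / Rp)^2
      f <- f - params$c_adhesion * ((RA - d) / RA)^2
      u <- dvec / d
      F[i, ] <- F[i, ] + f * u
      F[j, ] <- F[j, ] - f * u
    }
  }
  F
}

# Dense affine operator for one FTCS step on an n^3 Neumann lattice:
# u' = M u + b. Built index by index from the update formula, independently
# of the compiled stencil.
dense_ftcs_operator <- function(n, h, D, lam, dt, Ap = NULL, Am = NULL) {
  N <- n^3
  idx <- function(i, j, k) i + (j - 1) * n + (k - 1) * n * n
  clamp <- function(i) min(max(i, 1), n)  # flux-form ghost node
  M <- matrix(0, N, N)
  b <- numeric(N)
  ddt <- D * dt / h^2
  ap <- if (is.null(Ap)) array(0, c(n, n, n)) else Ap
  am <- if (is.null(Am)) array(0, c(n, n, n)) else Am
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    r <- idx(i, j, k)
    M[r, r] <- M[r, r] + (1 - lam * dt) - 6 * ddt -
      dt * ap[i, j, k] - dt * am[i, j, k]
    for (nb in list(c(clamp(i + 1), j, k), c(clamp(i - 1), j, k),
                    c(i, clamp(j + 1), k), c(i, clamp(j - 1), k),
                    c(i, j, clamp(k + 1)), c(i, j, clamp(k - 1)))) {
      M[r, idx(nb[1], nb[2], nb[3])] <-
        M[r, idx(nb[1], nb[2], nb[3])] + ddt
    }
    b[r] <- dt * ap[i, j, k]
  }
  list(M = M, b = b)
}

# Hand-walked arc length along a simple mother -> daughter chain, summing
# segment lengths between (exclusive) start agent and the chain end/branch.
chain_arc_lengths <- function(seg_len, n_segments) {
  # for agent q in 1..n (1 attached to the branch point), the arc length
  # back to the branch point is (q - 1) * seg_len
  (seq_len(n_segments) - 1) * seg_len
}

# Three-sigma binomial check helper
within_3se <- function(phat, p, n) {
  se <- sqrt(max(p * (1 - p), 1e-12) / n)
  abs(phat - p) <= 3 * se + 1e-12
}

# A tiny straight-chain vessel forest for unit tests: n segments of length
# len along +x starting at `start`, constant diameter.
straight_chain <- function(n, len = 10, start = c(0, 0, 0), diameter = 10,
                           id0 = 1L) {
  ids <- id0 + seq_len(n) - 1L
  x0 <- start[1] + (seq_len(n) - 1) * len
  new_vessel_tree(
    id = ids,
    mother = c(NA_integer_, ids[-n]),
    start = cbind(x0, start[2], start[3]),
    end = cbind(x0 + len, start[2], start[3]),
    diameter = diameter
  )
}
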