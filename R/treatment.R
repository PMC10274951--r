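# Treatment schedule bookkeeping and the TRA-induced DOX supply factor.
#
# Trastuzumab regularizes the vasculature and improves its delivery
# properties; the model captures this with a supply state chi that charges
# toward chi_max (time constant tau_up) while TRA is delivered and
# discharges (tau_down) otherwise, like an RC capacitor. The vessel DOX
# source term is multiplied by phi = 1 + chi.

#' Treatment state
#'
#' Per-drug delivery windows plus the capacitor parameters of the supply
#' factor. Windows are half-open intervals `[start, end)` in simulation
#' hours, sorted and non-overlapping within each drug.
#'
#' @param dox_windows,tra_windows Two-column matrices (or tibbles with
#'   columns `start`, `end`) of window bounds in hours; `NULL` for no
#'   treatment.
#' @param chi_max Ceiling of the supply state.
#' @param tau_up,tau_down Charge / discharge time constants, hours.
#' @param chi Initial supply state in `[0, chi_max]`.
#' @return A list of class `treatment_state`.
#' @export
treatment_state <- function(dox_windows = NULL, tra_windows = NULL,
                            chi_max = 1, tau_up = 12, tau_down = 48,
                            chi = 0) {
  norm <- function(w, lab) {
    if (is.null(w) || NROW(w) == 0) {
      return(tibble::tibble(start = numeric(0), end = numeric(0)))
    }
    w <- if (is.matrix(w)) tibble::tibble(start = w[, 1], end = w[, 2])
         else tibble::as_tibble(w)[, c("start", "end")]
    if (any(w$end <= w$start)) {
      abort(paste0("treatment_state: ", lab, " windows must have end > start"))
    }
    w <- w[order(w$start), ]
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])) {
      abort(paste0("treatment_state: ", lab, " windows must not overlap"))
    }
    w
  }
  if (tau_up <= 0 || tau_down <= 0) {
    abort("treatment_state: time constants must be positive")
  }
  if (chi < 0 || chi > chi_max) {
    abort("treatment_state: chi must lie in [0, chi_max]")
  }
  structure(list(dox_windows = norm(dox_windows, "DOX"),
                 tra_windows = norm(tra_windows, "TRA"),
                 chi = chi, chi_max = chi_max,
                 tau_up = tau_up, tau_down = tau_down),
            class = "treatment_state")
}

#' One explicit-Euler step of the supply state
#'
#' Charges toward `chi_max` while TRA is being delivered, discharges toward
#' zero otherwise; the result is clamped to `[0, chi_max]` to guard against
#' overshoot at large steps. The supply state never reads the DOX schedule.
#'
#' @param chi Current supply state.
#' @param tra_active Logical: is a TRA window open?
#' @param tau_up,tau_down Time constants, hours (positive).
#' @param chi_max Ceiling.
#' @param dt Step length, hours.
#' @return Updated supply state.
#' @examples
#' chi_step(0, TRUE, tau_up = 10, tau_down = 48, chi_max = 1, dt = 1)
#' @export
chi_step <- function(chi, tra_active, tau_up, tau_down, chi_max, dt) {
  if (tau_up <= 0 || tau_down <= 0) {
    abort("chi_step: time constants must be positive")
  }
  out <- if (tra_active) chi + dt * (chi_max - chi) / tau_up
         else chi - dt * chi / tau_down
  min(max(out, 0), chi_max)
}

#' DOX supply factor
#'
#' `phi = 1 + chi`: the multiplicative enhancement of vessel-delivered DOX.
#' Always at least one.
#'
#' @param chi Supply state, `>= 0`.
#' @return The supply factor.
#' @export
phi <- function(chi) {
  if (any(chi < 0)) abort("phi: chi must be nonnegative")
  1 + chi
}

#' Which treatment windows are open at time t
#'
#' Half-open membership: `t` belongs to a window `[start, end)`.
#'
#' @param t Time(s) in simulation hours.
#' @param state A [treatment_state()].
#' @return For scalar `t` a named logical vector `c(dox = , tra = )`; for
#'   vector `t` a two-column logical matrix.
#' @export
windows_active <- function(t, state) {
  inside <- function(w) {
    if (nrow(w) == 0) return(rep(FALSE, length(t)))
    vapply(t, function(tt) any(tt >= w$start & tt < w$end), logical(1))
  }
  res <- cbind(dox = inside(state$dox_windows),
               tra = inside(state$tra_windows))
  if (length(t) == 1) res[1, ] else res
}
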