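#' Create a single-cell state
#'
#' @param P Protein content (aa); must be > 0.
#' @param R RNA/ribosome content in RNA mass units; defaults to the
#'   rho-consistent value \code{rho * P} when growth parameters are given.
#' @param t_birth Birth time (min).
#' @param age_genealogical Completed divisions (bud scars); 0 for a newborn
#'   daughter.
#' @param phase One of \code{"T1a"}, \code{"T1b"}, \code{"T2"},
#'   \code{"Budded"}.
#' @param phase_clock Minutes elapsed in the current phase.
#' @param P_bud Protein accumulated since budding (aa).
#' @param lineage Parent identifier, or \code{NA} for a founder.
#' @param params Optional \code{\link{growth_params}} used to default
#'   \code{R}.
#' @return An object of class \code{"cell_state"}.
#' @export
cell_state <- function(P, R = NULL, t_birth = 0, age_genealogical = 0L,
                       phase = "T1a", phase_clock = 0, P_bud = 0,
                       lineage = NA_integer_, params = growth_params()) {
  stopifnot(P > 0, phase %in% c("T1a", "T1b", "T2", "Budded"),
            phase_clock >= 0, P_bud >= 0, P_bud <= P, age_genealogical >= 0)
  if (is.null(R)) R <- params$rho * P
  stopifnot(R >= 0)
  structure(list(P = P, R = R, t_birth = t_birth,
                 age_genealogical = as.integer(age_genealogical),
                 phase = phase, phase_clock = phase_clock,
                 budded = identical(phase, "Budded"), P_bud = P_bud,
                 lineage = lineage),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("Cell: P = %.4g aa, R = %.4g, age %d, phase %s (%.1f min)%s\n",
              x$P, x$R, x$age_genealogical, x$phase, x$phase_clock,
              if (x$budded) sprintf(", P_bud = %.4g", x$P_bud) else ""))
  invisible(x)
}

# Vectorized RK4 step of the two-variable growth system
#   dP/dt = K2 R - delta_P P
#   dR/dt = k_R (rho P - R) - delta_R R
# P and R are equal-length numeric vectors; returns a list(P, R, dP) where
# dP is the protein made during the step (used to fill the bud compartment).
grow_rk4 <- function(P, R, gp, dt) {
  f <- function(P, R) {
    list(dP = gp$K2 * R - gp$delta_P * P,
         dR = gp$k_R * (gp$rho * P - R) - gp$delta_R * R)
  }
  k1 <- f(P, R)
  k2 <- f(P + dt / 2 * k1$dP, R + dt / 2 * k1$dR)
  k3 <- f(P + dt / 2 * k2$dP, R + dt / 2 * k2$dR)
  k4 <- f(P + dt * k3$dP, R + dt * k3$dR)
  Pn <- P + dt / 6 * (k1$dP + 2 * k2$dP + 2 * k3$dP + k4$dP)
  Rn <- R + dt / 6 * (k1$dR + 2 * k2$dR + 2 * k3$dR + k4$dR)
  list(P = Pn, R = Rn, dP = Pn - P)
}

#' Advance a cell by one growth step
#'
#' One fixed-step fourth-order Runge-Kutta update of the protein/RNA system
#' \deqn{dP/dt = K_2 R - \delta_P P, \quad dR/dt = k_R(\rho P - R) - \delta_R R.}
#' During the budded phase the protein made in the step accrues to the bud
#' compartment \code{P_bud}.
#'
#' @param cell A \code{\link{cell_state}}.
#' @param params A \code{\link{growth_params}}.
#' @param dt Step size (min), > 0.
#' @return The advanced \code{cell_state}.
#' @examples
#' c0 <- cell_state(P = 1e10)
#' step_growth(c0, growth_params(), dt = 0.1)$P
#' @export
step_growth <- function(cell, params = growth_params(), dt = 0.1) {
  stopifnot(inherits(cell, "cell_state"), dt > 0)
  st <- grow_rk4(cell$P, cell$R, params, dt)
  if (!all(is.finite(c(st$P, st$R))) || st$P <= 0)
    stop("non-finite or non-positive state after growth step (cell born at t = ",
         cell$t_birth, ")")
  cell$P <- st$P
  cell$R <- st$R
  if (cell$budded) cell$P_bud <- cell$P_bud + st$dP
  cell$phase_clock <- cell$phase_clock + dt
  cell
}
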