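#' Phase durations from population fractions
#'
#' The classical population-kinetics relations for an exponentially growing
#' budding-yeast culture: given the overall duplication time T, the budded
#' fraction F_B, the binucleate fraction F_G1star, and the budded parent and
#' daughter fractions of the whole population (F_PB, F_DB),
#' \deqn{T_B = \log_2(1+F_B)\,T,\quad T_{G1^*} = \log_2(1+F_{G1^*})\,T,}
#' \deqn{T_P = \log_2(F_B/F_{PB})\,T,\quad T_D = \log_2(F_B/F_{DB})\,T,}
#' with growth rate \eqn{\mu = \ln 2 / T}.
#'
#' @param F_B Budded fraction of the population, in \[0, 1\].
#' @param F_G1star Binucleate fraction, in \[0, 1\].
#' @param F_PB Budded parents as a fraction of the whole population.
#' @param F_DB Budded daughters as a fraction of the whole population.
#' @param T Overall duplication time (min), > 0.
#' @return A list of class \code{"cycle_times"}: \code{T_B},
#'   \code{T_G1star}, \code{T_P}, \code{T_D}, \code{mu} and \code{T}.
#' @examples
#' phase_durations(F_B = 0.6, F_G1star = 0.1, F_PB = 0.3, F_DB = 0.3, T = 120)
#' @export
phase_durations <- function(F_B, F_G1star = NA_real_, F_PB = NA_real_,
                            F_DB = NA_real_, T) {
  stopifnot(T > 0, F_B >= 0, F_B <= 1)
  out <- list(T_B = log2(1 + F_B) * T,
              T_G1star = if (is.na(F_G1star)) NA_real_ else log2(1 + F_G1star) * T,
              T_P = NA_real_, T_D = NA_real_,
              mu = log(2) / T, T = T)
  if (!is.na(F_PB)) {
    if (F_PB <= 0) stop("F_PB must be > 0: T_P is undefined at F_PB = 0")
    if (F_PB > F_B + 1e-12) stop("F_PB cannot exceed F_B")
    out$T_P <- log2(F_B / F_PB) * T
  }
  if (!is.na(F_DB)) {
    if (F_DB <= 0) stop("F_DB must be > 0: T_D is undefined at F_DB = 0")
    if (F_DB > F_B + 1e-12) stop("F_DB cannot exceed F_B")
    out$T_D <- log2(F_B / F_DB) * T
  }
  class(out) <- "cycle_times"
  out
}

#' @export
print.cycle_times <- function(x, ...) {
  cat(sprintf("Cycle times (T = %.4g min, mu = %.5g 1/min):\n", x$T, x$mu))
  cat(sprintf("  T_B = %.4g, T_G1* = %.4g, T_P = %.4g, T_D = %.4g min\n",
              x$T_B, x$T_G1star, x$T_P, x$T_D))
  invisible(x)
}

#' Residual of the asymmetric-division consistency relation
#'
#' For asymmetrically dividing cells the parent and daughter cycle times
#' must satisfy \eqn{e^{-\mu T_D} + e^{-\mu T_P} = 1}. This returns
#' \eqn{e^{-\mu T_D} + e^{-\mu T_P} - 1}; zero at a consistent triple.
#'
#' @param T_P Parent cycle time (min).
#' @param T_D Daughter cycle time (min).
#' @param mu Population growth rate (1/min).
#' @return The residual (dimensionless).
#' @export
asymmetry_residual <- function(T_P, T_D, mu) {
  exp(-mu * T_D) + exp(-mu * T_P) - 1
}

#' Solve the daughter cycle time from the consistency relation
#'
#' Finds the unique \eqn{T_D} with
#' \eqn{e^{-\mu T_D} + e^{-\mu T_P} = 1} by monotone bisection on the
#' bracket \eqn{[0, 10\,T]} (the residual is strictly decreasing in T_D).
#'
#' @param T_P Parent cycle time (min), > 0.
#' @param mu Population growth rate (1/min), > 0; requires
#'   \eqn{e^{-\mu T_P} < 1}.
#' @param tol Absolute tolerance on T_D (min).
#' @return The daughter cycle time (min).
#' @examples
#' solve_daughter_time(T_P = 90, mu = log(2) / 100)
#' @export
solve_daughter_time <- function(T_P, mu, tol = 1e-9) {
  if (!is.finite(mu) || mu <= 0 || !is.finite(T_P) || T_P <= 0)
    stop("require mu > 0 and T_P > 0 so that exp(-mu*T_P) < 1")
  T_ref <- log(2) / mu
  lo <- 0; hi <- 10 * T_ref
  f <- function(td) asymmetry_residual(T_P, td, mu)
  if (f(hi) > 0) stop("no root in bracket [0, 10 T]: T_P too large?")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Protein landmarks of the asymmetric cycle
#'
#' Evaluates, exactly as printed in the source relations, the parent mean
#' protein content
#' \deqn{P_P = P/\mu\,(T_P - T_D + T_D e^{\mu T_P})}
#' and the protein content at S-phase onset
#' \deqn{P_s = P_P\, e^{\mu (T_P - T_B)},}
#' plus the division/trigger ratio \eqn{h = P_{cd}/P_s} when \code{P_cd} is
#' given. The printed form of the first relation has unusual dimensional
#' bookkeeping (protein times time); \code{convention = "product"} offers
#' the alternative reading \eqn{P \mu (T_P - T_D + T_D e^{\mu T_P})},
#' clearly non-canonical, for exploratory use.
#'
#' @param P Mean protein content of the population.
#' @param mu Growth rate (1/min).
#' @param T_P,T_D,T_B Parent, daughter and budded-phase durations (min).
#' @param P_cd Optional protein content at division, for \code{h}.
#' @param convention \code{"printed"} (default) or \code{"product"}.
#' @return A list with \code{P_P}, \code{P_s} and (if available) \code{h}.
#' @export
protein_landmarks <- function(P, mu, T_P, T_D, T_B, P_cd = NA_real_,
                              convention = c("printed", "product")) {
  convention <- match.arg(convention)
  stopifnot(P > 0, mu > 0, T_P > 0, T_D > 0, T_B > 0)
  core <- T_P - T_D + T_D * exp(mu * T_P)
  P_P <- switch(convention,
                printed = P / mu * core,
                product = P * mu * core)
  P_s <- P_P * exp(mu * (T_P - T_B))
  h <- if (is.na(P_cd)) NA_real_ else P_cd / P_s
  list(P_P = P_P, P_s = P_s, h = h, convention = convention)
}

#' Cross-validate formula-derived durations against a simulation
#'
#' Derives T_B, T_G1*, T_P, T_D from a simulated population's fractions and
#' duplication time via \code{\link{phase_durations}}, and compares them
#' with the same durations measured directly from the event log, reporting
#' relative deviations and the consistency-relation residual.
#'
#' @param stats A \code{"population_stats"} object (from
#'   \code{\link{compute_stats}}).
#' @return A list with \code{derived}, \code{measured}, \code{relative_deviation}
#'   (named vectors over T_B, T_P, T_D), \code{eq5_residual}, and
#'   \code{available}.
#' @export
crossvalidate_with_simulation <- function(stats) {
  stopifnot(inherits(stats, "population_stats"))
  if (!is.finite(stats$MDT) || stats$n_cycles_post < 10 ||
      !is.finite(stats$T_P) || !is.finite(stats$T_D))
    return(list(available = FALSE, derived = NULL, measured = NULL,
                relative_deviation = NULL, eq5_residual = NA_real_))
  ct <- phase_durations(F_B = stats$F_B, F_G1star = stats$F_G1star,
                        F_PB = stats$F_PB, F_DB = stats$F_DB, T = stats$MDT)
  # mean budded time of completed cycles: T_G1 (unbudded) vs full cycle
  measured <- c(T_B = mean(c(stats$T_P - stats$T_G1P,
                             stats$T_D - stats$T_G1D)),
                T_P = stats$T_P, T_D = stats$T_D)
  derived <- c(T_B = ct$T_B, T_P = ct$T_P, T_D = ct$T_D)
  mu <- log(2) / stats$MDT
  list(available = TRUE, derived = derived, measured = measured,
       relative_deviation = derived / measured - 1,
       eq5_residual = asymmetry_residual(stats$T_P, stats$T_D, mu))
}
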