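#' Population simulation configuration
#'
#' @param n_lines Number of founder germinal lines (independent progenitor
#'   cells).
#' @param target_cells Population size at which the simulation stops.
#' @param horizon Maximum simulated time (min).
#' @param seed RNG seed; identical (seed, config) gives identical event logs.
#' @param CV_partition Coefficient of variation of the multiplicative
#'   lognormal noise on the bud partition at division.
#' @param CV_timer Coefficient of variation of newborn timer draws
#'   (overrides the value in \code{timer_settings} when not \code{NA}).
#' @param dt Shared integration/controller step (min).
#' @param burn_in_doublings Transient-discard rule: statistics only use
#'   events after the population has doubled this many times from the
#'   founders.
#' @return An object of class \code{"population_config"}.
#' @export
population_config <- function(n_lines = 10, target_cells = 50000,
                              horizon = 8000, seed = 1,
                              CV_partition = 0.10, CV_timer = NA_real_,
                              dt = 0.5, burn_in_doublings = 5) {
  stopifnot(n_lines >= 1, target_cells >= n_lines, horizon > 0, dt > 0,
            CV_partition >= 0, burn_in_doublings >= 0)
  structure(list(n_lines = as.integer(n_lines),
                 target_cells = as.integer(target_cells),
                 horizon = horizon, seed = as.integer(seed),
                 CV_partition = CV_partition, CV_timer = CV_timer,
                 dt = dt, burn_in_doublings = burn_in_doublings),
            class = "population_config")
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)   # mean-preserving
}

# Effective Cln3/Far1 size threshold for a condition: the wild-type
# reference threshold scaled by the imported growth interface. This is the
# coarse-grained encoding of carbon-source modulation of critical size.
far1_effective <- function(settings, K2, rho) {
  K2_ref <- settings$K2_ref
  rho_ref <- settings$rho_ref
  if (is.na(K2_ref) || is.na(rho_ref)) {
    ref <- reference_interface()
    if (is.na(K2_ref)) K2_ref <- ref[["K2"]]
    if (is.na(rho_ref)) rho_ref <- ref[["rho"]]
  }
  settings$far1_ref * (K2 / K2_ref)^settings$theta_K2 *
    (rho / rho_ref)^settings$theta_rho
}

# Stretch the reference timers to the condition's growth timescale:
# T -> T * (lambda_ref / lambda)^gamma_T.
scale_timer_settings <- function(settings, lambda_cell) {
  if (settings$gamma_T == 0 || lambda_cell <= 0) return(settings)
  lambda_ref <- settings$lambda_ref
  if (is.na(lambda_ref)) {
    ref <- reference_interface()
    lambda_ref <- ref[["K2"]] * ref[["rho"]]
  }
  f <- (lambda_ref / lambda_cell)^settings$gamma_T
  for (nm in c("T1a", "T2", "TB", "TG1star"))
    settings[[nm]] <- settings[[nm]] * f
  settings
}

#' Divide a cell into parent and daughter
#'
#' The daughter receives the bud compartment perturbed by a multiplicative
#' partition draw; the parent keeps the remainder, so protein is conserved
#' exactly. The parent gains one unit of genealogical age; both cells
#' re-enter G1 with reset clocks.
#'
#' @param cell A budded \code{\link{cell_state}} at its division event.
#' @param partition_factor Multiplicative noise draw applied to the bud
#'   compartment (1 = noise off). Draws implying a non-positive compartment
#'   for either cell must be redrawn by the caller; here they error.
#' @param time Division time (min), recorded as the newborns' birth time.
#' @return A list with elements \code{parent} and \code{daughter}.
#' @examples
#' b <- cell_state(P = 100, phase = "Budded", P_bud = 40)
#' divide_cell(b)   # parent 60, daughter 40
#' @export
divide_cell <- function(cell, partition_factor = 1, time = 0) {
  stopifnot(inherits(cell, "cell_state"), cell$budded)
  P_d <- cell$P_bud * partition_factor
  if (P_d <= 0 || P_d >= cell$P)
    stop("partition draw implies a non-positive compartment; redraw")
  frac <- P_d / cell$P
  daughter <- cell_state(P = P_d, R = cell$R * frac, t_birth = time,
                         age_genealogical = 0L, phase = "T1a",
                         phase_clock = 0, P_bud = 0, lineage = NA_integer_)
  parent <- cell
  parent$P <- cell$P - P_d
  parent$R <- cell$R - cell$R * frac
  parent$age_genealogical <- cell$age_genealogical + 1L
  parent$phase <- "T1a"; parent$budded <- FALSE
  parent$phase_clock <- 0; parent$P_bud <- 0
  parent$t_birth <- time
  list(parent = parent, daughter = daughter)
}

#' Simulate a pedigree-structured population
#'
#' Grows a population from founder cells under balanced nutrient conditions:
#' every cell runs the protein/RNA growth system, a cell-cycle controller
#' (the coarse Cln3/Far1 trigger plus timers by default, or the molecular
#' Whi5/SBF G1/S module), and divisions inject lognormal noise into newborn
#' timers and the bud partition. The run stops when \code{target_cells} live
#' cells exist or the horizon is reached.
#'
#' @param alloc An \code{"allocation_solution"} (the (K2, rho) interface is
#'   read from it) or a \code{\link{growth_params}} object.
#' @param settings A \code{\link{timer_settings}}.
#' @param cfg A \code{\link{population_config}}.
#' @param controller \code{"timer"} (default) or \code{"g1s_molecular"}.
#' @param g1s A \code{\link{g1s_params}} object (molecular controller only).
#' @param growth Optional \code{\link{growth_params}} overriding the
#'   defaults derived from \code{alloc} (degradation rates etc.).
#' @return An object of class \code{"yeast_population"}: live-cell table
#'   (\code{cells}), completed-cycle event log (\code{cycles}), division
#'   times (\code{births}), pedigree (child, parent), final \code{time},
#'   the growth interface used, and flags.
#' @export
simulate_population <- function(alloc, settings = timer_settings(),
                                cfg = population_config(),
                                controller = c("timer", "g1s_molecular"),
                                g1s = g1s_params(), growth = NULL) {
  controller <- match.arg(controller)
  if (inherits(alloc, "allocation_solution")) {
    if (!alloc$feasible || alloc$lambda <= 0)
      stop("allocation is infeasible (lambda = 0); nothing to simulate")
    gp <- growth_params(K2 = alloc$K2, rho = alloc$rho)
  } else if (inherits(alloc, "growth_params")) {
    gp <- alloc
  } else stop("`alloc` must be an allocation_solution or growth_params")
  if (!is.null(growth)) {
    stopifnot(inherits(growth, "growth_params"))
    gp$delta_P <- growth$delta_P; gp$delta_R <- growth$delta_R
    gp$k_R <- growth$k_R
  }
  if (!is.na(cfg$CV_timer)) settings$CV_timer <- cfg$CV_timer

  set.seed(cfg$seed)
  dt <- cfg$dt
  eps <- 1e-9
  thr0 <- far1_effective(settings, gp$K2, gp$rho)
  lambda_cell <- gp$K2 * gp$rho - gp$delta_P
  settings <- scale_timer_settings(settings, lambda_cell)
  molecular <- controller == "g1s_molecular"

  cap <- max(2L * cfg$target_cells, 256L)
  n <- cfg$n_lines
  # per-cell state vectors
  id <- integer(cap); parent <- rep(NA_integer_, cap)
  P <- numeric(cap); R <- numeric(cap); age <- integer(cap)
  phase <- integer(cap)        # 1 T1a, 2 T1b (or molecular G1), 3 T2, 4 Budded
  clock <- numeric(cap); tstart <- numeric(cap)
  d1a <- numeric(cap); d2 <- numeric(cap); dB <- numeric(cap)
  dG1s <- numeric(cap); thr <- numeric(cap)
  Pbud <- numeric(cap); P0 <- numeric(cap)
  ttrig <- rep(NA_real_, cap); Ptrig <- rep(NA_real_, cap)
  tbud <- rep(NA_real_, cap)
  if (molecular) {
    W <- numeric(cap); C0 <- numeric(cap); C1 <- numeric(cap)
    C2 <- numeric(cap); C3 <- numeric(cap); C4 <- numeric(cap)
  }

  draw_timers <- function(k) {
    list(d1a = settings$T1a * lognormal_factor(k, settings$CV_timer),
         d2  = settings$T2  * lognormal_factor(k, settings$CV_timer),
         dB  = settings$TB  * lognormal_factor(k, settings$CV_timer),
         thr = thr0 * lognormal_factor(k, settings$CV_far1))
  }
  # the nuclear/cell-division separation scales with the drawn budded timer
  g1s_frac <- if (settings$TB > 0) settings$TG1star / settings$TB else 0

  # molecular G1 state at cycle entry: a brief association burst rebinds
  # Whi5 to SBF; slow association (whi5-4E emulation) leaves free SBF behind
  g1s_init <- function(k) {
    S <- rep(g1s$SBF_total, k); Wf <- rep(g1s$Whi5_total, k)
    Cb <- numeric(k)
    nsub <- 25L; h <- g1s$rebind_time / nsub
    for (i in seq_len(nsub)) {
      rate <- g1s$k14 * Wf * S
      dC <- pmin(rate * h, Wf, S)
      Cb <- Cb + dC; Wf <- Wf - dC; S <- S - dC
    }
    list(W = Wf, C0 = Cb)
  }

  init_cycle <- function(idx, born_P, born_R, t) {
    k <- length(idx)
    P[idx] <<- born_P; R[idx] <<- born_R; P0[idx] <<- born_P
    tstart[idx] <<- t; clock[idx] <<- 0; Pbud[idx] <<- 0
    ttrig[idx] <<- NA_real_; Ptrig[idx] <<- NA_real_; tbud[idx] <<- NA_real_
    tm <- draw_timers(k)
    d1a[idx] <<- tm$d1a; d2[idx] <<- tm$d2; dB[idx] <<- tm$dB
    dG1s[idx] <<- tm$dB * g1s_frac; thr[idx] <<- tm$thr
    if (molecular) {
      ini <- g1s_init(k)
      W[idx] <<- ini$W; C0[idx] <<- ini$C0
      C1[idx] <<- 0; C2[idx] <<- 0; C3[idx] <<- 0; C4[idx] <<- 0
      phase[idx] <<- 2L
    } else phase[idx] <<- 1L
  }

  # founders are drawn from an approximate stationary composition: spread
  # genealogical ages (geometric, as in a balanced pedigree) and sizes on
  # the parent-size ladder, so the inoculum desynchronizes immediately and
  # the old-parent tail of the size distribution fills in quickly
  founder_age <- if (n > 1) pmin(stats::rgeom(n, 0.45), 8L) else 0L
  esc <- exp(lambda_cell * (settings$T1a + settings$T2))
  founder_P <- 0.9 * thr0 * esc^founder_age *
    lognormal_factor(n, if (n > 1) 0.25 else 0)
  id[1:n] <- 1:n
  age[1:n] <- as.integer(founder_age)
  init_cycle(1:n, founder_P, gp$rho * founder_P, 0)
  next_id <- n + 1L

  # completed-cycle log (one row per division event)
  log_cap <- max(2L * cfg$target_cells, 256L); log_n <- 0L
  lg <- list(cell = integer(log_cap), class_age = integer(log_cap),
             t_start = numeric(log_cap), t_trig = numeric(log_cap),
             t_bud = numeric(log_cap), t_nuc = numeric(log_cap),
             t_div = numeric(log_cap), P0 = numeric(log_cap),
             Ps = numeric(log_cap), Pcd = numeric(log_cap),
             P_daughter = numeric(log_cap), daughter = integer(log_cap))
  births <- numeric(cap); n_births <- 0L
  ped_child <- integer(cap); ped_parent <- integer(cap); n_ped <- 0L

  t <- 0
  warn_flags <- character(0)
  while (n < cfg$target_cells && t < cfg$horizon - eps) {
    live <- seq_len(n)
    g <- grow_rk4(P[live], R[live], gp, dt)
    if (!all(is.finite(g$P)) || any(g$P <= 0))
      stop("non-finite or non-positive protein during integration at t = ", t)
    P[live] <- g$P; R[live] <- g$R
    bud_live <- live[phase[live] == 4L]
    Pbud[bud_live] <- Pbud[bud_live] + g$dP[phase[live] == 4L]
    clock[live] <- clock[live] + dt
    t <- t + dt

    # -- divisions ---------------------------------------------------------
    div <- live[phase[live] == 4L & clock[live] >= dB[live] - eps]
    if (length(div)) {
      k <- length(div)
      u <- lognormal_factor(k, cfg$CV_partition)
      Pd <- Pbud[div] * u
      bad <- which(Pd <= 0 | Pd >= P[div])
      tries <- 0L
      while (length(bad)) {
        u[bad] <- lognormal_factor(length(bad), cfg$CV_partition)
        Pd[bad] <- Pbud[div][bad] * u[bad]
        bad <- which(Pd <= 0 | Pd >= P[div])
        tries <- tries + 1L
        if (tries > 100L) { Pd[bad] <- Pbud[div][bad]; break }
      }
      Pcd <- P[div]
      frac <- Pd / Pcd
      Rd <- R[div] * frac

      # log completed cycles
      need <- log_n + k
      if (need > log_cap) {
        new_cap <- max(2L * log_cap, need)
        for (nm in names(lg)) lg[[nm]] <- c(lg[[nm]], vector(typeof(lg[[nm]]), new_cap - log_cap))
        log_cap <- new_cap
      }
      rows <- (log_n + 1L):(log_n + k)
      ids_new <- next_id:(next_id + k - 1L)
      lg$cell[rows] <- id[div]; lg$class_age[rows] <- age[div]
      lg$t_start[rows] <- tstart[div]; lg$t_trig[rows] <- ttrig[div]
      lg$t_bud[rows] <- tbud[div]
      lg$t_nuc[rows] <- pmax(t - dG1s[div], tbud[div])
      lg$t_div[rows] <- t
      lg$P0[rows] <- P0[div]; lg$Ps[rows] <- Ptrig[div]
      lg$Pcd[rows] <- Pcd; lg$P_daughter[rows] <- Pd
      lg$daughter[rows] <- ids_new
      log_n <- log_n + k

      # parent keeps the remainder, ages by one, restarts G1
      P[div] <- Pcd - Pd; R[div] <- R[div] - Rd
      age[div] <- age[div] + 1L
      init_cycle(div, P[div], R[div], t)

      # daughters appended
      idx_new <- (n + 1L):(n + k)
      if (n + k > cap) stop("population capacity exceeded")
      id[idx_new] <- ids_new
      parent[idx_new] <- id[div]
      age[idx_new] <- 0L
      init_cycle(idx_new, Pd, Rd, t)
      ped_child[(n_ped + 1L):(n_ped + k)] <- ids_new
      ped_parent[(n_ped + 1L):(n_ped + k)] <- id[div]
      n_ped <- n_ped + k
      births[(n_births + 1L):(n_births + k)] <- t
      n_births <- n_births + k
      next_id <- next_id + k
      n <- n + k
      live <- seq_len(n)
    }

    if (!molecular) {
      # T2 expiry -> budding
      b <- live[phase[live] == 3L & clock[live] >= d2[live] - eps]
      if (length(b)) {
        phase[b] <- 4L; clock[b] <- 0; tbud[b] <- t; Pbud[b] <- 0
      }
      # T1a expiry -> T1b (threshold gate opens this same boundary)
      a <- live[phase[live] == 1L & clock[live] >= d1a[live] - eps]
      if (length(a)) { phase[a] <- 2L; clock[a] <- clock[a] - d1a[a] }
      # Cln3 (proportional to P) meets the Far1 threshold -> trigger
      tr <- live[phase[live] == 2L & P[live] >= thr[live]]
      if (length(tr)) {
        phase[tr] <- 3L; clock[tr] <- 0
        ttrig[tr] <- t; Ptrig[tr] <- P[tr]
      }
    } else {
      un <- live[phase[live] == 2L]
      if (length(un)) {
        # mass-action G1/S module: Cln3-driven multisite phosphorylation of
        # SBF-bound Whi5 releases SBF; START at the active free-SBF
        # threshold. Whi5-SBF association happens only in the entry burst
        # (nuclear Whi5 is exported once phosphorylated), so the free Whi5
        # pool is inert during G1.
        cln3 <- g1s$cln3_scale * gp$K2 * R[un]
        nsub <- g1s$substeps; h <- dt / nsub
        c0 <- C0[un]; c1 <- C1[un]; c2 <- C2[un]
        c3 <- C3[un]; c4 <- C4[un]
        for (s in seq_len(nsub)) {
          ph <- g1s$k_phos * cln3
          dc0 <- (-ph * c0 - g1s$alpha_W * c0) * h
          dc1 <- (ph * (c0 - c1) - g1s$alpha_W * c1) * h
          dc2 <- (ph * (c1 - c2) - g1s$alpha_W * c2) * h
          dc3 <- (ph * (c2 - c3) - g1s$alpha_W * c3) * h
          dc4 <- (ph * c3 - g1s$k_release * c4 - g1s$alpha_W * c4) * h
          c0 <- c0 + dc0; c1 <- c1 + dc1
          c2 <- c2 + dc2; c3 <- c3 + dc3; c4 <- c4 + dc4
          if (any(c(c0, c1, c2, c3, c4) < -1e-6))
            stop("negative concentration in G1/S module integration")
          c0 <- pmax(c0, 0); c1 <- pmax(c1, 0)
          c2 <- pmax(c2, 0); c3 <- pmax(c3, 0); c4 <- pmax(c4, 0)
        }
        C0[un] <- c0; C1[un] <- c1; C2[un] <- c2
        C3[un] <- c3; C4[un] <- c4
        Sfree <- pmax(g1s$SBF_total - (c0 + c1 + c2 + c3 + c4), 0)
        gate <- if (g1s$k_sbf_act > 0) cln3 / (g1s$k_sbf_act + cln3) else 1
        fire <- un[gate * Sfree / g1s$SBF_total >= g1s$release_threshold]
        if (length(fire)) {
          phase[fire] <- 4L; clock[fire] <- 0
          ttrig[fire] <- t; Ptrig[fire] <- P[fire]
          tbud[fire] <- t; Pbud[fire] <- 0
        }
      }
    }
  }

  if (n < 2 * cfg$n_lines)
    warn_flags <- c(warn_flags, "horizon_before_two_doublings")

  live <- seq_len(n)
  cells <- data.frame(
    id = id[live], parent = parent[live], P = P[live], R = R[live],
    age = age[live], phase = c("T1a", "T1b", "T2", "Budded")[phase[live]],
    phase_clock = clock[live], t_cycle_start = tstart[live],
    P0 = P0[live], P_bud = Pbud[live], d_TB = dB[live],
    d_TG1star = dG1s[live], stringsAsFactors = FALSE)
  cycles <- data.frame(
    cell = lg$cell[seq_len(log_n)], class_age = lg$class_age[seq_len(log_n)],
    t_start = lg$t_start[seq_len(log_n)], t_trig = lg$t_trig[seq_len(log_n)],
    t_bud = lg$t_bud[seq_len(log_n)], t_nuc = lg$t_nuc[seq_len(log_n)],
    t_div = lg$t_div[seq_len(log_n)], P0 = lg$P0[seq_len(log_n)],
    Ps = lg$Ps[seq_len(log_n)], Pcd = lg$Pcd[seq_len(log_n)],
    P_daughter = lg$P_daughter[seq_len(log_n)],
    daughter = lg$daughter[seq_len(log_n)])
  structure(list(
    cells = cells, cycles = cycles,
    births = births[seq_len(n_births)],
    pedigree = data.frame(child = ped_child[seq_len(n_ped)],
                          parent = ped_parent[seq_len(n_ped)]),
    time = t, config = cfg, settings = settings,
    interface = c(K2 = gp$K2, rho = gp$rho, far1_eff = thr0,
                  lambda_cell = lambda_cell),
    controller = controller, flags = warn_flags),
    class = "yeast_population")
}

#' @export
print.yeast_population <- function(x, ...) {
  cat(sprintf("Simulated yeast population: %d cells, %d founders, t = %.0f min (%s controller)\n",
              nrow(x$cells), x$config$n_lines, x$time, x$controller))
  cat(sprintf("  interface: K2 = %.4g, rho = %.4g, size threshold = %.3g aa\n",
              x$interface[["K2"]], x$interface[["rho"]], x$interface[["far1_eff"]]))
  cat(sprintf("  mean P = %.4g aa, budded fraction = %.3f\n",
              mean(x$cells$P), mean(x$cells$phase == "Budded")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.yeast_population <- function(object, ...) {
  s <- compute_stats(object)
  print(s)
  invisible(s)
}

#' @export
plot.yeast_population <- function(x, breaks = 64, ...) {
  graphics::hist(x$cells$P, breaks = breaks,
                 xlab = "protein content (aa)", main = "Protein distribution",
                 ...)
  invisible(x)
}

#' Population statistics
#'
#' Computes the growth and temporal readouts of a simulated population:
#' protein-content moments from the final snapshot, budding and
#' genealogical fractions, the mass duplication time (exponential fit to
#' post-burn-in log cell counts), G1 lengths and cycle times split by
#' newborn class, and the protein landmarks P0, Ps, Pcd from the event log.
#'
#' @param pop A \code{"yeast_population"}.
#' @param burn_in Optional burn-in time (min); defaults to the config rule
#'   (time of \code{burn_in_doublings} population doublings).
#' @return An object of class \code{"population_stats"} (a named list).
#' @export
compute_stats <- function(pop, burn_in = NULL) {
  stopifnot(inherits(pop, "yeast_population"))
  cells <- pop$cells; cyc <- pop$cycles
  n0 <- pop$config$n_lines
  if (is.null(burn_in)) {
    target_n <- n0 * 2^pop$config$burn_in_doublings
    k <- target_n - n0   # births needed
    burn_in <- if (length(pop$births) >= k && k >= 1) sort(pop$births)[k] else
      if (k < 1) 0 else NA_real_
  }
  unavailable <- function() NA_real_

  P <- cells$P
  P_mean <- mean(P); SD_P <- stats::sd(P); CV_P <- SD_P / P_mean
  budded <- cells$phase == "Budded"
  is_parent <- cells$age > 0
  F_B <- mean(budded)
  F_PB <- mean(budded & is_parent); F_DB <- mean(budded & !is_parent)
  F_PNB <- mean(!budded & is_parent); F_DNB <- mean(!budded & !is_parent)
  binuc <- budded & cells$phase_clock >= (cells$d_TB - cells$d_TG1star)
  F_G1star <- mean(binuc)

  # MDT from the log cell-count trajectory: a first fit over everything
  # after burn-in, then a refit over the last three duplication times,
  # where the genealogical-age composition has converged
  MDT <- NA_real_; mdt_r2 <- NA_real_
  window_start <- burn_in
  if (!is.na(burn_in) && length(pop$births) > 50) {
    bt <- sort(pop$births)
    Nt <- n0 + seq_along(bt)
    fit_from <- function(t0) {
      keep <- bt >= t0
      if (sum(keep) <= 20) return(NULL)
      stats::lm(log(Nt[keep]) ~ bt[keep])
    }
    fit <- fit_from(burn_in)
    if (!is.null(fit)) {
      MDT <- log(2) / stats::coef(fit)[[2]]
      window_start <- max(burn_in, pop$time - 3 * MDT)
      fit2 <- fit_from(window_start)
      if (!is.null(fit2)) {
        MDT <- log(2) / stats::coef(fit2)[[2]]
        mdt_r2 <- summary(fit2)$r.squared
      } else {
        window_start <- burn_in
        mdt_r2 <- summary(fit)$r.squared
      }
    }
  }

  post <- if (!is.na(burn_in)) cyc[cyc$t_div >= burn_in, , drop = FALSE] else cyc[0, ]
  dau <- post$class_age == 0
  m <- function(x) if (length(x) && any(is.finite(x))) mean(x[is.finite(x)]) else unavailable()
  T_G1D <- m(post$t_bud[dau] - post$t_start[dau])
  T_G1P <- m(post$t_bud[!dau] - post$t_start[!dau])
  T_trigD <- m(post$t_trig[dau] - post$t_start[dau])
  T_trigP <- m(post$t_trig[!dau] - post$t_start[!dau])
  T_D <- m(post$t_div[dau] - post$t_start[dau])
  T_P <- m(post$t_div[!dau] - post$t_start[!dau])
  P0_mean <- m(post$P0); Ps_mean <- m(post$Ps); Pcd_mean <- m(post$Pcd)

  # stationarity proxy: relative drift of division size over one MDT,
  # measured on the late (composition-converged) window
  drift <- NA_real_
  if (is.finite(MDT)) {
    late <- post[post$t_div >= window_start, , drop = FALSE]
    if (nrow(late) > 20) {
      fit <- stats::lm(Pcd ~ t_div, data = late)
      drift <- stats::coef(fit)[[2]] * MDT / mean(late$Pcd)
    }
  }

  structure(list(
    P_mean = P_mean, SD_P = SD_P, CV_P = CV_P,
    P0_mean = P0_mean, Ps_mean = Ps_mean, Pcd_mean = Pcd_mean,
    MDT = MDT, mdt_r2 = mdt_r2, lambda_pop = log(2) / MDT,
    T_G1D = T_G1D, T_G1P = T_G1P, T_trigD = T_trigD, T_trigP = T_trigP,
    T_D = T_D, T_P = T_P,
    F_B = F_B, F_PB = F_PB, F_PNB = F_PNB, F_DB = F_DB, F_DNB = F_DNB,
    F_G1star = F_G1star,
    n_cells = nrow(cells), n_parents = sum(is_parent),
    n_daughters = sum(!is_parent),
    burn_in = burn_in, drift_P = drift,
    n_cycles_post = nrow(post)),
    class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("Population statistics (%d cells; %d parents / %d daughters)\n",
              x$n_cells, x$n_parents, x$n_daughters))
  cat(sprintf("  <P> = %.4g aa, SD = %.3g, CV = %.3f\n", x$P_mean, x$SD_P, x$CV_P))
  cat(sprintf("  P0 = %.4g, Ps = %.4g, Pcd = %.4g aa\n",
              x$P0_mean, x$Ps_mean, x$Pcd_mean))
  cat(sprintf("  MDT = %.1f min (lambda = %.5f 1/min)\n", x$MDT, x$lambda_pop))
  cat(sprintf("  T_G1: daughters %.1f, parents %.1f min; cycles T_D %.1f, T_P %.1f min\n",
              x$T_G1D, x$T_G1P, x$T_D, x$T_P))
  cat(sprintf("  fractions: F_B %.3f (PB %.3f, DB %.3f, PNB %.3f, DNB %.3f), F_G1* %.3f\n",
              x$F_B, x$F_PB, x$F_DB, x$F_PNB, x$F_DNB, x$F_G1star))
  invisible(x)
}

#' @export
as.data.frame.population_stats <- function(x, ...) {
  as.data.frame(unclass(x)[!vapply(unclass(x), is.null, logical(1))])
}

#' Replicate populations and summarize
#'
#' Runs \code{n_rep} independent populations (seeds \code{seed + 0:(n_rep-1)})
#' and tabulates per-replicate statistics with their mean and SD.
#'
#' @param alloc,settings,cfg,controller,g1s As in
#'   \code{\link{simulate_population}}.
#' @param n_rep Number of replicate populations (>= 2).
#' @param seeds Optional explicit per-replicate seeds (length \code{n_rep});
#'   default \code{seed + 0:(n_rep-1)}.
#' @return A list with \code{replicates} (data frame, one row each),
#'   \code{mean} and \code{sd} (named numeric vectors).
#' @export
replicate_stats <- function(alloc, settings = timer_settings(),
                            cfg = population_config(), n_rep = 20,
                            controller = "timer", g1s = g1s_params(),
                            seeds = NULL) {
  stopifnot(n_rep >= 2)
  if (is.null(seeds)) seeds <- cfg$seed + seq_len(n_rep) - 1L
  stopifnot(length(seeds) == n_rep)
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    cfg_i <- cfg; cfg_i$seed <- seeds[i]
    pop <- simulate_population(alloc, settings, cfg_i, controller, g1s)
    rows[[i]] <- as.data.frame(compute_stats(pop))
    rows[[i]]$seed <- cfg_i$seed
  }
  reps <- do.call(rbind, rows)
  num <- vapply(reps, is.numeric, logical(1))
  list(replicates = reps,
       mean = colMeans(reps[num], na.rm = TRUE),
       sd = apply(reps[num], 2, stats::sd, na.rm = TRUE))
}

#' One-at-a-time sensitivity scan
#'
#' Perturbs one parameter at a time (forward and backward multiplicative
#' steps), reruns the population, and tabulates the relative change of the
#' monitored outputs (mean, SD and CV of protein content; MDT; parent and
#' daughter G1 lengths) against the nominal run.
#'
#' @param alloc,settings,cfg As in \code{\link{simulate_population}}.
#' @param parameters Character vector of parameter names to scan; names in
#'   \code{settings} (e.g. \code{"T2"}, \code{"TB"}, \code{"far1_ref"}) or
#'   \code{"K2"}/\code{"rho"} of the interface.
#' @param steps Multiplicative factors; must include values above and below
#'   1 (forward and backward).
#' @return A data frame: parameter, step, output, nominal, perturbed,
#'   relative_change, feasible.
#' @export
sensitivity_scan <- function(alloc, settings = timer_settings(),
                             cfg = population_config(),
                             parameters = c("T2", "TB", "far1_ref"),
                             steps = c(0.8, 1.25)) {
  if (!(any(steps > 1) && any(steps < 1)) && !all(steps == 1))
    warning("steps should include forward (>1) and backward (<1) factors")
  outputs <- c("P_mean", "SD_P", "CV_P", "MDT", "T_G1P", "T_G1D")
  if (inherits(alloc, "allocation_solution"))
    gp0 <- growth_params(K2 = alloc$K2, rho = alloc$rho)
  else gp0 <- alloc
  run <- function(gp, st) {
    pop <- simulate_population(gp, st, cfg)
    s <- compute_stats(pop)
    unlist(s[outputs])
  }
  nominal <- run(gp0, settings)
  rows <- list()
  for (par in parameters) {
    for (stp in steps) {
      gp <- gp0; st <- settings
      if (par %in% names(st)) st[[par]] <- st[[par]] * stp
      else if (par %in% c("K2", "rho")) gp[[par]] <- gp[[par]] * stp
      else stop("unknown scan parameter: ", par)
      res <- tryCatch(run(gp, st), error = function(e) NULL)
      ok <- !is.null(res)
      for (o in outputs) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = par, step = stp, output = o,
          nominal = nominal[[o]],
          perturbed = if (ok) res[[o]] else NA_real_,
          relative_change = if (ok) res[[o]] / nominal[[o]] - 1 else NA_real_,
          feasible = ok)
      }
    }
  }
  do.call(rbind, rows)
}
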