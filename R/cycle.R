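#' Molecular G1/S module parameters
#'
#' Parameters of the mass-action Whi5/SBF module that can replace the
#' coarse Cln3/Far1 trigger and G1 timers. SBF is inhibited by bound Whi5;
#' Cln3 (whose level tracks the cell's protein synthesis capacity, K2 * R)
#' drives sequential phosphorylation of the four functional Whi5 sites on
#' the complex; fully phosphorylated Whi5 releases SBF, and bound Whi5 is
#' also slowly cleared. START fires when the free-SBF fraction reaches
#' \code{release_threshold}.
#'
#' Abundances are in arbitrary units with \code{SBF_total = 1}. A total
#' Whi5 of 0 encodes the \emph{whi5} deletion.
#'
#' @param Whi5_total Total Whi5 amount per newborn (0 = whi5 null).
#' @param SBF_total Total SBF amount.
#' @param k14 SBF-Whi5 association rate (1/(unit min)).
#' @param k_phos Per-site phosphorylation rate constant per unit Cln3
#'   (1/(unit min)); four sequential functional sites.
#' @param alpha_W Clearance rate of SBF-bound Whi5 (1/min).
#' @param k_release Release rate of SBF from the fully phosphorylated
#'   complex (1/min).
#' @param cln3_scale Converts the synthesis capacity K2 * R (aa/min) into
#'   Cln3 abundance units.
#' @param k_sbf_act Half-activation Cln3 level of SBF itself: freed SBF
#'   still requires Cln3/CDK activity to fire transcription, so START needs
#'   both Whi5 removal and sufficient Cln3. This keeps a weak size input
#'   even with Whi5 absent (the whi5 null is small, not sizeless).
#' @param release_threshold Active free-SBF fraction at which START fires.
#' @param rebind_time Duration (min) of the association burst that rebinds
#'   Whi5 to SBF at cycle entry.
#' @param substeps Explicit-Euler substeps per controller step.
#' @return An object of class \code{"g1s_params"}.
#' @export
g1s_params <- function(Whi5_total = 1.25, SBF_total = 1,
                       k14 = 2, k_phos = 0.2011, alpha_W = 0.008,
                       k_release = 10, cln3_scale = 4e-9,
                       k_sbf_act = 0.5,
                       release_threshold = 0.5,
                       rebind_time = 3, substeps = 4L) {
  stopifnot(Whi5_total >= 0, SBF_total > 0, k14 >= 0, k_phos >= 0,
            alpha_W >= 0, k_release >= 0, cln3_scale >= 0, k_sbf_act >= 0,
            release_threshold > 0, release_threshold <= 1,
            rebind_time >= 0, substeps >= 1)
  structure(list(Whi5_total = Whi5_total, SBF_total = SBF_total,
                 k14 = k14, k_phos = k_phos, alpha_W = alpha_W,
                 k_release = k_release, cln3_scale = cln3_scale,
                 k_sbf_act = k_sbf_act,
                 release_threshold = release_threshold,
                 rebind_time = rebind_time, substeps = as.integer(substeps)),
            class = "g1s_params")
}

#' @export
print.g1s_params <- function(x, ...) {
  cat(sprintf("G1/S molecular module: Whi5 = %.3g, SBF = %.3g, k14 = %.3g, k_phos = %.3g/site\n",
              x$Whi5_total, x$SBF_total, x$k14, x$k_phos))
  cat(sprintf("  alpha_W = %.3g, release at free-SBF fraction %.2f\n",
              x$alpha_W, x$release_threshold))
  invisible(x)
}

#' Named mutant presets for the G1/S module
#'
#' \code{"whi5_delta"} sets total Whi5 to zero; \code{"whi5_4E"} emulates
#' the phospho-mimetic mutant by weakening SBF-Whi5 association (k14 x 1/10)
#' and halving the clearance of bound Whi5.
#'
#' @param name One of \code{"wild_type"}, \code{"whi5_delta"},
#'   \code{"whi5_4E"}.
#' @param base Base parameters to overlay.
#' @return A \code{\link{g1s_params}} object.
#' @export
g1s_preset <- function(name = c("wild_type", "whi5_delta", "whi5_4E"),
                       base = g1s_params()) {
  name <- match.arg(name)
  switch(name,
         wild_type = base,
         whi5_delta = apply_overlay(base, c(Whi5_total = 0)),
         whi5_4E = apply_overlay(base, c(k14 = 1 / 10, alpha_W = 0.5)))
}

cycle_event <- function(kind, time, cell_id = NA_integer_, P = NA_real_) {
  list(kind = kind, time = time, cell = cell_id, P_at_event = P)
}

# Attach controller bookkeeping to a cell on cycle entry (single-cell API).
init_cell_cycle <- function(cell, settings, params, mol = NULL) {
  settings <- scale_timer_settings(settings, params$K2 * params$rho - params$delta_P)
  cv <- settings$CV_timer
  cell$timers <- list(
    d1a = settings$T1a * lognormal_factor(1, cv),
    d2 = settings$T2 * lognormal_factor(1, cv),
    dB = settings$TB * lognormal_factor(1, cv))
  cell$timers$dG1s <- cell$timers$dB *
    if (settings$TB > 0) settings$TG1star / settings$TB else 0
  cell$far1 <- far1_effective(settings, params$K2, params$rho) *
    lognormal_factor(1, settings$CV_far1)
  cell$trigger <- list(fired = FALSE)
  cell$nuc_emitted <- FALSE
  if (!is.null(mol)) {
    S <- mol$SBF_total; Wf <- mol$Whi5_total; Cb <- 0
    nsub <- 25L; h <- mol$rebind_time / nsub
    for (i in seq_len(nsub)) {
      dC <- min(mol$k14 * Wf * S * h, Wf, S)
      Cb <- Cb + dC; Wf <- Wf - dC; S <- S - dC
    }
    cell$g1s <- list(W = Wf, C = c(Cb, 0, 0, 0, 0))
    cell$phase <- "T1b"
  }
  cell
}

# Shared budded-phase bookkeeping for both controllers.
budded_transitions <- function(cell, time, events) {
  if (!cell$nuc_emitted &&
      cell$phase_clock >= cell$timers$dB - cell$timers$dG1s - 1e-9) {
    events[[length(events) + 1L]] <-
      cycle_event("nuclear_division", time, P = cell$P)
    cell$nuc_emitted <- TRUE
  }
  if (cell$phase_clock >= cell$timers$dB - 1e-9) {
    events[[length(events) + 1L]] <-
      cycle_event("cell_division", time, P = cell$P)
  }
  list(cell = cell, events = events)
}

#' Advance the coarse timer controller by one step
#'
#' The default cycle controller: a fixed T1a period, a threshold-gated T1b
#' during which Cln3 (proportional to protein content) must meet the Far1
#' threshold, a fixed T2 until budding, and the budded timer T_B whose final
#' T_G1star separates nuclear from cell division. Growth itself is advanced
#' by \code{\link{step_growth}}; call the controller after each growth step
#' with the same \code{dt}.
#'
#' @param cell A \code{\link{cell_state}} (the controller attaches timer
#'   bookkeeping on first use).
#' @param settings A \code{\link{timer_settings}}.
#' @param params A \code{\link{growth_params}} (supplies the interface that
#'   scales the size threshold).
#' @param dt Step (min); must match the growth step already applied.
#' @param time Current simulation time (min).
#' @return A list \code{(cell, events)}; events is a list of cycle events
#'   (\code{trigger_fired}, \code{budded}, \code{nuclear_division},
#'   \code{cell_division}).
#' @export
timer_controller_step <- function(cell, settings = timer_settings(),
                                  params = growth_params(), dt = 0.5,
                                  time = 0) {
  stopifnot(inherits(cell, "cell_state"), dt > 0)
  if (is.null(cell$timers)) cell <- init_cell_cycle(cell, settings, params)
  events <- list()
  if (cell$phase == "Budded") {
    bt <- budded_transitions(cell, time, events)
    return(bt)
  }
  if (cell$phase == "T2" && cell$phase_clock >= cell$timers$d2 - 1e-9) {
    cell$phase <- "Budded"; cell$budded <- TRUE
    cell$phase_clock <- 0; cell$P_bud <- 0
    events[[length(events) + 1L]] <- cycle_event("budded", time, P = cell$P)
    return(list(cell = cell, events = events))
  }
  if (cell$phase == "T1a" && cell$phase_clock >= cell$timers$d1a - 1e-9) {
    cell$phase <- "T1b"
    cell$phase_clock <- cell$phase_clock - cell$timers$d1a
  }
  if (cell$phase == "T1b") {
    cln3 <- cell$P   # Cln3 abundance tracks protein content
    if (!cell$trigger$fired && cln3 >= cell$far1) {
      cell$trigger$fired <- TRUE
      cell$phase <- "T2"; cell$phase_clock <- 0
      events[[length(events) + 1L]] <-
        cycle_event("trigger_fired", time, P = cell$P)
    }
  }
  list(cell = cell, events = events)
}

#' Advance the molecular Whi5/SBF controller by one step
#'
#' Replaces the coarse trigger and G1 timers: during the unbudded phase the
#' mass-action Whi5/SBF system is integrated (association k14, Cln3-driven
#' 4-site phosphorylation, clearance alpha_W, release of SBF), and START
#' fires — budding immediately — when the free-SBF fraction reaches the
#' release threshold. The budded phase is the unchanged timer T_B.
#'
#' @param cell A \code{\link{cell_state}}.
#' @param mol A \code{\link{g1s_params}}.
#' @param params A \code{\link{growth_params}}.
#' @param settings Timer settings (budded-phase timers only).
#' @param dt Step (min).
#' @param time Current time (min).
#' @return A list \code{(cell, events)}.
#' @export
molecular_controller_step <- function(cell, mol = g1s_params(),
                                      params = growth_params(),
                                      settings = timer_settings(),
                                      dt = 0.5, time = 0) {
  stopifnot(inherits(cell, "cell_state"), dt > 0)
  if (is.null(cell$timers))
    cell <- init_cell_cycle(cell, settings, params, mol = mol)
  events <- list()
  if (cell$phase == "Budded") return(budded_transitions(cell, time, events))

  cln3 <- mol$cln3_scale * params$K2 * cell$R
  st <- c(W = cell$g1s$W, cell$g1s$C)
  h <- dt / mol$substeps
  # association only happens in the cycle-entry burst; during G1 the free
  # Whi5 pool is inert (phosphorylated Whi5 is exported, no rebinding)
  for (s in seq_len(mol$substeps)) {
    ph <- mol$k_phos * cln3
    d <- c(0,
           -ph * st[2] - mol$alpha_W * st[2],
           ph * (st[2] - st[3]) - mol$alpha_W * st[3],
           ph * (st[3] - st[4]) - mol$alpha_W * st[4],
           ph * (st[4] - st[5]) - mol$alpha_W * st[5],
           ph * st[5] - mol$k_release * st[6] - mol$alpha_W * st[6])
    st <- st + d * h
    if (any(st < -1e-6))
      stop("negative concentration in G1/S module integration")
    st <- pmax(st, 0)
  }
  cell$g1s$W <- st[[1]]; cell$g1s$C <- unname(st[2:6])
  Sfree <- max(mol$SBF_total - sum(st[2:6]), 0)
  gate <- if (mol$k_sbf_act > 0) cln3 / (mol$k_sbf_act + cln3) else 1
  if (gate * Sfree / mol$SBF_total >= mol$release_threshold) {
    cell$trigger$fired <- TRUE
    events[[length(events) + 1L]] <-
      cycle_event("trigger_fired", time, P = cell$P)
    cell$phase <- "Budded"; cell$budded <- TRUE
    cell$phase_clock <- 0; cell$P_bud <- 0
    events[[length(events) + 1L]] <- cycle_event("budded", time, P = cell$P)
  }
  list(cell = cell, events = events)
}

#' Validate a cycle controller against the plug-in contract
#'
#' Feeds the controller a canned growth trace from a reference newborn and
#' checks that (i) it emits events in the legal within-cycle order
#' trigger_fired, budded, nuclear_division, cell_division; (ii) it completes
#' at least one full cycle; (iii) it is deterministic under a fixed seed.
#'
#' @param controller \code{"timer"}, \code{"g1s_molecular"}, or a function
#'   \code{(cell, params, settings, dt, time) -> list(cell, events)}.
#' @param params,settings,g1s Model parameters for the trace.
#' @param horizon Trace length (min).
#' @param seed RNG seed for the two determinism runs.
#' @return A list with \code{pass} (logical) and \code{failures}
#'   (character vector of named contract violations).
#' @export
controller_contract_check <- function(controller, params = growth_params(),
                                      settings = timer_settings(),
                                      g1s = g1s_params(),
                                      horizon = 400, seed = 42) {
  stepfun <- if (is.function(controller)) controller
  else if (identical(controller, "timer"))
    function(cell, dt, time)
      timer_controller_step(cell, settings, params, dt, time)
  else if (identical(controller, "g1s_molecular"))
    function(cell, dt, time)
      molecular_controller_step(cell, g1s, params, settings, dt, time)
  else stop("unknown controller: ", controller)
  if (is.function(controller))
    stepfun <- function(cell, dt, time)
      controller(cell, params, settings, dt, time)

  run_trace <- function() {
    set.seed(seed)
    thr <- far1_effective(settings, params$K2, params$rho)
    cell <- cell_state(P = 0.7 * thr, params = params)
    dt <- 0.5; t <- 0
    events <- list()
    while (t < horizon) {
      cell <- step_growth(cell, params, dt)
      t <- t + dt
      out <- stepfun(cell, dt, t)
      cell <- out$cell
      events <- c(events, out$events)
      div <- Filter(function(e) e$kind == "cell_division", out$events)
      if (length(div)) {
        # reset for the next cycle; stub controllers may divide an unbudded
        # cell, in which case we just halve it to keep the trace going
        if (isTRUE(cell$budded) && cell$P_bud > 0) {
          halves <- divide_cell(cell, partition_factor = 1, time = t)
          cell <- halves$parent
        } else {
          cell$P <- cell$P / 2; cell$R <- cell$R / 2
          cell$phase <- "T1a"; cell$budded <- FALSE
          cell$phase_clock <- 0; cell$P_bud <- 0
        }
        cell$timers <- NULL   # controller re-initializes on next step
      }
    }
    events
  }
  ev1 <- tryCatch(run_trace(), error = function(e) e)
  ev2 <- tryCatch(run_trace(), error = function(e) e)
  if (inherits(ev1, "error"))
    return(list(pass = FALSE,
                failures = paste("trace error:", conditionMessage(ev1))))
  failures <- character(0)
  order_rank <- c(trigger_fired = 1, budded = 2, nuclear_division = 3,
                  cell_division = 4)
  kinds <- vapply(ev1, `[[`, character(1), "kind")
  times <- vapply(ev1, `[[`, numeric(1), "time")
  if (!length(ev1)) failures <- c(failures, "no events emitted")
  if (any(!kinds %in% names(order_rank)))
    failures <- c(failures, "unknown event kind")
  # split into cycles at cell_division and check the rank order inside each
  cyc_id <- cumsum(c(0, utils::head(kinds, -1) == "cell_division"))
  for (cid in unique(cyc_id)) {
    r <- order_rank[kinds[cyc_id == cid]]
    if (any(diff(r) < 0) || (4 %in% r && !(2 %in% r))) {
      failures <- c(failures, "event order"); break
    }
  }
  if (!"cell_division" %in% kinds)
    failures <- c(failures, "no complete cycle within horizon")
  same <- length(ev1) == length(ev2) &&
    identical(vapply(ev2, `[[`, character(1), "kind"), kinds) &&
    isTRUE(all.equal(vapply(ev2, `[[`, numeric(1), "time"), times))
  if (!same) failures <- c(failures, "not deterministic under fixed seed")
  list(pass = length(failures) == 0, failures = failures)
}
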