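# Single-cell controller behavior and the plug-in contract. Population
# conditions use a toy interface so the tests do not depend on the shipped
# metabolic calibration.

toy_settings <- function(far1_ref = 1e10, ...) {
  gp <- toy_growth()
  timer_settings(T1a = 10, T2 = 12, TB = 70, TG1star = 12, CV_timer = 0,
                 far1_ref = far1_ref, theta_K2 = 0, theta_rho = 0,
                 K2_ref = gp$K2, rho_ref = gp$rho, gamma_T = 0, ...)
}

run_single_cell <- function(cell, gp, settings, dt = 0.1, horizon = 300,
                            controller = timer_controller_step, ...) {
  t <- 0; events <- list()
  while (t < horizon) {
    cell <- step_growth(cell, gp, dt)
    t <- t + dt
    out <- controller(cell, settings, gp, dt = dt, time = t, ...)
    cell <- out$cell
    events <- c(events, out$events)
    if (any(vapply(out$events, `[[`, character(1), "kind") == "cell_division"))
      break
  }
  list(cell = cell, events = events,
       kinds = vapply(events, `[[`, character(1), "kind"),
       times = vapply(events, `[[`, numeric(1), "time"))
}

test_that("a zero threshold makes G1 exactly T1a + T1b + T2", {
  gp <- toy_growth()
  st <- toy_settings(far1_ref = 1e-12)  # fires as soon as T1a ends: T1b = 0
  res <- run_single_cell(cell_state(P = 1e9, params = gp), gp, st)
  i_trig <- which(res$kinds == "trigger_fired")
  i_bud <- which(res$kinds == "budded")
  expect_equal(res$times[i_trig], st$T1a, tolerance = 1e-9)
  expect_equal(res$times[i_bud], st$T1a + st$T2, tolerance = 1e-9)
})

test_that("events come in legal order with the correct timer gaps", {
  gp <- toy_growth()
  st <- toy_settings()
  res <- run_single_cell(cell_state(P = 0.6e10, params = gp), gp, st)
  expect_identical(res$kinds, c("trigger_fired", "budded",
                                "nuclear_division", "cell_division"))
  t <- res$times
  expect_equal(t[2] - t[1], st$T2, tolerance = 1e-9)          # T2
  expect_equal(t[4] - t[2], st$TB, tolerance = 1e-9)          # TB
  expect_equal(t[4] - t[3], st$TG1star, tolerance = 1e-9)     # TG1*
})

test_that("the trigger fires at the size threshold and scales with it", {
  gp <- toy_growth()
  lam <- gp$K2 * gp$rho
  for (thr in c(0.8e10, 1.6e10)) {
    st <- toy_settings(far1_ref = thr)
    res <- run_single_cell(cell_state(P = 0.5e10, params = gp), gp, st,
                           horizon = 600)
    i <- which(res$kinds == "trigger_fired")
    P_s <- res$events[[i]]$P_at_event
    expect_gte(P_s, thr)
    expect_lt(P_s, thr * exp(lam * 0.1) * 1.001)  # first crossing, <1 step late
  }
  # doubling the threshold strictly increases the trigger size
  Ps_at <- function(thr) {
    st <- toy_settings(far1_ref = thr)
    res <- run_single_cell(cell_state(P = 0.5e10, params = gp), gp, st,
                           horizon = 600)
    res$events[[which(res$kinds == "trigger_fired")]]$P_at_event
  }
  expect_gt(Ps_at(1.6e10), Ps_at(0.8e10))
})

test_that("deterministic daughter lineage converges to identical cycles", {
  gp <- toy_growth()
  st <- toy_settings()
  cell <- cell_state(P = 0.4e10, params = gp)
  g1 <- numeric(0); pcd <- numeric(0)
  t <- 0
  for (gen in 1:15) {
    born <- t; t_bud <- NA
    repeat {
      cell <- step_growth(cell, gp, 0.1)
      t <- t + 0.1
      out <- timer_controller_step(cell, st, gp, dt = 0.1, time = t)
      cell <- out$cell
      kinds <- vapply(out$events, `[[`, character(1), "kind")
      if ("budded" %in% kinds) t_bud <- t
      if ("cell_division" %in% kinds) break
    }
    g1 <- c(g1, t_bud - born); pcd <- c(pcd, cell$P)
    halves <- divide_cell(cell, 1, time = t)
    cell <- halves$daughter       # follow the daughter line
    cell$timers <- NULL
  }
  n <- length(g1)
  expect_equal(g1[n], g1[n - 1], tolerance = 1e-3)
  expect_equal(pcd[n], pcd[n - 1], tolerance = 1e-3)
})

test_that("whi5 deletion fires START earlier than wild type", {
  gp <- toy_growth()
  st <- toy_settings()
  start_time <- function(preset) {
    mol <- g1s_preset(preset)
    res <- run_single_cell(cell_state(P = 0.6e10, params = gp), gp,
                           settings = mol, dt = 0.1, horizon = 600,
                           controller = function(cell, settings, params, dt,
                                                 time)
                             molecular_controller_step(cell, settings, params,
                                                       st, dt, time))
    i <- which(res$kinds == "trigger_fired")
    if (length(i)) res$times[i] else Inf
  }
  t_wt <- start_time("wild_type")
  t_delta <- start_time("whi5_delta")
  t_4e <- start_time("whi5_4E")
  expect_lt(t_delta, t_wt)
  expect_lte(t_delta, t_4e)
  expect_lte(t_4e, t_wt)
})

test_that("a fully inhibited G1/S module never fires START", {
  gp <- toy_growth()
  st <- toy_settings()
  mol <- g1s_params(k_phos = 0, Whi5_total = 10, SBF_total = 1,
                    alpha_W = 0)
  cell <- cell_state(P = 0.6e10, params = gp)
  t <- 0; fired <- FALSE
  while (t < 500) {
    cell <- step_growth(cell, gp, 0.5)
    t <- t + 0.5
    out <- molecular_controller_step(cell, mol, gp, st, 0.5, t)
    cell <- out$cell
    if (length(out$events)) { fired <- TRUE; break }
  }
  expect_false(fired)
})

test_that("both shipped controllers satisfy the plug-in contract", {
  gp <- toy_growth()
  st <- toy_settings()
  rep1 <- controller_contract_check("timer", params = gp, settings = st)
  expect_true(rep1$pass)
  rep2 <- controller_contract_check("g1s_molecular", params = gp,
                                    settings = st)
  expect_true(rep2$pass)
})

test_that("a stub emitting division before budding fails the contract", {
  bad <- function(cell, params, settings, dt, time) {
    ev <- if (time > 50 && !isTRUE(cell$divided_once)) {
      cell$divided_once <- TRUE
      list(cycle_event <- list(kind = "cell_division", time = time,
                               cell = NA_integer_, P_at_event = cell$P))
    } else list()
    list(cell = cell, events = ev)
  }
  rep <- controller_contract_check(bad, params = toy_growth(),
                                   settings = toy_settings())
  expect_false(rep$pass)
  expect_true(any(grepl("event order", rep$failures)))
})

test_that("molecular controller rejects negative-concentration dynamics", {
  gp <- toy_growth()
  st <- toy_settings()
  mol <- g1s_params(k_phos = 5e4, substeps = 1)  # wildly stiff phosphorylation
  cell <- cell_state(P = 0.6e10, params = gp)
  cell <- step_growth(cell, gp, 0.5)
  expect_error(
    molecular_controller_step(cell, mol, gp, st, dt = 0.5, time = 0.5),
    "negative concentration")
})
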