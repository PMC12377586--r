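# Population engine: conservation, pedigree, determinism, balanced-growth
# self-consistency. Runs use a toy growth interface and reduced populations
# so the suite stays fast.

toy_pop_settings <- function(...) {
  gp <- toy_growth()
  timer_settings(T1a = 6, T2 = 9, TB = 72, TG1star = 13,
                 far1_ref = 1e10, theta_K2 = 0, theta_rho = 0,
                 K2_ref = gp$K2, rho_ref = gp$rho, gamma_T = 0, ...)
}

test_that("division conserves protein exactly and ages correctly", {
  b <- cell_state(P = 100, phase = "Budded", P_bud = 40)
  b$age_genealogical <- 2L
  out <- divide_cell(b, partition_factor = 1, time = 10)
  expect_equal(out$parent$P, 60)
  expect_equal(out$daughter$P, 40)
  expect_equal(out$parent$P + out$daughter$P, 100)
  expect_equal(out$parent$age_genealogical, 3L)
  expect_equal(out$daughter$age_genealogical, 0L)
  expect_equal(out$daughter$t_birth, 10)
  # noise draws implying an empty compartment are rejected
  expect_error(divide_cell(b, partition_factor = 0), "redraw")
  expect_error(divide_cell(b, partition_factor = 100), "redraw")
})

test_that("engine divisions conserve protein through the event log", {
  gp <- toy_growth()
  pop <- simulate_population(gp, toy_pop_settings(),
                             small_config(target_cells = 800))
  cyc <- pop$cycles
  # for every division, the dividing cell's next-cycle birth size plus the
  # daughter's birth size must equal the recorded division size exactly
  for (i in sample.int(nrow(cyc), 100)) {
    row <- cyc[i, ]
    nxt <- cyc[cyc$cell == row$cell & cyc$t_start == row$t_div, ]
    P_parent_next <- if (nrow(nxt)) nxt$P0[1] else
      pop$cells$P0[pop$cells$id == row$cell &
                     pop$cells$t_cycle_start == row$t_div]
    if (!length(P_parent_next)) next
    expect_equal(P_parent_next + row$P_daughter, row$Pcd, tolerance = 1e-12)
  }
})

test_that("pedigree is a forest rooted at the founders", {
  pop <- simulate_population(toy_growth(), toy_pop_settings(),
                             small_config(target_cells = 600))
  ped <- pop$pedigree
  n0 <- pop$config$n_lines
  expect_false(any(duplicated(ped$child)))         # one parent each
  expect_false(any(ped$child %in% seq_len(n0)))    # founders have none
  expect_setequal(setdiff(pop$cells$id, ped$child), seq_len(n0))
  # every parent is a known cell and no child precedes its parent
  expect_true(all(ped$parent %in% pop$cells$id))
  expect_true(all(ped$child > ped$parent))
  expect_equal(nrow(pop$cells), n0 + nrow(ped))
})

test_that("identical seed and config give identical event logs", {
  gp <- toy_growth()
  st <- toy_pop_settings(CV_far1 = 0.05)
  cfg <- small_config(target_cells = 500, seed = 123)
  p1 <- simulate_population(gp, st, cfg)
  p2 <- simulate_population(gp, st, cfg)
  expect_identical(p1$cycles, p2$cycles)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$births, p2$births)
  p3 <- simulate_population(gp, st, small_config(target_cells = 500, seed = 124))
  expect_false(identical(p1$cycles, p3$cycles))
})

test_that("noise-free symmetric division doubles synchronously 1,2,4,8", {
  gp <- toy_growth()
  st <- symmetric_settings(gp)
  cfg <- population_config(n_lines = 1, target_cells = 60, horizon = 3000,
                           seed = 1, CV_partition = 0, dt = 0.5)
  pop <- simulate_population(gp, st, cfg)
  # births arrive in synchronized waves of the current population size
  waves <- rle(pop$births)
  expect_true(all(waves$lengths == 2^(seq_along(waves$lengths) - 1)))
  # and the wave spacing is one full cycle
  gaps <- diff(waves$values)
  expect_lt(diff(range(gaps)), 1e-6)
})

test_that("symmetric noise-free populations have equal parent/daughter G1", {
  gp <- toy_growth()
  st <- symmetric_settings(gp)
  cfg <- population_config(n_lines = 1, target_cells = 400, horizon = 6000,
                           seed = 1, CV_partition = 0, dt = 0.5)
  s <- compute_stats(simulate_population(gp, st, cfg))
  expect_equal(s$T_G1D, s$T_G1P, tolerance = 1e-6)
  expect_equal(s$F_PB + s$F_PNB + s$F_DB + s$F_DNB, 1, tolerance = 1e-9)
})

test_that("balanced growth: MDT matches the single-cell rate and Eq-5 closes", {
  gp <- toy_growth()
  st <- toy_pop_settings()
  pop <- simulate_population(gp, st, small_config(target_cells = 6000))
  s <- compute_stats(pop)
  lam_cell <- gp$K2 * gp$rho
  # population MDT equals the balanced single-cell doubling time
  expect_equal(s$MDT, log(2) / lam_cell, tolerance = 0.02)
  # the MDT slope fit is an excellent exponential fit
  expect_gt(s$mdt_r2, 0.999)
  # asymmetric-division consistency from event-log cycle times
  mu <- log(2) / s$MDT
  expect_lt(abs(asymmetry_residual(s$T_P, s$T_D, mu)), 0.02)
  # daughters dally in G1 at least as long as parents
  expect_gte(s$T_G1D, s$T_G1P)
  # fractions partition the population
  expect_equal(s$F_PB + s$F_PNB + s$F_DB + s$F_DNB, 1, tolerance = 1e-9)
  # stationarity: division size drifts < 1% of its mean over one MDT
  expect_lt(abs(s$drift_P), 0.01)
})

test_that("stationary statistics are population-size independent", {
  gp <- toy_growth()
  st <- toy_pop_settings()
  s1 <- compute_stats(simulate_population(gp, st, small_config(target_cells = 6000)))
  s2 <- compute_stats(simulate_population(gp, st,
                                          small_config(target_cells = 600, seed = 9)))
  expect_equal(s1$P_mean, s2$P_mean, tolerance = 0.04)
})

test_that("formula-derived durations cross-validate against the event log", {
  gp <- toy_growth()
  st <- toy_pop_settings()
  s <- compute_stats(simulate_population(gp, st, small_config(target_cells = 6000)))
  cvr <- crossvalidate_with_simulation(s)
  expect_true(cvr$available)
  expect_lt(max(abs(cvr$relative_deviation)), 0.06)
  expect_lt(abs(cvr$eq5_residual), 0.02)
  # heavier timer noise degrades the match but Eq 5 keeps closing
  s2 <- compute_stats(simulate_population(
    gp, toy_pop_settings(CV_timer = 0.3),
    small_config(target_cells = 6000, seed = 21)))
  cvr2 <- crossvalidate_with_simulation(s2)
  expect_lt(abs(cvr2$eq5_residual), 0.05)
  # an empty log is reported as unavailable, not zero
  empty <- s; empty$n_cycles_post <- 0L
  expect_false(crossvalidate_with_simulation(empty)$available)
})

test_that("replicate runs: equal seeds collapse the SD, rows match n_rep", {
  gp <- toy_growth()
  st <- toy_pop_settings()
  cfg <- small_config(target_cells = 400)
  rs <- replicate_stats(gp, st, cfg, n_rep = 2, seeds = c(5, 5))
  expect_equal(nrow(rs$replicates), 2)
  expect_equal(unname(rs$sd["P_mean"]), 0)
  rs2 <- replicate_stats(gp, st, cfg, n_rep = 3)
  expect_equal(nrow(rs2$replicates), 3)
  expect_gt(rs2$sd[["P_mean"]], 0)
})

test_that("sensitivity scan: null perturbation is exactly zero, T2 raises size", {
  gp <- toy_growth()
  st <- toy_pop_settings()
  cfg <- small_config(target_cells = 1200)
  null_scan <- sensitivity_scan(gp, st, cfg, parameters = "T2", steps = 1)
  expect_true(all(null_scan$relative_change == 0))
  scan <- sensitivity_scan(gp, st, cfg, parameters = "T2",
                           steps = c(0.7, 1.4))
  up <- scan[scan$step == 1.4 & scan$output == "P_mean", ]
  down <- scan[scan$step == 0.7 & scan$output == "P_mean", ]
  expect_gt(up$relative_change, 0)     # longer T2 -> larger cells
  expect_lt(down$relative_change, 0)
})

test_that("population warns when the horizon forecloses growth", {
  gp <- toy_growth()
  pop <- simulate_population(gp, toy_pop_settings(),
                             population_config(target_cells = 1000,
                                               horizon = 30, seed = 2))
  expect_true("horizon_before_two_doublings" %in% pop$flags)
})
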