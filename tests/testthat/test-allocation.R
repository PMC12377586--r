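# The allocation optimum is checked against an exhaustive grid oracle on a
# reduced instance, and its balances/feasibility invariants on the full
# five-class problem.

test_that("zero carbon is infeasible with a zero-growth flagged solution", {
  sol <- solve_allocation(nutrient_condition("glucose", 0, F = 0.5))
  expect_false(sol$feasible)
  expect_equal(sol$lambda, 0)
  expect_true(all(sol$fluxes == 0))
})

test_that("F = 0 shuts fermentation down completely", {
  sol <- solve_allocation(nutrient_condition("glucose", 2, F = 0))
  expect_equal(sol$phi[["fermentation"]], 0)
  expect_equal(sol$fluxes[["fermentation"]], 0)
  expect_gt(sol$fluxes[["respiration"]], 0)
})

test_that("optimizer beats an exhaustive grid oracle on a reduced instance", {
  # 3 free classes: transport made effectively free, F = 1 (no respiration),
  # no energy-activity coupling, no maintenance
  p <- metabolic_params(k_cat_hxt = 1e9, K_M_hxt = 0.1,
                        k_cat_gly = 0.15, k_cat_ferm = 0.4,
                        k_trans = 0.04, act_min = 1,
                        e_atp_aa = 5, c_pyr_aa = 1, y_atp_gly = 2,
                        atp_maintenance = 0,
                        phi_max = 0.45, phi_other = 0.05)
  cond <- nutrient_condition("glucose", 2, F = 1)
  sol <- solve_allocation(cond, p)

  # oracle: enumerate (phi_gly, phi_ferm, phi_ribo) on a 0.005 grid and
  # compute the largest lambda each candidate supports:
  #   ATP:     y_gly * v_glc = e_aa * lambda   (glycolytic ATP only)
  #   carbon:  2 v_glc = v_ferm + c_aa * lambda
  # feasibility: v_glc <= k_gly phi_gly, v_ferm <= k_ferm phi_ferm,
  #              lambda <= k_trans phi_ribo
  budget <- p$phi_max - p$phi_other
  grid <- seq(0, budget, by = 0.005)
  best <- 0
  for (pg in grid) for (pf in grid) {
    if (pg + pf > budget) next
    pr <- budget - pg - pf          # give the rest to ribosomes
    lam_gly <- p$y_atp_gly * p$k_cat_gly * pg / p$e_atp_aa
    # v_ferm = 2 v_glc - lambda = (e_aa - 1) lambda / ... carbon balance:
    lam_ferm <- p$k_cat_ferm * pf /
      (2 * p$e_atp_aa / p$y_atp_gly - p$c_pyr_aa)
    lam_ribo <- p$k_trans * pr
    best <- max(best, min(lam_gly, lam_ferm, lam_ribo))
  }
  expect_gte(sol$lambda, best - 1e-6)
  # and the continuous optimum is no better than the grid by more than the
  # grid resolution effect
  expect_lt(sol$lambda, best * 1.05)
})

test_that("budget and balances hold at every optimum", {
  conds <- list(nutrient_condition("glucose", 2, F = 0.9),
                nutrient_condition("glucose", 0.1, F = 0.3),
                nutrient_condition("glucose", 5, F = 1),
                nutrient_condition("ethanol", 2))
  for (cd in conds) {
    sol <- solve_allocation(cd)
    p <- sol$params
    expect_true(all(sol$phi >= -1e-12))
    expect_lte(sum(sol$phi) + p$phi_other, p$phi_max + 1e-9)
    expect_equal(sum(sol$phi) + p$phi_other, p$phi_max, tolerance = 1e-6)
    fl <- sol$fluxes
    if (cd$source == "glucose") {
      # carbon: glycolytic pyruvate = catabolism + biosynthetic drain
      expect_equal(2 * fl[["uptake"]],
                   fl[["fermentation"]] + fl[["respiration"]] +
                     p$c_pyr_aa * sol$lambda, tolerance = 1e-6)
      # imposed fermentative split
      vcat <- fl[["fermentation"]] + fl[["respiration"]]
      if (vcat > 0)
        expect_equal(fl[["fermentation"]] / vcat, cd$F, tolerance = 1e-9)
      # ATP: substrate-level + respiratory production covers demand
      atp_in <- p$y_atp_gly * fl[["uptake"]] +
        p$y_atp_resp_pyr * fl[["respiration"]]
      atp_out <- p$e_atp_aa * sol$lambda + p$atp_maintenance
      expect_equal(atp_in, atp_out, tolerance = 1e-6)
    } else {
      expect_equal(fl[["uptake"]],
                   fl[["respiration"]] + fl[["gluconeogenesis"]],
                   tolerance = 1e-6)
      atp_in <- p$y_atp_resp_etoh * fl[["respiration"]]
      atp_out <- (p$e_atp_aa + p$e_atp_gng * p$c_pyr_aa) * sol$lambda +
        p$atp_maintenance
      expect_equal(atp_in, atp_out, tolerance = 1e-6)
    }
  }
})

test_that("lambda is monotone nondecreasing in glucose concentration", {
  cc <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 1, 2, 3.5, 5)
  for (F in c(0.2, 0.9)) {
    lam <- vapply(cc, function(c)
      solve_allocation(nutrient_condition("glucose", c, F = F))$lambda,
      numeric(1))
    expect_true(all(diff(lam) >= -1e-12))
  }
})

test_that("respiratory allocation falls and ribosomes rise along sweeps", {
  # F sweep at fixed glucose: phi_respiration nonincreasing in F
  Fs <- seq(0, 1, by = 0.1)
  tab <- allocation_series(lapply(Fs, function(f)
    nutrient_condition("glucose", 2, F = f)))
  expect_true(all(diff(tab$phi_respiration) <= 1e-12))
  # glucose sweep at fixed F: phi_ribo (hence rho) nondecreasing in lambda
  cc <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)
  tab2 <- allocation_series(lapply(cc, function(c)
    nutrient_condition("glucose", c, F = 0.9)))
  ord <- order(tab2$lambda)
  expect_true(all(diff(tab2$phi_ribosome[ord]) >= -1e-12))
  expect_true(all(diff(tab2$rho[ord]) >= -1e-12))
})

test_that("series of one condition equals a single solve", {
  cd <- nutrient_condition("glucose", 0.5, F = 0.6)
  tab <- allocation_series(list(cd))
  sol <- solve_allocation(cd)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$lambda, sol$lambda)
  expect_equal(tab$K2, sol$K2)
})

test_that("parameters the instance cannot use are structurally null", {
  # ethanol-transport capacity is irrelevant on glucose at F = 1
  base <- solve_allocation(nutrient_condition("glucose", 2, F = 1))
  pert <- solve_allocation(
    nutrient_condition("glucose", 2, F = 1),
    apply_overlay(metabolic_params(), c(k_cat_etoh_transport = 2)))
  expect_equal(base$lambda, pert$lambda)
  expect_equal(base$phi, pert$phi)
})

test_that("overlays validate names and factors", {
  p <- metabolic_params()
  expect_equal(apply_overlay(p, c(k_cat_hxt = 0.2))$k_cat_hxt,
               p$k_cat_hxt * 0.2)
  expect_error(apply_overlay(p, c(nope = 2)), "unknown parameter")
  expect_error(apply_overlay(p, c(k_cat_hxt = -1)), "finite")
})
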