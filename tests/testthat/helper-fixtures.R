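# Shared small fixtures. Populations here are deliberately small so the
# default test run stays fast; statistical assertions use tolerances sized
# for these populations.

small_config <- function(target_cells = 3000, seed = 7, ...) {
  population_config(target_cells = target_cells, seed = seed, ...)
}

wt_allocation <- function(conc = 2, source = "glucose") {
  solve_allocation(nutrient_condition(source, conc))
}

# Deterministic symmetric toy configuration: no noise, threshold disabled,
# budded timer chosen so the bud holds exactly half the division protein
# (e^{lambda*TB} = 2), making every division symmetric and the population
# fully synchronous.
symmetric_settings <- function(gp) {
  lam <- gp$K2 * gp$rho - gp$delta_P
  timer_settings(T1a = 10, T2 = 10, TB = log(2) / lam, TG1star = 5,
                 CV_timer = 0, far1_ref = 1, # threshold below any cell size
                 theta_K2 = 0, theta_rho = 0,
                 K2_ref = gp$K2, rho_ref = gp$rho,
                 gamma_T = 0)
}

toy_growth <- function() growth_params(K2 = 0.02, rho = 0.35)
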