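#' Define a simulation scenario
#'
#' A scenario bundles everything needed to reproduce one simulation
#' campaign: the nutrient conditions, multiplicative parameter overlays
#' (mutants), the choice of cycle controller and G1/S preset, how the
#' fermentative ratio is set, and the replicate plan. Scenario definitions
#' are data: the shipped campaigns live as YAML files under
#' \code{system.file("scenarios", package = "yeastpop")}.
#'
#' @param name Scenario name.
#' @param conditions List of \code{\link{nutrient_condition}}s (or lists
#'   with \code{source}/\code{concentration}/\code{F} fields).
#' @param overlay Named multiplicative factors on
#'   \code{\link{metabolic_params}} entries (0 = knockout).
#' @param interface_overlay Named factors applied to the exported interface
#'   (\code{K2}, \code{rho}) after the allocation solve, for perturbations
#'   downstream of metabolism (e.g. crippled ribosome biogenesis).
#' @param F_policy \code{"curve"} (wild-type fitted F(glucose) curve) or
#'   \code{"optimal"} (growth-maximizing F; used for metabolic mutants whose
#'   measured yields are not package inputs).
#' @param controller \code{"timer"} or \code{"g1s_molecular"}.
#' @param g1s_preset Preset name for the molecular module (see
#'   \code{\link{g1s_preset}}).
#' @param target_cells,n_rep,seed Replicate plan.
#' @return An object of class \code{"scenario"}.
#' @export
scenario <- function(name, conditions, overlay = NULL,
                     interface_overlay = NULL,
                     F_policy = c("curve", "optimal"),
                     controller = c("timer", "g1s_molecular"),
                     g1s_preset = "wild_type",
                     target_cells = 50000, n_rep = 1, seed = 1) {
  F_policy <- match.arg(F_policy)
  controller <- match.arg(controller)
  conditions <- lapply(conditions, function(cd) {
    if (inherits(cd, "nutrient_condition")) return(cd)
    nutrient_condition(cd$source, cd$concentration,
                       F = if (is.null(cd$F)) NA_real_ else cd$F,
                       Y_etoh = if (is.null(cd$Y_etoh)) NA_real_ else cd$Y_etoh)
  })
  if (!is.null(overlay)) {
    # validated against the parameter schema right away
    invisible(apply_overlay(metabolic_params(), overlay))
  }
  structure(list(name = name, conditions = conditions, overlay = overlay,
                 interface_overlay = interface_overlay,
                 F_policy = F_policy, controller = controller,
                 g1s_preset = g1s_preset,
                 target_cells = as.integer(target_cells),
                 n_rep = as.integer(n_rep), seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario `%s`: %d condition(s), %s controller, F policy `%s`\n",
              x$name, length(x$conditions), x$controller, x$F_policy))
  if (!is.null(x$overlay))
    cat("  overlay:", paste(names(x$overlay), unlist(x$overlay),
                            sep = " x ", collapse = ", "), "\n")
  invisible(x)
}

#' Load a shipped scenario definition
#'
#' @param name Scenario name (file \code{<name>.yaml} under the package's
#'   \code{scenarios/} directory) or a path to a YAML file.
#' @return A \code{\link{scenario}}.
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("scenarios", paste0(name, ".yaml"), package = "yeastpop")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario: ", name)
  raw <- yaml::read_yaml(path)
  do.call(scenario, raw)
}

#' Run a scenario end to end
#'
#' For each condition: resolve F (fitted curve or growth-optimal), solve
#' the proteome allocation under the scenario overlay, simulate the
#' population, compute statistics, and bin the protein distribution —
#' either with a frozen reference alignment (when given) or on the
#' population's own amino-acid scale.
#'
#' @param s A \code{\link{scenario}} (or scenario name for
#'   \code{\link{load_scenario}}).
#' @param params Base metabolic parameters (before the overlay).
#' @param settings Timer settings.
#' @param cfg Base population configuration; the scenario's replicate plan
#'   overrides \code{target_cells} and \code{seed}.
#' @param alignment Optional \code{"alignment_result"} with the frozen
#'   reference (origin, width).
#' @return An object of class \code{"scenario_bundle"}: per-condition list
#'   of \code{allocation}, \code{stats}, \code{histogram}, \code{P} (live
#'   cell protein values), plus the scenario and seeds used.
#' @export
run_scenario <- function(s, params = metabolic_params(),
                         settings = timer_settings(),
                         cfg = population_config(),
                         alignment = NULL) {
  if (is.character(s)) s <- load_scenario(s)
  stopifnot(inherits(s, "scenario"))
  p <- apply_overlay(params, s$overlay)
  cfg$target_cells <- s$target_cells
  results <- list()
  for (i in seq_along(s$conditions)) {
    cd <- s$conditions[[i]]
    if (cd$source == "glucose" && is.na(cd$F) && is.na(cd$Y_etoh) &&
        s$F_policy == "optimal")
      cd$F <- optimal_F(cd$concentration, p)$F
    alloc <- solve_allocation(cd, p)
    if (!is.null(s$interface_overlay)) {
      io <- unlist(s$interface_overlay)
      bad <- setdiff(names(io), c("K2", "rho"))
      if (length(bad)) stop("interface overlay allows only K2, rho; got ",
                            paste(bad, collapse = ", "))
      for (nm in names(io)) alloc[[nm]] <- alloc[[nm]] * io[[nm]]
    }
    cfg_i <- cfg
    cfg_i$seed <- s$seed + (i - 1L) * 1000L
    pop <- simulate_population(alloc, settings, cfg_i,
                               controller = s$controller,
                               g1s = g1s_preset(s$g1s_preset))
    st <- compute_stats(pop)
    hist <- if (!is.null(alignment)) {
      reuse_alignment(alignment, pop$cells$P)$histogram
    } else {
      rng <- range(pop$cells$P)
      build_histogram(pop$cells$P, rng[1],
                      (rng[2] - rng[1]) / 1024 * (1 + 1e-9),
                      scale = "amino_acids")
    }
    key <- sprintf("%s_%g", cd$source, cd$concentration)
    results[[key]] <- list(condition = alloc$condition, allocation = alloc,
                           stats = st, histogram = hist, P = pop$cells$P,
                           seed = cfg_i$seed)
  }
  structure(list(scenario = s, results = results),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("Scenario bundle `%s` (%d condition(s))\n",
              x$scenario$name, length(x$results)))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-14s F = %.3f, lambda = %.5f, <P> = %.4g aa, MDT = %.1f min\n",
                nm, r$condition$F, r$allocation$lambda, r$stats$P_mean,
                r$stats$MDT))
  }
  invisible(x)
}

#' Nutritional size-modulation ratio
#'
#' The ratio of mean protein contents between growth in 2\% glucose and in
#' ethanol: about 1.8 when nutritional modulation of cell size is fully
#' operative and near 1 when it is lost.
#'
#' @param bundle A \code{"scenario_bundle"} containing a 2\% glucose and an
#'   ethanol condition.
#' @return The dimensionless ratio.
#' @export
size_modulation_ratio <- function(bundle) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  keys <- names(bundle$results)
  glc <- grep("^glucose_2$", keys, value = TRUE)
  eth <- grep("^ethanol_", keys, value = TRUE)
  if (!length(glc)) stop("bundle is missing the 2% glucose condition")
  if (!length(eth)) stop("bundle is missing the ethanol condition")
  bundle$results[[glc[1]]]$stats$P_mean /
    bundle$results[[eth[1]]]$stats$P_mean
}

#' F-by-glucose heat-map scan
#'
#' Simulates populations over a grid of imposed fermentative ratios and
#' glucose concentrations and tabulates the monitored outputs (mean, SD and
#' CV of protein content; MDT; parent and daughter G1 lengths) as matrices
#' suitable for heat-map rendering.
#'
#' @param glucose Glucose concentrations (\% w/v).
#' @param F_grid Imposed fermentative ratios in \[0, 1\].
#' @param params,settings,cfg As in \code{\link{run_scenario}}; use a
#'   reduced \code{cfg$target_cells} for tractable scans.
#' @param outputs Monitored statistics.
#' @return A list of matrices (rows = F values, columns = glucose), one per
#'   output, plus \code{failed} (logical matrix).
#' @export
fxg_heatmap <- function(glucose, F_grid,
                        params = metabolic_params(),
                        settings = timer_settings(),
                        cfg = population_config(target_cells = 4000),
                        outputs = c("P_mean", "SD_P", "CV_P", "MDT",
                                    "T_G1P", "T_G1D")) {
  stopifnot(length(glucose) >= 1, length(F_grid) >= 1)
  mats <- lapply(outputs, function(o)
    matrix(NA_real_, length(F_grid), length(glucose),
           dimnames = list(paste0("F=", F_grid), paste0("glc=", glucose))))
  names(mats) <- outputs
  failed <- matrix(FALSE, length(F_grid), length(glucose))
  for (i in seq_along(F_grid)) for (j in seq_along(glucose)) {
    res <- tryCatch({
      alloc <- solve_allocation(
        nutrient_condition("glucose", glucose[j], F = F_grid[i]), params)
      if (!alloc$feasible) stop("infeasible")
      pop <- simulate_population(alloc, settings, cfg)
      compute_stats(pop)
    }, error = function(e) NULL)
    if (is.null(res)) { failed[i, j] <- TRUE; next }
    for (o in outputs) mats[[o]][i, j] <- res[[o]]
  }
  c(mats, list(failed = failed))
}
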