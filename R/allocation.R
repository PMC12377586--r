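#' Growth-maximizing proteome allocation
#'
#' For a nutrient condition (carbon source, concentration, fermentative
#' ratio F) the solver allocates the bounded proteome budget across five
#' protein classes — glucose carriers (HXT), glycolysis/gluconeogenesis,
#' fermentation, respiration and ribosome/translation — so as to maximize
#' the balanced exponential growth rate lambda, and exports the growth
#' interface: the per-ribosome synthesis rate K2 and the target RNA/protein
#' ratio rho.
#'
#' The allocation program is linear in the class fractions at fixed F:
#' each pathway flux is capped by \code{k_cat * phi} (Michaelis-Menten
#' saturated for transport), glycolytic pyruvate is split F:(1-F) between
#' fermentation and respiration, carbon and ATP must balance, and the class
#' fractions plus the housekeeping fraction must fit in \code{phi_max}. At
#' the optimum every capacity constraint and both balances bind — any slack
#' would waste budget that could hold ribosomes — so the optimum is obtained
#' by propagating the balances at a candidate lambda and locating the unique
#' lambda at which the proteome budget is exactly exhausted (a monotone
#' 1-D root). The ribosome class carries an energy-coupled activity factor
#' saturating with the specific substrate-level (glycolytic) ATP flux, which
#' makes K2 — not only lambda — nutrient dependent.
#'
#' @param condition A \code{\link{nutrient_condition}}. A missing F is
#'   resolved via \code{\link{resolve_F}} with the supplied curve.
#' @param params A \code{\link{metabolic_params}} object.
#' @param curve Fermentative-ratio curve used when F is unresolved.
#'
#' @return An object of class \code{"allocation_solution"}: a list with
#'   \code{lambda} (1/min), \code{phi} (named fractions over the five
#'   classes), \code{fluxes} (pyruvate-equivalents/min per unit protein),
#'   \code{K2} (aa per RNA unit per min), \code{K2_per_ribosome}
#'   (aa/ribosome/min), \code{rho}, \code{q_slp} (specific substrate-level
#'   ATP flux), \code{feasible}, and the resolved \code{condition}.
#'   Infeasible inputs (e.g. zero carbon) return \code{lambda = 0} with
#'   \code{feasible = FALSE} rather than an error.
#' @examples
#' sol <- solve_allocation(nutrient_condition("glucose", 2, F = 0.9))
#' sol$lambda
#' colSums(cbind(sol$phi))  # within the allocatable budget
#' @export
solve_allocation <- function(condition, params = metabolic_params(),
                             curve = wildtype_fermentation_curve()) {
  stopifnot(inherits(condition, "nutrient_condition"))
  condition <- resolve_F(condition, curve)
  p <- params
  validate_metabolic_params(p)

  empty <- function(feasible) {
    phi <- c(HXT = 0, glycolysis = 0, fermentation = 0, respiration = 0,
             ribosome = 0)
    fluxes <- c(uptake = 0, glycolysis = 0, fermentation = 0,
                respiration = 0, gluconeogenesis = 0, biosynthesis = 0,
                atp_substrate_level = 0, atp_total = 0)
    structure(list(lambda = 0, phi = phi, fluxes = fluxes,
                   K2 = p$k_trans * p$act_min / p$chi_rna,
                   K2_per_ribosome = p$k_trans * p$act_min / p$chi_rna * p$rib_rna_aa,
                   rho = NA_real_, q_slp = 0,
                   feasible = feasible, condition = condition,
                   budget_used = p$phi_other, params = p),
              class = "allocation_solution")
  }
  if (condition$concentration <= 0) return(empty(FALSE))

  budget <- p$phi_max - p$phi_other
  alloc_at <- function(lambda) allocation_at_lambda(lambda, condition, p)
  g <- function(lambda) sum(alloc_at(lambda)$phi) - budget

  if (g(0) >= 0) return(empty(FALSE))
  lambda_hi <- p$k_trans * p$phi_max
  root <- stats::uniroot(g, c(0, lambda_hi), tol = 1e-12)
  a <- alloc_at(root$root)

  rho <- p$chi_rna * a$phi[["ribosome"]]
  K2 <- if (rho > 0) (root$root + 0) / rho * 1 else NA_real_
  # K2 is the realized elongation flux per RNA unit: lambda / rho. It equals
  # k_trans * act / chi_rna by construction of the ribosome capacity.
  out <- list(lambda = root$root, phi = a$phi, fluxes = a$fluxes,
              K2 = K2, K2_per_ribosome = K2 * p$rib_rna_aa,
              rho = rho, q_slp = a$q_slp, feasible = TRUE,
              condition = condition,
              budget_used = sum(a$phi) + p$phi_other, params = p)
  class(out) <- "allocation_solution"
  out
}

# Propagate carbon/ATP balances and binding capacity constraints at a fixed
# candidate growth rate; returns class fractions and fluxes.
allocation_at_lambda <- function(lambda, condition, p) {
  F <- condition$F
  m0 <- p$atp_maintenance
  if (condition$source == "glucose") {
    sat <- condition$concentration / (p$K_M_hxt + condition$concentration)
    den <- p$y_atp_gly / 2 + p$y_atp_resp_pyr * (1 - F)
    num <- (p$e_atp_aa - p$y_atp_gly * p$c_pyr_aa / 2) * lambda + m0
    v_cat <- num / den                     # catabolized pyruvate flux
    v_glc <- (v_cat + p$c_pyr_aa * lambda) / 2
    v_ferm <- F * v_cat
    v_resp <- (1 - F) * v_cat
    # catabolic substrate-level ATP flux: the overflow-metabolism signal
    # coupled to ribosome activity (biosynthetic carbon does not signal)
    q <- p$y_atp_gly * v_cat / 2
    act <- ribo_activity(q, p)
    phi <- c(HXT = v_glc / (p$k_cat_hxt * sat),
             glycolysis = v_glc / p$k_cat_gly,
             fermentation = v_ferm / p$k_cat_ferm,
             respiration = v_resp / p$k_cat_resp_pyr,
             ribosome = lambda / (p$k_trans * act))
    fluxes <- c(uptake = v_glc, glycolysis = 2 * v_glc,
                fermentation = v_ferm, respiration = v_resp,
                gluconeogenesis = 0, biosynthesis = lambda,
                atp_substrate_level = p$y_atp_gly * v_glc,
                atp_total = p$y_atp_gly * v_glc +
                  p$y_atp_resp_pyr * v_resp)
  } else {
    sat <- condition$concentration / (p$K_M_etoh + condition$concentration)
    v_resp <- ((p$e_atp_aa + p$e_atp_gng * p$c_pyr_aa) * lambda + m0) /
      p$y_atp_resp_etoh
    v_gng <- p$c_pyr_aa * lambda
    v_e <- v_resp + v_gng
    act <- ribo_activity(0, p)
    phi <- c(HXT = v_e / (p$k_cat_etoh_transport * sat),
             glycolysis = v_gng / p$k_cat_gng,
             fermentation = 0,
             respiration = v_resp / p$k_cat_resp_etoh,
             ribosome = lambda / (p$k_trans * act))
    fluxes <- c(uptake = v_e, glycolysis = 0, fermentation = 0,
                respiration = v_resp, gluconeogenesis = v_gng,
                biosynthesis = lambda,
                atp_substrate_level = 0,
                atp_total = p$y_atp_resp_etoh * v_resp)
  }
  list(phi = phi, fluxes = fluxes,
       q_slp = if (condition$source == "glucose") q else 0)
}

# Energy-coupled ribosome activity: elongation saturates with the specific
# substrate-level ATP flux (Hill form with a respiratory floor).
ribo_activity <- function(q, p) {
  n <- p$hill_act
  p$act_min + (1 - p$act_min) * q^n / (p$K_act^n + q^n)
}

#' @export
print.allocation_solution <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("Allocation optimum: %g%% %s, F = %.3f\n",
              cond$concentration, cond$source, cond$F))
  if (!x$feasible) {
    cat("  infeasible: lambda = 0 (no positive-growth allocation)\n")
    return(invisible(x))
  }
  cat(sprintf("  lambda = %.5f 1/min (MDT %.1f min)\n",
              x$lambda, log(2) / x$lambda))
  cat("  phi:", paste(sprintf("%s %.4f", names(x$phi), x$phi), collapse = ", "),
      "\n")
  cat(sprintf("  interface: K2 = %.4g aa/RNA/min (%.0f aa/ribosome/min), rho = %.4f\n",
              x$K2, x$K2_per_ribosome, x$rho))
  invisible(x)
}

#' @export
coef.allocation_solution <- function(object, ...) object$phi

#' @export
summary.allocation_solution <- function(object, ...) {
  out <- c(lambda = object$lambda, object$phi,
           K2 = object$K2, rho = object$rho,
           budget_used = object$budget_used)
  print(object)
  invisible(out)
}

#' Solve a series of nutrient conditions
#'
#' One allocation optimum per condition, in input order, flattened to a
#' data frame suitable for sweeps and F-by-glucose heat maps.
#'
#' @param conditions A list of \code{\link{nutrient_condition}} objects.
#' @param params A \code{\link{metabolic_params}}.
#' @param curve Fermentative-ratio curve for unresolved F.
#' @return A data frame with one row per condition: source, concentration,
#'   F, lambda, the five phi fractions, K2, rho and the feasibility flag.
#' @export
allocation_series <- function(conditions, params = metabolic_params(),
                              curve = wildtype_fermentation_curve()) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  rows <- lapply(conditions, function(cd) {
    s <- solve_allocation(cd, params, curve)
    data.frame(source = s$condition$source,
               concentration = s$condition$concentration,
               F = s$condition$F,
               lambda = s$lambda,
               phi_HXT = s$phi[["HXT"]],
               phi_glycolysis = s$phi[["glycolysis"]],
               phi_fermentation = s$phi[["fermentation"]],
               phi_respiration = s$phi[["respiration"]],
               phi_ribosome = s$phi[["ribosome"]],
               K2 = s$K2, rho = s$rho,
               feasible = s$feasible)
  })
  do.call(rbind, rows)
}

#' Growth-optimal fermentative ratio
#'
#' Scans F over a grid and returns the value maximizing lambda for the given
#' glucose condition. Used for mutant overlays, whose measured fermentative
#' ratios are not inputs of the package: a strain with crippled transport or
#' glycolysis is assumed to run the catabolic split that maximizes its
#' growth rate, which reproduces the respiratory shift of such mutants.
#'
#' @param concentration Glucose concentration (\% w/v).
#' @param params A \code{\link{metabolic_params}}.
#' @param grid Candidate F values.
#' @return A list with \code{F} (argmax), \code{lambda}, and the full
#'   \code{profile} data frame.
#' @export
optimal_F <- function(concentration, params = metabolic_params(),
                      grid = seq(0, 1, by = 0.01)) {
  lam <- vapply(grid, function(f) {
    solve_allocation(nutrient_condition("glucose", concentration, F = f),
                     params)$lambda
  }, numeric(1))
  i <- which.max(lam)
  list(F = grid[i], lambda = lam[i],
       profile = data.frame(F = grid, lambda = lam))
}

# Wild-type reference interface (K2, rho) at 2% glucose with default
# parameters; memoized. The cycle module scales its size threshold by the
# condition interface relative to this reference, so mutants and poor media
# are always measured against the same wild-type anchor.
.yeastpop_env <- new.env(parent = emptyenv())

#' @export
#' @rdname solve_allocation
reference_interface <- function() {
  if (is.null(.yeastpop_env$ref)) {
    sol <- solve_allocation(nutrient_condition("glucose", 2),
                            metabolic_params())
    .yeastpop_env$ref <- c(K2 = sol$K2, rho = sol$rho)
  }
  .yeastpop_env$ref
}
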