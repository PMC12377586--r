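#' Metabolic parameters of the allocation solver
#'
#' Parameters of the coarse-grained self-replicator behind the allocation
#' solver. Fluxes are expressed in pyruvate-equivalent carbon units per
#' minute per unit of total protein (aa); one glucose yields two
#' pyruvate-equivalents, and one excreted ethanol carries one
#' pyruvate-equivalent, so the stoichiometric maximum fermentative yield is
#' two ethanol per glucose. Catalytic coefficients \code{k_cat_*} are flux
#' capacity per unit proteome fraction per minute.
#'
#' @param k_cat_hxt Glucose transport capacity (glucose units/min per
#'   proteome fraction).
#' @param K_M_hxt Half-saturation glucose concentration of transport (\% w/v).
#' @param k_cat_gly Glycolytic capacity (glucose units/min per fraction).
#' @param k_cat_ferm Fermentation capacity (pyruvate units/min per fraction).
#' @param k_cat_resp_pyr Pyruvate respiration capacity (pyruvate units/min
#'   per fraction). Deliberately low relative to \code{k_cat_ferm}: the
#'   overflow-metabolism trade-off (fermentation yields less ATP per carbon
#'   but far more ATP per unit proteome) lives in this contrast.
#' @param k_cat_resp_etoh Ethanol respiration capacity.
#' @param k_cat_gng Gluconeogenic capacity (precursor aa units/min per
#'   fraction), used only on ethanol.
#' @param k_cat_etoh_transport Ethanol transport capacity.
#' @param K_M_etoh Half-saturation ethanol concentration (\% v/v).
#' @param y_atp_gly ATP per glucose through glycolysis (substrate-level).
#' @param y_atp_resp_pyr ATP per pyruvate respired.
#' @param y_atp_resp_etoh ATP per ethanol respired.
#' @param e_atp_aa ATP cost per polymerized amino acid.
#' @param e_atp_gng Extra ATP cost per precursor amino acid made
#'   gluconeogenically from ethanol.
#' @param c_pyr_aa Pyruvate-equivalents of carbon per amino-acid precursor.
#' @param atp_maintenance Growth-independent ATP demand (ATP/min per unit
#'   protein).
#' @param k_trans Maximal peptide-elongation capacity per unit ribosomal
#'   proteome (1/min); the per-ribosome synthesis rate K2 equals
#'   \code{k_trans} times the energy-coupled activity factor.
#' @param act_min Floor of the ribosome activity factor (fully respiratory
#'   conditions).
#' @param K_act Half-activation substrate-level ATP flux for the ribosome
#'   activity factor (ATP/min per unit protein).
#' @param hill_act Hill coefficient of the activity factor.
#' @param phi_max Total allocatable proteome fraction.
#' @param phi_other Fixed housekeeping fraction inside \code{phi_max}.
#' @param chi_rna RNA mass per unit ribosomal-class proteome mass; converts
#'   the ribosomal allocation into the exported RNA/protein ratio rho.
#' @param rib_rna_aa RNA mass per ribosome in amino-acid-equivalent units;
#'   converts the per-RNA-unit synthesis rate into aa/ribosome/min.
#'
#' @return An object of class \code{"metabolic_params"}.
#' @export
metabolic_params <- function(k_cat_hxt = 0.434832,
                             K_M_hxt = 0.10,
                             k_cat_gly = 0.0768055,
                             k_cat_ferm = 10.2719,
                             k_cat_resp_pyr = 0.0521307,
                             k_cat_resp_etoh = 0.078094,
                             k_cat_gng = 0.134328,
                             k_cat_etoh_transport = 0.02536,
                             K_M_etoh = 0.30,
                             y_atp_gly = 2,
                             y_atp_resp_pyr = 13,
                             y_atp_resp_etoh = 11,
                             e_atp_aa = 5,
                             e_atp_gng = 2,
                             c_pyr_aa = 1,
                             atp_maintenance = 0.005,
                             k_trans = 0.0349036,
                             act_min = 0.529246,
                             K_act = 0.00904493,
                             hill_act = 1.68541,
                             phi_max = 0.45,
                             phi_other = 0.05,
                             chi_rna = 1.6,
                             rib_rna_aa = 15500) {
  p <- list(k_cat_hxt = k_cat_hxt, K_M_hxt = K_M_hxt, k_cat_gly = k_cat_gly,
            k_cat_ferm = k_cat_ferm, k_cat_resp_pyr = k_cat_resp_pyr,
            k_cat_resp_etoh = k_cat_resp_etoh, k_cat_gng = k_cat_gng,
            k_cat_etoh_transport = k_cat_etoh_transport, K_M_etoh = K_M_etoh,
            y_atp_gly = y_atp_gly, y_atp_resp_pyr = y_atp_resp_pyr,
            y_atp_resp_etoh = y_atp_resp_etoh, e_atp_aa = e_atp_aa,
            e_atp_gng = e_atp_gng, c_pyr_aa = c_pyr_aa,
            atp_maintenance = atp_maintenance, k_trans = k_trans,
            act_min = act_min, K_act = K_act, hill_act = hill_act,
            phi_max = phi_max, phi_other = phi_other,
            chi_rna = chi_rna, rib_rna_aa = rib_rna_aa)
  validate_metabolic_params(p)
  structure(p, class = "metabolic_params")
}

validate_metabolic_params <- function(p) {
  kc <- c("k_cat_hxt", "k_cat_gly", "k_cat_ferm", "k_cat_resp_pyr",
          "k_cat_resp_etoh", "k_cat_gng", "k_cat_etoh_transport", "k_trans")
  for (nm in kc)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("metabolic parameter `", nm, "` must be > 0")
  if (p$phi_max <= 0 || p$phi_max > 1) stop("phi_max must lie in (0, 1]")
  if (p$phi_other < 0 || p$phi_other >= p$phi_max)
    stop("phi_other must satisfy 0 <= phi_other < phi_max")
  if (p$act_min <= 0 || p$act_min > 1) stop("act_min must lie in (0, 1]")
  invisible(TRUE)
}

#' @export
print.metabolic_params <- function(x, ...) {
  cat("Metabolic parameters (coarse-grained self-replicator)\n")
  cat(sprintf("  transport:   k_cat_hxt = %.3g (K_M = %.3g%%), k_cat_etoh = %.3g (K_M = %.3g%%)\n",
              x$k_cat_hxt, x$K_M_hxt, x$k_cat_etoh_transport, x$K_M_etoh))
  cat(sprintf("  pathways:    k_cat_gly = %.3g, k_cat_ferm = %.3g, k_cat_resp_pyr = %.3g, k_cat_resp_etoh = %.3g, k_cat_gng = %.3g\n",
              x$k_cat_gly, x$k_cat_ferm, x$k_cat_resp_pyr, x$k_cat_resp_etoh, x$k_cat_gng))
  cat(sprintf("  ATP yields:  %.3g/glc (glycolysis), %.3g/pyr (respiration), %.3g/EtOH\n",
              x$y_atp_gly, x$y_atp_resp_pyr, x$y_atp_resp_etoh))
  cat(sprintf("  costs:       %.3g ATP/aa + %.3g maintenance; gng +%.3g ATP/aa; %.3g pyr/aa\n",
              x$e_atp_aa, x$atp_maintenance, x$e_atp_gng, x$c_pyr_aa))
  cat(sprintf("  translation: k_trans = %.3g, activity floor %.3g, K_act = %.3g (Hill %g)\n",
              x$k_trans, x$act_min, x$K_act, x$hill_act))
  cat(sprintf("  budget:      phi_max = %.3g, phi_other = %.3g\n", x$phi_max, x$phi_other))
  invisible(x)
}

#' Apply a multiplicative overlay to named parameters
#'
#' Mutant scenarios are expressed as multiplicative factors on named
#' parameters of any of the package's parameter objects (a factor of exactly
#' 0 encodes a knockout). Unknown names are an error so that scenario files
#' cannot silently drift from the parameter schema.
#'
#' @param params A parameter object (a named list).
#' @param overlay Named numeric vector/list of multiplicative factors.
#' @return The modified parameter object (same class).
#' @examples
#' p <- metabolic_params()
#' apply_overlay(p, c(k_cat_hxt = 1/5))$k_cat_hxt
#' @export
apply_overlay <- function(params, overlay) {
  if (is.null(overlay) || length(overlay) == 0) return(params)
  overlay <- unlist(overlay)
  bad <- setdiff(names(overlay), names(params))
  if (length(bad))
    stop("overlay references unknown parameter(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(overlay) | overlay < 0))
    stop("overlay factors must be finite and >= 0")
  for (nm in names(overlay))
    params[[nm]] <- params[[nm]] * overlay[[nm]]
  params
}

#' Single-cell growth parameters
#'
#' The (K2, rho) pair is the interface imported from the allocation solver:
#' K2 is the protein synthesis rate per ribosome-equivalent (aa per RNA unit
#' per minute) and rho the target RNA/protein mass ratio. The remaining
#' rates shape the relaxation of the ribosome (RNA) pool and turnover.
#'
#' @param K2 Protein synthesis rate per RNA unit (1/min).
#' @param rho Target RNA/protein ratio (dimensionless).
#' @param delta_P Protein degradation rate (1/min).
#' @param delta_R RNA/ribosome degradation rate (1/min).
#' @param k_R Relaxation rate of the RNA pool toward its rho-implied target
#'   (1/min); fast by default, i.e. a quasi-equilibrated ribosome fraction.
#' @param rna_per_ribosome Conversion constant between RNA units and
#'   ribosome counts (bookkeeping only).
#' @return An object of class \code{"growth_params"}.
#' @export
growth_params <- function(K2 = 0.016976, rho = 0.38703,
                          delta_P = 0, delta_R = 0,
                          k_R = 4, rna_per_ribosome = 15500) {
  stopifnot(K2 > 0, rho > 0, delta_P >= 0, delta_R >= 0, k_R >= 0)
  structure(list(K2 = K2, rho = rho, delta_P = delta_P, delta_R = delta_R,
                 k_R = k_R, rna_per_ribosome = rna_per_ribosome),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth parameters: K2 = %.4g aa/RNA-unit/min, rho = %.4g RNA/protein\n",
              x$K2, x$rho))
  cat(sprintf("  delta_P = %.3g, delta_R = %.3g, k_R = %.3g 1/min\n",
              x$delta_P, x$delta_R, x$k_R))
  cat(sprintf("  implied balanced single-cell rate: %.4g 1/min\n",
              x$K2 * x$rho - x$delta_P))
  invisible(x)
}

#' Cell-cycle timer settings
#'
#' The unbudded G1 phase is the sequence T1a (fixed), T1b (threshold-gated:
#' it lasts until the Cln3/Far1 trigger fires) and T2 (fixed); the budded
#' phase is the timer T_B, of which the final T_G1star separates nuclear
#' from cell division. Newborn cells draw their fixed timers from lognormal
#' distributions with coefficient of variation \code{CV_timer}.
#'
#' @param T1a Fixed early-G1 timer (min).
#' @param T2 Timer between trigger firing and budding (min).
#' @param TB Budded-phase timer (min).
#' @param TG1star Terminal sub-period of TB separating nuclear and cell
#'   division (min); must not exceed \code{TB}.
#' @param CV_timer Coefficient of variation of newborn timer draws.
#' @param far1_ref Reference Cln3/Far1 size threshold (aa) at the reference
#'   interface (K2_ref, rho_ref).
#' @param theta_K2,theta_rho Scaling exponents of the threshold in the
#'   imported interface parameters: the nutritional modulation of critical
#'   size, coarse-grained as
#'   \code{far1_eff = far1_ref * (K2/K2_ref)^theta_K2 * (rho/rho_ref)^theta_rho}.
#' @param K2_ref,rho_ref Reference interface values (wild type, 2\% glucose).
#' @param CV_far1 Optional CV of a per-newborn lognormal draw of the
#'   threshold; default off.
#' @param gamma_T Timer-scaling exponent: timers are specified at the
#'   reference condition and stretch as \code{(lambda_ref/lambda)^gamma_T}
#'   with the condition's balanced growth rate, coupling the cycle timescale
#'   to the growth interface. \code{gamma_T = 1} (default) makes the cycle
#'   geometry — budding index, phase fractions — condition-invariant;
#'   \code{gamma_T = 0} freezes the timers in absolute minutes.
#' @param lambda_ref Reference growth rate (1/min) for the timer scaling.
#' @return An object of class \code{"timer_settings"}.
#' @export
timer_settings <- function(T1a = 6, T2 = 9, TB = 72, TG1star = 13,
                           CV_timer = 0.15,
                           far1_ref = 2.6e10,
                           theta_K2 = 1.538, theta_rho = -0.0287,
                           K2_ref = NA_real_, rho_ref = NA_real_,
                           CV_far1 = 0,
                           gamma_T = 1, lambda_ref = NA_real_) {
  stopifnot(T1a >= 0, T2 >= 0, TB >= 0, TG1star >= 0, TG1star <= TB,
            CV_timer >= 0, far1_ref > 0, CV_far1 >= 0, gamma_T >= 0)
  structure(list(T1a = T1a, T2 = T2, TB = TB, TG1star = TG1star,
                 CV_timer = CV_timer, far1_ref = far1_ref,
                 theta_K2 = theta_K2, theta_rho = theta_rho,
                 K2_ref = K2_ref, rho_ref = rho_ref, CV_far1 = CV_far1,
                 gamma_T = gamma_T, lambda_ref = lambda_ref),
            class = "timer_settings")
}

#' @export
print.timer_settings <- function(x, ...) {
  cat(sprintf("Timer settings: T1a = %g, T2 = %g, TB = %g (TG1* = %g) min; CV_timer = %g\n",
              x$T1a, x$T2, x$TB, x$TG1star, x$CV_timer))
  cat(sprintf("  Cln3/Far1 size threshold: far1_ref = %.3g aa, theta_K2 = %g, theta_rho = %g\n",
              x$far1_ref, x$theta_K2, x$theta_rho))
  invisible(x)
}

#' Read or write a parameter file
#'
#' Parameter files are YAML with one block per parameter object
#' (\code{metabolic}, \code{timers}, \code{population}, \code{g1s}); each
#' block holds name/value pairs understood by the corresponding constructor.
#'
#' @param path File path.
#' @return \code{read_params}: a named list of parameter objects.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$metabolic)) out$metabolic <- do.call(metabolic_params, raw$metabolic)
  if (!is.null(raw$timers)) out$timers <- do.call(timer_settings, raw$timers)
  if (!is.null(raw$population)) out$population <- do.call(population_config, raw$population)
  if (!is.null(raw$g1s)) out$g1s <- do.call(g1s_params, raw$g1s)
  out
}

#' @rdname read_params
#' @param params Named list of parameter objects (as from \code{read_params}).
#' @export
write_params <- function(params, path) {
  raw <- lapply(params, function(p) lapply(unclass(p), function(v) v))
  yaml::write_yaml(raw, path)
  invisible(path)
}
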