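#' Define a nutrient condition
#'
#' A nutrient condition is the external input to the metabolic allocation
#' solver: the identity and concentration of the carbon source, plus the
#' fermentative ratio \code{F} describing how glucose catabolism is split
#' between fermentation (ethanol excretion) and respiration. \code{F} can be
#' given directly, derived from an experimental ethanol/glucose yield
#' \code{Y_etoh} (see \code{\link{derive_F}}), or left \code{NA} so that the
#' wild-type saturating curve \code{F(c)} supplies it downstream.
#'
#' @param source Carbon source, \code{"glucose"} or \code{"ethanol"}.
#' @param concentration Concentration, \% w/v for glucose and \% v/v for
#'   ethanol. Must be >= 0.
#' @param F Fermentative ratio in \[0, 1\]. \code{F = 1} is full fermentation,
#'   \code{F = 0} full respiration. Forced to 0 for ethanol. At most one of
#'   \code{F} and \code{Y_etoh} may be supplied.
#' @param Y_etoh Optional ethanol mass produced per glucose mass consumed
#'   (g/g), from which \code{F} is derived.
#'
#' @return An object of class \code{"nutrient_condition"}.
#' @examples
#' nutrient_condition("glucose", 2, F = 0.9)
#' nutrient_condition("ethanol", 2)
#' @export
nutrient_condition <- function(source = c("glucose", "ethanol"),
                               concentration,
                               F = NA_real_,
                               Y_etoh = NA_real_) {
  source <- match.arg(source)
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            is.finite(concentration), concentration >= 0)
  if (!is.na(F) && !is.na(Y_etoh))
    stop("supply at most one of `F` and `Y_etoh`; the other is derived")
  if (source == "ethanol") {
    if (!is.na(F) && F != 0)
      stop("F must be 0 for ethanol-grown cells (got ", F, ")")
    F <- 0
  }
  if (!is.na(F) && (F < 0 || F > 1))
    stop("F must lie in [0, 1] (got ", F, ")")
  if (!is.na(Y_etoh) && Y_etoh < 0)
    stop("Y_etoh must be >= 0 (got ", Y_etoh, ")")
  structure(list(source = source,
                 concentration = concentration,
                 F = F,
                 Y_etoh = Y_etoh),
            class = "nutrient_condition")
}

#' @export
print.nutrient_condition <- function(x, ...) {
  cat("Nutrient condition: ", x$concentration, "% ", x$source, sep = "")
  if (!is.na(x$F)) cat(", F =", signif(x$F, 3))
  if (!is.na(x$Y_etoh)) cat(", Y_etoh =", signif(x$Y_etoh, 3), "g/g")
  cat("\n")
  invisible(x)
}

# Mass of 2 ethanol (2 x 46 g/mol) over one glucose (180 g/mol): the
# stoichiometric maximum ethanol/glucose yield, mapping to F = 1.
Y_ETOH_MAX <- 92 / 180

#' Derive the fermentative ratio from an ethanol/glucose yield
#'
#' The fermentative ratio is the fraction of catabolized glucose carbon
#' excreted as ethanol, normalized so that the stoichiometric maximum yield
#' (2 ethanol per glucose, mass ratio 92/180 g/g) maps to \code{F = 1}.
#' Ethanol-grown cells have \code{F = 0} by definition.
#'
#' @param condition A \code{\link{nutrient_condition}}.
#' @return The condition with \code{F} filled in.
#' @examples
#' derive_F(nutrient_condition("glucose", 2, Y_etoh = 0.35))$F
#' @export
derive_F <- function(condition) {
  stopifnot(inherits(condition, "nutrient_condition"))
  if (condition$source == "ethanol") {
    condition$F <- 0
    return(condition)
  }
  if (!is.na(condition$F)) return(condition)
  if (is.na(condition$Y_etoh))
    stop("cannot derive F: supply Y_etoh (or F) for glucose-grown cells")
  if (condition$Y_etoh > Y_ETOH_MAX + 1e-12)
    stop("Y_etoh = ", condition$Y_etoh,
         " exceeds the stoichiometric maximum 92/180 = ",
         signif(Y_ETOH_MAX, 6), " g/g")
  condition$F <- condition$Y_etoh / Y_ETOH_MAX
  condition
}

#' Fit the saturating fermentative-ratio curve F(glucose)
#'
#' Fits \deqn{F(c) = F_0 + (F_{max} - F_0) \, c / (K_F + c)} to measured
#' (glucose concentration, F) pairs by nonlinear least squares. \code{F_0} is
#' the respiratory floor at vanishing glucose, \code{F_max} the asymptotic
#' fermentative ratio, and \code{K_F} the half-saturation concentration. The
#' fitted curve is what supplies wild-type \code{F} values across a glucose
#' series when no measured yield is available.
#'
#' @param glucose Numeric vector of glucose concentrations (\% w/v).
#' @param F Numeric vector of fermentative ratios in \[0, 1\].
#' @return An object of class \code{"fermentation_curve"} with components
#'   \code{F_0}, \code{F_max}, \code{K_F}, \code{rss} and \code{data}.
#' @examples
#' cv <- fit_fermentation_curve(c(0.05, 0.1, 0.2, 0.5, 2, 5),
#'                              c(0.28, 0.42, 0.58, 0.75, 0.88, 0.92))
#' predict(cv, 1)
#' @export
fit_fermentation_curve <- function(glucose, F) {
  stopifnot(length(glucose) == length(F), length(glucose) >= 3,
            all(is.finite(glucose)), all(is.finite(F)),
            all(glucose >= 0), all(F >= -1e-9), all(F <= 1 + 1e-9))
  if (length(unique(glucose)) < 3)
    stop("need at least 3 distinct glucose concentrations to fit the curve")
  dat <- data.frame(c = glucose, F = F)
  if (diff(range(F)) < 1e-12) {
    # Constant data: flat curve, K_F unidentifiable (kept at the median c).
    out <- list(F_0 = F[1], F_max = F[1], K_F = stats::median(glucose[glucose > 0], na.rm = TRUE),
                rss = 0, data = dat, fit = NULL)
    if (!is.finite(out$K_F)) out$K_F <- 1
    class(out) <- "fermentation_curve"
    return(out)
  }
  start <- list(F0 = max(min(F), 0),
                Fmax = min(max(F), 1),
                KF = max(stats::median(glucose), 1e-3))
  fit <- minpack.lm::nlsLM(
    F ~ F0 + (Fmax - F0) * c / (KF + c),
    data = dat, start = start,
    lower = c(0, 0, 1e-8), upper = c(1, 1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  out <- list(F_0 = unname(cf["F0"]), F_max = unname(cf["Fmax"]),
              K_F = unname(cf["KF"]),
              rss = sum(stats::residuals(fit)^2),
              data = dat, fit = fit)
  if (out$F_0 > out$F_max) { # enforce the monotone orientation
    tmp <- out$F_0; out$F_0 <- out$F_max; out$F_max <- tmp
  }
  class(out) <- "fermentation_curve"
  out
}

#' @export
print.fermentation_curve <- function(x, ...) {
  cat("Saturating fermentative-ratio curve F(c) = F_0 + (F_max - F_0) c/(K_F + c)\n")
  cat(sprintf("  F_0 = %.4f, F_max = %.4f, K_F = %.4f %% glucose, RSS = %.3g\n",
              x$F_0, x$F_max, x$K_F, x$rss))
  invisible(x)
}

#' @export
coef.fermentation_curve <- function(object, ...) {
  c(F_0 = object$F_0, F_max = object$F_max, K_F = object$K_F)
}

#' Evaluate a fitted fermentative-ratio curve
#'
#' @param object A \code{"fermentation_curve"}.
#' @param newdata Glucose concentrations (\% w/v); a numeric vector.
#' @param ... Unused.
#' @return Fermentative ratios, clipped to \[0, 1\].
#' @export
predict.fermentation_curve <- function(object, newdata, ...) {
  c <- as.numeric(newdata)
  f <- object$F_0 + (object$F_max - object$F_0) * c / (object$K_F + c)
  pmin(pmax(f, 0), 1)
}

#' @export
plot.fermentation_curve <- function(x, ...) {
  cc <- seq(0, max(x$data$c) * 1.1, length.out = 200)
  plot(x$data$c, x$data$F, xlab = "glucose (% w/v)",
       ylab = "fermentative ratio F", ylim = c(0, 1), pch = 19, ...)
  graphics::lines(cc, predict(x, cc), col = "blue")
  invisible(x)
}

#' Shipped wild-type fermentative-ratio curve
#'
#' The calibrated wild-type curve used whenever a glucose condition carries
#' no measured F or yield. Its anchors reproduce the respiro-fermentative
#' physiology of a Crabtree-positive lab strain: a respiratory floor at
#' vanishing glucose, near-full fermentation at 2\% glucose and above, and
#' half-saturation well below 1\% glucose. The constants are a package
#' calibration, not a measured dataset.
#'
#' @return A \code{"fermentation_curve"}.
#' @export
wildtype_fermentation_curve <- function() {
  out <- list(F_0 = 0.02, F_max = 0.97, K_F = 0.35,
              rss = NA_real_,
              data = data.frame(c = numeric(0), F = numeric(0)),
              fit = NULL)
  class(out) <- "fermentation_curve"
  out
}

#' Resolve the fermentative ratio of a condition
#'
#' Fills \code{F} using, in order of precedence: a user-supplied \code{F}, a
#' supplied yield \code{Y_etoh} (via \code{\link{derive_F}}), or the
#' wild-type curve \code{F(c)}.
#'
#' @param condition A \code{\link{nutrient_condition}}.
#' @param curve A \code{"fermentation_curve"}; default the shipped wild-type
#'   calibration.
#' @return The condition with \code{F} set.
#' @export
resolve_F <- function(condition, curve = wildtype_fermentation_curve()) {
  stopifnot(inherits(condition, "nutrient_condition"))
  if (condition$source == "ethanol") { condition$F <- 0; return(condition) }
  if (!is.na(condition$F)) return(condition)
  if (!is.na(condition$Y_etoh)) return(derive_F(condition))
  condition$F <- predict(curve, condition$concentration)
  condition
}
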