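# Two-state thermal unfolding analysis of CD melts.
#
# Model: Yobs(T) = [(Yn + Mn*T) + (Yd + Md*T) * K(T)] / (1 + K(T))
# with K(T) = exp(-dG(T) / (R*T)) and dG(T) = dH * (1 - T/Tm)  (van't Hoff,
# dCp = 0), T in Kelvin. dS is derived as dH/Tm so that dG(Tm) = 0 exactly.

#' Gas constant in kcal mol^-1 K^-1
#'
#' Used throughout the thermodynamic computations; all internal
#' temperatures are Kelvin.
#' @export
R_GAS <- 1.987204e-3

#' Convert Celsius to Kelvin
#' @param t_c temperature in degrees Celsius
#' @return temperature in Kelvin
#' @export
celsius_to_kelvin <- function(t_c) t_c + 273.15

#' Convert Kelvin to Celsius
#' @param t_k temperature in Kelvin
#' @return temperature in degrees Celsius
#' @export
kelvin_to_celsius <- function(t_k) t_k - 273.15

#' Convert raw CD signal to mean residue ellipticity
#'
#' Normalises an observed circular dichroism signal in millidegrees by the
#' cuvette path length, molar protein concentration and number of residues,
#' giving mean residue ellipticity in deg cm^2 dmol^-1.
#'
#' @param signal_mdeg observed CD signal, millidegrees (vectorised)
#' @param concentration_M protein concentration, mol L^-1 (> 0)
#' @param n_residues number of residues in the construct (>= 1)
#' @param path_length_cm cuvette path length, cm (> 0)
#' @return mean residue ellipticity, deg cm^2 dmol^-1
#' @examples
#' mdeg_to_mre(100, 30e-6, 79, 0.1)
#' @export
mdeg_to_mre <- function(signal_mdeg, concentration_M, n_residues, path_length_cm) {
  if (!is.numeric(concentration_M) || length(concentration_M) != 1L ||
      !is.finite(concentration_M) || concentration_M <= 0)
    stop("`concentration_M` must be a single positive number", call. = FALSE)
  if (!is.numeric(n_residues) || length(n_residues) != 1L ||
      !is.finite(n_residues) || n_residues < 1)
    stop("`n_residues` must be a count >= 1", call. = FALSE)
  if (!is.numeric(path_length_cm) || length(path_length_cm) != 1L ||
      !is.finite(path_length_cm) || path_length_cm <= 0)
    stop("`path_length_cm` must be a single positive number", call. = FALSE)
  signal_mdeg / (10 * path_length_cm * concentration_M * n_residues)
}

#' Construct a melt curve object
#'
#' A temperature-indexed CD trace for one construct at one pH. Temperatures
#' are stored in degrees Celsius (the acquisition convention) and converted
#' to Kelvin only inside the thermodynamic computations.
#'
#' @param temperature_c temperatures, degrees Celsius, strictly increasing
#' @param signal CD signal at each temperature
#' @param unit signal unit, \code{"mdeg"} (millidegrees) or \code{"mre"}
#'   (mean residue ellipticity)
#' @param wavelength_nm monitoring wavelength, nm (default 208)
#' @param variant construct label
#' @param ph buffer pH
#' @return an object of class \code{melt_curve}
#' @export
melt_curve <- function(temperature_c, signal, unit = c("mdeg", "mre"),
                       wavelength_nm = 208, variant = NA_character_, ph = NA_real_) {
  unit <- match.arg(unit)
  if (length(temperature_c) != length(signal))
    stop("temperature and signal must have equal length", call. = FALSE)
  if (length(temperature_c) < 10)
    stop("a melt curve needs at least 10 points", call. = FALSE)
  if (any(!is.finite(temperature_c)) || any(!is.finite(signal)))
    stop("non-finite values in melt curve", call. = FALSE)
  if (is.unsorted(temperature_c, strictly = TRUE))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (any(temperature_c < -10) || any(temperature_c > 120))
    stop("temperatures outside the plausible [-10, 120] degC window", call. = FALSE)
  structure(
    list(temperature_c = as.numeric(temperature_c), signal = as.numeric(signal),
         unit = unit, wavelength_nm = wavelength_nm, variant = variant, ph = ph),
    class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s, pH %s: %d points, %.0f-%.0f degC, %s at %g nm\n",
              ifelse(is.na(x$variant), "?", x$variant),
              ifelse(is.na(x$ph), "?", format(x$ph)),
              length(x$temperature_c), min(x$temperature_c), max(x$temperature_c),
              x$unit, x$wavelength_nm))
  invisible(x)
}

#' Predicted CD signal of the two-state unfolding model
#'
#' Evaluates the two-state expression with linear pre- and post-transition
#' baselines at temperature(s) \code{T_k}: the native baseline is
#' \code{Yn + Mn*T}, the denatured baseline \code{Yd + Md*T}, and the two are
#' mixed by the unfolding equilibrium constant
#' \code{K(T) = exp(-dH*(1 - T/Tm) / (R*T))}.
#'
#' @param T_k temperature(s), Kelvin (> 0)
#' @param Yn,Mn intercept and slope of the native (pre-transition) baseline
#'   (signal units; slope per Kelvin)
#' @param Yd,Md intercept and slope of the denatured (post-transition) baseline
#' @param dH van't Hoff unfolding enthalpy, kcal mol^-1
#' @param Tm melting temperature, Kelvin
#' @return predicted signal, same length as \code{T_k}
#' @export
two_state_signal <- function(T_k, Yn, Mn, Yd, Md, dH, Tm) {
  if (any(T_k <= 0)) stop("temperatures must be positive Kelvin", call. = FALSE)
  dG <- dH * (1 - T_k / Tm)
  K <- exp(-dG / (R_GAS * T_k))
  ((Yn + Mn * T_k) + (Yd + Md * T_k) * K) / (1 + K)
}

#' Fit the two-state thermal unfolding model to a melt curve
#'
#' Least-squares estimation of the six parameters (Yn, Mn, Yd, Md, dH, Tm)
#' by Levenberg-Marquardt. Initialisation: Tm0 at the temperature of maximum
#' |dY/dT| (central differences); baselines from ordinary least squares on
#' the first and last 15\% of points; three restarts with dH0 of 15, 30 and
#' 60 kcal mol^-1, keeping the attempt with the lowest residual sum of
#' squares. dS is derived as dH/Tm.
#'
#' A fit is flagged \code{converged} only when the optimizer met its
#' tolerance and the fitted Tm lies inside the scanned temperature range.
#' The qualitative \code{cooperative} label is \code{"non-cooperative"} when
#' the fit did not converge, Tm falls outside the scan, fitted dH is below
#' 5 kcal mol^-1, or the transition amplitude at Tm is less than three times
#' the residual RMSE; otherwise \code{"cooperative"}.
#'
#' @param curve a \code{\link{melt_curve}} with >= 10 points spanning >= 30 degC
#' @return an object of class \code{two_state_fit}: a list with elements
#'   \code{Yn}, \code{Mn}, \code{Yd}, \code{Md} (baselines, per-Kelvin slopes),
#'   \code{dH} (kcal mol^-1), \code{Tm} (Kelvin), \code{Tm_c} (Celsius),
#'   \code{dS} (= dH/Tm, kcal mol^-1 K^-1), \code{Tm_se} (standard error of Tm
#'   in K, NA when unavailable), \code{rmse}, \code{converged} and
#'   \code{cooperative}
#' @export
fit_two_state <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  T_k <- celsius_to_kelvin(curve$temperature_c)
  y <- curve$signal
  if (diff(range(curve$temperature_c)) < 30)
    stop("melt must span at least 30 degC for a stable baseline fit", call. = FALSE)
  n <- length(y)

  # Tm seed: steepest point of the trace by central differences
  dy <- (y[3:n] - y[1:(n - 2)]) / (T_k[3:n] - T_k[1:(n - 2)])
  Tm0 <- T_k[which.max(abs(dy)) + 1L]
  # clamp away from the scan edges so baselines keep leverage
  Tm0 <- min(max(Tm0, T_k[3]), T_k[n - 2])

  # baseline seeds from the flanks
  k <- max(2L, ceiling(0.15 * n))
  bn <- stats::lsfit(T_k[1:k], y[1:k])$coefficients
  bd <- stats::lsfit(T_k[(n - k + 1):n], y[(n - k + 1):n])$coefficients

  best <- NULL
  best_ok <- FALSE
  for (dH0 in c(15, 30, 60)) {
    start <- list(Yn = unname(bn[1]), Mn = unname(bn[2]),
                  Yd = unname(bd[1]), Md = unname(bd[2]),
                  dH = dH0, Tm = Tm0)
    att <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_signal(T_k, Yn, Mn, Yd, Md, dH, Tm),
        start = start,
        lower = c(-Inf, -Inf, -Inf, -Inf, 0.1, min(T_k) - 50),
        upper = c(Inf, Inf, Inf, Inf, 500, max(T_k) + 50),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(att)) next
    rss <- sum(stats::residuals(att)^2)
    if (is.null(best) || rss < best$rss) {
      info <- att$convInfo
      best <- list(fit = att, rss = rss,
                   opt_ok = isTRUE(info$isConv) || info$stopCode %in% 1:3)
    }
  }

  if (is.null(best)) {
    # all restarts failed outright (e.g. an exactly linear trace makes the
    # Jacobian singular); report the best linear description instead
    bl <- stats::lsfit(T_k, y)
    res <- y - (bl$coefficients[1] + bl$coefficients[2] * T_k)
    out <- structure(
      list(Yn = unname(bl$coefficients[1]), Mn = unname(bl$coefficients[2]),
           Yd = unname(bl$coefficients[1]), Md = unname(bl$coefficients[2]),
           dH = 0, Tm = mean(T_k), Tm_c = kelvin_to_celsius(mean(T_k)),
           dS = 0, Tm_se = NA_real_,
           rmse = sqrt(mean(res^2)), converged = FALSE,
           cooperative = "non-cooperative",
           variant = curve$variant, ph = curve$ph),
      class = "two_state_fit")
    warning("two-state optimisation failed on all restarts; returning a linear description",
            call. = FALSE)
    return(out)
  }

  p <- as.list(stats::coef(best$fit))
  rmse <- sqrt(best$rss / n)
  tm_in_scan <- p$Tm >= min(T_k) && p$Tm <= max(T_k)
  converged <- best$opt_ok && tm_in_scan
  amp <- abs((p$Yd + p$Md * p$Tm) - (p$Yn + p$Mn * p$Tm))
  cooperative <- if (!converged || p$dH < 5 || amp < 3 * rmse)
    "non-cooperative" else "cooperative"
  tm_se <- tryCatch(sqrt(diag(stats::vcov(best$fit)))[["Tm"]],
                    error = function(e) NA_real_)

  structure(
    list(Yn = p$Yn, Mn = p$Mn, Yd = p$Yd, Md = p$Md,
         dH = p$dH, Tm = p$Tm, Tm_c = kelvin_to_celsius(p$Tm),
         dS = p$dH / p$Tm, Tm_se = tm_se,
         rmse = rmse, converged = converged, cooperative = cooperative,
         variant = curve$variant, ph = curve$ph),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> %s%s\n",
              ifelse(is.na(x$variant), "", paste0(x$variant, " ")),
              ifelse(is.na(x$ph), "", sprintf("(pH %s)", format(x$ph)))))
  cat(sprintf("  Tm = %.2f degC (%.2f K)%s, dH = %.2f kcal/mol, dS = %.4g kcal/mol/K\n",
              x$Tm_c, x$Tm,
              ifelse(is.na(x$Tm_se), "", sprintf(" +/- %.2f", x$Tm_se)),
              x$dH, x$dS))
  cat(sprintf("  rmse = %.4g, converged = %s, %s\n",
              x$rmse, x$converged, x$cooperative))
  invisible(x)
}

#' Unfolding free energy at a reference temperature
#'
#' \code{dG_u(T) = dH * (1 - T/Tm)} (equivalently \code{dH - T*dS} with
#' \code{dS = dH/Tm}). Zero exactly at \code{T_ref = Tm}; positive below Tm
#' for dH > 0 (the folded state is favoured).
#'
#' @param fit a \code{two_state_fit}
#' @param T_ref reference temperature, Kelvin (> 0); default 293.15 K (20 degC)
#' @return unfolding free energy, kcal mol^-1
#' @export
gibbs_free_energy <- function(fit, T_ref = 293.15) {
  stopifnot(inherits(fit, "two_state_fit"))
  if (!is.numeric(T_ref) || any(T_ref <= 0))
    stop("`T_ref` must be positive Kelvin", call. = FALSE)
  fit$dH * (1 - T_ref / fit$Tm)
}

#' Fraction of unfolded protein at a reference temperature
#'
#' \code{K/(1+K)} with \code{K = exp(-dG_u/(R*T_ref))}; exactly 0.5 at Tm.
#'
#' @inheritParams gibbs_free_energy
#' @return fraction in [0, 1]
#' @export
fraction_unfolded <- function(fit, T_ref = 293.15) {
  dG <- gibbs_free_energy(fit, T_ref)
  K <- exp(-dG / (R_GAS * T_ref))
  K / (1 + K)
}

#' Stability change upon mutation
#'
#' \code{ddG_u = dG_u(mutant) - dG_u(reference)} at a shared reference
#' temperature. Negative values mean the mutation destabilises the fold.
#'
#' @param fit_ref two-state fit of the reference construct
#' @param fit_mut two-state fit of the mutant
#' @param T_ref reference temperature, Kelvin
#' @param force compute even from non-converged fits (default FALSE)
#' @return ddG_u, kcal mol^-1
#' @export
delta_delta_G <- function(fit_ref, fit_mut, T_ref = 293.15, force = FALSE) {
  stopifnot(inherits(fit_ref, "two_state_fit"), inherits(fit_mut, "two_state_fit"))
  if (!force && (!isTRUE(fit_ref$converged) || !isTRUE(fit_mut$converged)))
    stop("both fits must be converged (use force = TRUE to override)", call. = FALSE)
  gibbs_free_energy(fit_mut, T_ref) - gibbs_free_energy(fit_ref, T_ref)
}
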