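# Fluorogenic protease inhibition metrics: AMC-release progress curves to
# initial rates, residual activity against an uninhibited control, dose
# series with an interpolated IC50, and E-64 active-site titration of the
# functional enzyme concentration.

#' Construct a progress-curve object
#'
#' Time course of released-fluorophore (AMC) fluorescence during substrate
#' turnover.
#'
#' @param time_s times, seconds, ascending, >= 0
#' @param fluorescence fluorescence, arbitrary units
#' @param inhibitor inhibitor name (optional)
#' @param concentration_uM inhibitor concentration, micromolar (optional)
#' @param enzyme enzyme name (optional)
#' @return an object of class \code{progress_curve}
#' @export
progress_curve <- function(time_s, fluorescence, inhibitor = NA_character_,
                           concentration_uM = NA_real_, enzyme = NA_character_) {
  if (length(time_s) != length(fluorescence))
    stop("time and fluorescence must have equal length", call. = FALSE)
  if (length(time_s) < 6)
    stop("a progress curve needs at least 6 points", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(fluorescence)))
    stop("non-finite values in progress curve", call. = FALSE)
  if (any(time_s < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(time_s = as.numeric(time_s),
                 fluorescence = as.numeric(fluorescence),
                 inhibitor = inhibitor, concentration_uM = concentration_uM,
                 enzyme = enzyme),
            class = "progress_curve")
}

#' Initial rate of a progress curve
#'
#' Ordinary least-squares slope over the early, linear part of the curve
#' (by default the first 25\% of points). Negative fitted slopes are clipped
#' to zero with a warning, since a release assay cannot run backwards.
#'
#' @param curve a \code{\link{progress_curve}}
#' @param window fraction of points (from the start) used for the fit,
#'   default 0.25; must cover at least 4 points
#' @return initial rate, AU s^-1
#' @export
initial_rate <- function(curve, window = 0.25) {
  stopifnot(inherits(curve, "progress_curve"))
  n <- length(curve$time_s)
  k <- max(ceiling(window * n), 0L)
  if (k < 4)
    stop("rate window covers fewer than 4 points; widen `window`", call. = FALSE)
  fit <- stats::lsfit(curve$time_s[1:k], curve$fluorescence[1:k])
  slope <- unname(fit$coefficients[2])
  if (slope < 0) {
    warning("negative initial rate clipped to 0", call. = FALSE)
    slope <- 0
  }
  slope
}

#' Residual activity relative to an uninhibited control
#'
#' @param rate_inhibited initial rate in the presence of inhibitor, AU s^-1
#' @param rate_control uninhibited initial rate, AU s^-1 (> 0)
#' @param concentration_uM inhibitor concentration attached to the result
#' @return an object of class \code{activity_result} with \code{rate},
#'   \code{residual_pct} (100 * rate_inhibited / rate_control),
#'   \code{reduction_pct} (= 100 - residual_pct) and \code{concentration_uM}
#' @export
residual_activity <- function(rate_inhibited, rate_control,
                              concentration_uM = NA_real_) {
  if (!is.numeric(rate_control) || length(rate_control) != 1L ||
      !is.finite(rate_control) || rate_control <= 0)
    stop("`rate_control` must be a single positive rate", call. = FALSE)
  if (!is.numeric(rate_inhibited) || length(rate_inhibited) != 1L ||
      !is.finite(rate_inhibited) || rate_inhibited < 0)
    stop("`rate_inhibited` must be a single non-negative rate", call. = FALSE)
  res <- 100 * rate_inhibited / rate_control
  structure(list(rate = rate_inhibited, residual_pct = res,
                 reduction_pct = 100 - res,
                 concentration_uM = concentration_uM),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("<activity_result> residual %.1f%% (reduction %.1f%%)%s\n",
              x$residual_pct, x$reduction_pct,
              ifelse(is.na(x$concentration_uM), "",
                     sprintf(" at %g uM", x$concentration_uM))))
  invisible(x)
}

#' Assemble an inhibitor dose series and interpolate IC50
#'
#' Sorts \code{activity_result}s by inhibitor concentration; duplicate
#' concentrations are averaged (with a message). IC50 is estimated by
#' linear interpolation of residual activity against log10(concentration)
#' across the 50\% crossing, and reported only when the series brackets 50\%.
#'
#' @param results list of \code{\link{residual_activity}} results, each with
#'   a concentration
#' @return a list with \code{table} (data.frame: concentration_uM,
#'   residual_pct, reduction_pct, sorted by concentration) and \code{ic50_uM}
#'   (NA when the series does not bracket 50\%)
#' @export
dose_series <- function(results) {
  if (!length(results)) stop("empty dose series", call. = FALSE)
  ok <- vapply(results, inherits, logical(1), what = "activity_result")
  if (!all(ok)) stop("all entries must be activity_result objects", call. = FALSE)
  tab <- data.frame(
    concentration_uM = vapply(results, `[[`, numeric(1), "concentration_uM"),
    residual_pct = vapply(results, `[[`, numeric(1), "residual_pct"))
  if (anyNA(tab$concentration_uM))
    stop("every result in a dose series needs a concentration", call. = FALSE)
  if (anyDuplicated(tab$concentration_uM)) {
    message("duplicate concentrations averaged")
    tab <- stats::aggregate(residual_pct ~ concentration_uM, tab, mean)
  }
  tab <- tab[order(tab$concentration_uM), , drop = FALSE]
  tab$reduction_pct <- 100 - tab$residual_pct
  rownames(tab) <- NULL

  ic50 <- NA_real_
  pos <- tab[tab$concentration_uM > 0, , drop = FALSE]
  if (nrow(pos) >= 2) {
    r <- pos$residual_pct
    cross <- which(diff(sign(r - 50)) != 0)
    if (length(cross)) {
      j <- cross[1]
      lx <- log10(pos$concentration_uM)
      # linear interpolation in log-concentration across the first crossing
      frac <- (50 - r[j]) / (r[j + 1] - r[j])
      ic50 <- 10^(lx[j] + frac * (lx[j + 1] - lx[j]))
    } else if (any(r == 50)) {
      ic50 <- pos$concentration_uM[which(r == 50)[1]]
    }
  }
  list(table = tab, ic50_uM = ic50)
}

#' E-64 active-site titration
#'
#' In the tight-binding titration regime the residual rate falls linearly
#' with irreversible-inhibitor concentration, and the x-intercept of the
#' rate vs [E-64] line equals the concentration of active enzyme.
#'
#' @param concentration_nM E-64 concentrations, nM (>= 3 values)
#' @param rate initial rates at each concentration, AU s^-1
#' @param r2_min minimum r-squared for the titration to be declared valid
#'   (default 0.95)
#' @return an object of class \code{titration_result} with
#'   \code{active_concentration_nM} (x-intercept), \code{slope},
#'   \code{r_squared} and \code{valid}
#' @export
e64_titration <- function(concentration_nM, rate, r2_min = 0.95) {
  if (length(concentration_nM) != length(rate))
    stop("concentration and rate must have equal length", call. = FALSE)
  if (length(rate) < 3)
    stop("titration needs at least 3 concentrations", call. = FALSE)
  o <- order(concentration_nM)
  x <- concentration_nM[o]; y <- rate[o]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("rates do not decrease with inhibitor: titration regime violated",
         call. = FALSE)
  # r^2 computed directly (summary.lm warns on an exactly collinear fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  x_int <- -unname(stats::coef(fit)[1]) / slope
  structure(list(active_concentration_nM = x_int, slope = slope,
                 r_squared = r2, valid = r2 >= r2_min),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration_result> active enzyme = %.2f nM (r2 = %.4f%s)\n",
              x$active_concentration_nM, x$r_squared,
              if (x$valid) "" else ", below validity threshold"))
  invisible(x)
}
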