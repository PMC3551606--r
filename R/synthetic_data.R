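# Deterministic synthetic-data generators. Each emulates the acquisition
# settings of the corresponding experiment (thermal melts 4-96 degC in
# 2 degC steps monitored at 208 nm; emission spectra 290-400 nm at 0.5 nm;
# linear early-phase AMC release) so that every analysis stage is testable
# with no instrument data. All noise is i.i.d. Gaussian with an explicit
# seed; identical arguments give bit-identical output.

with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed must be set explicitly", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a CD thermal melt
#'
#' Evaluates the two-state model on a temperature grid (default the
#' acquisition grid, 4-96 degC in 2 degC steps) and adds Gaussian noise
#' whose standard deviation is \code{noise_frac} times the absolute
#' transition amplitude at Tm (the gap between the two baselines there).
#' Baseline slopes are per Kelvin.
#'
#' @param dH van't Hoff enthalpy, kcal mol^-1
#' @param Tm_c melting temperature, degrees Celsius
#' @param Yn,Mn,Yd,Md baseline intercepts/slopes (signal units, per Kelvin);
#'   defaults give a helical-protein-like melt at 208 nm (native signal
#'   more negative than denatured, gently sloping baselines)
#' @param noise_frac noise sd as a fraction of the transition amplitude
#'   (default 0, noiseless)
#' @param seed RNG seed; required whenever \code{noise_frac > 0}
#' @param grid_c temperature grid, degC (default \code{seq(4, 96, 2)})
#' @param variant,ph metadata carried on the curve
#' @return a \code{\link{melt_curve}}
#' @export
gen_melt <- function(dH, Tm_c, Yn = -28, Mn = 0.02, Yd = -4, Md = 0.008,
                     noise_frac = 0, seed = NULL,
                     grid_c = seq(4, 96, by = 2),
                     variant = NA_character_, ph = NA_real_) {
  if (noise_frac < 0) stop("`noise_frac` must be >= 0", call. = FALSE)
  if (Tm_c < 0 || Tm_c > 120)
    warning("Tm outside the 0-120 degC sanity window; generating anyway",
            call. = FALSE)
  Tm <- celsius_to_kelvin(Tm_c)
  T_k <- celsius_to_kelvin(grid_c)
  y <- two_state_signal(T_k, Yn, Mn, Yd, Md, dH, Tm)
  if (noise_frac > 0) {
    amp <- abs((Yd + Md * Tm) - (Yn + Mn * Tm))
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = noise_frac * amp))
  }
  melt_curve(grid_c, y, unit = "mdeg", variant = variant, ph = ph)
}

#' Simulate a fluorescence emission spectrum
#'
#' A Gaussian emission band \code{F_max * exp(-(lambda - lambda_max)^2 /
#' (2 width^2))} on the acquisition grid (290-400 nm, 0.5 nm steps by
#' default) plus Gaussian noise.
#'
#' @param lambda_max peak centre, nm; must lie inside the grid
#' @param F_max peak intensity, arbitrary units
#' @param width_nm Gaussian width (sd), nm (default 25, a typical tryptophan
#'   emission bandwidth)
#' @param noise_sd noise sd, arbitrary units (default 0)
#' @param seed RNG seed; required whenever \code{noise_sd > 0}
#' @param grid_nm wavelength grid (default \code{seq(290, 400, 0.5)})
#' @param variant,ph metadata carried on the spectrum
#' @return an \code{\link{emission_spectrum}}
#' @export
gen_emission <- function(lambda_max, F_max, width_nm = 25, noise_sd = 0,
                         seed = NULL, grid_nm = seq(290, 400, by = 0.5),
                         variant = NA_character_, ph = NA_real_) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (lambda_max < min(grid_nm) || lambda_max > max(grid_nm))
    stop("`lambda_max` lies outside the wavelength grid", call. = FALSE)
  y <- F_max * exp(-(grid_nm - lambda_max)^2 / (2 * width_nm^2))
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  emission_spectrum(grid_nm, y, variant = variant, ph = ph)
}

#' Simulate an AMC-release progress curve
#'
#' Linear early-phase substrate turnover: fluorescence = rate * t (+ noise).
#'
#' @param rate true initial rate, AU s^-1 (>= 0)
#' @param duration_s assay duration, s (> 0; default 300)
#' @param n_points number of time points (default 60)
#' @param noise_sd noise sd, AU (default 0)
#' @param seed RNG seed; required whenever \code{noise_sd > 0}
#' @param baseline fluorescence offset at t = 0 (default 0)
#' @return a \code{\link{progress_curve}}
#' @export
gen_progress <- function(rate, duration_s = 300, n_points = 60, noise_sd = 0,
                         seed = NULL, baseline = 0) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  t <- seq(0, duration_s, length.out = n_points)
  y <- baseline + rate * t
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  progress_curve(t, y)
}

#' Simulate a paired control/inhibited progress-curve experiment
#'
#' The inhibited curve's true rate is \code{residual_frac} times the
#' control rate, so the full assay pipeline (rates then normalisation)
#' should recover \code{100 * residual_frac} percent residual activity.
#'
#' @param control_rate uninhibited rate, AU s^-1
#' @param residual_frac true residual activity as a fraction in [0, 1]
#' @param concentration_uM inhibitor concentration recorded on the
#'   inhibited curve
#' @param seed RNG seed; required whenever \code{noise_sd > 0} (the two
#'   curves use seed and seed + 1)
#' @inheritParams gen_progress
#' @return list with \code{control} and \code{inhibited} progress curves
#' @export
gen_progress_pair <- function(control_rate, residual_frac,
                              concentration_uM = NA_real_, duration_s = 300,
                              n_points = 60, noise_sd = 0, seed = NULL) {
  if (residual_frac < 0 || residual_frac > 1)
    stop("`residual_frac` must be in [0, 1]", call. = FALSE)
  ctrl <- gen_progress(control_rate, duration_s, n_points, noise_sd, seed)
  inh <- gen_progress(control_rate * residual_frac, duration_s, n_points,
                      noise_sd, if (is.null(seed)) NULL else seed + 1L)
  inh$concentration_uM <- concentration_uM
  list(control = ctrl, inhibited = inh)
}

#' Simulate random protein sequences, optionally planting a motif match
#'
#' Residues are drawn uniformly from the 20 standard amino acids. When a
#' motif is planted, one exact match (constrained slots drawn from their
#' allowed sets, gaps random) is written into each sequence at a random
#' position, which is recorded.
#'
#' @param n number of sequences
#' @param length sequence length (>= motif span when planting)
#' @param planted_motif a \code{\link{motif_pattern}}, or NULL for pure
#'   random sequences
#' @param seed RNG seed (required)
#' @return data.frame with columns \code{id}, \code{sequence}, and
#'   \code{planted_at} (NA when nothing was planted)
#' @export
gen_sequences <- function(n, length, planted_motif = NULL, seed = NULL) {
  if (!is.null(planted_motif)) {
    stopifnot(inherits(planted_motif, "motif_pattern"))
    if (length < planted_motif$span)
      stop("sequence length shorter than the motif span", call. = FALSE)
  }
  with_seed(seed, {
    ids <- sprintf("seq%0*d", max(1L, nchar(as.character(max(n, 1)))), seq_len(n))
    seqs <- character(n)
    planted <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      res <- sample(AA20, length, replace = TRUE)
      if (!is.null(planted_motif)) {
        instance <- unlist(lapply(planted_motif$elements, function(e) {
          if (is.character(e)) sample(e, 1) else sample(AA20, e, replace = TRUE)
        }))
        at <- sample.int(length - planted_motif$span + 1L, 1L)
        res[at:(at + planted_motif$span - 1L)] <- instance
        planted[i] <- at
      }
      seqs[i] <- paste(res, collapse = "")
    }
    data.frame(id = ids, sequence = seqs, planted_at = planted,
               stringsAsFactors = FALSE)
  })
}
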