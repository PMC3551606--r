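# Independent oracles used across the suite. These deliberately avoid the
# package's fitting path.

# Brute-force two-state fit: exhaustive grid over (dH, Tm); for each pair
# the model is linear in the four baseline parameters, which are solved by
# ordinary least squares. Returns the best RMSE found.
grid_two_state_rmse <- function(temperature_c, signal,
                                dH_grid = seq(5, 150, by = 2.5),
                                Tm_step_k = 0.25) {
  R <- 1.987204e-3
  T_k <- temperature_c + 273.15
  Tm_grid <- seq(min(T_k), max(T_k), by = Tm_step_k)
  best <- Inf
  for (dH in dH_grid) {
    for (Tm in Tm_grid) {
      K <- exp(-dH * (1 - T_k / Tm) / (R * T_k))
      fn <- 1 / (1 + K)
      fd <- K / (1 + K)
      X <- cbind(fn, T_k * fn, fd, T_k * fd)
      rss <- sum(stats::lsfit(X, signal, intercept = FALSE)$residuals^2)
      if (rss < best) best <- rss
    }
  }
  sqrt(best / length(signal))
}

# Position-by-position motif checker: slides a window over the sequence and
# tests each slot against its allowed set (wildcard gaps accept the 20
# standard residues, never 'X').
brute_force_scan <- function(pattern, sequence) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(toupper(sequence), "")[[1]]
  span <- pattern$span
  hits <- integer(0)
  if (length(chars) >= span) {
    for (s in 1:(length(chars) - span + 1L)) {
      at <- s
      ok <- TRUE
      for (e in pattern$elements) {
        if (is.character(e)) {
          if (!(chars[at] %in% e)) { ok <- FALSE; break }
          at <- at + 1L
        } else {
          if (e > 0 && !all(chars[at:(at + e - 1L)] %in% aa20)) { ok <- FALSE; break }
          at <- at + e
        }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}
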