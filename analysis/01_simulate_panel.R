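#!/usr/bin/env Rscript
# Build the synthetic alanine-scanning panel.
#
# The study's raw spectra are not deposited, so the panel is emulated: for
# every construct the published ground truths (melting temperature at pH 6,
# emission maxima at pH 4/6, residual protease activity at 3 uM) are used as
# generator parameters, mild instrument-like noise is added, and the traces
# are written to scratch/panel_data/ in the two-column format the pipeline
# reads. A truth table goes to results/panel_truth.tsv so the downstream
# scripts can measure recovery.
#
# The double-mutant cycle C72S / D6A / R29A is included; the triple mutant's
# melting temperature is a synthetic stand-in (no published value exists for
# it in the main tables) and is labelled as such.

library(foldshift)

data_dir <- "scratch/panel_data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

# construct, qualitative folding-transition call, Tm (degC, pH 6),
# lambda_max pH 4 / pH 6 (nm), residual activity (%) of the single mutant
panel <- read.table(header = TRUE, text = "
name            note Tm_c  lam4  lam6 residual
C72S            O    58.0 336.5 326.5 14.7
C72S/W9A        X    30.0 341.5 337.5 87.8
C72S/Y12A       X    33.0 338.5 335.0 63.0
C72S/F16A       P    42.6 345.5 340.0 34.6
C72S/Y20A       X    33.9 341.0 338.5 47.8
C72S/Y32A       X    30.0 342.0 338.0 67.6
C72S/F46A       O    52.5 337.5 326.5 41.0
C72S/W53A       O    53.9 335.5 325.5 85.2
C72S/D6A        O    48.3 339.0 329.5 21.1
C72S/R29A       X    42.9 337.0 333.0 64.0
C72S/D6A/R29A   X    38.0 338.0 334.0 70.0
", stringsAsFactors = FALSE)
# the last row's values are synthetic stand-ins for the cycle demonstration

dH_vanthoff <- 40      # kcal/mol, one realistic van't Hoff enthalpy panel-wide
noise_frac <- 0.01     # melt noise, fraction of transition amplitude
emission_noise <- 10   # AU, ~1% of a typical F_max

stem <- function(name) gsub("/", "-", name, fixed = TRUE)

for (i in seq_len(nrow(panel))) {
  v <- panel[i, ]
  s <- stem(v$name)
  m <- gen_melt(dH = dH_vanthoff, Tm_c = v$Tm_c, noise_frac = noise_frac,
                seed = 100 + i, variant = v$name, ph = 6)
  write_trace(list(x = m$temperature_c, y = m$signal,
                   x_unit = "degC", y_unit = "mdeg"),
              file.path(data_dir, paste0(s, "_melt_pH6.csv")))
  e4 <- gen_emission(v$lam4, 1300, noise_sd = emission_noise, seed = 200 + i)
  e6 <- gen_emission(v$lam6, 1500, noise_sd = emission_noise, seed = 300 + i)
  write_trace(list(x = e4$wavelength_nm, y = e4$intensity,
                   x_unit = "nm", y_unit = "AU"),
              file.path(data_dir, paste0(s, "_emission_pH4.csv")))
  write_trace(list(x = e6$wavelength_nm, y = e6$intensity,
                   x_unit = "nm", y_unit = "AU"),
              file.path(data_dir, paste0(s, "_emission_pH6.csv")))
  pair <- gen_progress_pair(control_rate = 10, residual_frac = v$residual / 100,
                            noise_sd = 3, seed = 400 + i)
  write_trace(list(x = pair$control$time_s, y = pair$control$fluorescence,
                   x_unit = "s", y_unit = "AU"),
              file.path(data_dir, paste0(s, "_progress_control.csv")))
  write_trace(list(x = pair$inhibited$time_s, y = pair$inhibited$fluorescence,
                   x_unit = "s", y_unit = "AU"),
              file.path(data_dir, paste0(s, "_progress_inhibited.csv")))
}

# manifest: the D6-R29 cycle members share a cycle_id, listed in the order
# background, single mutant, single mutant, double mutant
manifest <- data.frame(
  name = panel$name,
  background = c("", rep("C72S", nrow(panel) - 1L)),
  cycle_id = ifelse(panel$name %in%
                      c("C72S", "C72S/D6A", "C72S/R29A", "C72S/D6A/R29A"),
                    "D6-R29", ""),
  note = panel$note)
write.table(manifest, file.path(data_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write.table(panel, "results/panel_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("simulated", nrow(panel), "constructs into", data_dir, "\n")
cat("truth table: results/panel_truth.tsv\n")
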