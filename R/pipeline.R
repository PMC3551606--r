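# End-to-end orchestration over a variant manifest: for each construct,
# whatever subset of {melt (pH 6), emission (pH 4 and 6), progress curves}
# exists in the data directory is analysed; missing stages give NA columns,
# and per-variant failures are recorded without aborting the run.
#
# Data directory layout (all plain two-column CSV/TSV):
#   <name>_melt_pH<ph>.csv          CD melt (temperature degC, signal mdeg)
#   <name>_emission_pH<ph>.csv      emission spectrum (nm, AU)
#   <name>_progress_control.csv     uninhibited AMC progress curve (s, AU)
#   <name>_progress_inhibited.csv   inhibited progress curve (s, AU)
# Construct names containing '/' map to file stems with '-' (C72S/W9A ->
# C72S-W9A).

variant_stem <- function(name) gsub("/", "-", name, fixed = TRUE)

panel_path <- function(dir, name, what) {
  stem <- file.path(dir, paste0(variant_stem(name), "_", what))
  for (ext in c(".csv", ".tsv")) {
    p <- paste0(stem, ext)
    if (file.exists(p)) return(p)
  }
  NA_character_
}

#' Run the full analysis panel over a variant manifest
#'
#' For every construct in the manifest, fits the pH 6 thermal melt,
#' extracts the emission maxima at both pH values and their blue shift
#' (MEWD), and computes residual protease activity from the paired
#' progress curves; stages whose input files are absent yield NA columns.
#' Cycles declared via the manifest's \code{cycle_id} column (four
#' constructs sharing an id) are evaluated as double-mutant cycles.
#'
#' @param manifest path to a manifest TSV (see \code{\link{read_manifest}})
#'   or an already-read manifest data.frame
#' @param data_dir directory holding the per-variant trace files (layout
#'   above)
#' @param t_ref_c reference temperature for free energies, degC (default 20)
#' @param ph_melt pH label of the melt data (default 6)
#' @param reference construct whose dG_u anchors ddG_u (default the first
#'   manifest entry)
#' @param inhibitor_concentration_uM concentration label attached to
#'   residual activities (default 3)
#' @param peak_method emission-peak refinement passed to
#'   \code{\link{find_peak}}: \code{"parabolic"} (default, exact on clean or
#'   replicate-averaged spectra) or \code{"gauss"} (whole-band fit, use for
#'   noisy single scans)
#' @return list with \code{summary} (one row per variant, schema of
#'   \code{\link{write_results_table}} plus \code{dG_u_kcal_mol},
#'   \code{f_unfolded}, \code{ddG_u_kcal_mol}), \code{cycles} (data.frame of
#'   cycle results), \code{fits} (named list of \code{two_state_fit}s) and
#'   \code{failures} (per-variant error messages)
#' @export
run_panel <- function(manifest, data_dir, t_ref_c = 20, ph_melt = 6,
                      reference = NULL, inhibitor_concentration_uM = 3,
                      peak_method = c("parabolic", "gauss")) {
  peak_method <- match.arg(peak_method)
  man <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (!is.data.frame(man) || !"name" %in% names(man))
    stop("malformed manifest: need a data.frame with a 'name' column",
         call. = FALSE)
  T_ref <- celsius_to_kelvin(t_ref_c)
  fits <- list()
  failures <- list()
  rows <- vector("list", nrow(man))

  note_fail <- function(name, stage, e) {
    failures[[length(failures) + 1]] <<- sprintf("%s/%s: %s", name, stage,
                                                 conditionMessage(e))
    NULL
  }

  for (i in seq_len(nrow(man))) {
    nm <- man$name[i]
    row <- list(variant = nm,
                pH4_helicity_note = if (nzchar(man$note[i])) man$note[i] else NA,
                Tm_C = NA_real_, Tm_err = NA_real_,
                lambda_max_pH4 = NA_real_, F_max_pH4 = NA_real_,
                lambda_max_pH6 = NA_real_, F_max_pH6 = NA_real_,
                MEWD_nm = NA_real_, residual_activity_pct = NA_real_,
                dG_u_kcal_mol = NA_real_, f_unfolded = NA_real_,
                ddG_u_kcal_mol = NA_real_)

    p <- panel_path(data_dir, nm, sprintf("melt_pH%g", ph_melt))
    if (!is.na(p)) {
      fit <- tryCatch({
        tr <- read_trace(p, "melt", variant = nm, ph = ph_melt)
        fit_two_state(as_domain(tr))
      }, error = function(e) note_fail(nm, "melt", e))
      if (!is.null(fit)) {
        fits[[nm]] <- fit
        row$Tm_C <- fit$Tm_c
        row$Tm_err <- fit$Tm_se
        row$dG_u_kcal_mol <- gibbs_free_energy(fit, T_ref)
        row$f_unfolded <- fraction_unfolded(fit, T_ref)
      }
    }

    peaks <- list()
    for (ph in c(4, 6)) {
      p <- panel_path(data_dir, nm, sprintf("emission_pH%g", ph))
      if (is.na(p)) next
      pk <- tryCatch({
        tr <- read_trace(p, "emission", variant = nm, ph = ph)
        find_peak(as_domain(tr), method = peak_method)
      }, error = function(e) note_fail(nm, sprintf("emission_pH%g", ph), e))
      if (!is.null(pk)) peaks[[as.character(ph)]] <- pk
    }
    if (!is.null(peaks[["4"]])) {
      row$lambda_max_pH4 <- peaks[["4"]]$lambda_max
      row$F_max_pH4 <- peaks[["4"]]$F_max
    }
    if (!is.null(peaks[["6"]])) {
      row$lambda_max_pH6 <- peaks[["6"]]$lambda_max
      row$F_max_pH6 <- peaks[["6"]]$F_max
    }
    if (!is.null(peaks[["4"]]) && !is.null(peaks[["6"]]))
      row$MEWD_nm <- peaks[["4"]]$lambda_max - peaks[["6"]]$lambda_max

    pc <- panel_path(data_dir, nm, "progress_control")
    pi_ <- panel_path(data_dir, nm, "progress_inhibited")
    if (!is.na(pc) && !is.na(pi_)) {
      act <- tryCatch({
        r_ctrl <- initial_rate(as_domain(read_trace(pc, "progress")))
        r_inh <- initial_rate(as_domain(read_trace(pi_, "progress")))
        residual_activity(r_inh, r_ctrl, inhibitor_concentration_uM)
      }, error = function(e) note_fail(nm, "inhibition", e))
      if (!is.null(act)) row$residual_activity_pct <- act$residual_pct
    }

    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }

  summary <- if (nrow(man)) do.call(rbind, rows) else
    data.frame(variant = character(0))

  # ddG_u against the reference construct
  ref <- if (is.null(reference)) man$name[1] else reference
  if (!is.null(ref) && !is.na(ref) && !is.null(fits[[ref]])) {
    g_ref <- gibbs_free_energy(fits[[ref]], T_ref)
    summary$ddG_u_kcal_mol <- summary$dG_u_kcal_mol - g_ref
  }

  # double-mutant cycles: four manifest rows sharing a cycle_id, in the
  # order background, single mutant 1, single mutant 2, double mutant
  cyc_rows <- list()
  if (nrow(man)) {
    ids <- setdiff(unique(man$cycle_id), "")
    for (cid in ids) {
      members <- man$name[man$cycle_id == cid]
      res <- tryCatch({
        if (length(members) != 4)
          stop("cycle '", cid, "' has ", length(members),
               " members; need exactly 4", call. = FALSE)
        spec <- cycle_spec(cid, members[1], members[2], members[3], members[4])
        run_cycle(spec, fits, T_ref)
      }, error = function(e) note_fail(cid, "cycle", e))
      if (!is.null(res))
        cyc_rows[[cid]] <- data.frame(
          cycle_id = cid, ddG_int_kcal_mol = unname(res$ddG_int),
          T_ref_K = T_ref,
          dG_wt = unname(res$components["wt"]),
          dG_m1 = unname(res$components["m1"]),
          dG_m2 = unname(res$components["m2"]),
          dG_dm = unname(res$components["dm"]),
          stringsAsFactors = FALSE)
    }
  }
  cycles <- if (length(cyc_rows)) do.call(rbind, c(cyc_rows, make.row.names = FALSE))
    else data.frame(cycle_id = character(0), ddG_int_kcal_mol = numeric(0))

  list(summary = summary, cycles = cycles, fits = fits,
       failures = unlist(failures))
}
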