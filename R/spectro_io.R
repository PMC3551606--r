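# I/O for the plain-text formats the pipeline touches: two-column
# instrument traces (CSV or TSV), FASTA sequence files, the variant
# manifest, and the per-variant results table.

trace_units <- list(
  melt     = c(x = "degC", y = "mdeg"),
  emission = c(x = "nm",   y = "AU"),
  progress = c(x = "s",    y = "AU"))

#' Read a two-column instrument trace
#'
#' Parses a comma- or tab-separated two-column numeric table (optional
#' single header line; comment lines start with \code{#}), sorts rows by the
#' x axis, and returns a validated trace with units inferred from
#' \code{kind}: \code{melt} is temperature (degC) vs CD signal (mdeg),
#' \code{emission} is wavelength (nm) vs intensity (AU), \code{progress} is
#' time (s) vs fluorescence (AU).
#'
#' @param path file path
#' @param kind one of \code{"melt"}, \code{"emission"}, \code{"progress"}
#' @param variant,ph,replicate optional metadata carried on the trace
#' @return an object of class \code{raw_trace}: \code{x}, \code{y},
#'   \code{x_unit}, \code{y_unit}, \code{kind} plus the metadata
#' @export
read_trace <- function(path, kind = c("melt", "emission", "progress"),
                       variant = NA_character_, ph = NA_real_, replicate = 1L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)

  # delimiter sniffing: tab wins if present, else comma
  delim <- if (any(grepl("\t", lines))) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad))
    stop("row ", bad[1], " of ", path, " does not have two fields", call. = FALSE)

  parse_row <- function(f) suppressWarnings(as.numeric(trimws(f[1:2])))
  first <- parse_row(fields[[1]])
  has_header <- anyNA(first)
  if (has_header) fields <- fields[-1]
  if (length(fields) < 5)
    stop("trace in ", path, " has fewer than 5 data rows", call. = FALSE)
  vals <- vapply(fields, parse_row, numeric(2))
  if (anyNA(vals)) {
    row <- which(apply(is.na(vals), 2, any))[1] + has_header
    stop("non-numeric cell at data row ", row, " of ", path, call. = FALSE)
  }
  x <- vals[1, ]; y <- vals[2, ]
  if (anyDuplicated(x))
    stop("duplicate x values in ", path, call. = FALSE)
  o <- order(x)
  u <- trace_units[[kind]]
  structure(list(x = x[o], y = y[o], x_unit = unname(u["x"]),
                 y_unit = unname(u["y"]), kind = kind,
                 variant = variant, ph = ph, replicate = replicate),
            class = "raw_trace")
}

#' Write a two-column trace
#'
#' Writes a \code{raw_trace} (or plain x/y vectors) as a comma-separated
#' two-column file with a header naming the units, re-readable by
#' \code{\link{read_trace}} losslessly (to 1e-9; full double precision is
#' written).
#'
#' @param trace a \code{raw_trace}, or a list with \code{x} and \code{y}
#' @param path output path
#' @return invisibly, the path
#' @export
write_trace <- function(trace, path) {
  x <- trace$x; y <- trace$y
  hdr <- sprintf("%s,%s",
                 if (!is.null(trace$x_unit)) trace$x_unit else "x",
                 if (!is.null(trace$y_unit)) trace$y_unit else "y")
  body <- sprintf("%s,%s", formatC(x, digits = 17, format = "g"),
                  formatC(y, digits = 17, format = "g"))
  ok <- tryCatch({ writeLines(c(hdr, body), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write trace to ", path, call. = FALSE)
  invisible(path)
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d points, x %g-%g %s, y in %s\n",
              x$kind, length(x$x), min(x$x), max(x$x), x$x_unit, x$y_unit))
  invisible(x)
}

#' Coerce a raw trace into its analysis container
#'
#' \code{melt} traces become \code{\link{melt_curve}}s, \code{emission}
#' traces \code{\link{emission_spectrum}}s, \code{progress} traces
#' \code{\link{progress_curve}}s.
#'
#' @param trace a \code{raw_trace}
#' @return the matching domain object
#' @export
as_domain <- function(trace) {
  stopifnot(inherits(trace, "raw_trace"))
  switch(trace$kind,
    melt = melt_curve(trace$x, trace$y, unit = "mdeg",
                      variant = trace$variant, ph = trace$ph),
    emission = emission_spectrum(trace$x, trace$y,
                                 variant = trace$variant, ph = trace$ph),
    progress = progress_curve(trace$x, trace$y))
}

#' Read a FASTA file of amino-acid sequences
#'
#' Reads standard FASTA via \pkg{Biostrings}; record ids are the header
#' token up to the first whitespace and sequences are upper-cased. Gap
#' (\code{-}) and stop (\code{*}) characters are preserved on read and
#' flagged per record (the motif scanner degaps as needed); any other
#' character outside A-Z is rejected.
#'
#' @param path FASTA file path
#' @return data.frame with columns \code{id}, \code{sequence},
#'   \code{has_gaps}
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # pre-scan: Biostrings silently drops invalid letters, but an illegal
  # character should be a validation error naming the record
  lines <- readLines(path, warn = FALSE)
  current <- "<no header>"
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      current <- sub("\\s.*$", "", substring(ln, 2))
    } else if (grepl("[^A-Za-z*[:space:]-]", ln)) {
      stop("illegal character in FASTA record '", current, "'", call. = FALSE)
    }
  }
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  data.frame(id = ids, sequence = unname(seqs),
             has_gaps = grepl("[-*]", seqs), stringsAsFactors = FALSE)
}

#' Write FASTA records
#'
#' @param records data.frame with \code{id} and \code{sequence} columns, or
#'   a named character vector
#' @param path output path
#' @param width line-wrap width (default 60)
#' @return invisibly, the path
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    sq <- records$sequence[i]
    chunks <- substring(sq, seq(1, nchar(sq), width),
                        pmin(seq(1, nchar(sq), width) + width - 1, nchar(sq)))
    lines <- c(lines, paste0(">", records$id[i]), chunks)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a construct name into its mutation list
#'
#' Construct names use the slash convention (\code{"C72S/W9A"}); each token
#' is wild-type residue, 1-based position, substituted residue.
#'
#' @param name construct label; \code{"WT"} (any case) means no mutations
#' @param background optional background construct label
#' @return an object of class \code{variant_record}: \code{name},
#'   \code{background}, and \code{mutations} (data.frame: \code{wt},
#'   \code{pos}, \code{mut})
#' @export
variant_record <- function(name, background = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("construct name must be a non-empty string", call. = FALSE)
  muts <- data.frame(wt = character(0), pos = integer(0), mut = character(0),
                     stringsAsFactors = FALSE)
  if (toupper(name) != "WT") {
    tokens <- strsplit(name, "/", fixed = TRUE)[[1]]
    ok <- grepl("^[A-Za-z]\\d+[A-Za-z]$", tokens)
    if (!all(ok))
      stop("malformed mutation token '", tokens[which(!ok)[1]], "' in ", name,
           call. = FALSE)
    muts <- data.frame(
      wt = toupper(sub("^([A-Za-z]).*$", "\\1", tokens)),
      pos = as.integer(sub("^[A-Za-z](\\d+)[A-Za-z]$", "\\1", tokens)),
      mut = toupper(sub("^.*([A-Za-z])$", "\\1", tokens)),
      stringsAsFactors = FALSE)
    if (any(muts$pos < 1)) stop("positions must be >= 1", call. = FALSE)
    if (anyDuplicated(muts$pos))
      stop("duplicate mutated position in ", name, call. = FALSE)
  }
  structure(list(name = name, background = background, mutations = muts),
            class = "variant_record")
}

#' Read a variant manifest
#'
#' Tab-separated table of the constructs in a panel. Required column:
#' \code{name}. Optional: \code{background}, \code{cycle_id}, \code{note}
#' (a user-supplied qualitative label, e.g. a folding-transition call,
#' carried verbatim into the results table).
#'
#' @param path manifest TSV path
#' @return data.frame with one row per construct and a
#'   \code{variant_record} list-column \code{record}
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"name" %in% names(tab))
    stop("manifest must have a 'name' column", call. = FALSE)
  for (col in c("background", "cycle_id", "note"))
    if (!col %in% names(tab)) tab[[col]] <- character(nrow(tab))
  tab[is.na(tab)] <- ""
  # construct names following the slash convention get a parsed mutation
  # record; arbitrary labels are allowed through with record = NULL
  tab$record <- lapply(seq_len(nrow(tab)), function(i)
    tryCatch(variant_record(tab$name[i], tab$background[i]),
             error = function(e) NULL))
  tab
}

results_columns <- c("variant", "pH4_helicity_note", "Tm_C", "Tm_err",
                     "lambda_max_pH4", "F_max_pH4", "lambda_max_pH6",
                     "F_max_pH6", "MEWD_nm", "residual_activity_pct")

#' Write the per-variant results table
#'
#' Tab-separated file, one header line, fixed column order (variant,
#' pH4_helicity_note, Tm_C, Tm_err, lambda_max_pH4, F_max_pH4,
#' lambda_max_pH6, F_max_pH6, MEWD_nm, residual_activity_pct); missing
#' values are written as \code{NA}.
#'
#' @param rows data.frame of per-variant summaries (missing columns are
#'   filled with NA); may have zero rows
#' @param path output path
#' @return invisibly, the path
#' @export
write_results_table <- function(rows, path) {
  if (is.null(rows) || !nrow(rows)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(results_columns)),
                                  results_columns))
  } else {
    out <- rows
    for (col in results_columns) if (!col %in% names(out)) out[[col]] <- NA
    out <- out[, results_columns, drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results table to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a results table written by \code{write_results_table}
#'
#' @param path results TSV path
#' @return data.frame in the declared column order
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
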