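# PROSITE-like scanning of the conserved propeptide aromatic motif
# W-x(2)-[FYW]-x(3)-[FY]-x(3)-Y-x(12)-[FYW] (and any user pattern of the
# same grammar) against amino-acid sequences.
#
# Grammar: dash-separated tokens; a token is a single residue letter, a
# bracketed alternative set like [FYW], or x(n) for exactly n arbitrary
# residues (fixed gaps, no ranges). 'X' in a scanned sequence is treated as
# an unknown residue and matches no slot, wildcard gaps included.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The conserved propeptide aromatic motif
#'
#' Pattern string for the aromatic residues of hydrophobic Core 1 shared by
#' propeptide-like cysteine protease inhibitors and cathepsin propeptides:
#' a tryptophan, then at fixed spacings three aromatic slots and a final
#' aromatic 13 residues after the conserved tyrosine (span 25). Callers may
#' edit the string and re-parse if a different final spacing is wanted.
#' @export
AROMATIC_CORE_MOTIF <- "W-x(2)-[FYW]-x(3)-[FY]-x(3)-Y-x(12)-[FYW]"

#' Parse a PROSITE-like motif pattern
#'
#' @param text pattern string, e.g. \code{"W-x(2)-[FYW]-x(3)-[FY]"}: tokens
#'   separated by dashes, each a single residue letter, a bracketed set, or
#'   \code{x(n)} meaning exactly n arbitrary residues
#' @return an object of class \code{motif_pattern} with \code{elements}
#'   (list of residue-set character vectors and integer gap lengths),
#'   \code{span} (total length in residues) and \code{source_text}
#' @examples
#' parse_motif("W-x(2)-Y")$span  # 4
#' @export
parse_motif <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty motif pattern", call. = FALSE)
  tokens <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  if (!length(tokens)) stop("empty motif pattern", call. = FALSE)
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (grepl("^[A-Za-z]$", tok) && toupper(tok) != "X") {
      elements[[i]] <- toupper(tok)
    } else if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
      set <- unique(strsplit(toupper(substr(tok, 2, nchar(tok) - 1)), "")[[1]])
      elements[[i]] <- set
    } else if (grepl("^[xX]\\(\\d+\\)$", tok)) {
      n <- as.integer(sub("^[xX]\\((\\d+)\\)$", "\\1", tok))
      elements[[i]] <- n
    } else {
      stop("malformed motif token: '", tok, "'", call. = FALSE)
    }
  }
  if (!is.character(elements[[1]]) || !is.character(elements[[length(elements)]]))
    stop("motif must start and end with a residue slot, not a gap", call. = FALSE)
  span <- sum(vapply(elements, function(e) if (is.character(e)) 1L else e,
                     integer(1)))
  structure(list(elements = elements, span = span, source_text = text),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (span %d)\n", x$source_text, x$span))
  invisible(x)
}

# regex with a lookahead wrapper so overlapping matches are all found;
# wildcard gaps match the 20 standard residues only (not 'X')
motif_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(e) {
    if (is.character(e)) {
      if (length(e) == 1L) e else paste0("[", paste(e, collapse = ""), "]")
    } else {
      sprintf("[%s]{%d}", paste(AA20, collapse = ""), e)
    }
  }, character(1))
  paste0(parts, collapse = "")
}

# 1-based positions (within the motif) of the constrained residue slots
constrained_offsets <- function(pattern) {
  pos <- integer(0); at <- 1L
  for (e in pattern$elements) {
    if (is.character(e)) { pos <- c(pos, at); at <- at + 1L }
    else at <- at + e
  }
  pos
}

#' Scan a sequence for motif matches
#'
#' Reports all (possibly overlapping) matches of the pattern, 1-based and
#' left to right. Matching is case-insensitive; an \code{'X'} in the
#' sequence (unknown residue) matches no slot.
#'
#' @param pattern a \code{\link{motif_pattern}}
#' @param sequence amino-acid string, no gap (\code{-}) or stop (\code{*})
#'   characters
#' @param sequence_id label carried into the hit table
#' @return data.frame of hits: \code{sequence_id}, \code{start}, \code{end}
#'   (1-based inclusive), and \code{matched} (the residues at the
#'   constrained slots, comma-joined as \code{pos:residue})
#' @export
scan_motif <- function(pattern, sequence, sequence_id = NA_character_) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single string", call. = FALSE)
  seq_up <- toupper(sequence)
  if (grepl("[-*]", seq_up))
    stop("sequence contains gap/stop characters; degap before scanning ",
         "(see scan_fasta for alignment-aware scanning)", call. = FALSE)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq_up) < pattern$span) return(empty)
  rx <- paste0("(?=", motif_regex(pattern), ")")
  m <- gregexpr(rx, seq_up, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  offs <- constrained_offsets(pattern)
  matched <- vapply(starts, function(s) {
    paste(sprintf("%d:%s", s + offs - 1L,
                  substring(seq_up, s + offs - 1L, s + offs - 1L)),
          collapse = ",")
  }, character(1))
  data.frame(sequence_id = rep(sequence_id, length(starts)),
             start = starts, end = starts + pattern$span - 1L,
             matched = matched, stringsAsFactors = FALSE)
}

#' Scan a set of FASTA records for motif matches
#'
#' Applies \code{\link{scan_motif}} to each record. Records containing
#' alignment gaps are degapped before scanning and the hit coordinates are
#' remapped to the original gapped columns (\code{start}/\code{end} then
#' refer to alignment columns). Duplicate record ids are scanned with a
#' warning.
#'
#' @param pattern a \code{\link{motif_pattern}}
#' @param records a data.frame as returned by \code{\link{read_fasta}}
#'   (columns \code{id}, \code{sequence}), or a named character vector of
#'   sequences
#' @return data.frame of hits across all records (see \code{scan_motif});
#'   an extra logical column \code{gapped_coords} marks rows whose
#'   coordinates refer to alignment columns
#' @export
scan_fasta <- function(pattern, records) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  out <- list()
  if (nrow(records) && anyDuplicated(records$id))
    warning("duplicate sequence ids in FASTA input; all records scanned",
            call. = FALSE)
  for (i in seq_len(nrow(records))) {
    sq <- toupper(records$sequence[i])
    sq_clean <- gsub("[-*]", "", sq)
    hits <- scan_motif(pattern, sq_clean, sequence_id = records$id[i])
    gapped <- nchar(sq_clean) != nchar(sq)
    if (gapped && nrow(hits)) {
      # map degapped positions back to original (alignment) columns
      keep <- which(strsplit(sq, "")[[1]] != "-" & strsplit(sq, "")[[1]] != "*")
      hits$start <- keep[hits$start]
      hits$end <- keep[hits$end]
    }
    hits$gapped_coords <- rep(gapped, nrow(hits))
    out[[i]] <- hits
  }
  if (!length(out))
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      gapped_coords = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
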