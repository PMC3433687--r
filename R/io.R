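# Readers and writers for the plain-text formats used throughout:
# FASTA proteomes and hotspot windows, P-site tables, interval tables,
# hotspot tables (TSV and GFF3).

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return data frame with columns `id` (header token before the first
#'   whitespace) and `sequence` (uppercased).  An empty file yields an empty
#'   data frame with a warning.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(data.frame(id = character(0), sequence = character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)
  res <- data.frame(id = ids, sequence = toupper(as.character(set)))
  if (any(nchar(res$sequence) == 0L)) stop("empty sequence in '", path, "'")
  rownames(res) <- NULL
  res
}

#' Write protein sequences to a FASTA file
#'
#' @param proteome data frame with columns `id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, proteome$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Validate a table of phosphorylation sites against a proteome
#'
#' Each site must point at an S, T or Y residue of the named protein at its
#' 0-based `position`.
#'
#' @param psites data frame with columns `protein_id`, `position`, `residue`.
#' @param proteome proteome data frame (`id`, `sequence`).
#' @return the sites, sorted per protein by position, with duplicates removed.
#' @export
validate_psites <- function(psites, proteome) {
  stopifnot(all(c("protein_id", "position", "residue") %in% names(psites)))
  psites$position <- as.integer(psites$position)
  seqs <- proteome_lookup(proteome)
  unk <- which(!(psites$protein_id %in% names(seqs)))
  if (length(unk)) stop_rows("P-site for unknown protein_id", unk)
  bad_res <- which(!(psites$residue %in% c("S", "T", "Y")))
  if (length(bad_res)) stop_rows("P-site residue not one of S/T/Y", bad_res)
  lens <- nchar(seqs[psites$protein_id])
  oob <- which(psites$position < 0L | psites$position >= lens)
  if (length(oob)) stop_rows("P-site position out of range", oob)
  actual <- substring(seqs[psites$protein_id], psites$position + 1L,
                      psites$position + 1L)
  mm <- which(actual != psites$residue)
  if (length(mm)) stop_rows("P-site residue disagrees with protein sequence", mm)
  out <- unique(psites[, c("protein_id", "position", "residue")])
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tab-separated P-site table
#'
#' Expects a header line with columns `protein_id`, `position` (0-based) and
#' `residue`; every row is validated against the proteome.
#'
#' @inheritParams validate_psites
#' @param path TSV file.
#' @return validated, sorted site data frame.
#' @export
read_psites <- function(path, proteome) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, colClasses = c("character", "integer", "character"))
  if (nrow(tab) == 0L) warning("P-site table '", path, "' is empty")
  validate_psites(tab, proteome)
}

#' Write a P-site table
#' @param psites data frame with columns `protein_id`, `position`, `residue`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_psites <- function(psites, path) {
  utils::write.table(psites[, c("protein_id", "position", "residue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interval table (peptide coverage or disorder)
#'
#' Columns `protein_id`, `start`, `end`; 0-based half-open.  Intervals are
#' normalized (sorted, overlapping/adjacent intervals merged per protein).
#'
#' @param path TSV file.
#' @param proteome optional proteome for bounds validation.
#' @return normalized interval data frame.
#' @export
read_intervals <- function(path, proteome = NULL) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, colClasses = c("character", "integer", "integer"))
  normalize_intervals(tab, proteome)
}

#' Write an interval table
#' @param intervals data frame with columns `protein_id`, `start`, `end`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals[, c("protein_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

hotspot_columns <- c("protein_id", "window_start", "window_end", "n_sites",
                     "site_positions", "score")

#' Write hotspots as TSV or GFF3
#'
#' The TSV keeps the package's internal convention (0-based half-open window
#' coordinates, comma-joined 0-based site positions).  GFF3 output converts
#' to the standard 1-based inclusive convention (`start = window_start + 1`,
#' `end = window_end`) with feature type `phosphorylation_hotspot`.
#'
#' @param hotspots hotspot data frame (as returned by [detect_hotspots()] or
#'   read back by [read_hotspots()]).
#' @param path output file.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_hotspots <- function(hotspots, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  h <- hotspots
  if (!"score" %in% names(h)) h$score <- NA_real_
  if (format == "tsv") {
    utils::write.table(h[, hotspot_columns], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(h)) {
      attrs <- sprintf("ID=hotspot_%s_%d;n_sites=%d;sites=%s",
                       h$protein_id, h$window_start, h$n_sites,
                       h$site_positions)
      writeLines(sprintf("%s\thotspotter\tphosphorylation_hotspot\t%d\t%d\t%s\t.\t.\t%s",
                         h$protein_id, h$window_start + 1L, h$window_end,
                         ifelse(is.na(h$score), ".", format(h$score, digits = 6)),
                         attrs), con)
    }
  }
  invisible(path)
}

#' Read a hotspot TSV written by [write_hotspots()]
#' @param path TSV file.
#' @return hotspot data frame.
#' @export
read_hotspots <- function(path) {
  stopifnot(file.exists(path))
  utils::read.delim(path, colClasses = c("character", "integer", "integer",
                                         "integer", "character", "numeric"))
}
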