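# Shared constants and small helpers.

# The 20 standard amino acids in fixed alphabetical (one-letter) order.  The
# composition-vector layout depends on this ordering; it must never change.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Tolerated ambiguity codes: sequences may contain them, but windows that do
# are excluded from feature extraction and scanning.
AMBIGUITY_CODES <- c("X", "B", "Z", "U", "J", "O", "*")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strip the isoform suffix from a protein accession
#'
#' Accessions such as `"AT1G01540.1"` carry a `".n"` isoform suffix; the gene
#' identifier is the accession with that suffix removed.
#'
#' @param protein_id character vector of accessions.
#' @return character vector of gene identifiers.
#' @examples
#' gene_id(c("AT1G01540.1", "AT1G01540.2")) # both "AT1G01540"
#' @export
gene_id <- function(protein_id) {
  sub("\\.\\d+$", "", protein_id)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Named lookup protein_id -> sequence from a proteome data frame.
proteome_lookup <- function(proteome) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  stats::setNames(proteome$sequence, proteome$id)
}

stop_rows <- function(msg, rows) {
  stop(msg, ": rows ", paste(utils::head(rows, 20L), collapse = ", "),
       if (length(rows) > 20L) " ..." else "", call. = FALSE)
}

#' Longest sequence segment shared by two or more sequences
#'
#' Length of the longest exact substring occurring in at least two distinct
#' sequences of `x`.  Used to verify that hotspot training windows are
#' mutually dissimilar (no shared segment longer than a few residues), which
#' is what licenses window-level cross-validation grouped by hotspot.
#'
#' @param x character vector of sequences (length >= 2).
#' @return integer, the maximal shared substring length (0 if even no single
#'   residue is shared).
#' @examples
#' longest_shared_segment(c("MRGRSYTPS", "AATPSGG")) # "TPS" -> 3
#' @export
longest_shared_segment <- function(x) {
  stopifnot(is.character(x), length(x) >= 2L)
  shared_at <- function(k) {
    km <- lapply(x, function(s) {
      n <- nchar(s)
      if (n < k) character(0) else unique(substring(s, 1:(n - k + 1L), k:n))
    })
    anyDuplicated(unlist(km)) > 0L
  }
  lo <- 0L
  hi <- max(nchar(x))
  while (lo < hi) { # binary search: shared_at is monotone decreasing in k
    mid <- as.integer((lo + hi + 1L) %/% 2L)
    if (shared_at(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Merge overlapping or adjacent half-open intervals of one protein.
# `df` has columns start, end; returns the same, sorted and disjoint.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me) { # overlap or adjacency
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Normalize coverage or disorder intervals
#'
#' Sorts per-protein 0-based half-open intervals and merges overlapping or
#' adjacent ones, optionally validating bounds against a proteome.
#'
#' @param intervals data frame with columns `protein_id`, `start`, `end`.
#' @param proteome optional proteome data frame (`id`, `sequence`); when
#'   given, intervals must satisfy `0 <= start < end <= protein length`.
#' @return data frame with the same columns, per protein disjoint and sorted.
#' @export
normalize_intervals <- function(intervals, proteome = NULL) {
  stopifnot(all(c("protein_id", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(intervals[, c("protein_id", "start", "end")])
  bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end))
  if (length(bad)) stop_rows("invalid interval (need 0 <= start < end)", bad)
  if (!is.null(proteome)) {
    seqs <- proteome_lookup(proteome)
    unk <- which(!(intervals$protein_id %in% names(seqs)))
    if (length(unk)) stop_rows("interval for unknown protein_id", unk)
    lens <- nchar(seqs[intervals$protein_id])
    oob <- which(intervals$end > lens)
    if (length(oob)) stop_rows("interval end beyond protein length", oob)
  }
  parts <- split(intervals, intervals$protein_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    m <- merge_intervals(d$start, d$end)
    data.frame(protein_id = d$protein_id[1], start = as.integer(m$start),
               end = as.integer(m$end))
  }))
  rownames(out) <- NULL
  out[order(out$protein_id, out$start), , drop = FALSE]
}
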