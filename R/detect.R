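# Hotspot detection: maximal gap-constrained runs of P-sites, and window
# padding around the run core.

#' Pad a hotspot core into a composition window
#'
#' The window always includes `min_flank` residues beyond the terminal sites
#' (clipped at the protein termini).  When the flank rule alone yields fewer
#' than `min_len` residues, the window is centered on the core midpoint and
#' extended to `min_len`; at a half-integer midpoint the more N-terminal
#' start is taken, and a window that would cross a terminus is shifted into
#' the protein.  Proteins shorter than `min_len` yield the whole protein,
#' flagged as truncated.
#'
#' @param core_start,core_end 0-based positions of the first and last site.
#' @param protein_length protein length in residues.
#' @param min_len minimum window length (default 17).
#' @param min_flank minimum flank beyond the terminal sites (default 3).
#' @return integer vector `c(start, end)`, 0-based half-open, with attribute
#'   `truncated = TRUE` when the protein is shorter than `min_len`.
#' @examples
#' pad_hotspot(89, 113, 500)  # c(86, 117): flanks of exactly 3
#' pad_hotspot(190, 195, 500) # c(184, 201): centered, lower start at midpoint .5
#' pad_hotspot(4, 8, 500)     # c(0, 17): clipped at the N-terminus
#' @export
pad_hotspot <- function(core_start, core_end, protein_length,
                        min_len = 17L, min_flank = 3L) {
  stopifnot(core_start >= 0, core_start <= core_end,
            core_end < protein_length)
  if (protein_length < min_len) {
    out <- c(0L, as.integer(protein_length))
    attr(out, "truncated") <- TRUE
    warning("protein shorter than the minimum window length (",
            protein_length, " < ", min_len, "); emitting the whole protein")
    return(out)
  }
  core_len <- core_end - core_start + 1L
  if (core_len + 2L * min_flank >= min_len) {
    ws <- max(0L, core_start - min_flank)
    we <- min(as.integer(protein_length), core_end + 1L + min_flank)
    # terminal clipping may shrink the flank window below min_len; extend
    # into the protein on the unclipped side
    if (we - ws < min_len) {
      if (ws == 0L) we <- min(as.integer(protein_length), as.integer(min_len))
      if (we == protein_length) ws <- max(0L, we - as.integer(min_len))
    }
  } else {
    mid <- (core_start + core_end) / 2
    ws <- as.integer(floor(mid - (min_len - 1L) / 2))
    we <- ws + as.integer(min_len)
    if (ws < 0L) { ws <- 0L; we <- as.integer(min_len) }
    if (we > protein_length) {
      we <- as.integer(protein_length)
      ws <- we - as.integer(min_len)
    }
  }
  c(as.integer(ws), as.integer(we))
}

# Split sorted positions into maximal runs with neighbor gaps <= max_gap.
# Returns a list of integer vectors.
site_runs <- function(positions, max_gap) {
  if (length(positions) == 0L) return(list())
  brk <- c(0L, cumsum(diff(positions) > max_gap))
  unname(split(positions, brk))
}

#' Detect phosphorylation hotspots from experimental sites
#'
#' A hotspot is a maximal run of at least `min_sites` sites along one protein
#' in which each neighboring pair is at most `max_gap` residues apart
#' (position difference of exactly `max_gap` qualifies).  Each qualifying run
#' is padded into a window via [pad_hotspot()] when the proteome is supplied.
#'
#' @param psites validated site data frame (`protein_id`, `position`,
#'   `residue`); see [validate_psites()].
#' @param proteome optional proteome data frame; required for window padding
#'   and window sequences.
#' @param min_sites minimum run size (default 4).
#' @param max_gap maximum neighbor spacing (default 10).
#' @param min_len minimum padded window length (default 17).
#' @param min_flank minimum flank beyond terminal sites (default 3).
#' @return data frame with one row per hotspot: `protein_id`, `core_start`,
#'   `core_end`, `n_sites`, `site_positions` (comma-joined, 0-based),
#'   `window_start`, `window_end`, `window_sequence` (NA without a proteome),
#'   `hotspot_id`.
#' @export
detect_hotspots <- function(psites, proteome = NULL, min_sites = 4L,
                            max_gap = 10L, min_len = 17L, min_flank = 3L) {
  empty <- data.frame(protein_id = character(0), core_start = integer(0),
                      core_end = integer(0), n_sites = integer(0),
                      site_positions = character(0), window_start = integer(0),
                      window_end = integer(0), window_sequence = character(0),
                      hotspot_id = character(0))
  if (nrow(psites) == 0L) return(empty)
  seqs <- if (!is.null(proteome)) proteome_lookup(proteome) else NULL
  rows <- list()
  for (pid in unique(psites$protein_id)) {
    pos <- sort(unique(psites$position[psites$protein_id == pid]))
    for (run in site_runs(pos, max_gap)) {
      if (length(run) < min_sites) next
      cs <- run[1]; ce <- run[length(run)]
      if (!is.null(seqs)) {
        L <- nchar(seqs[[pid]])
        w <- pad_hotspot(cs, ce, L, min_len = min_len, min_flank = min_flank)
        wseq <- substring(seqs[[pid]], w[1] + 1L, w[2])
      } else {
        w <- c(NA_integer_, NA_integer_); wseq <- NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, core_start = cs, core_end = ce,
        n_sites = length(run),
        site_positions = paste(run, collapse = ","),
        window_start = w[1], window_end = w[2], window_sequence = wseq)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$hotspot_id <- paste0(out$protein_id, "|", out$core_start)
  rownames(out) <- NULL
  out
}

#' Parse comma-joined site positions back into integer vectors
#' @param site_positions character vector of comma-joined positions.
#' @return list of integer vectors.
#' @export
parse_site_positions <- function(site_positions) {
  lapply(strsplit(site_positions, ","), as.integer)
}
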