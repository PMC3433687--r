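# Whole-proteome scanning: per-window decision scores, residue-level
# positive masks, consolidation of positive runs into predicted hotspots,
# and scan summaries.

#' Score every sliding window of a proteome
#'
#' One decision score per 0-based window start `0..L-k` per protein; windows
#' containing ambiguity codes carry `NA`.  Proteins shorter than `k` yield an
#' empty track.
#'
#' @param model `"hotspot_svm"` classifier.
#' @param proteome proteome data frame.
#' @param k window length (default 17).
#' @return named list (one numeric vector per protein) of class
#'   `"score_track"`; element `i` of a vector is the score of the window
#'   starting at 0-based position `i - 1`.
#' @export
score_proteome <- function(model, proteome, k = 17L) {
  tracks <- lapply(proteome$id, function(pid) {
    sq <- proteome$sequence[proteome$id == pid]
    X <- sequence_feature_matrix(sq, k = k)
    if (nrow(X) == 0L) return(numeric(0))
    decision_scores(model, X)
  })
  structure(stats::setNames(tracks, proteome$id), class = "score_track",
            k = k)
}

#' Residue-level positive mask from a score track
#'
#' A residue is positive when covered by at least one window whose score
#' exceeds `threshold`: positive predictions take precedence over negative
#' ones at the 16 residues shared by adjacent windows.
#'
#' @param track numeric score vector for one protein (one element per window
#'   start), or a `"score_track"` list.
#' @param threshold decision-score threshold.
#' @param k window length (default 17).
#' @param protein_length optional protein length; defaults to
#'   `length(track) + k - 1`.
#' @return logical vector over residues (or a named list of them).
#' @export
positive_residues <- function(track, threshold, k = 17L,
                              protein_length = NULL) {
  if (is.list(track))
    return(lapply(track, positive_residues, threshold = threshold, k = k))
  L <- protein_length %||% (length(track) + k - 1L)
  mask <- rep(FALSE, L)
  pos <- which(!is.na(track) & track > threshold)
  for (s in pos) mask[s:(s + k - 1L)] <- TRUE
  mask
}

# Runs of consecutive positive window starts, merged when neighboring runs'
# start positions are <= k apart, as half-open residue spans.
merged_run_spans <- function(pos_starts, k) {
  if (length(pos_starts) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      first_start = integer(0), last_start = integer(0)))
  brk <- c(0L, cumsum(diff(pos_starts) > 1L))
  runs <- lapply(split(pos_starts, brk), range)
  first <- vapply(runs, `[`, integer(1), 1L)
  last <- vapply(runs, `[`, integer(1), 2L)
  # left-to-right merge to fixpoint: merging never changes the last start of
  # the growing run, so a single pass closes the relation
  mf <- first[1]; ml <- last[1]
  out <- list()
  if (length(first) > 1L) for (i in 2:length(first)) {
    if (first[i] - ml <= k) {
      ml <- last[i]
    } else {
      out[[length(out) + 1L]] <- c(mf, ml)
      mf <- first[i]; ml <- last[i]
    }
  }
  out[[length(out) + 1L]] <- c(mf, ml)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2] + k, first_start = m[, 1],
             last_start = m[, 2])
}

# Does [start, end) of `chars` contain >= min_sites S/T/Y residues forming a
# gap-constrained run?  Returns the qualifying run positions or NULL.
sty_qualifying_run <- function(chars, start, end, min_sites, max_gap) {
  sty <- which(chars[(start + 1L):end] %in% c("S", "T", "Y")) + start - 1L
  for (run in site_runs(sty, max_gap))
    if (length(run) >= min_sites) return(run)
  NULL
}

#' Consolidate positive windows into predicted hotspots
#'
#' Maximal runs of consecutive positive window starts span
#' `[first start, last start + k)`; neighboring runs whose start positions
#' are at most `k` apart are merged (iterated to a fixpoint).  A merged run
#' is retained only if its residue span contains at least `min_sites` S/T/Y
#' residues forming a run with neighbor gaps at most `max_gap` -- the same
#' criterion imposed on experimental hotspots, evaluated over all S/T/Y
#' residues since predictions carry no site-level calls.
#'
#' @param tracks `"score_track"` from [score_proteome()], or a single
#'   numeric track with `sequence` given.
#' @param proteome proteome data frame (or a single sequence string when
#'   `tracks` is a single track).
#' @param threshold decision-score threshold (proteome default 1).
#' @param k window length (default 17).
#' @param min_sites,max_gap S/T/Y content-filter parameters.
#' @return data frame with one row per predicted hotspot: `protein_id`,
#'   `region_start`, `region_end` (0-based half-open), `n_windows`,
#'   `max_score`, `mean_score`, `sty_run` (comma-joined qualifying S/T/Y
#'   positions).
#' @export
consolidate_runs <- function(tracks, proteome, threshold = 1, k = 17L,
                             min_sites = 4L, max_gap = 10L) {
  if (!is.list(tracks)) {
    stopifnot(is.character(proteome), length(proteome) == 1L)
    proteome <- data.frame(id = "protein", sequence = proteome)
    tracks <- structure(list(protein = tracks), class = "score_track")
  }
  rows <- list()
  for (pid in names(tracks)) {
    track <- tracks[[pid]]
    pos <- which(!is.na(track) & track > threshold) - 1L # 0-based starts
    if (length(pos) == 0L) next
    spans <- merged_run_spans(pos, k)
    chars <- seq_chars(proteome$sequence[proteome$id == pid])
    for (i in seq_len(nrow(spans))) {
      run <- sty_qualifying_run(chars, spans$start[i], spans$end[i],
                                min_sites, max_gap)
      if (is.null(run)) next
      member <- pos[pos >= spans$first_start[i] & pos <= spans$last_start[i]]
      sc <- track[member + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, region_start = spans$start[i],
        region_end = spans$end[i], n_windows = length(member),
        max_score = max(sc), mean_score = mean(sc),
        sty_run = paste(run, collapse = ","))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), region_start = integer(0),
               region_end = integer(0), n_windows = integer(0),
               max_score = numeric(0), mean_score = numeric(0),
               sty_run = character(0))
  rownames(out) <- NULL
  out
}

#' Summarize a proteome scan
#'
#' @param runs predicted hotspots from [consolidate_runs()].
#' @param tracks the `"score_track"` the runs were derived from.
#' @param threshold the decision-score threshold used.
#' @return list with `n_windows` (scored windows), `n_positive` (windows
#'   above threshold), `n_hotspots`, `n_proteins`, `n_genes` (accessions
#'   with the isoform suffix stripped).
#' @export
summarize_scan <- function(runs, tracks, threshold) {
  all_scores <- unlist(tracks, use.names = FALSE)
  list(n_windows = sum(!is.na(all_scores)),
       n_positive = sum(all_scores > threshold, na.rm = TRUE),
       n_hotspots = nrow(runs),
       n_proteins = length(unique(runs$protein_id)),
       n_genes = length(unique(gene_id(runs$protein_id))))
}
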