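# Co-occurrence of hotspots with disorder intervals, and the
# random-placement null.

# Coerce a hotspot / predicted-run / interval data frame to protein_id,
# start, end.
as_regions <- function(x) {
  if (all(c("region_start", "region_end") %in% names(x)))
    return(data.frame(protein_id = x$protein_id, start = x$region_start,
                      end = x$region_end))
  if (all(c("window_start", "window_end") %in% names(x)))
    return(data.frame(protein_id = x$protein_id, start = x$window_start,
                      end = x$window_end))
  stopifnot(all(c("protein_id", "start", "end") %in% names(x)))
  x[, c("protein_id", "start", "end")]
}

#' Filter intervals by minimum length
#'
#' @param intervals interval data frame (`protein_id`, `start`, `end`).
#' @param min_len minimum length in residues (default 17, matching the
#'   minimum hotspot window).
#' @return the intervals of length `>= min_len`.
#' @export
filter_intervals <- function(intervals, min_len = 17L) {
  intervals[intervals$end - intervals$start >= min_len, , drop = FALSE]
}

#' Count overlaps between hotspots and disorder intervals
#'
#' A hotspot and an interval on the same protein overlap when they share at
#' least `min_shared` consecutive residues (intersection length of the
#' half-open spans).  A hotspot counts once however many intervals it hits,
#' and vice versa, so the two counts may differ.
#'
#' @param hotspots hotspot/run data frame (any of the package's region
#'   representations).
#' @param intervals disorder interval data frame.
#' @param min_shared minimum shared consecutive residues (default 3).
#' @return list with `n_hotspots_overlapping`, `n_intervals_overlapping`,
#'   `fraction` (of hotspots overlapping), `n_hotspots`, `n_intervals`.
#' @export
count_overlaps <- function(hotspots, intervals, min_shared = 3L) {
  h <- as_regions(hotspots)
  d <- as_regions(intervals)
  h_hit <- rep(FALSE, nrow(h))
  d_hit <- rep(FALSE, nrow(d))
  if (nrow(h) && nrow(d)) {
    d_by <- split(seq_len(nrow(d)), d$protein_id)
    for (i in seq_len(nrow(h))) {
      js <- d_by[[h$protein_id[i]]]
      if (is.null(js)) next
      shared <- pmin(h$end[i], d$end[js]) - pmax(h$start[i], d$start[js])
      hit <- shared >= min_shared
      if (any(hit)) {
        h_hit[i] <- TRUE
        d_hit[js[hit]] <- TRUE
      }
    }
  }
  list(n_hotspots_overlapping = sum(h_hit),
       n_intervals_overlapping = sum(d_hit),
       fraction = if (nrow(h)) sum(h_hit) / nrow(h) else NA_real_,
       n_hotspots = nrow(h), n_intervals = nrow(d))
}

#' Random-placement null for hotspot/disorder overlap
#'
#' Per repeat, every hotspot is reassigned to a uniformly chosen protein
#' (among those long enough to hold it) and a uniformly chosen start, with
#' placements within one repeat forbidden from overlapping each other
#' (rejection sampling, bounded retries); the overlap with the disorder
#' intervals is then recounted.  The hotspot count and length multiset are
#' conserved by construction.
#'
#' @param hotspots hotspot/run data frame.
#' @param proteome proteome data frame.
#' @param intervals disorder interval data frame.
#' @param repeats number of randomization repeats (default 10).
#' @param min_shared overlap criterion passed to [count_overlaps()].
#' @param max_tries rejection-sampling cap per hotspot (default 1000).
#' @return list with `mean`, `sd`, `mean_fraction`, and `counts` (overlap
#'   count per repeat).
#' @export
randomize_placement <- function(hotspots, proteome, intervals, repeats = 10L,
                                min_shared = 3L, max_tries = 1000L) {
  h <- as_regions(hotspots)
  lens <- h$end - h$start
  plens <- stats::setNames(nchar(proteome$sequence), proteome$id)
  if (max(lens) > max(plens))
    stop("hotspot longer than the longest protein cannot be placed")
  counts <- integer(repeats)
  for (r in seq_len(repeats)) {
    placed <- data.frame(protein_id = character(0), start = integer(0),
                         end = integer(0))
    for (i in order(lens, decreasing = TRUE)) {
      len <- lens[i]
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        pid <- proteome$id[sample.int(nrow(proteome), 1L)]
        L <- plens[[pid]]
        if (L < len) next
        s <- sample.int(L - len + 1L, 1L) - 1L
        prev <- placed[placed$protein_id == pid, , drop = FALSE]
        if (nrow(prev) &&
            any(pmin(prev$end, s + len) - pmax(prev$start, s) > 0L)) next
        placed <- rbind(placed, data.frame(protein_id = pid, start = s,
                                           end = s + len))
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place hotspot of length ", len,
                    " after ", max_tries, " tries")
    }
    counts[r] <- count_overlaps(placed, intervals,
                                min_shared = min_shared)$n_hotspots_overlapping
  }
  list(mean = mean(counts), sd = stats::sd(counts),
       mean_fraction = mean(counts) / nrow(h), counts = counts)
}
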