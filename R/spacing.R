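# Nearest-neighbor inter-P-site spacing within continuously covered regions,
# plus the two randomization nulls and the distribution comparison.

# Assign each site the index of the covering interval (NA if uncovered).
# `cov` is a normalized interval data frame for ONE protein.
segment_of <- function(positions, cov) {
  if (is.null(cov) || nrow(cov) == 0L) return(rep(NA_integer_, length(positions)))
  vapply(positions, function(p) {
    hit <- which(cov$start <= p & p < cov$end)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Nearest-neighbor distances between phosphorylation sites
#'
#' For every site that shares a continuously covered segment with at least
#' one other site, the distance to the closest other site in that segment
#' (in either sequence direction).  Sites whose nearest neighbor lies outside
#' every shared covered segment contribute nothing, as do proteins with a
#' single site.  Without a coverage table the whole protein counts as one
#' covered segment.
#'
#' @param psites validated site data frame.
#' @param coverage optional normalized coverage intervals
#'   ([normalize_intervals()]).
#' @return data frame with columns `protein_id`, `position`, `residue_class`
#'   (`"pST"` or `"pY"`) and `d_N` (positive integer).
#' @export
nearest_neighbor_distances <- function(psites, coverage = NULL) {
  out <- data.frame(protein_id = character(0), position = integer(0),
                    residue_class = character(0), d_N = integer(0))
  if (nrow(psites) == 0L) {
    warning("no P-sites supplied")
    return(out)
  }
  cov_by <- if (!is.null(coverage)) split(coverage, coverage$protein_id) else NULL
  rows <- list()
  for (pid in unique(psites$protein_id)) {
    d <- psites[psites$protein_id == pid, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    if (nrow(d) < 2L) next
    seg <- if (is.null(cov_by)) rep(1L, nrow(d)) else
      segment_of(d$position, cov_by[[pid]])
    for (s in unique(seg[!is.na(seg)])) {
      idx <- which(!is.na(seg) & seg == s)
      if (length(idx) < 2L) next
      pos <- d$position[idx]
      dn <- vapply(seq_along(pos),
                   function(i) min(abs(pos[i] - pos[-i])), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, position = pos,
        residue_class = ifelse(d$residue[idx] == "Y", "pY", "pST"),
        d_N = as.integer(dn))
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  out
}

# Regions over which a randomization operates: covered segments when a
# coverage table is given, otherwise the whole protein.
randomization_regions <- function(pid, L, coverage) {
  if (is.null(coverage)) return(data.frame(start = 0L, end = L))
  cov <- coverage[coverage$protein_id == pid, , drop = FALSE]
  if (nrow(cov) == 0L) return(cov[, c("start", "end")])
  cov[, c("start", "end")]
}

#' P-flag randomization null
#'
#' Reassigns the phosphorylation flags of each residue type uniformly without
#' replacement among that type's positions in the same region (covered
#' segment, or whole protein without coverage), leaving the sequence
#' untouched.  Per region and residue type the flag count is conserved, so
#' this null asks whether observed spacing merely reflects where the S/T/Y
#' residues themselves sit.
#'
#' @param psites validated site data frame.
#' @param proteome proteome data frame.
#' @param coverage optional normalized coverage intervals; flags on uncovered
#'   residues are left in place.
#' @return a site data frame with the same per-type counts.
#' @export
pflag_randomize <- function(psites, proteome, coverage = NULL) {
  seqs <- proteome_lookup(proteome)
  rows <- list()
  for (pid in unique(psites$protein_id)) {
    d <- psites[psites$protein_id == pid, , drop = FALSE]
    chars <- seq_chars(seqs[[pid]])
    regions <- randomization_regions(pid, length(chars), coverage)
    in_region <- rep(NA_integer_, length(chars))
    if (nrow(regions)) for (r in seq_len(nrow(regions)))
      in_region[(regions$start[r] + 1L):regions$end[r]] <- r
    keep <- d[is.na(in_region[d$position + 1L]), , drop = FALSE] # uncovered: untouched
    if (nrow(keep)) rows[[length(rows) + 1L]] <- keep
    for (r in seq_len(max(0L, nrow(regions)))) {
      dr <- d[!is.na(in_region[d$position + 1L]) &
                in_region[d$position + 1L] == r, , drop = FALSE]
      if (nrow(dr) == 0L) next
      for (res in c("S", "T", "Y")) {
        nflag <- sum(dr$residue == res)
        if (nflag == 0L) next
        avail <- which(chars == res & !is.na(in_region) & in_region == r) - 1L
        if (length(avail) < nflag)
          stop("protein ", pid, ": ", nflag, " ", res,
               "-flags but only ", length(avail), " ", res,
               " positions in the region")
        newpos <- sort(avail[sample.int(length(avail), nflag)])
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, position = newpos, residue = res)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else psites[0, ]
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequence randomization null
#'
#' Applies a uniform permutation to the residue positions of each region
#' (covered segment, or whole protein); phosphorylation flags travel with
#' their residues.  Composition and flag counts are conserved while any
#' positional preference of the S/T/Y residues themselves is destroyed.
#'
#' @inheritParams pflag_randomize
#' @return list with `proteome` (shuffled sequences) and `psites`
#'   (repositioned flags).
#' @export
sequence_randomize <- function(psites, proteome, coverage = NULL) {
  seqs <- proteome_lookup(proteome)
  new_seqs <- seqs
  rows <- list()
  for (pid in proteome$id) {
    chars <- seq_chars(seqs[[pid]])
    d <- psites[psites$protein_id == pid, , drop = FALSE]
    flagged <- rep(FALSE, length(chars))
    flagged[d$position + 1L] <- TRUE
    regions <- randomization_regions(pid, length(chars), coverage)
    if (nrow(regions)) for (r in seq_len(nrow(regions))) {
      idx <- (regions$start[r] + 1L):regions$end[r]
      perm <- sample.int(length(idx))
      chars[idx] <- chars[idx][perm]
      flagged[idx] <- flagged[idx][perm]
    }
    new_seqs[[pid]] <- paste(chars, collapse = "")
    pos <- which(flagged) - 1L
    if (length(pos))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, position = pos, residue = chars[pos + 1L])
  }
  psites_out <- if (length(rows)) do.call(rbind, rows) else psites[0, ]
  rownames(psites_out) <- NULL
  list(proteome = data.frame(id = proteome$id,
                             sequence = unname(new_seqs[proteome$id])),
       psites = psites_out)
}

#' Histogram of nearest-neighbor distances
#'
#' Relative frequencies of `d_N` in unit bins `1..max_bin` plus one open tail
#' bin, together with the fraction of distances below 6 and the mean.
#'
#' @param records data frame from [nearest_neighbor_distances()], or a
#'   numeric vector of distances.
#' @param max_bin last unit bin (default 25).
#' @return object of class `"distance_distribution"`: list with `breaks`
#'   (bin labels), `counts`, `freq` (sums to 1), `n`, `mean_dn`, `frac_lt6`.
#' @export
distance_histogram <- function(records, max_bin = 25L) {
  d <- if (is.data.frame(records)) records$d_N else records
  if (length(d) == 0L) stop("no distances to bin")
  stopifnot(all(d >= 1))
  counts <- c(tabulate(pmin(d, max_bin + 1L), nbins = max_bin + 1L))
  names(counts) <- c(as.character(1:max_bin), paste0(">", max_bin))
  structure(list(breaks = names(counts),
                 counts = counts,
                 freq = counts / length(d),
                 n = length(d),
                 mean_dn = mean(d),
                 frac_lt6 = mean(d < 6)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("Nearest-neighbor distance distribution\n")
  cat("  n =", x$n, " mean d_N =", round(x$mean_dn, 2),
      " fraction d_N < 6 =", round(x$frac_lt6, 3), "\n")
  invisible(x)
}

#' Chi-squared test of homogeneity between two binned distributions
#'
#' Pearson chi-squared on the 2 x k count table.  Bins whose expected count
#' under homogeneity falls below `min_expected` in either row are merged into
#' their left neighbor (the first bin into its right neighbor) before
#' testing; the statistic is referred to a chi-squared distribution with
#' k - 1 degrees of freedom for the k bins that remain.
#'
#' @param a,b `"distance_distribution"` objects on identical bins, or raw
#'   count vectors of equal length.
#' @param min_expected expected-count threshold for merging (default 5).
#' @return list with `statistic`, `df`, `p_value`, `k` (bins after merging).
#' @export
chi2_homogeneity <- function(a, b, min_expected = 5) {
  ca <- if (inherits(a, "distance_distribution")) a$counts else a
  cb <- if (inherits(b, "distance_distribution")) b$counts else b
  stopifnot(length(ca) == length(cb), all(ca >= 0), all(cb >= 0))
  merge_once <- function(ca, cb) {
    na <- sum(ca); nb <- sum(cb); N <- na + nb
    p <- (ca + cb) / N
    ea <- na * p; eb <- nb * p
    low <- which(pmin(ea, eb) < min_expected)
    if (length(low) == 0L || length(ca) <= 2L) return(NULL)
    i <- low[1]
    j <- if (i == 1L) 2L else i - 1L
    ca[j] <- ca[j] + ca[i]; cb[j] <- cb[j] + cb[i]
    list(ca = ca[-i], cb = cb[-i])
  }
  repeat {
    m <- merge_once(ca, cb)
    if (is.null(m)) break
    ca <- m$ca; cb <- m$cb
  }
  k <- length(ca)
  if (k < 2L) stop("fewer than 2 bins remain after merging")
  na <- sum(ca); nb <- sum(cb); N <- na + nb
  p <- (ca + cb) / N
  ea <- na * p; eb <- nb * p
  used <- ea > 0
  stat <- sum((ca[used] - ea[used])^2 / ea[used]) +
    sum((cb[used] - eb[used])^2 / eb[used])
  df <- k - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), k = k)
}
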