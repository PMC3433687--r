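# Brute-force reference implementations, deliberately written along different
# algorithmic paths than the package functions they check.

# Nearest-neighbor distances by exhaustive all-pairs search.
oracle_nn <- function(psites, coverage = NULL) {
  rows <- list()
  for (pid in unique(psites$protein_id)) {
    d <- psites[psites$protein_id == pid, ]
    cov <- if (is.null(coverage)) NULL else
      coverage[coverage$protein_id == pid, ]
    for (i in seq_len(nrow(d))) {
      best <- Inf
      for (j in seq_len(nrow(d))) {
        if (i == j) next
        if (!is.null(cov)) {
          together <- any(cov$start <= min(d$position[i], d$position[j]) &
                            max(d$position[i], d$position[j]) < cov$end)
          if (!together) next
        }
        best <- min(best, abs(d$position[i] - d$position[j]))
      }
      if (is.finite(best))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, position = d$position[i],
          residue_class = if (d$residue[i] == "Y") "pY" else "pST",
          d_N = as.integer(best))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue_class = character(0), d_N = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$protein_id, out$position), ]
}

# Maximal gap-constrained runs by enumerating every contiguous slice.
oracle_runs <- function(positions, min_sites = 4L, max_gap = 10L) {
  positions <- sort(unique(positions))
  n <- length(positions)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    run <- positions[i:j]
    if (length(run) > 1L && any(diff(run) > max_gap)) next
    left_max <- i == 1L || positions[i] - positions[i - 1L] > max_gap
    right_max <- j == n || positions[j + 1L] - positions[j] > max_gap
    if (left_max && right_max && length(run) >= min_sites)
      out[[length(out) + 1L]] <- run
  }
  out
}

# Run consolidation via residue mask -> connected components -> pairwise
# merge loop to fixpoint -> S/T/Y filter.
oracle_consolidate <- function(track, sequence, threshold, k = 17L,
                               min_sites = 4L, max_gap = 10L) {
  chars <- strsplit(sequence, "")[[1]]
  pos_starts <- which(!is.na(track) & track > threshold) - 1L
  if (length(pos_starts) == 0L)
    return(data.frame(region_start = integer(0), region_end = integer(0)))
  mask <- rep(FALSE, length(chars))
  for (s in pos_starts) mask[(s + 1L):(s + k)] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  comp <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  # member window starts per component
  members <- lapply(seq_len(nrow(comp)), function(i)
    pos_starts[pos_starts >= comp$start[i] & pos_starts < comp$end[i]])
  repeat {
    merged <- FALSE
    for (a in seq_len(nrow(comp))) {
      for (b in seq_len(nrow(comp))) {
        if (a == b) next
        gap <- min(abs(outer(members[[a]], members[[b]], "-")))
        if (gap <= k) {
          members[[a]] <- sort(c(members[[a]], members[[b]]))
          comp$start[a] <- min(comp$start[a], comp$start[b])
          comp$end[a] <- max(comp$end[a], comp$end[b])
          comp <- comp[-b, , drop = FALSE]
          members[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  keep <- vapply(seq_len(nrow(comp)), function(i) {
    sty <- which(chars[(comp$start[i] + 1L):comp$end[i]] %in%
                   c("S", "T", "Y")) + comp$start[i] - 1L
    length(oracle_runs(sty, min_sites, max_gap)) > 0L
  }, logical(1))
  comp <- comp[keep, , drop = FALSE]
  comp <- comp[order(comp$start), , drop = FALSE]
  rownames(comp) <- NULL
  data.frame(region_start = comp$start, region_end = comp$end)
}

# Overlap counting via explicit residue-set intersection.
oracle_overlap <- function(hot, dis, min_shared = 3L) {
  h_hit <- rep(FALSE, nrow(hot))
  d_hit <- rep(FALSE, nrow(dis))
  for (i in seq_len(nrow(hot))) for (j in seq_len(nrow(dis))) {
    if (hot$protein_id[i] != dis$protein_id[j]) next
    shared <- intersect(seq(hot$start[i], hot$end[i] - 1L),
                        seq(dis$start[j], dis$end[j] - 1L))
    if (length(shared) >= min_shared) {
      h_hit[i] <- TRUE
      d_hit[j] <- TRUE
    }
  }
  c(n_hot = sum(h_hit), n_dis = sum(d_hit))
}

# Naive composition oracle: count monomers and adjacent ordered pairs with an
# environment hash, then normalize by window length.
oracle_composition <- function(window) {
  chars <- strsplit(window, "")[[1]]
  L <- length(chars)
  env <- new.env()
  for (ch in chars) assign(ch, (get0(ch, env, ifnotfound = 0, inherits = FALSE)) + 1, envir = env)
  if (L >= 2L) for (i in 1:(L - 1L)) {
    key <- paste0(chars[i], chars[i + 1L])
    assign(key, (get0(key, env, ifnotfound = 0, inherits = FALSE)) + 1, envir = env)
  }
  out <- stats::setNames(numeric(420), feature_names())
  for (key in ls(env)) out[key] <- get(key, env) / L
  out
}
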