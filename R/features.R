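# 420-dimensional composition encoding: 20 monomer frequencies in fixed
# alphabetical order followed by 400 directed adjacent-dimer frequencies in
# lexicographic order, all normalized by the window length.

#' Canonical names of the 420 composition features
#'
#' Entries 1-20 are the monomers `A..Y` in alphabetical order; entries 21-420
#' the directed dimers `AA, AC, ..., YW, YY` in lexicographic order.  Model
#' portability depends on this ordering; it is frozen.
#'
#' @return character vector of length 420.
#' @export
feature_names <- function() {
  c(AA_ALPHABET, paste0(rep(AA_ALPHABET, each = 20L), AA_ALPHABET))
}

#' Enumerate sliding window segments of a sequence
#'
#' All segments of length `k` at increment `step` (default 1), with their
#' 0-based start offsets.  Sequences shorter than `k` yield no segments, with
#' a warning.
#'
#' @param sequence a single sequence string.
#' @param k segment length (default 17).
#' @param step start increment (default 1).
#' @return data frame with columns `start` (0-based) and `segment`.
#' @export
window_segments <- function(sequence, k = 17L, step = 1L) {
  stopifnot(length(sequence) == 1L, k >= 1L, step >= 1L)
  L <- nchar(sequence)
  if (L < k) {
    warning("sequence length ", L, " < window length ", k, "; no segments")
    return(data.frame(start = integer(0), segment = character(0)))
  }
  starts <- seq.int(0L, L - k, by = step)
  data.frame(start = starts,
             segment = substring(sequence, starts + 1L, starts + k))
}

#' Composition vector of one sequence window
#'
#' Counts of the 20 amino acids and of the 400 directed adjacent dimers
#' (each residue paired only with its C-terminal neighbor, so the counts are
#' asymmetric), all divided by the window length L.  The monomer block sums
#' to 1 and the dimer block to (L-1)/L.
#'
#' @param window a window sequence over the standard 20-letter alphabet.
#' @return named numeric vector of length 420 (see [feature_names()]).
#' @export
composition_vector <- function(window) {
  stopifnot(length(window) == 1L, nchar(window) >= 1L)
  codes <- match(seq_chars(window), AA_ALPHABET)
  if (anyNA(codes))
    stop("window contains non-standard residue(s); windows with ambiguity ",
         "codes are excluded from feature extraction")
  L <- length(codes)
  mono <- tabulate(codes, nbins = 20L)
  dim_counts <- if (L >= 2L)
    tabulate((codes[-L] - 1L) * 20L + codes[-1L], nbins = 400L)
  else integer(400L)
  stats::setNames(c(mono, dim_counts) / L, feature_names())
}

# Feature matrix for all k-windows of one sequence: (L-k+1) x 420, row i for
# 0-based start i-1.  Windows touching an ambiguity code become NA rows.
sequence_feature_matrix <- function(sequence, k = 17L) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < k) return(matrix(numeric(0), 0L, 420L,
                           dimnames = list(NULL, feature_names())))
  codes <- match(chars, AA_ALPHABET)
  pair <- (codes[-L] - 1L) * 20L + codes[-1L]
  n <- L - k + 1L
  out <- matrix(NA_real_, n, 420L, dimnames = list(NULL, feature_names()))
  bad <- is.na(codes)
  for (i in seq_len(n)) {
    idx <- i:(i + k - 1L)
    if (any(bad[idx])) next
    out[i, ] <- c(tabulate(codes[idx], nbins = 20L),
                  tabulate(pair[i:(i + k - 2L)], nbins = 400L)) / k
  }
  out
}

# Feature matrix for a character vector of equal-handling windows (rows may
# be NA when a window carries ambiguity codes and strict = FALSE).
window_feature_matrix <- function(windows, strict = TRUE) {
  out <- matrix(NA_real_, length(windows), 420L,
                dimnames = list(names(windows), feature_names()))
  for (i in seq_along(windows)) {
    v <- tryCatch(composition_vector(windows[i]), error = function(e) NULL)
    if (is.null(v)) {
      if (strict) stop("window ", i, " contains non-standard residues")
    } else out[i, ] <- v
  }
  out
}

#' Serine, threonine and tyrosine frequencies of windows
#'
#' @param windows character vector of window sequences.
#' @return matrix with one row per window and columns `fS`, `fT`, `fY`
#'   (count / window length).
#' @export
sty_frequencies <- function(windows) {
  counts <- vapply(windows, function(w) {
    ch <- seq_chars(w)
    c(sum(ch == "S"), sum(ch == "T"), sum(ch == "Y")) / length(ch)
  }, numeric(3))
  out <- t(counts)
  dimnames(out) <- list(names(windows), c("fS", "fT", "fY"))
  out
}
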