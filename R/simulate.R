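# Seeded synthetic phosphoproteome benchmarks: background proteins with
# planted SR-rich hotspot segments carrying clustered phosphorylation sites
# (short-gap preference, mode at gap 2), isolated background sites, partial
# peptide coverage, and disorder intervals enriched at planted hotspots.

# Typical eukaryotic proteome amino-acid frequencies (fixture choice, not an
# organism-specific claim), order ACDEFGHIKLMNPQRSTVWY.
BACKGROUND_FREQS <- c(A = 0.083, C = 0.014, D = 0.054, E = 0.067, F = 0.039,
                      G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.096,
                      M = 0.024, N = 0.040, P = 0.047, Q = 0.039, R = 0.055,
                      S = 0.066, T = 0.053, V = 0.068, W = 0.011, Y = 0.029)

# Hotspot-segment composition: strongly elevated S, R, P (and some Y/G/D/E),
# emulating the SR/RS-rich windows dominating the experimental hotspot set.
HOTSPOT_FREQS <- c(A = 0.020, C = 0.002, D = 0.050, E = 0.050, F = 0.008,
                   G = 0.050, H = 0.010, I = 0.008, K = 0.030, L = 0.015,
                   M = 0.005, N = 0.010, P = 0.120, Q = 0.015, R = 0.220,
                   S = 0.280, T = 0.040, V = 0.015, W = 0.002, Y = 0.050)

# Minority hotspot theme: threonine/tyrosine-driven clusters with ordinary
# serine content.  The experimental hotspot set is not uniformly SR-rich --
# a minority of windows carry few serines and sites on T/Y, which is what
# keeps the per-type frequency floors of the positive set low.
HOTSPOT_FREQS_TY <- c(A = 0.040, C = 0.005, D = 0.070, E = 0.070, F = 0.020,
                      G = 0.080, H = 0.020, I = 0.020, K = 0.060, L = 0.040,
                      M = 0.010, N = 0.030, P = 0.100, Q = 0.030, R = 0.080,
                      S = 0.060, T = 0.140, V = 0.030, W = 0.005, Y = 0.090)

#' Specification of a synthetic phosphoproteome
#'
#' The defaults define the benchmark conditions used throughout the test
#' suite: 200 proteins with log-normal lengths (median about 300 residues),
#' 50 planted SR-rich hotspot segments with strong compositional contrast to
#' the background, clustered sites whose gap distribution peaks at 2,
#' sparse isolated background sites, about 70% peptide coverage, and
#' disorder intervals enriched at planted hotspots.
#'
#' @param n_proteins number of proteins.
#' @param length_meanlog,length_sdlog log-normal protein-length parameters.
#' @param min_length minimum protein length.
#' @param background_freqs,hotspot_freqs amino-acid frequency tables
#'   (normalized internally).
#' @param hotspot_freqs_ty minority-theme (T/Y-driven) frequency table.
#' @param ty_theme_prob probability that a planted hotspot follows the
#'   minority theme instead of the SR-rich one (default 0.2).
#' @param dimer_prob probability of emitting a favored dimer (from
#'   `favored_dimers`) instead of a single residue while growing a hotspot
#'   segment; creates the RS/SR/SP adjacency bias.  Applies to the SR-rich
#'   theme only.
#' @param favored_dimers character vector of dimers.
#' @param n_hotspots number of planted hotspots (at most one per protein).
#' @param hotspot_len_range segment length range.
#' @param n_sites_range planted sites per hotspot.
#' @param gap_probs categorical distribution over site gaps 1..10 (mode 2).
#' @param background_site_rate per-S/T/Y probability of an isolated
#'   background site.
#' @param coverage_fraction target covered fraction per protein.
#' @param coverage_mean_len mean covered-segment length.
#' @param hotspot_disorder_prob probability that a planted hotspot receives
#'   a disorder interval (enrichment over background).
#' @param background_disorder_rate expected background disorder intervals
#'   per protein.
#' @param disorder_mean_len mean disorder-interval length.
#' @return list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_proteins = 200L,
                            length_meanlog = log(300), length_sdlog = 0.35,
                            min_length = 60L,
                            background_freqs = BACKGROUND_FREQS,
                            hotspot_freqs = HOTSPOT_FREQS,
                            hotspot_freqs_ty = HOTSPOT_FREQS_TY,
                            ty_theme_prob = 0.2,
                            dimer_prob = 0.35,
                            favored_dimers = c("RS", "SR", "SP"),
                            n_hotspots = 50L,
                            hotspot_len_range = c(17L, 40L),
                            n_sites_range = c(4L, 8L),
                            gap_probs = c(0.14, 0.30, 0.16, 0.10, 0.08,
                                          0.06, 0.05, 0.04, 0.04, 0.03),
                            background_site_rate = 0.005,
                            coverage_fraction = 0.7,
                            coverage_mean_len = 150L,
                            hotspot_disorder_prob = 0.7,
                            background_disorder_rate = 0.5,
                            disorder_mean_len = 40L) {
  stopifnot(n_proteins >= 1, n_hotspots >= 0, n_hotspots <= n_proteins,
            length(gap_probs) == 10L, all(gap_probs >= 0),
            background_site_rate >= 0, background_site_rate <= 1,
            coverage_fraction >= 0, coverage_fraction <= 1,
            hotspot_disorder_prob >= 0, hotspot_disorder_prob <= 1,
            hotspot_len_range[1] >= 17L,
            n_sites_range[1] >= 4L)
  if (hotspot_len_range[2] >= exp(length_meanlog + 3 * length_sdlog))
    stop("hotspot segments longer than essentially every protein; ",
         "infeasible spec")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 background_freqs = background_freqs / sum(background_freqs),
                 hotspot_freqs = hotspot_freqs / sum(hotspot_freqs),
                 hotspot_freqs_ty = hotspot_freqs_ty / sum(hotspot_freqs_ty),
                 ty_theme_prob = ty_theme_prob,
                 dimer_prob = dimer_prob, favored_dimers = favored_dimers,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_len_range = as.integer(hotspot_len_range),
                 n_sites_range = as.integer(n_sites_range),
                 gap_probs = gap_probs / sum(gap_probs),
                 background_site_rate = background_site_rate,
                 coverage_fraction = coverage_fraction,
                 coverage_mean_len = as.integer(coverage_mean_len),
                 hotspot_disorder_prob = hotspot_disorder_prob,
                 background_disorder_rate = background_disorder_rate,
                 disorder_mean_len = as.integer(disorder_mean_len)),
            class = "simulation_spec")
}

# Grow one hotspot segment of exactly `len` residues.  The SR theme mixes
# favored dimers into the draw; the T/Y theme samples its table directly.
grow_hotspot_segment <- function(spec, len, theme = c("sr", "ty")) {
  theme <- match.arg(theme)
  if (theme == "ty")
    return(sample(names(spec$hotspot_freqs_ty), len, replace = TRUE,
                  prob = spec$hotspot_freqs_ty))
  out <- character(0)
  while (length(out) < len) {
    if (stats::runif(1) < spec$dimer_prob) {
      d <- spec$favored_dimers[sample.int(length(spec$favored_dimers), 1L)]
      out <- c(out, seq_chars(d))
    } else {
      out <- c(out, sample(names(spec$hotspot_freqs), 1L,
                           prob = spec$hotspot_freqs))
    }
  }
  out[seq_len(len)]
}

# Plant clustered sites on the S/T/Y positions of a segment (0-based local
# coordinates).  Walks the S/T/Y positions taking gaps drawn from
# spec$gap_probs, snapped to the nearest available S/T/Y at distance <= 10.
# Returns NULL if fewer than n_sites can be placed.
plant_sites <- function(chars, spec, n_sites) {
  sty <- which(chars %in% c("S", "T", "Y")) - 1L
  if (length(sty) < n_sites) return(NULL)
  cur <- sty[1]
  sites <- cur
  while (length(sites) < n_sites) {
    g <- sample.int(10L, 1L, prob = spec$gap_probs)
    cand <- sty[sty > cur & sty <= cur + 10L]
    if (length(cand) == 0L) return(NULL)
    nxt <- cand[which.min(abs(cand - (cur + g)))]
    sites <- c(sites, nxt)
    cur <- nxt
  }
  sites
}

# Coverage segments for one protein: random segments until the covered
# fraction is reached, then merged.
draw_coverage <- function(L, spec) {
  covered <- 0L
  segs <- list()
  guard <- 0L
  while (covered < spec$coverage_fraction * L && guard < 200L) {
    guard <- guard + 1L
    len <- min(L, max(17L, stats::rgeom(1, 1 / spec$coverage_mean_len) + 17L))
    s <- sample.int(L - len + 1L, 1L) - 1L
    segs[[length(segs) + 1L]] <- c(s, s + len)
    m <- merge_intervals(vapply(segs, `[`, numeric(1), 1L),
                         vapply(segs, `[`, numeric(1), 2L))
    covered <- sum(m$end - m$start)
  }
  if (length(segs) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  merge_intervals(vapply(segs, `[`, numeric(1), 1L),
                  vapply(segs, `[`, numeric(1), 2L))
}

#' Generate a synthetic phosphoproteome dataset
#'
#' Draws a seeded dataset under a [simulation_spec()]: proteome, site table,
#' coverage and disorder intervals, plus the ground truth of every planted
#' hotspot.  Planted hotspots satisfy the detection definition (at least 4
#' sites on S/T/Y, neighbor gaps at most 10) by construction, and their
#' windows are always peptide-covered.  The same seed reproduces the dataset
#' byte for byte.
#'
#' @param spec a `"simulation_spec"`.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return list with data frames `proteome`, `psites`, `coverage`,
#'   `disorder`, `truth` (planted hotspots: `protein_id`, `core_start`,
#'   `core_end`, `window_start`, `window_end`, `site_positions`), and the
#'   `spec`.
#' @export
simulate_dataset <- function(spec = simulation_spec(), seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  lens <- pmax(spec$min_length,
               round(stats::rlnorm(spec$n_proteins, spec$length_meanlog,
                                   spec$length_sdlog)))
  ids <- sprintf("SYN%04dP.1", seq_len(spec$n_proteins))
  seqs <- lapply(lens, function(L)
    sample(names(spec$background_freqs), L, replace = TRUE,
           prob = spec$background_freqs))
  hot_proteins <- if (spec$n_hotspots > 0L)
    sort(sample.int(spec$n_proteins, spec$n_hotspots)) else integer(0)
  truth <- list()
  psite_rows <- list()
  for (p in hot_proteins) {
    L <- lens[p]
    theme <- if (stats::runif(1) < spec$ty_theme_prob) "ty" else "sr"
    repeat {
      hl <- sample(spec$hotspot_len_range[1]:spec$hotspot_len_range[2], 1L)
      ns <- sample(spec$n_sites_range[1]:spec$n_sites_range[2], 1L)
      seg <- grow_hotspot_segment(spec, hl, theme)
      local_sites <- plant_sites(seg, spec, ns)
      if (!is.null(local_sites)) break
    }
    at <- sample.int(L - hl + 1L, 1L) - 1L # 0-based insertion offset
    seqs[[p]][(at + 1L):(at + hl)] <- seg
    sites <- at + local_sites
    w <- pad_hotspot(sites[1], sites[length(sites)], L)
    truth[[length(truth) + 1L]] <- data.frame(
      protein_id = ids[p], core_start = sites[1],
      core_end = sites[length(sites)], window_start = w[1], window_end = w[2],
      site_positions = paste(sites, collapse = ","))
    psite_rows[[length(psite_rows) + 1L]] <- data.frame(
      protein_id = ids[p], position = sites,
      residue = seqs[[p]][sites + 1L])
  }
  # isolated background sites
  for (p in seq_len(spec$n_proteins)) {
    chars <- seqs[[p]]
    sty <- which(chars %in% c("S", "T", "Y")) - 1L
    if (p %in% hot_proteins) {
      tw <- truth[[match(p, hot_proteins)]]
      sty <- sty[sty < tw$window_start | sty >= tw$window_end]
    }
    flag <- sty[stats::runif(length(sty)) < spec$background_site_rate]
    if (length(flag))
      psite_rows[[length(psite_rows) + 1L]] <- data.frame(
        protein_id = ids[p], position = flag, residue = chars[flag + 1L])
  }
  # coverage: random segments, plus the planted windows (experimentally
  # observed hotspots are by definition peptide-covered)
  cov_rows <- list()
  for (p in seq_len(spec$n_proteins)) {
    segs <- draw_coverage(lens[p], spec)
    if (p %in% hot_proteins) {
      tw <- truth[[match(p, hot_proteins)]]
      segs <- merge_intervals(c(segs$start, tw$window_start),
                              c(segs$end, tw$window_end))
    }
    if (nrow(segs))
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        protein_id = ids[p], start = as.integer(segs$start),
        end = as.integer(segs$end))
  }
  # disorder: enriched at planted hotspots, sparse elsewhere
  dis_rows <- list()
  for (p in seq_len(spec$n_proteins)) {
    L <- lens[p]
    if (p %in% hot_proteins &&
        stats::runif(1) < spec$hotspot_disorder_prob) {
      tw <- truth[[match(p, hot_proteins)]]
      ext <- max(0L, (spec$disorder_mean_len -
                        (tw$window_end - tw$window_start)) %/% 2L)
      dis_rows[[length(dis_rows) + 1L]] <- data.frame(
        protein_id = ids[p], start = max(0L, tw$window_start - ext),
        end = min(L, tw$window_end + ext))
    }
    nbg <- stats::rpois(1, spec$background_disorder_rate)
    for (i in seq_len(nbg)) {
      len <- min(L, max(17L, stats::rgeom(1, 1 / spec$disorder_mean_len) + 17L))
      s <- sample.int(L - len + 1L, 1L) - 1L
      dis_rows[[length(dis_rows) + 1L]] <- data.frame(
        protein_id = ids[p], start = s, end = s + len)
    }
  }
  proteome <- data.frame(id = ids,
                         sequence = vapply(seqs, paste, character(1),
                                           collapse = ""))
  psites <- if (length(psite_rows)) do.call(rbind, psite_rows) else
    data.frame(protein_id = character(0), position = integer(0),
               residue = character(0))
  psites <- validate_psites(psites, proteome)
  coverage <- normalize_intervals(do.call(rbind, cov_rows), proteome)
  disorder <- if (length(dis_rows))
    normalize_intervals(do.call(rbind, dis_rows), proteome) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0))
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(protein_id = character(0), core_start = integer(0),
               core_end = integer(0), window_start = integer(0),
               window_end = integer(0), site_positions = character(0))
  list(proteome = proteome, psites = psites, coverage = coverage,
       disorder = disorder, truth = truth_df, spec = spec)
}

#' Write a simulated dataset to an output directory
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if missing).
#' @return named vector of the written file paths, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteome = file.path(outdir, "proteome.fasta"),
             psites = file.path(outdir, "psites.tsv"),
             coverage = file.path(outdir, "coverage.tsv"),
             disorder = file.path(outdir, "disorder.tsv"),
             truth = file.path(outdir, "truth_hotspots.tsv"))
  write_fasta(sim$proteome, paths["proteome"])
  write_psites(sim$psites, paths["psites"])
  write_intervals(sim$coverage, paths["coverage"])
  write_intervals(sim$disorder, paths["disorder"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Compositional contrast between planted hotspots and background
#'
#' L1 distance between the mean monomer composition (20 frequencies) of the
#' planted hotspot windows and that of an equal number of random background
#' windows, used to calibrate parameter-recovery expectations: 0 means
#' indistinguishable composition, 2 is the maximum (disjoint alphabets).
#'
#' @param sim result of [simulate_dataset()].
#' @param k window length for the background sample (default 17).
#' @return list with `l1_monomer`, `n_hotspot_windows`,
#'   `n_background_windows`.
#' @export
contrast_report <- function(sim, k = 17L) {
  tr <- sim$truth
  if (nrow(tr) == 0L) stop("no planted hotspots in this dataset")
  seqs <- proteome_lookup(sim$proteome)
  hw <- substring(seqs[tr$protein_id], tr$window_start + 1L, tr$window_end)
  hx <- window_feature_matrix(hw, strict = FALSE)[, 1:20, drop = FALSE]
  # background windows away from planted hotspots
  bg <- list()
  guard <- 0L
  while (length(bg) < nrow(tr) && guard < 50L * nrow(tr)) {
    guard <- guard + 1L
    p <- sample.int(nrow(sim$proteome), 1L)
    pid <- sim$proteome$id[p]
    L <- nchar(seqs[[pid]])
    if (L < k) next
    s <- sample.int(L - k + 1L, 1L) - 1L
    tw <- tr[tr$protein_id == pid, , drop = FALSE]
    if (nrow(tw) && s + k > tw$window_start[1] && s < tw$window_end[1]) next
    bg[[length(bg) + 1L]] <- substring(seqs[[pid]], s + 1L, s + k)
  }
  bx <- window_feature_matrix(unlist(bg), strict = FALSE)[, 1:20, drop = FALSE]
  l1 <- sum(abs(colMeans(hx, na.rm = TRUE) - colMeans(bx, na.rm = TRUE)))
  list(l1_monomer = l1, n_hotspot_windows = nrow(hx),
       n_background_windows = nrow(bx))
}
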