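scan_model <- local({
  set.seed(801)
  labeled <- separable_windows(n_groups = 8, per_group = 3)
  train_svm(labeled)
})

test_that("score tracks have one score per window start and ignore batch order", {
  prot <- data.frame(id = c("A1.1", "B2.1"),
                     sequence = c(strrep("S", 17),
                                  paste(rep(AA20, 5), collapse = "")))
  tr <- score_proteome(scan_model, prot)
  expect_length(tr[["A1.1"]], 1L)
  expect_length(tr[["B2.1"]], 100L - 17L + 1L)
  # shuffled protein order yields identical per-protein tracks
  tr2 <- score_proteome(scan_model, prot[2:1, ])
  expect_equal(tr[["A1.1"]], tr2[["A1.1"]])
  expect_equal(tr[["B2.1"]], tr2[["B2.1"]])
  # too-short protein: empty track
  short <- data.frame(id = "S1.1", sequence = strrep("A", 10))
  expect_length(score_proteome(scan_model, short)[["S1.1"]], 0L)
})

test_that("ambiguity-code windows carry missing scores", {
  prot <- data.frame(id = "X1.1",
                     sequence = paste0(strrep("S", 20), "X", strrep("S", 20)))
  tr <- score_proteome(scan_model, prot)[["X1.1"]]
  expect_true(any(is.na(tr)))
  expect_true(any(!is.na(tr)))
})

test_that("the residue mask gives positive windows precedence", {
  track <- rep(-1, 40)
  track[11] <- 2 # window start 10 (0-based)
  mask <- positive_residues(track, threshold = 0)
  expect_equal(which(mask) - 1L, 10:26)
  expect_equal(sum(positive_residues(rep(-1, 40), 0)), 0L)
})

test_that("consolidation spans, merging, and the S/T/Y filter follow the rules", {
  seqc <- strrep("S", 80)
  # consecutive starts 10,11,12 -> one run [10, 29)
  track <- rep(-2, 64)
  track[c(11, 12, 13)] <- 2
  runs <- consolidate_runs(track, seqc, threshold = 0)
  expect_equal(runs$region_start, 10L)
  expect_equal(runs$region_end, 29L)
  # starts 10 and 27 differ by exactly 17 -> merged
  track2 <- rep(-2, 64)
  track2[c(11, 28)] <- 2
  runs2 <- consolidate_runs(track2, seqc, threshold = 0)
  expect_equal(nrow(runs2), 1L)
  expect_equal(c(runs2$region_start, runs2$region_end), c(10L, 44L))
  # starts 10 and 28 differ by 18 -> separate runs
  track3 <- rep(-2, 64)
  track3[c(11, 29)] <- 2
  expect_equal(nrow(consolidate_runs(track3, seqc, threshold = 0)), 2L)
  # a positive run over poly-alanine is discarded by the S/T/Y filter
  polyA <- strrep("A", 80)
  expect_equal(nrow(consolidate_runs(track, polyA, threshold = 0)), 0L)
})

test_that("consolidation matches the mask/component/merge oracle on random tracks", {
  set.seed(802)
  for (rep in 1:500) {
    L <- sample(40:120, 1)
    seqc <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    track <- stats::rnorm(L - 16L, mean = -0.8)
    got <- consolidate_runs(track, seqc, threshold = 0)
    want <- oracle_consolidate(track, seqc, threshold = 0)
    expect_equal(got[, c("region_start", "region_end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("runs are disjoint and threshold-1 positives refine threshold-0 positives", {
  set.seed(803)
  for (rep in 1:50) {
    L <- sample(60:150, 1)
    seqc <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    track <- stats::rnorm(L - 16L, mean = 0)
    runs <- consolidate_runs(track, seqc, threshold = 0)
    if (nrow(runs) > 1L)
      expect_true(all(runs$region_start[-1] > runs$region_end[-nrow(runs)]))
    # every window positive at threshold 1 is positive at threshold 0
    expect_true(all(which(track > 1) %in% which(track > 0)))
    m1 <- positive_residues(track, 1, protein_length = L)
    m0 <- positive_residues(track, 0, protein_length = L)
    expect_true(all(!m1 | m0))
  }
})

test_that("scan summaries count windows, runs, proteins, and genes", {
  prot <- data.frame(id = c("AT1G01540.1", "AT1G01540.2"),
                     sequence = rep(strrep("S", 40), 2))
  tracks <- structure(list(`AT1G01540.1` = rep(2, 24),
                           `AT1G01540.2` = rep(2, 24)),
                      class = "score_track")
  runs <- consolidate_runs(tracks, prot, threshold = 1)
  s <- summarize_scan(runs, tracks, threshold = 1)
  expect_equal(s$n_windows, 48L)
  expect_equal(s$n_positive, 48L)
  expect_equal(s$n_hotspots, 2L)
  expect_equal(s$n_proteins, 2L)
  expect_equal(s$n_genes, 1L) # isoforms collapse to one gene
  empty <- summarize_scan(runs[0, ], structure(list(), class = "score_track"), 1)
  expect_equal(empty$n_hotspots, 0L)
  expect_equal(empty$n_windows, 0L)
})
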