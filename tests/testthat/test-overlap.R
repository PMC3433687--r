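test_that("interval length filtering keeps the 17-residue boundary", {
  iv <- data.frame(protein_id = "P1",
                   start = c(0L, 0L, 5L), end = c(16L, 17L, 40L))
  kept <- filter_intervals(iv)
  expect_equal(nrow(kept), 2L)
  expect_false(any(kept$end - kept$start < 17L))
})

test_that("overlap requires at least three shared consecutive residues", {
  hs <- data.frame(protein_id = "P1", window_start = 10L, window_end = 27L,
                   n_sites = 4L, site_positions = "11,13,15,17")
  yes <- data.frame(protein_id = "P1", start = 24L, end = 50L) # shares 3
  no <- data.frame(protein_id = "P1", start = 25L, end = 50L)  # shares 2
  expect_equal(count_overlaps(hs, yes)$n_hotspots_overlapping, 1L)
  expect_equal(count_overlaps(hs, no)$n_hotspots_overlapping, 0L)
  # symmetric at the pair level
  expect_equal(count_overlaps(yes, hs)$n_hotspots_overlapping, 1L)
})

test_that("a hotspot spanning two separated intervals counts once, intervals twice", {
  hs <- data.frame(protein_id = "P1", start = 0L, end = 60L)
  dis <- data.frame(protein_id = "P1", start = c(5L, 40L), end = c(15L, 55L))
  res <- count_overlaps(hs, dis)
  expect_equal(res$n_hotspots_overlapping, 1L)
  expect_equal(res$n_intervals_overlapping, 2L)
})

test_that("overlap counting matches the residue-set intersection oracle", {
  set.seed(901)
  for (rep in 1:500) {
    nh <- sample(1:6, 1); nd <- sample(1:6, 1)
    pids <- c("P1", "P2")
    mk <- function(n) {
      s <- sample(0:80, n, replace = TRUE)
      data.frame(protein_id = sample(pids, n, replace = TRUE),
                 start = s, end = s + sample(3:30, n, replace = TRUE))
    }
    hot <- mk(nh); dis <- mk(nd)
    got <- count_overlaps(hot, dis)
    want <- oracle_overlap(hot, dis)
    expect_equal(got$n_hotspots_overlapping, unname(want["n_hot"]))
    expect_equal(got$n_intervals_overlapping, unname(want["n_dis"]))
  }
})

test_that("random placement conserves lengths and handles forced/saturated cases", {
  # one protein exactly the hotspot length: placement forced at 0
  prot <- data.frame(id = "P1", sequence = strrep("A", 17))
  hs <- data.frame(protein_id = "P1", start = 0L, end = 17L)
  dis_all <- data.frame(protein_id = "P1", start = 0L, end = 17L)
  set.seed(902)
  r <- randomize_placement(hs, prot, dis_all, repeats = 5)
  expect_equal(r$counts, rep(1L, 5))
  expect_equal(r$mean_fraction, 1)
  # disorder covering everything saturates the fraction at 1
  prot2 <- data.frame(id = paste0("Q", 1:5, ".1"),
                      sequence = rep(strrep("A", 100), 5))
  dis2 <- data.frame(protein_id = prot2$id, start = 0L, end = 100L)
  hs2 <- data.frame(protein_id = prot2$id[1:3],
                    start = c(0L, 20L, 50L), end = c(20L, 40L, 70L))
  r2 <- randomize_placement(hs2, prot2, dis2, repeats = 5)
  expect_equal(r2$mean_fraction, 1)
  # impossible placement errors out
  long_hs <- data.frame(protein_id = "Q1.1", start = 0L, end = 300L)
  expect_error(randomize_placement(long_hs, prot2, dis2), "longer")
})

test_that("randomized overlap tracks the analytic uniform-placement expectation", {
  # 20 proteins of length 100, disorder on [0, 50) of each; a 17-mer placed
  # uniformly overlaps (>= 3 shared) iff its start <= 47: p = 48/84
  set.seed(903)
  prot <- data.frame(id = sprintf("U%02d.1", 1:20),
                     sequence = rep(strrep("A", 100), 20))
  dis <- data.frame(protein_id = prot$id, start = 0L, end = 50L)
  hs <- data.frame(protein_id = prot$id[1:10], start = 10L, end = 27L)
  r <- randomize_placement(hs, prot, dis, repeats = 50)
  p <- 48 / 84
  se <- sqrt(10 * p * (1 - p)) / sqrt(50) / 10
  expect_lt(abs(r$mean_fraction - p), 3 * se + 0.02)
})

test_that("enriched synthetic disorder yields observed overlap above the null", {
  sim <- simulate_dataset(simulation_spec(n_proteins = 80, n_hotspots = 30),
                          seed = 904)
  dis <- filter_intervals(sim$disorder)
  obs <- count_overlaps(sim$truth, dis)$n_hotspots_overlapping
  rnd <- randomize_placement(sim$truth, sim$proteome, dis, repeats = 10)
  expect_gt(obs, rnd$mean)
})
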