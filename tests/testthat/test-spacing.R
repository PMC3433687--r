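test_that("nearest-neighbor distances match direct expectations", {
  sim <- protein_with_sites(150, c(102L, 106L, 107L, 110L))
  nn <- nearest_neighbor_distances(sim$psites, full_coverage(sim$proteome))
  expect_equal(nn$d_N, c(4L, 1L, 1L, 3L))
  expect_true(all(nn$residue_class == "pST"))

  # single-site proteins contribute nothing
  one <- protein_with_sites(50, 10L)
  expect_equal(nrow(nearest_neighbor_distances(one$psites,
                                               full_coverage(one$proteome))), 0L)
})

test_that("sites split across coverage intervals are excluded", {
  sim <- protein_with_sites(100, c(10L, 60L))
  cov <- data.frame(protein_id = "P1", start = c(0L, 50L), end = c(30L, 90L))
  expect_equal(nrow(nearest_neighbor_distances(sim$psites, cov)), 0L)
  # but one shared interval keeps them
  cov2 <- data.frame(protein_id = "P1", start = 0L, end = 90L)
  expect_equal(nearest_neighbor_distances(sim$psites, cov2)$d_N, c(50L, 50L))
})

test_that("nearest-neighbor distances match the all-pairs oracle", {
  set.seed(501)
  for (rep in 1:500) {
    n <- sample(2:10, 1)
    pos <- sort(sample(0:199, n))
    sim <- protein_with_sites(200, pos,
                              residues = sample(c("S", "T", "Y"), n, TRUE))
    cov <- if (rep %% 2 == 0) full_coverage(sim$proteome) else {
      # two random covered segments
      s1 <- sort(sample(0:100, 2)); s2 <- sort(sample(101:200, 2))
      normalize_intervals(data.frame(protein_id = "P1",
                                     start = c(s1[1], s2[1]),
                                     end = c(s1[2] + 1L, s2[2] + 1L)))
    }
    got <- nearest_neighbor_distances(sim$psites, cov)
    want <- oracle_nn(sim$psites, cov)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("P-flag randomization conserves per-type counts and the sequence", {
  set.seed(502)
  sim <- protein_with_sites(300, c(10L, 20L, 30L, 40L, 55L),
                            residues = c("S", "S", "T", "Y", "S"))
  for (rep in 1:20) {
    r <- pflag_randomize(sim$psites, sim$proteome)
    expect_equal(table(r$residue), table(sim$psites$residue))
    # flags still sit on matching residues of the unchanged sequence
    expect_silent(validate_psites(r, sim$proteome))
  }
})

test_that("P-flag reassignment is uniform over same-type positions", {
  # protein made of 20 S residues, 5 flags: each position should be picked
  # with probability 1/4 across repeats (3-sigma binomial band, fixed seed)
  set.seed(503)
  prot <- data.frame(id = "P1", sequence = strrep("S", 20))
  ps <- data.frame(protein_id = "P1", position = 0:4, residue = "S")
  nrep <- 1000
  hits <- integer(20)
  for (i in seq_len(nrep)) {
    r <- pflag_randomize(ps, prot)
    hits[r$position + 1L] <- hits[r$position + 1L] + 1L
  }
  p <- 5 / 20
  sigma <- sqrt(p * (1 - p) / nrep)
  expect_true(all(abs(hits / nrep - p) < 3 * sigma))
})

test_that("P-flag randomization errors when flags exceed available positions", {
  # an S flag whose region contains no S position at all cannot be reassigned
  expect_error(pflag_randomize(
    data.frame(protein_id = "P1", position = 0L, residue = "S"),
    data.frame(id = "P1", sequence = "AAAAA")), "positions")
  # zero flags yield an empty site table
  prot <- data.frame(id = "P1", sequence = "SSSS")
  empty_sites <- data.frame(protein_id = character(0), position = integer(0),
                            residue = character(0))
  expect_equal(nrow(pflag_randomize(empty_sites, prot)), 0L)
})

test_that("sequence randomization conserves composition and flag count", {
  set.seed(504)
  sim <- protein_with_sites(200, c(5L, 9L, 11L, 40L))
  for (rep in 1:20) {
    r <- sequence_randomize(sim$psites, sim$proteome)
    expect_equal(sort(strsplit(r$proteome$sequence, "")[[1]]),
                 sort(strsplit(sim$proteome$sequence, "")[[1]]))
    expect_equal(nrow(r$psites), nrow(sim$psites))
    expect_silent(validate_psites(r$psites, r$proteome))
  }
  # single-residue region is the identity
  tiny <- list(proteome = data.frame(id = "P1", sequence = "S"),
               psites = data.frame(protein_id = "P1", position = 0L,
                                   residue = "S"))
  r <- sequence_randomize(tiny$psites, tiny$proteome)
  expect_equal(r$proteome$sequence, "S")
  expect_equal(r$psites$position, 0L)
})

test_that("distance histograms normalize and locate the clustered peak", {
  h1 <- distance_histogram(rep(1L, 10))
  expect_equal(unname(h1$freq[1]), 1)
  expect_equal(sum(h1$freq), 1)

  set.seed(505)
  mixed <- distance_histogram(sample(1:40, 500, replace = TRUE))
  expect_equal(sum(mixed$freq), 1, tolerance = 1e-9)

  # clustered synthetic data: pooled d_N peaks at the generator's modal gap 2
  sim <- simulate_dataset(simulation_spec(n_proteins = 60, n_hotspots = 30),
                          seed = 506)
  nn <- nearest_neighbor_distances(sim$psites, sim$coverage)
  h <- distance_histogram(nn)
  expect_equal(names(which.max(h$freq)), "2")
  expect_error(distance_histogram(integer(0)), "no distances")
})

test_that("the homogeneity test matches hand-computed cases", {
  same <- chi2_homogeneity(c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- chi2_homogeneity(c(10, 0), c(0, 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, 7.744216e-06, tolerance = 1e-6)

  # low-expectation bins get merged before testing
  merged <- chi2_homogeneity(c(100, 100, 1), c(100, 100, 2))
  expect_equal(merged$k, 2L)
})
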