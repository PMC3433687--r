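test_that("positive-set sizes follow the step-1 segmentation arithmetic", {
  mk <- function(len) data.frame(hotspot_id = paste0("h", len),
                                 window_sequence = strrep("S", len),
                                 window_start = 0L)
  expect_equal(nrow(build_positive_set(mk(17))), 1L)
  expect_equal(nrow(build_positive_set(mk(71))), 55L)
})

test_that("S/T/Y floors are per-type minima over the positive windows", {
  pos <- data.frame(window = c(paste0("SS", strrep("A", 15)),
                               paste0("SSSSS", strrep("A", 12))),
                    label = "positive", group_id = c("h1", "h2"), start = 0L)
  fl <- sty_floors(pos)
  expect_equal(unname(fl["minS"]), 2 / 17)
  expect_equal(unname(fl["minT"]), 0)
  # single window: floors equal its frequencies
  fl1 <- sty_floors(pos[1, ])
  expect_equal(unname(fl1), unname(sty_frequencies(pos$window[1])[1, ]))
})

test_that("negatives tile covered regions, avoid hotspots, and satisfy floors", {
  set.seed(701)
  sim <- simulate_dataset(simulation_spec(n_proteins = 40, n_hotspots = 12),
                          seed = 701)
  hs <- detect_hotspots(sim$psites, sim$proteome)
  pos <- build_positive_set(hs)
  floors <- sty_floors(pos)
  neg <- suppressWarnings(
    build_negative_set(sim$proteome, sim$coverage, hs, floors,
                       n_positives = nrow(pos)))
  expect_true(all(nchar(neg$window) == 17L))
  expect_lte(nrow(neg), 8L * nrow(pos))
  # floor re-check oracle
  f <- sty_frequencies(neg$window)
  expect_true(all(f[, "fS"] >= floors[["minS"]]))
  expect_true(all(f[, "fT"] >= floors[["minT"]]))
  expect_true(all(f[, "fY"] >= floors[["minY"]]))
  # no negative window overlaps a hotspot window on the same protein
  neg_pid <- sub(":.*$", "", neg$group_id)
  for (i in seq_len(nrow(neg))) {
    h <- hs[hs$protein_id == neg_pid[i], ]
    if (nrow(h) == 0) next
    expect_true(all(neg$start[i] + 17L <= h$window_start |
                      neg$start[i] >= h$window_end))
  }
})

test_that("grouped folds keep hotspots intact and conserve the class ratio", {
  set.seed(702)
  labeled <- separable_windows(n_groups = 15, per_group = 4)
  # inflate negatives to an 8:1 ratio
  neg <- labeled[labeled$label == "negative", ]
  extra <- do.call(rbind, replicate(7, neg, simplify = FALSE))
  extra$group_id <- paste0(extra$group_id, "_", rep(1:7, each = nrow(neg)))
  labeled <- rbind(labeled, extra)
  fold <- make_group_folds(labeled, folds = 5L)
  for (f in 1:5) {
    test_groups <- unique(labeled$group_id[fold == f])
    train_groups <- unique(labeled$group_id[fold != f])
    expect_length(intersect(test_groups, train_groups), 0L)
    npos <- sum(labeled$label[fold != f] == "positive")
    nneg <- sum(labeled$label[fold != f] == "negative")
    expect_gt(nneg / npos, 6.5)
    expect_lt(nneg / npos, 9.5)
  }
})

test_that("the SVM separates well-separated classes and scores deterministically", {
  set.seed(703)
  labeled <- separable_windows(n_groups = 8, per_group = 3)
  X <- hotspotter:::window_feature_matrix(labeled$window)
  model <- train_svm(X, labeled$label, params = list(C = 1, gamma = 4, j = 8))
  s <- decision_scores(model, X)
  expect_true(all((s > 0) == (labeled$label == "positive")))
  # identical rows receive identical scores
  expect_equal(decision_scores(model, X[c(1, 1), , drop = FALSE]),
               rep(s[1], 2))
  expect_error(train_svm(X, rep("positive", nrow(X))), "both classes")
})

test_that("grouped cross-validation is perfect on separable data and the singleton grid returns itself", {
  set.seed(704)
  labeled <- separable_windows(n_groups = 10, per_group = 4)
  cv <- cross_validate(labeled, params = list(C = 1, gamma = 4, j = 8))
  expect_equal(cv$pooled$TPR, 1)
  expect_equal(cv$pooled$FPR, 0)
  expect_equal(cv$mean_F, 1)

  gs <- grid_search(labeled, grids = list(C = 1, gamma = 4, j = 8))
  expect_equal(gs$best, list(C = 1, gamma = 4, j = 8))
  expect_equal(nrow(gs$table), 1L)
  expect_equal(gs$best_F, 1)
})

test_that("the default grids span the full exhaustive search space", {
  cfg <- run_config()
  expect_equal(length(cfg$grid_C), 35L)
  expect_equal(length(cfg$grid_gamma), 17L)
  expect_equal(length(cfg$grid_j), 7L)
  combos <- expand.grid(cfg$grid_C, cfg$grid_gamma, cfg$grid_j)
  expect_equal(nrow(combos), 4165L)
})

test_that("label permutation destroys cross-validated skill", {
  set.seed(705)
  labeled <- separable_windows(n_groups = 8, per_group = 3)
  base_rate <- mean(labeled$label == "positive")
  fs <- replicate(10, {
    perm <- labeled
    perm$label <- sample(perm$label)
    # regroup so folds stay valid after permutation
    perm$group_id <- paste0(perm$label, "_g", sample(1:8, nrow(perm), TRUE))
    cv <- tryCatch(cross_validate(perm, params = list(C = 1, gamma = 4, j = 8)),
                   error = function(e) NULL)
    if (is.null(cv)) NA_real_ else cv$pooled$F
  })
  fs <- fs[!is.na(fs)]
  # F-score should hover near the chance level implied by the base rate,
  # far below the perfect score on true labels
  expect_lt(mean(fs), 0.85)
  expect_gt(mean(fs), 0)
})

test_that("confusion summary derives all rates from raw counts", {
  cs <- confusion_summary(230, 51, 2864, 135)
  expect_equal(round(100 * cs$TPR), 63)
  expect_equal(round(100 * cs$FPR), 2)
  expect_equal(round(100 * cs$PPV), 82)
  expect_equal(round(100 * cs$NPV), 95)
  # degenerate classifiers
  all_neg <- confusion_summary(0, 0, 100, 25)
  expect_equal(all_neg$NPV, 100 / 125)
  expect_equal(all_neg$F, 0)
})

test_that("raising the decision threshold never increases false positives", {
  set.seed(706)
  labeled <- separable_windows(n_groups = 8, per_group = 3)
  X <- hotspotter:::window_feature_matrix(labeled$window)
  model <- train_svm(X, labeled$label)
  s <- decision_scores(model, X)
  fp <- vapply(seq(-2, 2, by = 0.25),
               function(t) sum(s > t & labeled$label == "negative"),
               numeric(1))
  expect_true(all(diff(fp) <= 0))
})
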