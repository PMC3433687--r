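# Training-set construction, RBF-SVM fitting with asymmetric class costs,
# hotspot-grouped cross-validation, and the hyperparameter grid search.

#' Build the positive training set from hotspot windows
#'
#' Every hotspot window is subdivided into all segments of length `k` at a
#' one-residue increment; each segment is one positive example carrying its
#' source hotspot as `group_id`, so cross-validation folds can be partitioned
#' by hotspot rather than by (heavily overlapping) windows.  Duplicate
#' segments, if any, are counted in the `n_duplicate` attribute.
#'
#' @param hotspots data frame with `hotspot_id`, `window_sequence` (and
#'   optionally `window_start`), e.g. from [detect_hotspots()] or
#'   [reference_hotspots()].
#' @param k window length (default 17).
#' @return data frame with columns `window`, `label` (`"positive"`),
#'   `group_id`, `start` (0-based protein coordinate when `window_start` is
#'   available).
#' @export
build_positive_set <- function(hotspots, k = 17L) {
  stopifnot(all(c("hotspot_id", "window_sequence") %in% names(hotspots)))
  ws <- if ("window_start" %in% names(hotspots)) hotspots$window_start else
    rep(0L, nrow(hotspots))
  rows <- lapply(seq_len(nrow(hotspots)), function(i) {
    seg <- window_segments(hotspots$window_sequence[i], k = k)
    data.frame(window = seg$segment, label = "positive",
               group_id = hotspots$hotspot_id[i],
               start = ws[i] + seg$start)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ndup <- sum(duplicated(out$window))
  if (ndup > 0L) message(ndup, " duplicate positive segment(s)")
  attr(out, "n_duplicate") <- ndup
  out
}

#' Minimum S/T/Y frequencies over the positive set
#'
#' The per-type frequency floors used to filter negative candidate windows:
#' a negative must contain serine, threonine and tyrosine at frequencies at
#' least as high as the lowest observed in any positive window, so that the
#' classifier cannot separate the classes on trivially reduced
#' phosphorylatable content.
#'
#' @param positive_set data frame from [build_positive_set()].
#' @return named numeric vector `c(minS, minT, minY)`.
#' @export
sty_floors <- function(positive_set) {
  stopifnot(nrow(positive_set) > 0L)
  f <- sty_frequencies(positive_set$window)
  stats::setNames(apply(f, 2L, min), c("minS", "minT", "minY"))
}

# Per-protein difference: coverage intervals minus hotspot window spans.
subtract_windows <- function(cov, windows) {
  if (nrow(windows) == 0L) return(cov)
  out <- list()
  for (i in seq_len(nrow(cov))) {
    s <- cov$start[i]; e <- cov$end[i]
    pieces <- data.frame(start = s, end = e)
    for (j in seq_len(nrow(windows))) {
      ws <- windows$start[j]; we <- windows$end[j]
      new <- list()
      for (p in seq_len(nrow(pieces))) {
        ps <- pieces$start[p]; pe <- pieces$end[p]
        if (we <= ps || ws >= pe) {
          new[[length(new) + 1L]] <- c(ps, pe)
        } else {
          if (ws > ps) new[[length(new) + 1L]] <- c(ps, ws)
          if (we < pe) new[[length(new) + 1L]] <- c(we, pe)
        }
      }
      pieces <- if (length(new)) as.data.frame(do.call(rbind, new)) else
        data.frame(V1 = integer(0), V2 = integer(0))
      names(pieces) <- c("start", "end")
      if (nrow(pieces) == 0L) break
    }
    out[[length(out) + 1L]] <- pieces
  }
  res <- do.call(rbind, out)
  res[res$end - res$start > 0L, , drop = FALSE]
}

#' Build the negative training set
#'
#' Peptide-covered regions, minus all hotspot windows, are tiled into
#' non-overlapping windows of length `k`; tiles failing any S/T/Y frequency
#' floor or containing ambiguity codes are dropped; the remainder is randomly
#' downsampled to `ratio` times the positive count.  Negatives may contain
#' isolated phosphorylation sites: only clustering distinguishes the classes.
#'
#' @param proteome proteome data frame.
#' @param coverage normalized coverage intervals.
#' @param hotspots hotspot data frame whose windows are excluded
#'   (`protein_id`, `window_start`, `window_end`).
#' @param floors named vector from [sty_floors()].
#' @param n_positives positive-set size the ratio refers to.
#' @param ratio negative:positive ratio (default 8).
#' @param k window length (default 17).
#' @return data frame with columns `window`, `label` (`"negative"`),
#'   `group_id` (source region), `start`.
#' @export
build_negative_set <- function(proteome, coverage, hotspots, floors,
                               n_positives, ratio = 8L, k = 17L) {
  seqs <- proteome_lookup(proteome)
  cov_by <- split(coverage, coverage$protein_id)
  hs_by <- if (nrow(hotspots)) split(hotspots, hotspots$protein_id) else list()
  rows <- list()
  for (pid in names(cov_by)) {
    cov <- cov_by[[pid]]
    hs <- hs_by[[pid]]
    regions <- if (!is.null(hs))
      subtract_windows(cov, data.frame(start = hs$window_start,
                                       end = hs$window_end))
    else cov[, c("start", "end")]
    for (r in seq_len(nrow(regions))) {
      len <- regions$end[r] - regions$start[r]
      if (len < k) next
      starts <- regions$start[r] + k * (0:(len %/% k - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        window = substring(seqs[[pid]], starts + 1L, starts + k),
        label = "negative",
        group_id = paste0(pid, ":", regions$start[r]),
        start = as.integer(starts))
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = character(0), label = character(0),
               group_id = character(0), start = integer(0))
  if (nrow(cand)) {
    std <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                  cand$window)
    if (any(!std)) message(sum(!std), " candidate window(s) with ambiguity ",
                           "codes excluded")
    cand <- cand[std, , drop = FALSE]
  }
  if (nrow(cand)) {
    f <- sty_frequencies(cand$window)
    keep <- f[, "fS"] >= floors[["minS"]] & f[, "fT"] >= floors[["minT"]] &
      f[, "fY"] >= floors[["minY"]]
    cand <- cand[keep, , drop = FALSE]
  }
  want <- as.integer(ratio * n_positives)
  if (nrow(cand) > want) {
    cand <- cand[sample.int(nrow(cand), want), , drop = FALSE]
  } else if (nrow(cand) < want) {
    warning("only ", nrow(cand), " negative candidates available (",
            want, " requested); keeping all")
  }
  cand <- cand[order(cand$group_id, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Assign grouped cross-validation folds
#'
#' Positive groups (hotspots) are partitioned across folds so that the
#' windows of one hotspot never straddle a train/test boundary; negative
#' groups (regions) are then allocated greedily so that each fold's
#' negative:positive ratio stays close to the overall ratio.
#'
#' @param labeled combined labeled-window data frame (positives and
#'   negatives).
#' @param folds number of folds (default 5).
#' @return integer vector of fold ids (1..folds), one per row of `labeled`.
#' @export
make_group_folds <- function(labeled, folds = 5L) {
  pos <- labeled$label == "positive"
  pgroups <- unique(labeled$group_id[pos])
  if (length(pgroups) < folds)
    stop("need at least ", folds, " distinct positive groups")
  # greedy balance of positive windows across folds
  sizes <- table(labeled$group_id[pos])[sample(length(pgroups))]
  load <- rep(0L, folds)
  pg_fold <- stats::setNames(integer(length(sizes)), names(sizes))
  for (g in names(sizes)) {
    f <- which.min(load)
    pg_fold[g] <- f
    load[f] <- load[f] + sizes[[g]]
  }
  fold <- integer(nrow(labeled))
  fold[pos] <- pg_fold[labeled$group_id[pos]]
  # negatives: greedy fill toward per-fold targets proportional to positives
  neg_groups <- unique(labeled$group_id[!pos])
  ratio <- sum(!pos) / sum(pos)
  target <- load * ratio
  got <- rep(0L, folds)
  ng_sizes <- table(labeled$group_id[!pos])
  ng_fold <- stats::setNames(integer(length(neg_groups)), neg_groups)
  for (g in sample(neg_groups)) {
    f <- which.max(target - got)
    ng_fold[g] <- f
    got[f] <- got[f] + ng_sizes[[g]]
  }
  fold[!pos] <- ng_fold[labeled$group_id[!pos]]
  fold
}

#' Confusion-matrix summary with rates
#'
#' @param tp,fp,tn,fn window counts.
#' @return list with the counts plus `TPR`, `FPR`, `PPV`, `NPV` and the
#'   F-score (harmonic mean of `PPV` and `TPR`).
#' @export
confusion_summary <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  tpr <- div(tp, tp + fn)
  ppv <- div(tp, tp + fp)
  f <- if (is.na(tpr) || is.na(ppv) || tpr + ppv == 0) 0 else
    2 * ppv * tpr / (ppv + tpr)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       TPR = tpr, FPR = div(fp, fp + tn),
       PPV = ppv, NPV = div(tn, tn + fn), F = f)
}

#' Train the RBF-SVM hotspot classifier
#'
#' A soft-margin support vector machine with radial basis kernel
#' `exp(-gamma * ||x - y||^2)` on 420-dimensional composition vectors.  The
#' positive-class error weight `j` and the false-positive:false-negative
#' cost ratio are composed multiplicatively into per-class error weights
#' (`positive = j`, `negative = cost_ratio`).  Decision scores are raw
#' (uncalibrated) margin distances, positive toward the hotspot class.
#'
#' @param x numeric feature matrix (rows = windows, 420 columns) or a
#'   labeled-window data frame with a `window` column.
#' @param labels character/factor vector, `"positive"`/`"negative"`
#'   (unneeded when `x` is a labeled data frame).
#' @param params list with `C`, `gamma`, `j`.
#' @param cost_ratio false-positive cost multiplier (default 8).
#' @return object of class `"hotspot_svm"`.
#' @export
train_svm <- function(x, labels = NULL,
                      params = list(C = 1, gamma = 4, j = 8),
                      cost_ratio = 8) {
  if (is.data.frame(x)) {
    labels <- x$label
    x <- window_feature_matrix(x$window)
  }
  stopifnot(ncol(x) == 420L, length(labels) == nrow(x))
  y <- factor(labels, levels = c("negative", "positive"))
  if (any(table(y) == 0L)) stop("both classes must be present for training")
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = params$C, gamma = params$gamma,
                    class.weights = c(negative = cost_ratio,
                                      positive = params$j),
                    scale = FALSE)
  # libsvm orients decision values toward the class of the first training
  # row; fix the orientation so positive scores mean "hotspot".
  dv <- attr(stats::predict(fit, x[1:min(50L, nrow(x)), , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (grepl("^positive/", colnames(dv)[1])) 1 else -1
  structure(list(fit = fit, flip = flip, params = params,
                 cost_ratio = cost_ratio, feature_names = feature_names(),
                 n_train = nrow(x)),
            class = "hotspot_svm")
}

#' @export
print.hotspot_svm <- function(x, ...) {
  cat("RBF-SVM hotspot classifier\n")
  cat(sprintf("  C = %g, gamma = %g, j = %g, cost ratio = %g, %d training windows\n",
              x$params$C, x$params$gamma, x$params$j, x$cost_ratio, x$n_train))
  invisible(x)
}

#' Decision scores of the classifier on feature rows
#'
#' @param model `"hotspot_svm"` object.
#' @param x numeric feature matrix (420 columns); rows with NA (ambiguity
#'   windows) receive NA scores.
#' @return numeric vector of decision scores (positive toward hotspots).
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "hotspot_svm"), ncol(x) == 420L)
  out <- rep(NA_real_, nrow(x))
  ok <- !apply(is.na(x), 1L, any)
  if (any(ok)) {
    dv <- attr(stats::predict(model$fit, x[ok, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    out[ok] <- model$flip * as.numeric(dv[, 1])
  }
  out
}

#' Hotspot-grouped cross-validation
#'
#' Folds partition hotspot groups (see [make_group_folds()]); per fold a
#' classifier is trained on the remaining folds and scored on the held-out
#' windows, a window counting as positive when its decision score exceeds
#' `threshold`.
#'
#' @param labeled combined labeled-window data frame.
#' @param params SVM hyperparameters (list with `C`, `gamma`, `j`).
#' @param folds number of folds (default 5).
#' @param cost_ratio false-positive cost multiplier (default 8).
#' @param threshold decision-score threshold (default 0).
#' @param fold_id optional precomputed fold assignment (from
#'   [make_group_folds()]), reused across a grid search.
#' @param features optional precomputed feature matrix for `labeled`.
#' @return list with `folds` (per-fold metric data frame), `pooled`
#'   (confusion over all held-out windows), `mean_F`, and `scores` (held-out
#'   data frame with `row` (index into `labeled`), `fold`, `label`, `score`).
#' @export
cross_validate <- function(labeled, params = list(C = 1, gamma = 4, j = 8),
                           folds = 5L, cost_ratio = 8, threshold = 0,
                           fold_id = NULL, features = NULL) {
  if (is.null(fold_id)) fold_id <- make_group_folds(labeled, folds)
  if (is.null(features)) features <- window_feature_matrix(labeled$window)
  y <- labeled$label
  per_fold <- list()
  sc_rows <- list()
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    stopifnot(!any(labeled$group_id[test] %in% labeled$group_id[!test]))
    if (!any(y[test] == "positive") || length(unique(y[!test])) < 2L)
      stop("degenerate fold ", f, "; re-draw the fold assignment")
    model <- train_svm(features[!test, , drop = FALSE], y[!test],
                       params = params, cost_ratio = cost_ratio)
    s <- decision_scores(model, features[test, , drop = FALSE])
    pred_pos <- s > threshold
    cs <- confusion_summary(sum(pred_pos & y[test] == "positive"),
                            sum(pred_pos & y[test] == "negative"),
                            sum(!pred_pos & y[test] == "negative"),
                            sum(!pred_pos & y[test] == "positive"))
    per_fold[[length(per_fold) + 1L]] <- data.frame(fold = f, as.data.frame(cs))
    sc_rows[[length(sc_rows) + 1L]] <- data.frame(row = which(test), fold = f,
                                                  label = y[test], score = s)
  }
  fold_df <- do.call(rbind, per_fold)
  scores <- do.call(rbind, sc_rows)
  pooled <- confusion_summary(sum(fold_df$TP), sum(fold_df$FP),
                              sum(fold_df$TN), sum(fold_df$FN))
  list(folds = fold_df, pooled = pooled, mean_F = mean(fold_df$F),
       scores = scores)
}

#' Exhaustive grid search for the SVM hyperparameters
#'
#' Evaluates every combination of `grid_C`, `grid_gamma` and `grid_j` by
#' grouped cross-validation on one shared fold partition and selects the
#' combination with the maximal mean F-score.
#'
#' @inheritParams cross_validate
#' @param grids list with numeric vectors `C`, `gamma`, `j` (defaults are
#'   the full default ranges; see [run_config()]).
#' @return list with `best` (list `C`, `gamma`, `j`), `best_F`, and `table`
#'   (one row per combination with its mean F-score).
#' @export
grid_search <- function(labeled,
                        grids = list(C = 2^(-10:24), gamma = 2^(-10:6),
                                     j = 2^(-2:4)),
                        folds = 5L, cost_ratio = 8, threshold = 0) {
  stopifnot(length(grids$C) >= 1, length(grids$gamma) >= 1,
            length(grids$j) >= 1)
  fold_id <- make_group_folds(labeled, folds)
  features <- window_feature_matrix(labeled$window)
  combos <- expand.grid(C = grids$C, gamma = grids$gamma, j = grids$j,
                        KEEP.OUT.ATTRS = FALSE)
  combos$mean_F <- NA_real_
  for (i in seq_len(nrow(combos))) {
    cv <- cross_validate(labeled,
                         params = list(C = combos$C[i], gamma = combos$gamma[i],
                                       j = combos$j[i]),
                         folds = folds, cost_ratio = cost_ratio,
                         threshold = threshold, fold_id = fold_id,
                         features = features)
    combos$mean_F[i] <- cv$mean_F
  }
  best <- which.max(combos$mean_F)
  list(best = list(C = combos$C[best], gamma = combos$gamma[best],
                   j = combos$j[best]),
       best_F = combos$mean_F[best],
       table = combos)
}

#' Choose a decision threshold from held-out scores
#'
#' The smallest threshold at which the held-out false-positive rate does not
#' exceed `max_fpr` (the `1 - max_fpr` quantile of held-out negative scores).
#'
#' @param cv result of [cross_validate()].
#' @param max_fpr tolerated held-out false-positive rate (default 0.05).
#' @return numeric threshold.
#' @export
select_threshold <- function(cv, max_fpr = 0.05) {
  neg <- cv$scores$score[cv$scores$label == "negative"]
  stopifnot(length(neg) > 0L)
  as.numeric(stats::quantile(neg, 1 - max_fpr, type = 1, names = FALSE))
}
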