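#' Run configuration for the hotspot pipeline
#'
#' Collects the tunable parameters shared across detection, training and
#' scanning.  The defaults are the method's reference operating point:
#' composition windows of 17 residues, hotspots of at least 4 sites with
#' neighbor gaps of at most 10, 3-residue minimum flanks, a 1:8
#' positive:negative training ratio, an exhaustive power-of-two grid for the
#' SVM hyperparameters, an 8:1 false-positive:false-negative cost ratio, and
#' decision-score thresholds of 0 for training/cross-validation and 1 for
#' whole-proteome scanning.
#'
#' @param window_length window (and minimum hotspot) length in residues.
#' @param min_sites minimum number of sites in a hotspot run.
#' @param max_gap maximum residue spacing between neighboring sites in a run.
#' @param min_flank minimum flank beyond the terminal sites of a hotspot.
#' @param neg_pos_ratio negative:positive training-set size ratio.
#' @param grid_C,grid_gamma,grid_j hyperparameter grids (numeric vectors).
#' @param cost_ratio false-positive vs false-negative cost multiplier.
#' @param score_threshold_train decision-score threshold used in
#'   cross-validation.
#' @param score_threshold_scan stricter threshold for proteome scanning.
#' @param random_seed optional integer seed consumed by randomized steps.
#' @return a list of class `"run_config"`.
#' @examples
#' cfg <- run_config()
#' length(cfg$grid_C) * length(cfg$grid_gamma) * length(cfg$grid_j) # 4165
#' @export
run_config <- function(window_length = 17L,
                       min_sites = 4L,
                       max_gap = 10L,
                       min_flank = 3L,
                       neg_pos_ratio = 8L,
                       grid_C = 2^(-10:24),
                       grid_gamma = 2^(-10:6),
                       grid_j = 2^(-2:4),
                       cost_ratio = 8,
                       score_threshold_train = 0,
                       score_threshold_scan = 1,
                       random_seed = NULL) {
  stopifnot(window_length >= 1, min_sites >= 1, max_gap >= 1, min_flank >= 0,
            neg_pos_ratio >= 1, cost_ratio > 0,
            length(grid_C) >= 1, length(grid_gamma) >= 1, length(grid_j) >= 1,
            all(grid_C > 0), all(grid_gamma > 0), all(grid_j > 0))
  structure(list(window_length = as.integer(window_length),
                 min_sites = as.integer(min_sites),
                 max_gap = as.integer(max_gap),
                 min_flank = as.integer(min_flank),
                 neg_pos_ratio = as.integer(neg_pos_ratio),
                 grid_C = grid_C, grid_gamma = grid_gamma, grid_j = grid_j,
                 cost_ratio = cost_ratio,
                 score_threshold_train = score_threshold_train,
                 score_threshold_scan = score_threshold_scan,
                 random_seed = random_seed),
            class = "run_config")
}
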