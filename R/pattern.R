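#' Intracranial-EEG seizure propagation pattern
#'
#' A reduced description of one recorded seizure: which ROIs were sampled by
#' electrodes, which of those activated, and in what order.
#'
#' @param sampled ROI indices covered by electrodes
#' @param active subset of `sampled` that activated during the seizure
#' @param rank activation ranks within `active` (a permutation of
#'   `1..length(active)`; average ranks allowed for simultaneous activations)
#' @return an `ieeg_pattern`
#' @export
ieeg_pattern <- function(sampled, active, rank = seq_along(active)) {
  sampled <- unique(as.integer(sampled))
  active <- as.integer(active)
  if (length(sampled) == 0) stop("pattern must sample at least one ROI")
  if (!all(active %in% sampled)) stop("active ROIs must be a subset of sampled ROIs")
  if (anyDuplicated(active)) stop("active ROIs must be distinct")
  if (length(rank) != length(active)) stop("one rank per active ROI required")
  if (length(rank) && abs(sum(rank) - sum(seq_along(rank))) > 1e-9)
    stop("ranks must be (possibly midrank-tied) ranks of 1..n_active")
  structure(list(sampled = sampled, active = active, rank = as.numeric(rank)),
            class = "ieeg_pattern")
}

#' Read an iEEG pattern file
#'
#' CSV with columns `roi` (1-based ROI index), `sampled` (0/1), `active`
#' (0/1), `rank` (activation rank, empty/NA for inactive ROIs).
#' @param path file path
#' @return an `ieeg_pattern`
#' @export
read_ieeg_pattern <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("roi", "sampled", "active") %in% names(df)))
  sampled <- df$roi[df$sampled == 1]
  act <- df[df$active == 1, , drop = FALSE]
  ieeg_pattern(sampled, act$roi, act$rank)
}

#' Weighted Pearson correlation of two rank vectors
#'
#' Weighted means and covariances; used to compare activation orders with ROI
#' participation as weights.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param w nonnegative weights, not all zero
#' @return correlation in `[-1, 1]`, or `NA` when fewer than 3 points or when
#'   a weighted variance vanishes (undefined-correlation signal)
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  if (any(w < 0) || sum(w) == 0) stop("weights must be >= 0 and not all zero")
  if (length(x) < 3) return(NA_real_)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  max(-1, min(1, cxy / sqrt(vx * vy)))
}

model_active_set <- function(model, sampled, activity_threshold,
                             method = "balanced") {
  if (method %in% c("extent", "calibrated")) {
    # size-consistent active set: the top-k ROIs by participation, where k is
    # the expected number of sampled ROIs active in a single realization
    # (sum of participations). Participation aggregates over realizations and
    # so overstates any single seizure's extent; matching the expected extent
    # makes the overlap sensitive to the recovery rate, which controls how
    # far a typical seizure travels.
    part <- model$participation[sampled]
    k <- min(round(sum(part)), sum(part > 0))
    if (k <= 0) return(integer(0))
    return(sampled[order(-part, seq_along(part))[seq_len(k)]])
  }
  sampled[model$participation[sampled] >= activity_threshold]
}

set_agreement <- function(ref, mod) {
  if (length(ref) == 0) return(as.numeric(length(mod) == 0))
  length(intersect(mod, ref)) / length(ref)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Active/inactive overlap between model and iEEG patterns
#'
#' Restricted to the electrode-sampled ROIs; a model ROI counts as active when
#' its participation reaches `activity_threshold`. The default `"balanced"`
#' strategy averages the agreement of the active sets and of the inactive
#' sets, `(|Am ∩ Ai|/|Ai| + |Im ∩ Ii|/|Ii|) / 2`; an empty reference set
#' contributes 1 if the corresponding model set is also empty, else 0.
#'
#' @param model a `model_pattern`
#' @param ieeg an `ieeg_pattern`
#' @param activity_threshold participation threshold for model activity
#' @param method `"balanced"` (default), `"extent"` (balanced agreement with
#'   the size-consistent model active set: the top-k participation ROIs with
#'   k the expected per-realization active count), `"calibrated"` (one minus
#'   the mean squared difference between the 0/1 activation indicator and the
#'   model participation -- a proper score whose expectation is maximized
#'   exactly when the model reproduces the per-ROI activation probabilities,
#'   which makes it the strategy of choice for parameter fitting),
#'   `"jaccard"` (mean Jaccard index of the active and inactive sets), or
#'   `"agreement"` (fraction of sampled ROIs with matching status)
#' @return overlap in `[0, 1]`
#' @export
overlap_score <- function(model, ieeg, activity_threshold = 0.05,
                          method = c("balanced", "extent", "calibrated",
                                     "jaccard", "agreement")) {
  method <- match.arg(method)
  samp <- ieeg$sampled
  if (length(samp) == 0) stop("pattern samples no ROIs")
  if (method == "calibrated") {
    a <- as.numeric(samp %in% ieeg$active)
    return(1 - mean((a - model$participation[samp])^2))
  }
  a_m <- model_active_set(model, samp, activity_threshold, method)
  i_m <- setdiff(samp, a_m)
  a_i <- ieeg$active
  i_i <- setdiff(samp, a_i)
  switch(method,
         balanced = ,
         extent = (set_agreement(a_i, a_m) + set_agreement(i_i, i_m)) / 2,
         jaccard = (jaccard(a_m, a_i) + jaccard(i_m, i_i)) / 2,
         agreement = mean((samp %in% a_m) == (samp %in% a_i)))
}

#' Goodness of fit between model and iEEG seizure patterns
#'
#' `C = max(0, Cw) * P_overlap`, where `Cw` is the participation-weighted
#' correlation between iEEG activation ranks and model mean-activation-step
#' ranks over the ROIs active in both patterns, and `P_overlap` is
#' [overlap_score()]. Anti-correlated orders are floored to 0 so that
#' `C` stays in `[0, 1]`; fewer than 3 jointly active ROIs gives `C = 0`
#' with a `degenerate` flag.
#'
#' @inheritParams overlap_score
#' @return `C` in `[0, 1]` with attributes `cw`, `p_overlap`, `degenerate`
#' @export
goodness_of_fit <- function(model, ieeg, activity_threshold = 0.05,
                            method = c("balanced", "extent", "calibrated",
                                       "jaccard", "agreement")) {
  method <- match.arg(method)
  p_ov <- overlap_score(model, ieeg, activity_threshold, method)
  a_m <- model_active_set(model, ieeg$sampled, activity_threshold, method)
  joint <- intersect(a_m, ieeg$active)
  if (length(joint) < 3) {
    return(structure(0, cw = NA_real_, p_overlap = p_ov, degenerate = TRUE))
  }
  x <- rank(ieeg$rank[match(joint, ieeg$active)], ties.method = "average")
  y <- rank(model$mean_step[joint], ties.method = "average")
  w <- model$participation[joint]
  cw <- weighted_correlation(x, y, w)
  if (is.na(cw)) {
    return(structure(0, cw = NA_real_, p_overlap = p_ov, degenerate = TRUE))
  }
  structure(max(0, cw) * p_ov, cw = cw, p_overlap = p_ov,
            degenerate = FALSE, clipped = cw < 0)
}

#' Grid fit of the global density and recovery parameters
#'
#' For every `(rho, gamma)` grid point, each patient's network is thresholded
#' at `rho`, an SIR ensemble is simulated from the patient's seed set, the
#' aggregated model pattern is scored against the patient's iEEG pattern, and
#' the per-patient surfaces are averaged into the group surface
#' `C-bar(rho, gamma)`. The sweep is repeated `n_rep` times to attach
#' dispersion to the surfaces and to the group best-fit point.
#'
#' @param patients list of patient records, each a list with elements `net`
#'   (unthresholded `brain_network`), `seed_set` (ROI indices seeding the
#'   simulated seizure), and `ieeg` (an `ieeg_pattern`)
#' @param rho_grid,gamma_grid strictly increasing parameter grids (default
#'   12-point log grids over `[0.01, 0.35]` and `[0.01, 1]`)
#' @param n_realizations SIR realizations per grid point and patient
#' @param n_rep number of sweep repetitions
#' @param rng_seed base seed
#' @param activity_threshold,method passed to [goodness_of_fit()]
#' @return a `fit_map`: grids, per-patient mean surfaces `c_values`
#'   (rho x gamma x patient), group surface `c_bar`, per-repetition group
#'   argmaxes `rep_best` and their dispersion, and `best_point`
#'   (grid indices + values of the `c_bar` argmax)
#' @export
parameter_sweep <- function(patients, rho_grid = log_grid(12, c(0.01, 0.35)),
                            gamma_grid = log_grid(12, c(0.01, 1)),
                            n_realizations = 1000, n_rep = 10, rng_seed = 1,
                            activity_threshold = 0.05,
                            method = "balanced") {
  if (length(rho_grid) == 0 || length(gamma_grid) == 0) stop("empty parameter grid")
  if (is.unsorted(rho_grid, strictly = TRUE) || is.unsorted(gamma_grid, strictly = TRUE))
    stop("grids must be strictly increasing")
  np <- length(patients)
  stopifnot(np >= 1)
  cc <- array(0, dim = c(length(rho_grid), length(gamma_grid), np, n_rep))
  stream <- 0
  for (rep in seq_len(n_rep)) {
    for (p in seq_len(np)) {
      pat <- patients[[p]]
      for (i in seq_along(rho_grid)) {
        thr <- threshold_density(pat$net, rho_grid[i])
        for (j in seq_along(gamma_grid)) {
          stream <- stream + 1
          ens <- sir_ensemble(thr, pat$seed_set,
                              sir_params(gamma_grid[j], n_realizations,
                                         rng_seed * 1e6 + stream))
          mp <- aggregate_pattern(ens)
          cc[i, j, p, rep] <- as.numeric(
            goodness_of_fit(mp, pat$ieeg, activity_threshold, method))
        }
      }
    }
  }
  c_values <- apply(cc, c(1, 2, 3), mean)
  c_bar_rep <- apply(cc, c(1, 2, 4), mean)
  c_bar <- apply(c_bar_rep, c(1, 2), mean)
  argmax2 <- function(m) {
    k <- which(m == max(m), arr.ind = TRUE)
    k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
  }
  rep_best <- t(vapply(seq_len(n_rep),
                       function(r) argmax2(c_bar_rep[, , r]), integer(2)))
  colnames(rep_best) <- c("rho_idx", "gamma_idx")
  bp <- argmax2(c_bar)
  pat_best <- t(vapply(seq_len(np),
                       function(p) argmax2(c_values[, , p]), integer(2)))
  colnames(pat_best) <- c("rho_idx", "gamma_idx")
  structure(list(rho_grid = rho_grid, gamma_grid = gamma_grid,
                 c_values = c_values, c_bar = c_bar,
                 rep_best = rep_best, patient_best = pat_best,
                 best_point = list(rho_idx = unname(bp[1]),
                                   gamma_idx = unname(bp[2]),
                                   rho = rho_grid[bp[1]],
                                   gamma = gamma_grid[bp[2]],
                                   c_bar = max(c_bar)),
                 c_sd = stats::sd(apply(c_bar_rep, 3, max))),
            class = "fit_map")
}

#' @export
print.fit_map <- function(x, ...) {
  cat(sprintf("fit_map: %d x %d grid, %d patient(s)\n",
              length(x$rho_grid), length(x$gamma_grid), dim(x$c_values)[3]))
  cat(sprintf("  best fit: rho = %.4f, gamma = %.4f, C-bar = %.3f\n",
              x$best_point$rho, x$best_point$gamma, x$best_point$c_bar))
  invisible(x)
}
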