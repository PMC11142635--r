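#' SIR simulation parameters
#'
#' @param gamma global per-step recovery probability in `(0, 1]`; every
#'   infected node recovers with this probability at the end of each step.
#' @param n_realizations number of stochastic realizations to run.
#' @param rng_seed integer base seed; realization `r` uses the deterministic
#'   substream `(rng_seed, r)`, so results are independent of execution order.
#' @return a `sir_params` list
#' @export
sir_params <- function(gamma, n_realizations = 10000, rng_seed = 1) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  structure(list(gamma = gamma, n_realizations = as.integer(n_realizations),
                 rng_seed = as.numeric(rng_seed)),
            class = "sir_params")
}

check_seed_set <- function(seed_set, n) {
  seed_set <- unique(as.integer(seed_set))
  if (length(seed_set) == 0) stop("seed set must be nonempty")
  if (any(seed_set < 1 | seed_set > n)) stop("seed ROI index out of range")
  seed_set
}

#' Simulate one SIR seizure realization
#'
#' Discrete-time susceptible-infected-recovered dynamics: at each step every
#' currently infected node independently attempts to infect each susceptible
#' neighbour `j` with probability `w_ij`; then every node that was infected at
#' the start of the step recovers with probability `gamma`. Newly infected
#' nodes transmit (and may recover) only from the next step on. The process
#' runs to absorption (no infected nodes), which is guaranteed for
#' `gamma > 0`; a hard cap of `10 * N` steps raises an error otherwise.
#'
#' @param net a `brain_network` (typically already density-thresholded)
#' @param seed_set ROI indices infected at `t = 0`
#' @param params a [sir_params()] object; `n_realizations` is ignored here
#' @param realization substream index (>= 1) selecting which realization of
#'   the ensemble to reproduce
#' @return a `seizure_realization` with `seed_set`, `activation_step` (first
#'   infection step per ROI, `Inf` if never infected), `final_states`
#'   (`"S"`/`"R"`), and `ir` (fraction of ROIs ever infected)
#' @export
simulate_sir <- function(net, seed_set, params, realization = 1) {
  n <- n_roi(net)
  seed_set <- check_seed_set(seed_set, n)
  res <- cpp_sir_ensemble(net$weights, seed_set, 1L, params$gamma,
                          params$rng_seed, TRUE, as.integer(realization - 1))
  steps <- as.numeric(res$steps[1, ])
  steps[steps < 0] <- Inf
  structure(list(seed_set = seed_set,
                 activation_step = steps,
                 final_states = ifelse(is.finite(steps), "R", "S"),
                 ir = res$ir[1],
                 n_roi = n),
            class = "seizure_realization")
}

#' Infection ratio of a realization
#'
#' Fraction of ROIs that became infected at any point (seeds included,
#' regardless of later recovery).
#'
#' @param realization a `seizure_realization`
#' @return value in `[0, 1]`
#' @export
infection_ratio <- function(realization) {
  mean(is.finite(realization$activation_step))
}

#' Run an SIR ensemble
#'
#' Low-level ensemble driver shared by the pattern-fitting and resection
#' layers. `seed_sets` may be a single ROI vector (reused each realization) or
#' a list of per-realization ROI vectors (e.g. draws from a seed-probability
#' map). Calling twice with the same `rng_seed` on different networks yields
#' paired, common-random-number estimates.
#'
#' @param net a `brain_network`
#' @param seed_sets integer vector or list of integer vectors
#' @param params a [sir_params()]; when `seed_sets` is a list its length
#'   overrides `n_realizations`
#' @param keep_steps return the full realization-by-ROI activation-step matrix
#' @return list with `ir` (per-realization infection ratios), `participation`
#'   (per-ROI infection frequency), `mean_step` (mean first-infection step over
#'   realizations where infected; `NaN` if never), and optionally `steps`
#' @export
sir_ensemble <- function(net, seed_sets, params, keep_steps = FALSE) {
  n <- n_roi(net)
  if (is.list(seed_sets)) {
    seed_sets <- lapply(seed_sets, check_seed_set, n = n)
  } else {
    seed_sets <- check_seed_set(seed_sets, n)
  }
  res <- cpp_sir_ensemble(net$weights, seed_sets, params$n_realizations,
                          params$gamma, params$rng_seed, keep_steps)
  out <- list(ir = res$ir,
              participation = res$inf_count / res$n_real,
              mean_step = ifelse(res$inf_count > 0,
                                 res$step_sum / res$inf_count, NaN),
              n_real = res$n_real)
  if (keep_steps) {
    steps <- res$steps
    steps[steps < 0] <- NA_integer_
    out$steps <- steps
  }
  out
}

#' Aggregate realizations into a model seizure pattern
#'
#' The model pattern weights each ROI by the fraction of realizations in which
#' it took part in the simulated seizure (its participation) and summarizes
#' its timing by the mean first-infection step over those realizations.
#'
#' @param realizations a list of `seizure_realization` objects (all on the
#'   same network), or the result of [sir_ensemble()]
#' @return a `model_pattern` with `participation` and `mean_step` per ROI
#' @export
aggregate_pattern <- function(realizations) {
  if (!is.null(realizations$participation)) {
    return(model_pattern(realizations$participation, realizations$mean_step))
  }
  stopifnot(length(realizations) >= 1)
  n <- realizations[[1]]$n_roi
  steps <- vapply(realizations, function(r) r$activation_step, numeric(n))
  steps <- matrix(steps, nrow = n)
  inf <- is.finite(steps)
  cnt <- rowSums(inf)
  ssum <- rowSums(ifelse(inf, steps, 0))
  model_pattern(cnt / length(realizations), ifelse(cnt > 0, ssum / cnt, NaN))
}

#' Model seizure pattern
#'
#' @param participation per-ROI fraction of realizations infected, in `[0, 1]`
#' @param mean_step per-ROI mean first-infection step (`NaN` where never
#'   infected)
#' @return a `model_pattern`
#' @export
model_pattern <- function(participation, mean_step) {
  stopifnot(length(participation) == length(mean_step),
            all(participation >= 0 & participation <= 1))
  structure(list(participation = participation, mean_step = mean_step),
            class = "model_pattern")
}

#' Monte-Carlo mean infection ratio
#'
#' Averages the infection ratio over redraws of the seed set and the SIR
#' dynamics.
#'
#' @param net a `brain_network`
#' @param seed_sampler a fixed ROI vector, a list of per-realization ROI
#'   vectors, or a function `(r) -> ROI vector`
#' @param params a [sir_params()]
#' @return list with `mean` and `sd` of the infection ratio
#' @export
mean_ir <- function(net, seed_sampler, params) {
  seeds <- if (is.function(seed_sampler)) {
    lapply(seq_len(params$n_realizations), seed_sampler)
  } else seed_sampler
  ens <- sir_ensemble(net, seeds, params)
  list(mean = mean(ens$ir), sd = stats::sd(ens$ir))
}
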