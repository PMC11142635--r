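#' Apply a virtual resection
#'
#' Disconnects the resected ROIs by setting all their links to zero. The
#' nodes stay in the graph, so infection-ratio denominators remain comparable
#' before and after resection.
#'
#' @param net a `brain_network`
#' @param nodes ROI indices to resect (may be empty)
#' @return a new `brain_network`; the input is untouched
#' @export
apply_resection <- function(net, nodes) {
  nodes <- unique(as.integer(nodes))
  if (any(nodes < 1 | nodes > n_roi(net))) stop("resection ROI index out of range")
  w <- net$weights
  w[nodes, ] <- 0
  w[, nodes] <- 0
  brain_network(w, labels = net$labels, density = NA_real_)
}

#' Seed efficiency of a network
#'
#' Mean inverse network distance from the seed nodes to the remaining nodes,
#' `E = (1 / (N_seed * N2)) * sum_{i in seed} sum_{j in S2} 1 / d_ij`, with
#' both the seed and the non-seed set `S2` restricted to the giant component.
#' Unreachable pairs contribute 0; if no seed node lies in the giant
#' component the efficiency is 0.
#'
#' @param net a `brain_network`
#' @param seed_set ROI indices of the seed (nonempty)
#' @param convention distance convention, `"inverse_weight"` (default) or
#'   `"hop"`; see [shortest_path_distances()]
#' @param resected optional ROI indices treated as resected (links ignored)
#'   without materializing the resected matrix
#' @return seed efficiency (>= 0)
#' @export
seed_efficiency <- function(net, seed_set,
                            convention = c("inverse_weight", "hop"),
                            resected = integer(0)) {
  convention <- match.arg(convention)
  seed_set <- check_seed_set(seed_set, n_roi(net))
  cpp_seed_efficiency(net$weights, seed_set, as.integer(resected),
                      if (convention == "hop") 0L else 1L)
}

#' Normalized decrease in seizure propagation after a resection
#'
#' Paired estimator of `delta-IR = (IR0 - IR_R) / IR0`: each seed realization
#' is simulated on the intact and on the resected network with the same RNG
#' substream (common random numbers), and the per-realization ratios are
#' averaged. Resected seed nodes remain ictal at `t = 0` and count toward the
#' infection ratio but transmit nothing; resected non-seed nodes can never be
#' infected.
#'
#' @param net a `brain_network` (intact)
#' @param nodes resected ROI set (may be empty, giving exactly 0)
#' @param seed_sets list of per-realization seed ROI vectors (e.g. draws from
#'   a seed-probability map), or a single fixed seed vector
#' @param params a [sir_params()]
#' @return list with `mean`, `sd` (over realizations), `ir0`, `ir_r`
#'   (per-realization infection ratios)
#' @export
delta_ir <- function(net, nodes, seed_sets, params) {
  ens0 <- sir_ensemble(net, seed_sets, params)
  ensr <- sir_ensemble(apply_resection(net, nodes), seed_sets, params)
  d <- (ens0$ir - ensr$ir) / ens0$ir
  list(mean = mean(d), sd = stats::sd(d), ir0 = ens0$ir, ir_r = ensr$ir)
}

#' Simulated-annealing configuration for resection search
#'
#' The annealer minimizes the panel-mean seed efficiency with single-swap
#' proposals (exchange one resected node for one retained node), geometric
#' cooling `T <- cooling * T` from an initial temperature calibrated to the
#' target initial acceptance rate, `n_per_temp` proposals per temperature,
#' stopping when `T < t_min_frac * T0` or a full temperature passes without
#' an acceptance.
#'
#' @param n_restarts independent annealing runs per resection size; the best
#'   is kept
#' @param panel_size number of pre-sampled seed realizations forming the
#'   fixed evaluation panel
#' @param n_per_temp proposals per temperature
#' @param cooling geometric cooling factor in `(0, 1)`
#' @param t_min_frac stop when the temperature falls below this fraction of
#'   the initial temperature
#' @param init_accept target acceptance rate used to calibrate the initial
#'   temperature
#' @param max_temps hard cap on the number of temperatures
#' @return an `sa_config` list
#' @export
sa_config <- function(n_restarts = 10, panel_size = 20, n_per_temp = 100,
                      cooling = 0.95, t_min_frac = 1e-4, init_accept = 0.8,
                      max_temps = 500) {
  stopifnot(n_restarts >= 1, panel_size >= 1, n_per_temp >= 1,
            cooling > 0, cooling < 1, init_accept > 0, init_accept < 1)
  structure(list(n_restarts = n_restarts, panel_size = panel_size,
                 n_per_temp = n_per_temp, cooling = cooling,
                 t_min_frac = t_min_frac, init_accept = init_accept,
                 max_temps = max_temps),
            class = "sa_config")
}

#' Shortened annealing schedule for large batch experiments
#'
#' Same algorithm as [sa_config()] with fewer restarts, a smaller seed panel
#' and a shorter schedule; used where many patients are processed and the
#' per-patient optimum need not be tight.
#' @export
sa_config_fast <- function() {
  sa_config(n_restarts = 2, panel_size = 10, n_per_temp = 30,
            cooling = 0.9, t_min_frac = 1e-3, max_temps = 60)
}

#' Search for the size-S resection minimizing seed efficiency
#'
#' Runs the simulated annealer `n_restarts` times against a fixed panel of
#' seed realizations and returns the node set with the lowest panel-mean seed
#' efficiency ever evaluated across restarts.
#'
#' @param net a `brain_network`
#' @param seed_panel list of seed ROI vectors (the evaluation panel), e.g.
#'   draws from a seed-probability map
#' @param size resection size `S` with `1 <= S < N`
#' @param config an [sa_config()]
#' @param rng_seed base seed; restart `k` uses substream `(rng_seed, k)`
#' @param convention distance convention for seed efficiency
#' @return list with `nodes` (sorted ROI indices), `energy` (panel-mean seed
#'   efficiency), `restart_energies`
#' @export
anneal_min_seed_efficiency <- function(net, seed_panel, size,
                                       config = sa_config(), rng_seed = 1,
                                       convention = c("inverse_weight", "hop")) {
  convention <- match.arg(convention)
  n <- n_roi(net)
  if (size < 1 || size >= n) stop("resection size must satisfy 1 <= S < N")
  if (!is.list(seed_panel)) seed_panel <- list(seed_panel)
  seed_panel <- lapply(seed_panel, check_seed_set, n = n)
  conv <- if (convention == "hop") 0L else 1L
  best <- NULL
  energies <- numeric(config$n_restarts)
  for (k in seq_len(config$n_restarts)) {
    res <- cpp_anneal(net$weights, seed_panel, as.integer(size),
                      config$n_per_temp, config$cooling, config$t_min_frac,
                      config$init_accept, config$max_temps,
                      rng_seed * 1000 + k, conv)
    energies[k] <- res$energy
    if (is.null(best) || res$energy < best$energy) best <- res
    if (best$energy <= 1e-15) { energies <- energies[seq_len(k)]; break }
  }
  list(nodes = sort(as.integer(best$nodes)), energy = best$energy,
       restart_energies = energies)
}

#' Optimal and disconnecting resections over a size sweep
#'
#' For each resection size, the annealer searches for the node set minimizing
#' the panel-mean seed efficiency; the selected resection is then evaluated by
#' the paired normalized decrease in seizure propagation over independent seed
#' realizations. The optimal resection is the smallest whose delta-IR reaches
#' `delta_target` (default 0.90); the disconnecting resection is the smallest
#' with zero normalized seed efficiency (the seed isolated from the rest of
#' the giant component).
#'
#' @param net a `brain_network` at the operating density
#' @param seed_map a `seed_probability_map` used both for the annealing panel
#'   and for the delta-IR seed realizations
#' @param sizes increasing resection sizes to scan (default `1:20`)
#' @param params a [sir_params()] giving the recovery probability, the number
#'   of paired seed/SIR realizations, and the base seed
#' @param config an [sa_config()]
#' @param delta_target delta-IR threshold defining the optimal resection
#' @param convention distance convention for seed efficiency
#' @param early_stop stop scanning sizes once the optimal resection is found
#' @return a `sweep_result`: `table` (one row per evaluated size: size,
#'   seed efficiency, normalized efficiency `e_r`, delta-IR mean and sd),
#'   `nodes` (list of optimized node sets), `r_op`, `r_d` (each `NULL` when
#'   censored), `e0`, and `censored` flag
#' @export
resection_size_sweep <- function(net, seed_map, sizes = 1:20, params,
                                 config = sa_config(), delta_target = 0.90,
                                 convention = c("inverse_weight", "hop"),
                                 early_stop = FALSE) {
  convention <- match.arg(convention)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be increasing")
  n <- n_roi(net)
  if (any(sizes < 1 | sizes >= n)) stop("sizes must satisfy 1 <= S < N")

  # fixed seed panel for annealing and fixed realizations for delta-IR
  seed_state_guard()
  set.seed(params$rng_seed %% .Machine$integer.max)
  panel <- replicate(config$panel_size, sample_seed(seed_map), simplify = FALSE)
  seed_sets <- replicate(params$n_realizations, sample_seed(seed_map),
                         simplify = FALSE)
  e0 <- mean(vapply(panel, function(s)
    seed_efficiency(net, s, convention), numeric(1)))

  rows <- list(); nodes_list <- list()
  r_op <- NULL; r_d <- NULL
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    ann <- anneal_min_seed_efficiency(net, panel, s, config,
                                      rng_seed = params$rng_seed * 100 + s,
                                      convention = convention)
    eff <- delta_ir(net, ann$nodes, seed_sets, params)
    e_r <- if (e0 > 0) ann$energy / e0 else NA_real_
    rows[[si]] <- data.frame(size = s, energy = ann$energy, e_r = e_r,
                             delta_mean = eff$mean, delta_sd = eff$sd)
    nodes_list[[si]] <- ann$nodes
    if (is.null(r_op) && eff$mean >= delta_target) {
      r_op <- list(size = s, nodes = ann$nodes, delta = eff$mean,
                   e_r = e_r)
    }
    if (is.null(r_d) && !is.na(e_r) && e_r <= 1e-12) {
      r_d <- list(size = s, nodes = ann$nodes, delta = eff$mean)
    }
    if (early_stop && !is.null(r_op)) break
  }
  structure(list(table = do.call(rbind, rows), nodes = nodes_list,
                 r_op = r_op, r_d = r_d, e0 = e0,
                 censored = is.null(r_op), s_max = max(sizes)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d sizes scanned, E0 = %.4f\n",
              nrow(x$table), x$e0))
  if (is.null(x$r_op)) {
    cat(sprintf("  optimal resection: censored at S_max = %d\n", x$s_max))
  } else {
    cat(sprintf("  optimal resection: S = %d, delta-IR = %.3f\n",
                x$r_op$size, x$r_op$delta))
  }
  if (!is.null(x$r_d))
    cat(sprintf("  disconnecting resection: S = %d\n", x$r_d$size))
  invisible(x)
}

#' Overlap between an optimized resection and the planned resection area
#'
#' Default convention: intersection size over the smaller set size,
#' `|R ∩ RA| / min(|R|, |RA|)`; `"jaccard"` uses the union instead.
#'
#' @param r_nodes optimized resection ROI set (nonempty)
#' @param ra_nodes planned resection-area ROI set (nonempty)
#' @param method `"min"` (default) or `"jaccard"`
#' @return overlap in `[0, 1]`
#' @export
overlap_with_plan <- function(r_nodes, ra_nodes, method = c("min", "jaccard")) {
  method <- match.arg(method)
  r_nodes <- unique(as.integer(r_nodes))
  ra_nodes <- unique(as.integer(ra_nodes))
  if (length(r_nodes) == 0 || length(ra_nodes) == 0)
    stop("both ROI sets must be nonempty")
  i <- length(intersect(r_nodes, ra_nodes))
  if (method == "min") i / min(length(r_nodes), length(ra_nodes))
  else i / length(union(r_nodes, ra_nodes))
}

# restore the caller's global RNG state when the caller exits, so internal
# set.seed() calls do not perturb user-level randomness
seed_state_guard <- function() {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    expr <- bquote(assign(".Random.seed", .(old), globalenv()))
    do.call(on.exit, list(expr, add = TRUE), envir = parent.frame())
  }
  invisible(NULL)
}
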