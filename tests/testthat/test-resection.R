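test_that("virtual resection zeroes incident links and keeps the node count", {
  set.seed(6)
  net <- rand_net(8)
  expect_equal(apply_resection(net, integer(0))$weights, net$weights)
  expect_equal(apply_resection(net, 1:8)$weights, matrix(0, 8, 8,
               dimnames = dimnames(net$weights)))
  star <- brain_network({m <- matrix(0, 5, 5); m[1, 2:5] <- 0.9; m[2:5, 1] <- 0.9; m})
  expect_true(all(apply_resection(star, 1)$weights == 0))
  r <- apply_resection(net, c(3, 5))
  expect_equal(n_roi(r), 8)
  expect_true(all(r$weights[3, ] == 0) && all(r$weights[, 5] == 0))
  expect_false(all(net$weights[3, ] == 0))  # original untouched
})

test_that("seed efficiency matches the direct-formula oracle", {
  # 4-node path, seed at one end, hop distances: (1 + 1/2 + 1/3) / 3
  w <- matrix(0, 4, 4)
  for (i in 1:3) w[i, i + 1] <- w[i + 1, i] <- 1
  path <- brain_network(w)
  expect_equal(seed_efficiency(path, 1, "hop"), 11 / 18)

  star <- brain_network({m <- matrix(0, 5, 5); m[1, 2:5] <- 1; m[2:5, 1] <- 1; m})
  expect_equal(seed_efficiency(star, 1, "hop"), 1)

  # disconnected seed contributes nothing
  iso <- brain_network({m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 1; m})
  expect_equal(seed_efficiency(iso, 3), 0)

  set.seed(12)
  for (k in 1:8) {
    net <- rand_net(sample(5:10, 1), p = 0.45)
    seed <- sample(n_roi(net), sample(1:2, 1))
    res <- if (k %% 2) integer(0) else sample(setdiff(1:n_roi(net), seed), 1)
    for (conv in c("hop", "inverse_weight")) {
      expect_equal(seed_efficiency(net, seed, conv, resected = res),
                   seed_eff_oracle(net, seed, conv, resected = res),
                   tolerance = 1e-10)
    }
  }
})

test_that("resections can only lengthen paths, so efficiency falls on common support", {
  # Removing links never shortens any path; hence on any FIXED pair set the
  # summed inverse distance is non-increasing under nested resections. (The
  # efficiency itself is a mean whose support shrinks with the giant
  # component, so it is monotone only on common support.)
  set.seed(13)
  for (rep in 1:5) {
    net <- rand_net(12, p = 0.6)
    seed <- 1:2
    r1 <- 3:4
    r2 <- 3:6
    d0 <- shortest_path_distances(net)
    d1 <- shortest_path_distances(apply_resection(net, r1))
    d2 <- shortest_path_distances(apply_resection(net, r2))
    expect_true(all(d1 >= d0 - 1e-12))
    expect_true(all(d2 >= d1 - 1e-12))
    # common-support efficiency: restrict to pairs reachable under the larger
    # resection and to nodes outside both resections
    keep <- setdiff(seq_len(12), c(seed, r2))
    inv <- function(d) sum(ifelse(is.finite(d[seed, keep]) & d[seed, keep] > 0,
                                  1 / d[seed, keep], 0))
    expect_lte(inv(d2), inv(d1) + 1e-12)
  }
})

test_that("paired delta-IR is exact for degenerate resections", {
  set.seed(14)
  net <- rand_net(10, p = 0.7)
  seeds <- replicate(100, sample(10, 2), simplify = FALSE)
  p <- sir_params(0.5, 100, rng_seed = 21)
  expect_equal(delta_ir(net, integer(0), seeds, p)$mean, 0)

  # resection isolating the seed: IR_R equals the seed fraction exactly
  d <- delta_ir(net, setdiff(1:10, 1:2), list(1:2), sir_params(0.5, 1, rng_seed = 2))
  expect_equal(d$ir_r, 0.2)
  expect_equal(d$mean, 1 - 0.2 / d$ir0)

  # resecting a node with no path to the seed changes nothing
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.9
  w[4, 5] <- w[5, 4] <- 0.9
  split <- brain_network(w)
  expect_equal(delta_ir(split, 4, list(1, 1, 1), sir_params(0.4, 3, rng_seed = 5))$mean, 0)
})

test_that("annealing matches exhaustive subset search on small networks", {
  set.seed(15)
  hits <- 0; trials <- 0
  for (k in 1:6) {
    net <- rand_net(sample(8:11, 1), p = 0.5)
    panel <- replicate(3, sample(n_roi(net), 2), simplify = FALSE)
    S <- sample(2:3, 1)
    oracle <- brute_min_seed_eff(net, panel, S)
    ann <- anneal_min_seed_efficiency(net, panel, S,
                                      sa_config(n_restarts = 4, n_per_temp = 40,
                                                max_temps = 80),
                                      rng_seed = 100 + k)
    trials <- trials + 1
    if (abs(ann$energy - oracle$energy) < 1e-10) hits <- hits + 1
    # never worse than 5% above the optimum (and never below it)
    expect_gte(ann$energy, oracle$energy - 1e-12)
    expect_lte(ann$energy, oracle$energy * 1.05 + 1e-12)
    # bookkeeping: result is the best energy seen across restarts
    expect_equal(ann$energy, min(ann$restart_energies))
  }
  expect_gte(hits / trials, 0.95)
})

test_that("annealing resects the hub when that disconnects a leaf seed", {
  star <- brain_network({m <- matrix(0, 6, 6); m[1, 2:6] <- 0.8; m[2:6, 1] <- 0.8; m})
  ann <- anneal_min_seed_efficiency(star, list(3L), 1,
                                    sa_config(n_restarts = 3), rng_seed = 4)
  expect_equal(ann$nodes, 1)
  expect_equal(ann$energy, 0)
})

test_that("size sweeps find first-crossing optima and disconnections", {
  set.seed(16)
  spec <- cohort_spec(n_patients = 1, n_roi = 30, ez_size = 3, rng_seed = 77)
  pat <- generate_patient(spec, "SF", 77)
  net <- threshold_density(pat$net, spec$generating_rho)
  params <- sir_params(spec$generating_gamma, 60, rng_seed = 8)
  sw <- resection_size_sweep(net, pat$seed_map, sizes = c(1:3, 5, 7, 9), params,
                             config = sa_config_fast())
  expect_s3_class(sw, "sweep_result")
  expect_true(all(diff(sw$table$size) > 0))
  expect_true(all(sw$table$delta_mean <= 1 + 1e-12))
  if (!is.null(sw$r_op)) {
    first <- min(sw$table$size[sw$table$delta_mean >= 0.9])
    expect_equal(sw$r_op$size, first)
  } else {
    expect_true(sw$censored)
  }
  if (!is.null(sw$r_d)) {
    expect_equal(sw$r_d$size, min(sw$table$size[sw$table$e_r <= 1e-12]))
    # disconnection implies isolation-level decrease at that size
    row <- which(sw$table$size == sw$r_d$size)
    expect_gte(sw$table$delta_mean[row], max(sw$table$delta_mean) - 0.15)
  }
  expect_error(resection_size_sweep(net, pat$seed_map, c(3, 2), params), "increasing")
})

test_that("overlap with the planned area follows the min / jaccard conventions", {
  expect_equal(overlap_with_plan(1:4, 1:4), 1)
  expect_equal(overlap_with_plan(1:4, 5:8), 0)
  expect_equal(overlap_with_plan(1:4, c(2, 3, 4, 11:17)), 0.75)
  expect_equal(overlap_with_plan(1:4, c(2, 3, 4, 11:17), method = "jaccard"), 3 / 11)
  expect_error(overlap_with_plan(integer(0), 1:3), "nonempty")
})
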