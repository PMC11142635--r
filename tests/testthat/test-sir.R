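test_that("degenerate SIR cases match closed forms", {
  # isolated seed: IR = 1/N always
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 0.8
  net <- brain_network(w)
  r <- simulate_sir(net, 3, sir_params(0.5, rng_seed = 1))
  expect_equal(r$ir, 0.25)
  expect_equal(r$activation_step[3], 0)
  expect_true(all(is.infinite(r$activation_step[-3])))

  # 2-node net with w = 1: transmission succeeds before recovery can block it
  w2 <- matrix(0, 2, 2); w2[1, 2] <- w2[2, 1] <- 1
  n2 <- brain_network(w2)
  for (k in 1:20) expect_equal(simulate_sir(n2, 1, sir_params(0.9, rng_seed = k))$ir, 1)

  # deterministic full-spread regime
  full <- brain_network(matrix(1, 5, 5) - diag(5))
  m <- mean_ir(full, 1L, sir_params(1, 200, rng_seed = 3))
  expect_equal(m$mean, 1)
  expect_equal(m$sd, 0)
})

test_that("star-with-center-seed matches the geometric-sum closed form", {
  # per spoke: P(transmit) = w / (1 - (1-w)(1-gamma)) = 2/3 at w = gamma = 0.5
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5; w[1, 3] <- w[3, 1] <- 0.5
  net <- brain_network(w)
  n_real <- 10000
  ens <- sir_ensemble(net, 1L, sir_params(0.5, n_real, rng_seed = 7))
  se <- stats::sd(ens$ir) / sqrt(n_real)
  expect_lt(abs(mean(ens$ir) - 7 / 9), 3 * se)
})

test_that("infection ratio counts recovered nodes and respects conservation", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  net <- brain_network(w)
  r <- simulate_sir(net, 1, sir_params(1, rng_seed = 2))
  expect_equal(infection_ratio(r), 2 / 3)
  expect_equal(infection_ratio(r), 1 - mean(r$final_states == "S"))
  expect_true(all(r$final_states[is.finite(r$activation_step)] == "R"))
})

test_that("ensembles are reproducible and realization substreams are stable", {
  set.seed(1)
  net <- rand_net(8)
  p <- sir_params(0.4, 50, rng_seed = 11)
  e1 <- sir_ensemble(net, 1:2, p, keep_steps = TRUE)
  e2 <- sir_ensemble(net, 1:2, p, keep_steps = TRUE)
  expect_identical(e1, e2)
  # single-realization replay of substream k matches ensemble row k
  r4 <- simulate_sir(net, 1:2, p, realization = 4)
  steps4 <- e1$steps[4, ]
  steps4[is.na(steps4)] <- Inf
  expect_equal(r4$activation_step, as.numeric(steps4))
})

test_that("pattern aggregation equals per-realization arithmetic", {
  set.seed(3)
  net <- rand_net(7)
  p <- sir_params(0.5, 40, rng_seed = 5)
  reals <- lapply(1:40, function(k) simulate_sir(net, 2, p, realization = k))
  agg <- aggregate_pattern(reals)
  ens <- aggregate_pattern(sir_ensemble(net, 2, p))
  expect_equal(agg$participation, ens$participation)
  expect_equal(agg$mean_step, ens$mean_step)
  expect_equal(agg$participation[2], 1)
  expect_equal(agg$mean_step[2], 0)

  # fixture arithmetic: infected at steps {2, 4} in 2 of 4 realizations
  mk <- function(steps) structure(list(activation_step = steps, n_roi = 2),
                                  class = "seizure_realization")
  fx <- aggregate_pattern(list(mk(c(0, 2)), mk(c(0, 4)), mk(c(0, Inf)), mk(c(0, Inf))))
  expect_equal(fx$participation[2], 0.5)
  expect_equal(fx$mean_step[2], 3)

  # aggregation over halves equals the weighted mean of half-aggregates
  h1 <- aggregate_pattern(reals[1:20])
  h2 <- aggregate_pattern(reals[21:40])
  expect_equal(agg$participation, (h1$participation + h2$participation) / 2)
})

test_that("E[IR] is monotone in gamma and under edge removal", {
  set.seed(8)
  net <- rand_net(10, p = 0.5)
  seeds <- 1L
  irs <- vapply(c(0.1, 0.4, 0.8), function(g)
    mean(sir_ensemble(net, seeds, sir_params(g, 2000, rng_seed = 9))$ir), numeric(1))
  expect_true(all(diff(irs) < 0.02))  # non-increasing up to MC noise

  # removing links never increases spread (paired seeds)
  w2 <- net$weights
  nz <- which(w2 > 0 & upper.tri(w2), arr.ind = TRUE)
  drop <- nz[1:3, , drop = FALSE]
  w2[drop] <- 0; w2[drop[, c(2, 1)]] <- 0
  ir_full <- mean(sir_ensemble(net, seeds, sir_params(0.3, 2000, rng_seed = 9))$ir)
  ir_less <- mean(sir_ensemble(brain_network(w2), seeds,
                               sir_params(0.3, 2000, rng_seed = 9))$ir)
  expect_lte(ir_less, ir_full + 0.02)
})

test_that("seed validation rejects bad input", {
  net <- brain_network(matrix(c(0, 1, 1, 0), 2, 2))
  p <- sir_params(0.5)
  expect_error(simulate_sir(net, integer(0), p), "nonempty")
  expect_error(simulate_sir(net, 5, p), "range")
  expect_error(sir_params(0), "gamma")
  expect_error(sir_params(1.5), "gamma")
})

test_that("near the spreading transition the IR distribution is bistable", {
  # seizures either die out near the seed fraction or invade a macroscopic
  # part of the component, with (almost) nothing in between
  rg <- log_grid(12, c(0.01, 0.35)); gg <- log_grid(12, c(0.01, 1))
  spec <- cohort_spec(n_patients = 1, n_roi = 60, ez_size = 3,
                      generating_rho = rg[5], generating_gamma = gg[9],
                      rng_seed = 2)
  p <- generate_patient(spec, "SF", 2)
  net <- threshold_density(p$net, spec$generating_rho)
  set.seed(2)
  seeds <- replicate(2000, sample_seed(p$seed_map), simplify = FALSE)
  ens <- sir_ensemble(net, seeds, sir_params(spec$generating_gamma, 2000, 3))
  sf <- mean(lengths(seeds)) / 60
  expect_gt(mean(ens$ir <= 2 * sf), 0.1)            # die-out mode
  expect_gt(mean(ens$ir > 0.4), 0.01)               # macroscopic mode
  expect_lt(mean(ens$ir > 0.15 & ens$ir <= 0.4), 0.05)  # separated modes
})
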