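test_that("weighted correlation matches the direct weighted-moment formula", {
  expect_equal(weighted_correlation(1:5, 1:5, rep(1, 5)), 1)
  expect_equal(weighted_correlation(1:5, 5:1, rep(1, 5)), -1)
  x <- c(1, 2, 3); y <- c(1, 3, 2); w <- c(1, 1, 2)
  expect_equal(weighted_correlation(x, y, w), wcor_oracle(x, y, w))
  set.seed(4)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n); w <- stats::runif(n, 0.1, 2)
    expect_equal(weighted_correlation(x, y, w), wcor_oracle(x, y, w),
                 tolerance = 1e-12)
  }
  expect_true(is.na(weighted_correlation(1:2, 2:1, c(1, 1))))
  expect_true(is.na(weighted_correlation(c(1, 1, 1), 1:3, rep(1, 3))))
  expect_error(weighted_correlation(1:3, 1:3, c(0, 0, 0)), "weights")
})

test_that("overlap score follows the balanced-agreement conventions", {
  mp <- model_pattern(c(1, 1, 0, 0), c(0, 1, NaN, NaN))
  ie <- ieeg_pattern(sampled = 1:4, active = 1:2, rank = 1:2)
  expect_equal(overlap_score(mp, ie), 1)

  # complementary partitions
  mp2 <- model_pattern(c(0, 0, 1, 1), c(NaN, NaN, 0, 1))
  expect_equal(overlap_score(mp2, ie), 0)

  # half agreement on both sets: iEEG active {1,2}, model active {1,3}
  mp3 <- model_pattern(c(1, 0, 1, 0), c(0, NaN, 1, NaN))
  expect_equal(overlap_score(mp3, ie), 0.5)

  # restriction: ROIs outside sampled never matter
  mp4 <- model_pattern(c(1, 1, 0, 0, 1, 1), c(0, 1, NaN, NaN, 2, 3))
  ie4 <- ieeg_pattern(sampled = 1:4, active = 1:2, rank = 1:2)
  expect_equal(overlap_score(mp4, ie4), overlap_score(mp, ie))

  # empty-reference conventions
  all_active <- ieeg_pattern(sampled = 1:2, active = 1:2, rank = 1:2)
  mp5 <- model_pattern(c(1, 1), c(0, 1))
  expect_equal(overlap_score(mp5, all_active), 1)   # both inactive sets empty
  mp6 <- model_pattern(c(1, 0), c(0, NaN))
  expect_equal(overlap_score(mp6, all_active), 0.5 * (1 / 2 + 0))
})

test_that("goodness of fit multiplies clipped order correlation and overlap", {
  # perfect replay: model steps reproduce the iEEG order
  mp <- model_pattern(c(1, 1, 1, 1, 0), c(0, 1, 2, 3, NaN))
  ie <- ieeg_pattern(sampled = 1:5, active = 1:4, rank = 1:4)
  expect_equal(as.numeric(goodness_of_fit(mp, ie)), 1)

  # perfect overlap, anti-ordered activation -> floored to 0
  anti <- model_pattern(c(1, 1, 1, 1, 0), c(3, 2, 1, 0, NaN))
  g <- goodness_of_fit(anti, ie)
  expect_equal(as.numeric(g), 0)
  expect_true(attr(g, "clipped"))
  expect_equal(attr(g, "cw"), -1)

  # fewer than 3 jointly active ROIs -> degenerate flag
  tiny <- ieeg_pattern(sampled = 1:5, active = 1:2, rank = 1:2)
  gd <- goodness_of_fit(mp, tiny)
  expect_equal(as.numeric(gd), 0)
  expect_true(attr(gd, "degenerate"))

  # participation rescaling leaves C unchanged (weights enter as ratios)
  mp_half <- model_pattern(c(1, 1, 1, 1, 0) * 0.6, c(0, 1, 2, 3, NaN))
  expect_equal(attr(goodness_of_fit(mp_half, ie, activity_threshold = 0.05), "cw"),
               attr(goodness_of_fit(mp, ie, activity_threshold = 0.05), "cw"))
})

test_that("calibrated overlap is a proper score of participation", {
  ie <- ieeg_pattern(sampled = 1:4, active = c(1, 3), rank = 1:2)
  a <- c(1, 0, 1, 0)
  exact <- model_pattern(a, c(0, NaN, 1, NaN))
  off <- model_pattern(c(0.7, 0.3, 0.6, 0.4), c(0, 1, 1, 2))
  expect_equal(overlap_score(exact, ie, method = "calibrated"), 1)
  expect_lt(overlap_score(off, ie, method = "calibrated"), 1)
  expect_equal(overlap_score(off, ie, method = "calibrated"),
               1 - mean((a - c(0.7, 0.3, 0.6, 0.4))^2))
})

test_that("iEEG pattern construction validates its contract and round-trips", {
  expect_error(ieeg_pattern(1:3, 4), "subset")
  expect_error(ieeg_pattern(1:3, c(1, 1), c(1, 2)), "distinct")
  expect_error(ieeg_pattern(1:3, 1:2, c(1, 5)), "ranks")
  p <- ieeg_pattern(c(2, 5, 9), c(5, 9), c(2, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(roi = c(2, 5, 9, 11), sampled = c(1, 1, 1, 0),
                              active = c(0, 1, 1, 0), rank = c(NA, 2, 1, NA)),
                   f, row.names = FALSE)
  q <- read_ieeg_pattern(f)
  expect_equal(q$sampled, p$sampled)
  expect_equal(q$active, p$active)
  expect_equal(q$rank, p$rank)
})

test_that("parameter sweep surfaces average patients and locate a self-fit", {
  # one patient whose pattern is a deterministic replay of its own dynamics
  w <- matrix(0, 6, 6)
  for (i in 1:5) w[i, i + 1] <- w[i + 1, i] <- 1  # chain with certain spread
  net <- brain_network(w)
  ie <- ieeg_pattern(1:6, 1:6, 1:6)
  pats <- list(list(net = net, seed_set = 1L, ieeg = ie))
  # at rho = 0.3 only 4 of the 5 chain links survive (the last node is cut
  # off); at rho = 1 the replay is exact, so the argmax must sit there
  fm <- suppressWarnings(
    parameter_sweep(pats, rho_grid = c(0.3, 1), gamma_grid = c(0.3, 0.9),
                    n_realizations = 60, n_rep = 2, rng_seed = 3))
  expect_equal(dim(fm$c_bar), c(2, 2))
  expect_equal(fm$best_point$rho_idx, 2)
  expect_equal(max(fm$c_bar), 1)
  # group surface is the patient mean at every grid point
  expect_equal(fm$c_bar, apply(fm$c_values, c(1, 2), mean), tolerance = 1e-12)
  expect_error(parameter_sweep(pats, rho_grid = numeric(0)), "empty")
})
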