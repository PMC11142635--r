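test_that("ROC analysis matches the pairwise-ordering oracle", {
  # perfectly separated
  r <- roc_analysis(c(1, 2, 8, 9), c("SF", "SF", "NSF", "NSF"))
  expect_equal(r$auc, 1)
  expect_equal(unname(r$metrics[c("accuracy", "precision", "sensitivity", "f1")]),
               rep(1, 4))

  # constant scores: chance level
  expect_equal(roc_analysis(rep(2, 6), rep(c("SF", "NSF"), 3))$auc, 0.5)

  # brute-force AUC on random fixtures, both directions, with ties
  set.seed(17)
  for (k in 1:12) {
    n <- sample(8:20, 1)
    scores <- sample(seq(0, 5, 0.5), n, replace = TRUE)
    labels <- sample(c("SF", "NSF"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    for (dir in c("higher", "lower")) {
      expect_equal(roc_analysis(scores, labels, dir)$auc,
                   auc_oracle(scores, labels, dir), tolerance = 1e-12)
    }
  }
  expect_error(roc_analysis(1:3, rep("SF", 3)), "both outcome classes")
})

test_that("Youden point maximizes TPR - FPR with ties toward specificity", {
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c("SF", "SF", "NSF", "SF", "NSF", "NSF")
  r <- roc_analysis(scores, labels)
  j <- r$tpr - r$fpr
  expect_equal(max(j), r$metrics["sensitivity"] - (1 - r$metrics["specificity"]),
               ignore_attr = TRUE)
  best <- which(j == max(j))
  expect_equal(r$fpr[best[order(r$fpr[best])][1]],
               1 - unname(r$metrics["specificity"]))
  # metric formulas reconstruct from the stored confusion counts exactly
  k <- r$confusion
  expect_equal(unname(r$metrics["accuracy"]), unname((k["tp"] + k["tn"]) / sum(k)))
  expect_equal(unname(r$metrics["f1"]),
               unname(2 * k["tp"] / (2 * k["tp"] + k["fp"] + k["fn"])))
})

test_that("exact rank-sum enumeration matches closed cases and wilcox.test", {
  expect_equal(as.numeric(ranksum_exact(c(1, 2), c(3, 4))), 1 / 3)
  expect_equal(as.numeric(ranksum_exact(c(1, 2), c(1, 2))), 1)

  # invariance under strictly monotone transforms
  x <- c(0.3, 1.2, 2.2, 5); y <- c(0.9, 3.1, 4)
  expect_equal(as.numeric(ranksum_exact(x, y)),
               as.numeric(ranksum_exact(exp(x), exp(y))))

  # agreement with the stats implementation on tie-free samples
  set.seed(18)
  for (k in 1:8) {
    x <- stats::rnorm(sample(3:8, 1)); y <- stats::rnorm(sample(3:8, 1), mean = 0.5)
    expect_equal(as.numeric(ranksum_exact(x, y)),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  # large samples: flagged normal approximation
  p <- ranksum_exact(stats::rnorm(30), stats::rnorm(30), exact_limit = 40)
  expect_false(attr(p, "exact"))
  expect_error(ranksum_exact(numeric(0), 1:3), "nonempty")
})

test_that("LOOCV refits thresholds per fold and never sees the held-out label", {
  df <- cohort_table(data.frame(
    s_rop = c(1, 2, 3, 4, 10, 11, 12, 13),
    ov = rep(0.5, 8), dir_ra = rep(0.5, 8),
    outcome = rep(c("SF", "NSF"), each = 4)))
  pr <- loocv_predict(df, "s_rop")
  # the boundary NSF case can fall just below its fold's threshold (the
  # Youden point sits at an observed score), so one miss is acceptable
  expect_gte(unname(pr$metrics["accuracy"]), 7 / 8)

  # constant biomarker: every patient gets the same class
  dfc <- df; dfc$s_rop <- 5
  prc <- loocv_predict(dfc, "s_rop")
  expect_equal(length(unique(prc$calls)), 1)

  # planted group difference recovers sensitivity and specificity
  set.seed(19)
  ok <- replicate(40, {
    n <- 34; nsf <- 8
    out <- c(rep("NSF", nsf), rep("SF", n - nsf))
    val <- stats::rnorm(n, mean = ifelse(out == "NSF", 1.5, 0))
    d <- cohort_table(data.frame(s_rop = val, ov = 0, dir_ra = 0, outcome = out))
    m <- loocv_predict(d, "s_rop")$metrics
    c(m["sensitivity"], m["specificity"])
  })
  expect_gt(mean(ok[1, ]), 0.6)
  expect_gt(mean(ok[2, ]), 0.6)
})

test_that("combined vote calls NSF on at least two votes", {
  expect_equal(combined_vote(c("NSF", "NSF", "SF")), "NSF")
  expect_equal(combined_vote(c("SF", "SF", "SF")), "SF")
  expect_equal(combined_vote(c("NSF", "NSF", "NSF")), "NSF")
  expect_equal(combined_vote(c("NSF", "SF", "SF")), "SF")
  m <- rbind(c("NSF", "NSF", "SF"), c("SF", "SF", "NSF"))
  expect_equal(unname(combined_vote(m)), c("NSF", "SF"))
})

test_that("boosted undersampling prediction is deterministic and learns separable data", {
  set.seed(20)
  n <- 20
  out <- c(rep("NSF", 6), rep("SF", 14))
  df <- cohort_table(data.frame(
    s_rop = ifelse(out == "NSF", 10, 2) + stats::rnorm(n, sd = 0.2),
    ov = ifelse(out == "NSF", 0.2, 0.8) + stats::rnorm(n, sd = 0.05),
    dir_ra = ifelse(out == "NSF", 0.1, 0.9) + stats::rnorm(n, sd = 0.05),
    outcome = out))
  r1 <- rusboost_predict(df, n_rep = 5, rng_seed = 9)
  r2 <- rusboost_predict(df, n_rep = 5, rng_seed = 9)
  expect_identical(r1$confusion, r2$confusion)
  expect_gt(r1$metrics["accuracy"], 0.9)
  expect_equal(sum(r1$feature_importance), 1, tolerance = 1e-12)
  expect_error(rusboost_predict(df[c(1, 7:20), ], n_rep = 2), "2 cases per class")
})
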