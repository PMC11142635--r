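#' Cohort biomarker table
#'
#' Validates a per-patient table of the three model-derived biomarkers and the
#' surgical outcome. Nonseizure-free (`"NSF"`) is the positive class
#' throughout the classification layer.
#'
#' @param df data frame with columns `s_rop` (optimal resection size), `ov`
#'   (overlap of the optimized resection with the resection area), `dir_ra`
#'   (normalized decrease in propagation after resecting the resection area)
#'   and `outcome` (`"SF"`/`"NSF"`); extra columns are kept.
#' @return the validated data frame with class `cohort_table`
#' @export
cohort_table <- function(df) {
  need <- c("s_rop", "ov", "dir_ra", "outcome")
  if (!all(need %in% names(df))) stop("missing cohort columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (!all(df$outcome %in% c("SF", "NSF"))) stop("outcome must be SF or NSF")
  if (anyNA(df[, c("s_rop", "ov", "dir_ra")])) stop("missing biomarker values")
  class(df) <- c("cohort_table", class(df))
  df
}

#' Fixed classification directions of the three biomarkers
#'
#' Larger optimal resections, smaller overlap with the plan, and a smaller
#' effect of the planned resection all point toward a bad (NSF) outcome.
#' Directions are fixed a priori (not estimated from the data) to avoid
#' information leakage in cross-validation.
#'
#' @return named character vector: `"higher"` means higher values score as NSF
#' @export
biomarker_directions <- function() {
  c(s_rop = "higher", ov = "lower", dir_ra = "lower")
}

#' ROC analysis with Youden operating point
#'
#' Full threshold sweep with trapezoid AUC. A case is called NSF when its
#' (direction-adjusted) score is at or above the threshold. The operating
#' point maximizes the Youden index `TPR - FPR`; ties are resolved toward the
#' lower false-positive rate (favouring specificity).
#'
#' @param scores numeric biomarker values
#' @param labels `"SF"`/`"NSF"` per case; both classes must be present
#' @param direction `"higher"` if larger scores indicate NSF, else `"lower"`
#' @return a `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `youden_threshold` (on the adjusted scale), `confusion` (TP/FP/FN/TN at
#'   the Youden point), `metrics` (accuracy, precision, sensitivity,
#'   specificity, f1), and the `direction`
#' @export
roc_analysis <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores)) stop("missing scores")
  pos <- labels == "NSF"
  if (!any(pos) || all(pos)) stop("both outcome classes must be present")
  s <- if (direction == "higher") scores else -scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[order(fpr[best])][1]
  t0 <- thr[best]
  conf <- confusion_counts(s >= t0, pos)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 youden_threshold = t0, direction = direction,
                 confusion = conf, metrics = confusion_metrics(conf)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f; Youden point TPR = %.2f, FPR = %.2f\n",
              x$auc, x$metrics["sensitivity"], 1 - x$metrics["specificity"]))
  invisible(x)
}

# classify new scores with a fitted ROC at its Youden threshold
classify_roc <- function(roc, scores) {
  s <- if (roc$direction == "higher") scores else -scores
  ifelse(s >= roc$youden_threshold, "NSF", "SF")
}

confusion_counts <- function(called_pos, is_pos) {
  c(tp = sum(called_pos & is_pos), fp = sum(called_pos & !is_pos),
    fn = sum(!called_pos & is_pos), tn = sum(!called_pos & !is_pos))
}

confusion_metrics <- function(k) {
  tp <- k["tp"]; fp <- k["fp"]; fn <- k["fn"]; tn <- k["tn"]
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = unname((tp + tn) / sum(k)),
    precision = unname(safe(tp, tp + fp)),
    sensitivity = unname(safe(tp, tp + fn)),
    specificity = unname(safe(tn, tn + fp)),
    f1 = unname(safe(2 * tp, 2 * tp + fp + fn)))
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration of the rank-sum distribution over all
#' assignments of the pooled (midrank-tied) ranks, computed with a
#' count-preserving dynamic programme; `p = min(1, 2 * min(P(W <= w),
#' P(W >= w)))`. For pooled sample sizes above `exact_limit` the normal
#' approximation with tie correction is used and flagged.
#'
#' @param x,y numeric samples (both nonempty)
#' @param exact_limit largest pooled size for the exact enumeration
#' @return p-value with attributes `statistic` (rank sum of `x`) and `exact`
#' @export
ranksum_exact <- function(x, y, exact_limit = 40) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (n > exact_limit) {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    return(structure(p, statistic = w, exact = FALSE))
  }
  # DP over doubled ranks (integers even with midranks): number of size-nx
  # subsets attaining each doubled rank sum
  r2 <- as.integer(round(2 * r))
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  f <- matrix(0, nrow = nx + 1, ncol = smax + 1)  # f[k+1, s+1]
  f[1, 1] <- 1
  for (v in r2) {
    for (k in nx:1) {   # descending so each rank is used at most once
      idx <- which(f[k, ] > 0)
      idx <- idx[idx + v <= smax + 1]
      if (length(idx)) f[k + 1, idx + v] <- f[k + 1, idx + v] + f[k, idx]
    }
  }
  counts <- f[nx + 1, ]
  total <- sum(counts)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(counts[seq_len(w2 + 1)]) / total
  p_ge <- sum(counts[(w2 + 1):(smax + 1)]) / total
  structure(min(1, 2 * min(p_le, p_ge)), statistic = w, exact = TRUE)
}

#' Leave-one-out cross-validated single-biomarker prediction
#'
#' For each held-out patient a ROC is fitted on the remaining patients, the
#' Youden threshold is taken, and the held-out case is classified. Folds whose
#' training set contains a single class are flagged and excluded with a
#' warning. The fold threshold never sees the held-out label.
#'
#' @param cohort a [cohort_table()]
#' @param biomarker one of `"s_rop"`, `"ov"`, `"dir_ra"`
#' @param direction classification direction; defaults to the fixed
#'   [biomarker_directions()] entry
#' @return a `prediction_result`: per-patient `calls`, `confusion`, `metrics`,
#'   `excluded` fold indices
#' @export
loocv_predict <- function(cohort, biomarker,
                          direction = biomarker_directions()[[biomarker]]) {
  stopifnot(biomarker %in% names(cohort))
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 patients")
  scores <- cohort[[biomarker]]
  labels <- cohort$outcome
  calls <- rep(NA_character_, n)
  excluded <- integer(0)
  for (i in seq_len(n)) {
    tr_s <- scores[-i]; tr_l <- labels[-i]
    if (length(unique(tr_l)) < 2) {
      excluded <- c(excluded, i)
      next
    }
    roc <- roc_analysis(tr_s, tr_l, direction)
    calls[i] <- classify_roc(roc, scores[i])
  }
  if (length(excluded))
    warning(sprintf("%d fold(s) had a single training class; patients excluded",
                    length(excluded)))
  keep <- !is.na(calls)
  conf <- confusion_counts(calls[keep] == "NSF", labels[keep] == "NSF")
  structure(list(calls = calls, confusion = conf,
                 metrics = confusion_metrics(conf), excluded = excluded,
                 biomarker = biomarker),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("prediction_result%s: acc %.2f, prec %.2f, sens %.2f, F1 %.2f\n",
              if (is.null(x$biomarker)) "" else paste0(" (", x$biomarker, ")"),
              m["accuracy"], m["precision"], m["sensitivity"], m["f1"]))
  invisible(x)
}

#' Majority vote over the three per-biomarker calls
#'
#' A patient is called NSF when at least two of the three biomarker
#' classifiers call NSF.
#'
#' @param calls character vector (or matrix row) of exactly 3 `"SF"`/`"NSF"`
#'   calls, or an `n x 3` matrix for many patients
#' @return `"SF"`/`"NSF"` per patient
#' @export
combined_vote <- function(calls) {
  if (is.matrix(calls) || is.data.frame(calls)) {
    calls <- as.matrix(calls)
    stopifnot(ncol(calls) == 3)
    return(apply(calls, 1, combined_vote))
  }
  stopifnot(length(calls) == 3, all(calls %in% c("SF", "NSF")))
  if (sum(calls == "NSF") >= 2) "NSF" else "SF"
}

#' Combined three-biomarker LOOCV prediction
#'
#' Runs [loocv_predict()] for each biomarker and combines the per-patient
#' calls by the at-least-2-of-3 NSF vote.
#'
#' @param cohort a [cohort_table()]
#' @return a `prediction_result` with the per-biomarker call matrix attached
#'   as `per_biomarker`
#' @export
loocv_combined <- function(cohort) {
  bm <- names(biomarker_directions())
  per <- vapply(bm, function(b) loocv_predict(cohort, b)$calls,
                character(nrow(cohort)))
  keep <- stats::complete.cases(per)
  calls <- rep(NA_character_, nrow(cohort))
  calls[keep] <- combined_vote(per[keep, , drop = FALSE])
  conf <- confusion_counts(calls[keep] == "NSF", cohort$outcome[keep] == "NSF")
  structure(list(calls = calls, confusion = conf,
                 metrics = confusion_metrics(conf),
                 per_biomarker = per, biomarker = "combined"),
            class = "prediction_result")
}

# ---- adaptive boosting of depth-1 stumps --------------------------------

# Fit one weighted decision stump on feature matrix X (columns = features)
# and labels y in {-1, +1}. Returns feature, threshold, polarity minimizing
# the weighted error.
fit_stump <- function(X, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    xs <- X[, j]
    cuts <- sort(unique(xs))
    cuts <- c(cuts[1] - 1, (utils::head(cuts, -1) + utils::tail(cuts, -1)) / 2)
    for (t in cuts) {
      pred <- ifelse(xs > t, 1, -1)
      err <- sum(w[pred != y])
      if (err < best$err) best <- list(feature = j, threshold = t,
                                       polarity = 1, err = err)
      err2 <- sum(w[-pred != y])
      if (err2 < best$err) best <- list(feature = j, threshold = t,
                                        polarity = -1, err = err2)
    }
  }
  best
}

predict_stump <- function(stump, X) {
  stump$polarity * ifelse(X[, stump$feature] > stump$threshold, 1, -1)
}

# AdaBoost.M1 with stump base learners; y in {-1, +1}; learning rate scales
# the stage weights.
fit_adaboost <- function(X, y, n_learners, learn_rate = 1) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  for (m in seq_len(n_learners)) {
    st <- fit_stump(X, y, w)
    err <- max(st$err, 1e-10)
    if (err >= 0.5) break
    alpha <- learn_rate * 0.5 * log((1 - err) / err)
    st$alpha <- alpha
    learners[[length(learners) + 1]] <- st
    pred <- predict_stump(st, X)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  learners
}

predict_adaboost <- function(learners, X) {
  score <- rep(0, nrow(X))
  for (st in learners) score <- score + st$alpha * predict_stump(st, X)
  score
}

#' Boosted prediction with random undersampling (leave-one-out)
#'
#' Outer leave-one-out loop; within each fold the majority (SF) class is
#' randomly undersampled to the minority size, an adaptive-boosting ensemble
#' of depth-1 stumps over the three biomarkers is fitted (number of learners
#' = balanced training size - 1, learning rate 1.0), and the held-out case is
#' scored. Undersampling and boosting are repeated `n_rep` times and the
#' per-repetition confusion fractions are averaged. Feature importance is the
#' stage-weight-normalized usage of each biomarker across stumps.
#'
#' @param cohort a [cohort_table()] with at least 2 cases per class
#' @param n_rep undersampling/boosting repetitions (default 10)
#' @param rng_seed integer seed
#' @param learn_rate boosting learning rate
#' @return list with `confusion` (mean fractions: tp/fp/fn/tn rates by true
#'   class), `metrics` (computed from the mean confusion), `nsf_prob`
#'   (per-patient fraction of repetitions voting NSF), `feature_importance`
#' @export
rusboost_predict <- function(cohort, n_rep = 10, rng_seed = 1, learn_rate = 1) {
  bm <- names(biomarker_directions())
  X <- as.matrix(cohort[, bm])
  y <- ifelse(cohort$outcome == "NSF", 1, -1)
  n <- nrow(X)
  if (min(table(cohort$outcome)) < 2) stop("need at least 2 cases per class")
  seed_state_guard()
  set.seed(rng_seed)
  votes <- matrix(0, n, n_rep)
  imp <- stats::setNames(numeric(length(bm)), bm)
  for (rep in seq_len(n_rep)) {
    for (i in seq_len(n)) {
      Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
      min_n <- min(sum(yi == 1), sum(yi == -1))
      id_pos <- which(yi == 1); id_neg <- which(yi == -1)
      keep <- c(sample(id_pos, min_n), sample(id_neg, min_n))
      learners <- fit_adaboost(Xi[keep, , drop = FALSE], yi[keep],
                               n_learners = 2 * min_n - 1, learn_rate)
      votes[i, rep] <- sign(predict_adaboost(learners, X[i, , drop = FALSE]))
      for (st in learners) imp[st$feature] <- imp[st$feature] + abs(st$alpha)
    }
  }
  nsf_prob <- rowMeans(votes > 0)
  # mean confusion fractions over repetitions
  conf_rep <- vapply(seq_len(n_rep), function(r)
    confusion_counts(votes[, r] > 0, y == 1), numeric(4))
  conf <- rowMeans(conf_rep)
  names(conf) <- c("tp", "fp", "fn", "tn")
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(confusion = conf, metrics = confusion_metrics(conf),
       nsf_prob = nsf_prob, feature_importance = imp)
}
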