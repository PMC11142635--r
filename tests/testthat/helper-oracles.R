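# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: exhaustive enumeration of the SIR chain,
# Floyd-Warshall distances, brute-force subset search, and direct-formula
# statistics.

# random small weighted network (symmetric, zero diagonal)
rand_net <- function(n, p = 0.6, wmin = 0.2, wmax = 0.95) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- stats::runif(length(ut)) < p
  w[ut[on]] <- stats::runif(sum(on), wmin, wmax)
  w <- w + t(w)
  brain_network(w)
}

# Exhaustive enumeration of the synchronous SIR chain on tiny graphs.
# Returns the exact distribution over final ever-infected sets, keyed by the
# 0/1 pattern string over nodes. Self-loop states (no infection, no
# recovery) are removed by renormalization.
enumerate_sir_final <- function(W, seeds, gamma) {
  n <- nrow(W)
  memo <- new.env(parent = emptyenv())
  subsets_of <- function(x) {
    if (length(x) == 0) return(list(integer(0)))
    unlist(lapply(0:(2^length(x) - 1), function(m)
      list(x[bitwAnd(m, 2^(seq_along(x) - 1)) > 0])), recursive = FALSE)
  }
  rec <- function(state) {
    key <- paste(state, collapse = "")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    inf <- which(state == 1)
    if (length(inf) == 0) {
      out <- stats::setNames(1, paste(as.integer(state == 2), collapse = ""))
      memo[[key]] <- out
      return(out)
    }
    sus <- which(state == 0)
    pj <- vapply(sus, function(j)
      1 - prod(1 - W[inf, j]), numeric(1))
    acc <- new.env(parent = emptyenv())
    p_self <- 0
    for (infset in subsets_of(seq_along(sus))) {
      p_inf <- prod(pj[infset]) * prod(1 - pj[setdiff(seq_along(sus), infset)])
      if (p_inf == 0) next
      for (recset in subsets_of(inf)) {
        p <- p_inf * gamma^length(recset) * (1 - gamma)^(length(inf) - length(recset))
        if (p == 0) next
        ns <- state
        ns[sus[infset]] <- 1
        ns[recset] <- 2
        if (identical(ns, state)) { p_self <- p_self + p; next }
        sub <- rec(ns)
        for (k in names(sub)) {
          acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + p * sub[[k]]
        }
      }
    }
    ks <- ls(acc)
    out <- stats::setNames(vapply(ks, function(k) acc[[k]], numeric(1)) / (1 - p_self), ks)
    memo[[key]] <- out
    out
  }
  st <- integer(n)
  st[seeds] <- 1L
  rec(st)
}

# chi-square goodness of fit of Monte-Carlo final-set counts against exact
# probabilities, pooling categories with small expected counts
chisq_final_sets <- function(patterns, probs) {
  counts <- table(factor(patterns, levels = names(probs)))
  n <- sum(counts)
  expected <- probs * n
  small <- expected < 5
  if (sum(small) > 1) {
    counts <- c(counts[!small], other = sum(counts[small]))
    probs <- c(probs[!small], other = sum(probs[small]))
  }
  stats::chisq.test(counts, p = probs / sum(probs))$p.value
}

# Floyd-Warshall all-pairs distances
fw_dist <- function(net, convention = "inverse_weight") {
  w <- net$weights
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  len <- ifelse(w > 0, if (convention == "hop") 1 else 1 / w, Inf)
  d <- pmin(d, len)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# direct-formula seed efficiency from Floyd-Warshall distances
seed_eff_oracle <- function(net, seed, convention = "inverse_weight",
                            resected = integer(0)) {
  w <- net$weights
  w[resected, ] <- 0
  w[, resected] <- 0
  net2 <- brain_network(w)
  d <- fw_dist(net2, convention)
  comp_of <- function() {
    # components from finite hop distances
    dh <- fw_dist(net2, "hop")
    cid <- integer(nrow(w))
    cur <- 0
    for (i in seq_len(nrow(w))) if (cid[i] == 0) {
      cur <- cur + 1
      cid[is.finite(dh[i, ])] <- cur
    }
    cid
  }
  cid <- comp_of()
  sizes <- table(cid)
  g <- as.integer(names(sizes)[which.max(sizes)])
  seed_g <- intersect(seed, which(cid == g))
  if (length(seed_g) == 0) return(0)
  s2 <- setdiff(which(cid == g), seed)
  if (length(s2) == 0) return(0)
  vals <- d[seed_g, s2, drop = FALSE]
  sum(ifelse(is.finite(vals) & vals > 0, 1 / vals, 0)) /
    (length(seed_g) * length(s2))
}

# brute-force minimum panel-mean seed efficiency over all size-S subsets
brute_min_seed_eff <- function(net, panel, S, convention = "inverse_weight") {
  n <- n_roi(net)
  combs <- utils::combn(n, S)
  best <- Inf; best_set <- NULL
  for (k in seq_len(ncol(combs))) {
    r <- combs[, k]
    e <- mean(vapply(panel, function(s)
      seed_efficiency(net, s, convention, resected = r), numeric(1)))
    if (e < best) { best <- e; best_set <- r }
  }
  list(energy = best, nodes = best_set)
}

# pairwise-comparison AUC oracle (ties count one half)
auc_oracle <- function(scores, labels, direction = "higher") {
  s <- if (direction == "higher") scores else -scores
  pos <- s[labels == "NSF"]; neg <- s[labels == "SF"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct weighted-moment correlation
wcor_oracle <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  num <- sum(w * (x - mx) * (y - my))
  num / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}
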