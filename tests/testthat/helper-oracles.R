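# Independent brute-force oracles used to cross-check the package's
# metric and clustering implementations. These deliberately avoid the code
# paths (and where possible the base functions) used by the package.

oracle_confusion <- function(pred, gold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gold[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && gold[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && gold[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && gold[i] == 0) tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_kappa <- function(x, y) {
  labs <- sort(unique(c(x, y)))
  n <- length(x)
  po <- sum(x == y) / n
  pe <- 0
  for (l in labs) {
    pe <- pe + (sum(x == l) / n) * (sum(y == l) / n)
  }
  if (1 - pe < 1e-12) {
    return(if (po >= 1 - 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

# AUC as the mean over all (positive, negative) pairs of the indicator that
# the positive outranks the negative (ties count half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# midranks computed from first principles
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  mx <- mean(rx)
  my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_bin <- function(x) {
  vapply(x, function(v) if (v >= 3) 3 else v, numeric(1))
}

# Exhaustive Ward agglomeration: at every step scan all active cluster
# pairs, merge the pair with minimal within-variance increase
# dESS = ni*nj/(ni+nj) * ||ci - cj||^2, height = sqrt(2 * dESS).
# Tie-break: lowest (left, right) node-id pair.
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  members <- as.list(seq_len(n)) # node id -> leaf members, NULL if consumed
  active <- seq_len(n)
  merges <- NULL
  for (step in seq_len(n - 1)) {
    best <- NULL
    best_cost <- Inf
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        i <- active[ai]
        j <- active[bi]
        mi <- members[[i]]
        mj <- members[[j]]
        ci <- colMeans(x[mi, , drop = FALSE])
        cj <- colMeans(x[mj, , drop = FALSE])
        cost <- length(mi) * length(mj) / (length(mi) + length(mj)) *
          sum((ci - cj)^2)
        lo <- min(i, j)
        hi <- max(i, j)
        if (cost < best_cost - 1e-15 ||
          (abs(cost - best_cost) <= 1e-15 &&
            (is.null(best) || lo < best[1] || (lo == best[1] && hi < best[2])))) {
          best_cost <- cost
          best <- c(lo, hi)
        }
      }
    }
    new_id <- n + step
    members[[new_id]] <- c(members[[best[1]]], members[[best[2]]])
    active <- c(setdiff(active, best), new_id)
    merges <- rbind(merges, c(best[1], best[2], sqrt(2 * best_cost),
      length(members[[new_id]])
    ))
  }
  colnames(merges) <- c("left", "right", "height", "size")
  merges
}

# Partition from an oracle merge matrix at a strict-< threshold; clusters
# labelled by smallest member leaf.
oracle_cut <- function(merges, n, threshold) {
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  if (!is.null(merges)) {
    for (i in seq_len(nrow(merges))) {
      if (merges[i, "height"] < threshold) {
        new_id <- n + i
        members[[new_id]] <- c(members[[merges[i, 1]]], members[[merges[i, 2]]])
        active <- c(setdiff(active, merges[i, 1:2]), new_id)
      } else {
        # heights are monotone for Ward; later merges only get higher
        new_id <- n + i
        members[[new_id]] <- NA # placeholder so ids stay aligned
        active <- active
      }
    }
  }
  active <- active[!vapply(active, function(a) anyNA(members[[a]]), logical(1))]
  part <- integer(n)
  groups <- lapply(active, function(a) members[[a]])
  firsts <- vapply(groups, min, numeric(1))
  groups <- groups[order(firsts)]
  for (k in seq_along(groups)) part[groups[[k]]] <- k
  part
}

# O(n^2) greedy first-kept dedup oracle on unit vectors, same scan order.
oracle_dedup <- function(vectors, threshold, groups = NULL) {
  n <- nrow(vectors)
  if (is.null(groups)) groups <- rep(1L, n)
  keep <- logical(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (pos in seq_along(idx)) {
      i <- idx[pos]
      merged <- FALSE
      for (qos in seq_len(pos - 1)) {
        j <- idx[qos]
        if (!keep[j]) next
        cs <- sum(vectors[i, ] * vectors[j, ]) /
          (sqrt(sum(vectors[i, ]^2)) * sqrt(sum(vectors[j, ]^2)))
        if (cs >= threshold - 1e-12) {
          merged <- TRUE
          break
        }
      }
      keep[i] <- !merged
    }
  }
  keep
}

# Adjusted Rand index of two labelings against each other (mclust is the
# primary route in acceptance tests; this stays for environments without it).
helper_ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
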