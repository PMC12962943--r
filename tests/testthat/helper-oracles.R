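# Independent brute-force oracles used to verify the implementation.

# Pair-enumeration GLCM: loop over every pixel and offset explicitly.
brute_glcm <- function(q, mask, levels, offset) {
  nr <- nrow(q); nc <- ncol(q)
  C <- matrix(0, levels, levels)
  for (r in seq_len(nr)) {
    for (c_ in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c_ + offset[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r, c_] || !mask[r2, c2]) next
      a <- q[r, c_] + 1; b <- q[r2, c2] + 1
      C[a, b] <- C[a, b] + 1
      C[b, a] <- C[b, a] + 1
    }
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# Run enumeration along one direction by explicit line walking.
brute_runs <- function(q, mask, direction) {
  nr <- nrow(q); nc <- ncol(q)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(1, 0), "135" = c(1, 1))
  starts <- list()
  for (r in seq_len(nr)) for (c_ in seq_len(nc)) {
    pr <- r - step[1]; pc <- c_ - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc) starts[[length(starts) + 1]] <- c(r, c_)
  }
  runs <- NULL
  for (s in starts) {
    r <- s[1]; c_ <- s[2]
    cur_level <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && c_ >= 1 && c_ <= nc) {
      v <- if (mask[r, c_]) q[r, c_] else NA
      if (!is.na(v) && !is.na(cur_level) && v == cur_level) {
        cur_len <- cur_len + 1
      } else {
        if (cur_len > 0) runs <- rbind(runs, c(cur_level, cur_len))
        cur_level <- v; cur_len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c_ <- c_ + step[2]
    }
    if (cur_len > 0) runs <- rbind(runs, c(cur_level, cur_len))
  }
  runs
}

# Exact two-sided rank-sum p-value by enumerating all label assignments
# (midrank statistic), for small groups.
perm_wilcoxon_p <- function(x, y_grp) {
  n <- length(x)
  n1 <- sum(y_grp)
  r <- rank(x)
  obs <- sum(r[y_grp])
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Brute-force AUC by counting positive-negative pairs (ties count half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden search over all midpoints between distinct scores.
brute_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cand <- (u[-length(u)] + u[-1]) / 2
  best_j <- -Inf; best_t <- cand[1]
  for (t in cand) {
    j <- mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 && t > best_t)) {
      best_j <- j; best_t <- t
    }
  }
  best_t
}
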