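# Independent brute-force oracles used by the texture / segmentation tests.
# These deliberately use naive per-pixel loops and share no code with the
# package implementation.

# --- texture matrix oracles (levels: integer matrix, NA outside the mask) ---

oracle_glcm <- function(levels, n_bins) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  P <- matrix(0, n_bins, n_bins)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(levels[r, c])) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(levels[r2, c2])) next
      P[levels[r, c], levels[r2, c2]] <- P[levels[r, c], levels[r2, c2]] + 1
      P[levels[r2, c2], levels[r, c]] <- P[levels[r2, c2], levels[r, c]] + 1
    }
  }
  P
}

oracle_gldm <- function(levels, n_bins, alpha = 0) {
  nr <- nrow(levels); nc <- ncol(levels)
  recs <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(levels[r, c])) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(levels[r2, c2]) &&
          abs(levels[r2, c2] - levels[r, c]) <= alpha) dep <- dep + 1
    }
    recs <- rbind(recs, c(levels[r, c], dep + 1))
  }
  nd <- max(recs[, 2])
  P <- matrix(0, n_bins, nd)
  for (i in seq_len(nrow(recs))) P[recs[i, 1], recs[i, 2]] <-
      P[recs[i, 1], recs[i, 2]] + 1
  P
}

# runs along one direction for every starting line, via explicit walking
oracle_glrlm_angle <- function(levels, n_bins, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  starts <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - dr; pc <- c - dc
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts <- rbind(starts, c(r, c))
  }
  runs <- NULL
  for (i in seq_len(nrow(starts))) {
    r <- starts[i, 1]; c <- starts[i, 2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs <- rbind(runs, c(cur, len))
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + dr; c <- c + dc
    }
    if (!is.na(cur)) runs <- rbind(runs, c(cur, len))
  }
  maxlen <- if (is.null(runs)) 1 else max(runs[, 2])
  P <- matrix(0, n_bins, maxlen)
  if (!is.null(runs))
    for (i in seq_len(nrow(runs)))
      P[runs[i, 1], runs[i, 2]] <- P[runs[i, 1], runs[i, 2]] + 1
  P
}

# zones by recursive flood fill (8-connectivity, equal level)
oracle_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  zones <- NULL
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (is.na(levels[r0, c0]) || seen[r0, c0]) next
    lv <- levels[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if ((dr | dc) && r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            !seen[r2, c2] && !is.na(levels[r2, c2]) &&
            levels[r2, c2] == lv) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
    zones <- rbind(zones, c(lv, size))
  }
  zones  # matrix: (level, size) per zone
}

oracle_glszm <- function(levels, n_bins) {
  z <- oracle_zones(levels)
  P <- matrix(0, n_bins, max(z[, 2]))
  for (i in seq_len(nrow(z))) P[z[i, 1], z[i, 2]] <- P[z[i, 1], z[i, 2]] + 1
  P
}

# NGTDM columns n_i and s_i by per-pixel loops
oracle_ngtdm <- function(levels, n_bins) {
  nr <- nrow(levels); nc <- ncol(levels)
  n_i <- numeric(n_bins); s_i <- numeric(n_bins)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(levels[r, c])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(levels[r2, c2])) nb <- c(nb, levels[r2, c2])
    }
    if (length(nb) == 0) next
    g <- levels[r, c]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  list(n_i = n_i, s_i = s_i)
}

# random small level matrix with a random mask
random_level_matrix <- function(n_bins, max_side = 8) {
  nr <- sample(2:max_side, 1); nc <- sample(2:max_side, 1)
  lev <- matrix(sample(seq_len(n_bins), nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(stats::runif(nr * nc) < 0.75, nr, nc)
  if (!any(mask)) mask[1, 1] <- TRUE
  lev[!mask] <- NA_integer_
  lev
}

# exact trapezoidal area under the empirical ROC of scores vs labels
oracle_roc_auc <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 1) / n1,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 0) / n0,
                     numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
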