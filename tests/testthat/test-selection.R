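# Feature-selection cascade: pruning, screening, mRMR, recursive elimination.

test_that("correlation pruning drops later duplicates deterministically", {
  set.seed(1)
  base <- rnorm(20)
  df <- data.frame(a = base, b = rnorm(20), c = base, d = -base,
                   e = rnorm(20))
  labs <- data.frame(tcfa = rep(c(TRUE, FALSE), 10),
                     mc = rep(c(TRUE, FALSE), 10),
                     tcfa_mc = rep(c(TRUE, FALSE), 10))
  ft <- feature_table(df, labs)
  pruned <- suppressMessages(prune_correlated(ft))
  # duplicate (r = 1) and negation (r = -1) of `a` are both dropped
  expect_true("a" %in% colnames(pruned))
  expect_false(any(c("c", "d") %in% colnames(pruned)))
  expect_true(all(c("b", "e") %in% colnames(pruned)))
})

test_that("correlation pruning matches a brute-force all-pairs filter", {
  set.seed(42)
  n <- 20; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  # inject correlated pairs
  X[, 5] <- X[, 2] + rnorm(n, sd = 0.01)
  X[, 9] <- -X[, 3] + rnorm(n, sd = 0.01)
  colnames(X) <- sprintf("f%02d", 1:p)
  labs <- data.frame(tcfa = rep(c(TRUE, FALSE), 10),
                     mc = rep(c(TRUE, FALSE), 10),
                     tcfa_mc = rep(c(TRUE, FALSE), 10))
  ft <- feature_table(as.data.frame(X), labs)
  pruned <- suppressMessages(prune_correlated(ft, 0.95))

  # oracle: scan columns in order, keep unless |r| > 0.95 with a kept one
  kept <- character(0)
  for (j in seq_len(p)) {
    ok <- TRUE
    for (k in kept)
      if (abs(cor(X[, j], X[, match(k, colnames(X))])) > 0.95) ok <- FALSE
    if (ok) kept <- c(kept, colnames(X)[j])
  }
  expect_identical(colnames(pruned), kept)

  # constant columns are kept with a warning
  X2 <- cbind(X[, 1:3], const = rep(1, n))
  ft2 <- feature_table(as.data.frame(X2), labs)
  expect_warning(suppressMessages(prune_correlated(ft2)), "constant")
})

test_that("univariate screen calibrates against rank statistics", {
  cv <- cv_protocol(n_repeats = 50L, rng_seed = 11L)
  set.seed(2)
  n <- 30
  y <- sample(rep(c(TRUE, FALSE), 15))
  mono <- rnorm(n) + 2 * y               # informative, monotone effect
  flat <- rep(1.0, n)                    # constant
  sep <- as.numeric(y) * 10 + seq_len(n) * 1e-3  # perfectly separating
  ft <- feature_table(data.frame(mono = mono, flat = flat, sep = sep),
                      data.frame(tcfa = y, mc = y, tcfa_mc = y))
  aucs <- screen_univariate(ft, "tcfa", cv)
  expect_equal(unname(aucs["flat"]), 0.5, tolerance = 0.02)
  # noise-free monotone feature: CV AUC equals the Mann-Whitney AUC (= 1)
  expect_equal(unname(aucs["sep"]), auc_mw(sep, y), tolerance = 1e-12)
  # noisy monotone feature: CV AUC tracks the Mann-Whitney AUC up to the
  # attenuation induced by pooling out-of-fold scores across folds
  mw <- auc_mw(mono, y)
  expect_equal(unname(aucs["mono"]), mw, tolerance = 0.06)
  expect_gt(unname(aucs["mono"]), 0.75)
  # single-feature interface agrees with the vectorized screen
  expect_equal(univariate_auc(ft, "mono", "tcfa", cv),
               unname(aucs["mono"]))
})

test_that("top-k per family pools at most 15 per family", {
  ft <- random_feature_table(n = 30, per_family = 20, seed = 3)
  set.seed(4)
  auc_map <- setNames(runif(ncol(ft), 0.3, 0.9), colnames(ft))
  top <- top_k_per_family(auc_map, 15)
  expect_length(top, 105)
  fam <- feature_family(top)
  expect_true(all(table(fam) == 15))
  # reproducible
  expect_identical(top, top_k_per_family(auc_map, 15))
  # a family with fewer survivors than k contributes what it has
  sub <- auc_map[c(which(feature_family(names(auc_map)) != "ngtdm"),
                   which(feature_family(names(auc_map)) == "ngtdm")[1:7])]
  top2 <- top_k_per_family(sub, 15)
  expect_equal(sum(feature_family(top2) == "ngtdm"), 7)
})

test_that("mRMR greedy selection matches an exhaustive trace", {
  set.seed(5)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = 20)
  f1 <- rnorm(n) + 2 * y          # informative
  f2 <- f1                        # exact duplicate of f1
  f3 <- rnorm(n) + 1 * y
  f4 <- rnorm(n)
  f5 <- rnorm(n)
  f6 <- rnorm(n) + 0.5 * y
  df <- data.frame(f1, f2, f3, f4, f5, f6)
  ft <- feature_table(df, data.frame(tcfa = y, mc = y, tcfa_mc = y))

  expect_identical(sort(mrmr_select(ft, "tcfa", 6)), sort(colnames(df)))
  expect_error(mrmr_select(ft, "tcfa", 0), "positive")
  expect_error(mrmr_select(ft, "tcfa", 7), "exceeds")

  # oracle: replay the greedy MID criterion step by step
  disc3 <- function(x) {
    m <- mean(x); s <- sd(x)
    findInterval(x, c(m - s, m + s)) + 1L
  }
  mi <- function(a, b) {
    tab <- table(a, b); p <- tab / sum(tab)
    pa <- rowSums(p); pb <- colSums(p); e <- outer(pa, pb)
    sum(p[p > 0] * log2(p[p > 0] / e[p > 0]))
  }
  D <- vapply(df, disc3, integer(n))
  rel <- vapply(1:6, function(j) mi(D[, j], y), numeric(1))
  sel <- integer(0); rem <- 1:6
  for (step in 1:3) {
    crit <- if (!length(sel)) rel[rem] else
      rel[rem] - vapply(rem, function(j)
        mean(vapply(sel, function(s) mi(D[, s], D[, j]), numeric(1))),
        numeric(1))
    pick <- rem[which.max(crit)]
    sel <- c(sel, pick); rem <- setdiff(rem, pick)
  }
  expect_identical(mrmr_select(ft, "tcfa", 3), colnames(df)[sel])

  # the duplicate of an already selected feature carries maximal redundancy:
  # it is never chosen right after its twin
  k4 <- mrmr_select(ft, "tcfa", 4)
  expect_false(identical(sort(k4[1:2]), c("f1", "f2")))
})

test_that("recursive elimination keeps the informative feature", {
  set.seed(6)
  n <- 30
  y <- sample(rep(c(TRUE, FALSE), 15))
  df <- data.frame(signal = rnorm(n) + 3 * y,
                   matrix(rnorm(n * 9), n, 9,
                          dimnames = list(NULL, sprintf("noise%d", 1:9))))
  ft <- feature_table(df, data.frame(tcfa = y, mc = y, tcfa_mc = y))
  cv <- cv_protocol(n_repeats = 30L, rng_seed = 8L)
  rec <- recursive_elimination(ft, "tcfa", cv)
  expect_true("signal" %in% rec$final_set)
  expect_lte(length(rec$final_set), 10)
  expect_equal(nrow(rec$auc_by_size), 10)

  # all-noise candidates: the selected subset stays near chance
  df0 <- as.data.frame(matrix(rnorm(n * 10), n, 10,
                              dimnames = list(NULL, sprintf("n%d", 1:10))))
  ft0 <- feature_table(df0, data.frame(tcfa = y, mc = y, tcfa_mc = y))
  rec0 <- recursive_elimination(ft0, "tcfa", cv)
  final_auc <- evaluate_model(ft0, rec0$final_set, "tcfa", cv)$mean_auc
  expect_gt(final_auc, 0.4)
  expect_lt(final_auc, 0.72)
})

test_that("full cascade is deterministic and respects stage cardinalities", {
  ft <- random_feature_table(n = 30, per_family = 20, n_informative = 5,
                             effect = 2, seed = 9)
  cv <- cv_protocol(n_repeats = 20L, rng_seed = 10L)
  tr1 <- suppressMessages(select_features(ft, "tcfa", cv))
  tr2 <- suppressMessages(select_features(ft, "tcfa", cv))
  expect_identical(tr1$final_set, tr2$final_set)
  expect_identical(tr1$mrmr50, tr2$mrmr50)
  expect_lte(length(tr1$top105), 105)
  expect_lte(length(tr1$mrmr50), 50)
  expect_lte(length(tr1$candidate10), 10)
  expect_lte(length(tr1$final_set), 10)
  expect_true(all(tr1$top105 %in% tr1$surviving_after_correlation))
  expect_true(all(tr1$mrmr50 %in% tr1$top105))
  expect_true(all(tr1$final_set %in% tr1$candidate10))
  # manhattan data covers every screened feature
  md <- manhattan_data(tr1$univariate_auc)
  expect_equal(nrow(md), length(tr1$surviving_after_correlation))
})
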