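# Repeated stratified CV evaluation: AUC identity, determinism, calibration.

test_that("pooled-score AUC equals the Mann-Whitney statistic exactly", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    y <- integer(n)
    y[sample(n, sample(2:(n - 2), 1))] <- 1L
    # scores with ties to exercise midrank handling
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(auc_mw(scores, y), oracle_roc_auc(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("ridge logistic approaches glm as the penalty vanishes", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(runif(n) < plogis(0.3 + X %*% c(1, -0.5, 0)))
  ours <- ridge_logistic(X, y, lambda = 1e-10)
  ref <- unname(coef(glm(y ~ X, family = binomial())))
  expect_equal(ours, ref, tolerance = 1e-5)
})

test_that("stratified folds keep both classes everywhere", {
  cv <- cv_protocol(n_folds = 3L)
  y <- c(rep(1L, 5), rep(0L, 25))
  set.seed(14)
  for (i in 1:20) {
    folds <- pcatomics:::make_folds(y, cv)
    for (f in 1:3) {
      expect_gte(sum(y[folds == f] == 1), 1)
      expect_gte(sum(y[folds == f] == 0), 1)
    }
  }
  expect_error(pcatomics:::make_folds(c(1L, 1L, rep(0L, 10)), cv),
               "class count")
})

test_that("a perfectly separating feature gives AUC 1 with zero spread", {
  n <- 30
  y <- rep(c(TRUE, FALSE), 15)
  ft <- feature_table(
    data.frame(sep = as.numeric(y) * 5 + seq_len(n) * 1e-3,
               other = rnorm(n)),
    data.frame(tcfa = y, mc = y, tcfa_mc = y))
  md <- evaluate_model(ft, "sep", "tcfa", cv_protocol(n_repeats = 25L,
                                                      rng_seed = 15L))
  expect_equal(md$mean_auc, 1.0)
  expect_equal(md$sd_auc, 0.0)
  expect_length(md$per_repeat_auc, 25)
})

test_that("permutation null is centred at one half", {
  set.seed(16)
  n <- 30
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  # average over independent label permutations of a fixed feature matrix;
  # pooling out-of-fold scores is known to be slightly pessimistic on null
  # data, so the permutation mean sits a little below 0.5
  means <- vapply(1:30, function(i) {
    y <- sample(rep(c(TRUE, FALSE), 15))
    ft <- feature_table(as.data.frame(X),
                        data.frame(tcfa = y, mc = y, tcfa_mc = y))
    evaluate_model(ft, colnames(X), "tcfa",
                   cv_protocol(n_repeats = 30L, rng_seed = 100 + i))$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("model results are deterministic and internally consistent", {
  ft <- random_feature_table(n = 30, per_family = 3, n_informative = 3,
                             effect = 2, seed = 17)
  cv <- cv_protocol(n_repeats = 30L, rng_seed = 18L)
  feats <- colnames(ft)[1:5]
  m1 <- evaluate_model(ft, feats, "tcfa", cv)
  m2 <- evaluate_model(ft, feats, "tcfa", cv)
  expect_identical(m1$per_repeat_auc, m2$per_repeat_auc)
  expect_equal(m1$mean_auc, mean(m1$per_repeat_auc))
  expect_equal(m1$sd_auc, sd(m1$per_repeat_auc))
  expect_true(all(diff(m1$mean_roc$tpr) >= -1e-12))
  expect_equal(m1$mean_roc$fpr, seq(0, 1, length.out = 101))
  expect_true(m1$mean_auc >= 0 && m1$mean_auc <= 1)
})

test_that("compare_ranges tabulates every supplied model", {
  ft_loi <- random_feature_table(n = 30, per_family = 3, n_informative = 2,
                                 effect = 2, seed = 19, range_kind = "LOI")
  ft_ves <- random_feature_table(n = 30, per_family = 3, n_informative = 2,
                                 effect = 2, seed = 19, range_kind = "Vessel")
  cv <- cv_protocol(n_repeats = 10L, rng_seed = 20L)
  models <- list()
  for (tg in c("tcfa", "mc", "tcfa_mc")) {
    models[[paste0(tg, "_LOI")]] <-
      evaluate_model(ft_loi, colnames(ft_loi)[1:3], tg, cv)
    models[[paste0(tg, "_Vessel")]] <-
      evaluate_model(ft_ves, colnames(ft_ves)[1:3], tg, cv)
  }
  tab <- compare_ranges(models)
  expect_equal(nrow(tab), 6)
  expect_setequal(paste(tab$target, tab$range),
                  c("TCFA LOI", "TCFA Vessel", "MC LOI", "MC Vessel",
                    "TCFA_MC LOI", "TCFA_MC Vessel"))
  # identical inputs give identical summaries
  tab2 <- compare_ranges(models)
  expect_identical(tab, tab2)
  # summary mean equals the independently recomputed mean of per-repeat AUCs
  expect_equal(tab$mean_auc[1],
               mean(models[[1]]$per_repeat_auc))
  expect_false(is.null(attr(tab, "roc")))
})

test_that("Mann-Whitney AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    n <- 25
    y <- sample(c(rep(1L, 10), rep(0L, 15)))
    s <- rnorm(n) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc_mw(s, y), ref, tolerance = 1e-12)
  }
})
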