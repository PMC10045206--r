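# Texture matrices and features against brute-force enumeration oracles.

test_that("discretization maps the HU window onto 1..n_bins", {
  expect_equal(discretize(-190, 8), 1L)
  expect_equal(discretize(-30, 8), 8L)
  # midpoint of the window with 16 bins of width 10 HU
  expect_equal(discretize(-110, 16), 9L)
  expect_equal(discretize(c(-500, 10), 8), c(1L, 8L))  # clamped
  expect_length(discretize(numeric(0), 8), 0)
  expect_true(all(discretize(rep(-77.3, 50), 32) ==
                    discretize(-77.3, 32)))
})

test_that("GLCM of simple patterns matches hand enumeration", {
  lev <- matrix(1L, 2, 2)
  P <- glcm_matrix(lev, 1)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  # 3x3 checkerboard of levels 1/2
  lev <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L), 3, 3)
  P <- glcm_matrix(lev, 2)
  expect_equal(P, t(P), ignore_attr = TRUE)
  cnt <- oracle_glcm(lev, 2)
  expect_equal(unclass(P)[seq_along(cnt)], cnt / sum(cnt),
               ignore_attr = TRUE)

  # diagonal-uniform GLCM has zero contrast; uniform GLCM has energy 1/Ng^2
  Pd <- diag(4) / 4; attr(Pd, "n_pairs") <- 16
  expect_equal(unname(glcm_features(Pd)["contrast"]), 0)
  Pu <- matrix(1 / 16, 4, 4); attr(Pu, "n_pairs") <- 16
  expect_equal(unname(glcm_features(Pu)["joint_energy"]), 1 / 16)

  # joint entropy against direct summation
  ent <- -sum(P[P > 0] * log2(P[P > 0]))
  expect_equal(unname(glcm_features(P)["joint_entropy"]), ent)
})

test_that("GLCM degenerate masks use the documented conventions", {
  lev <- matrix(c(1L, NA), 1, 2)    # single pixel: no pairs
  P <- glcm_matrix(lev, 4)
  expect_equal(attr(P, "n_pairs"), 0)
  f <- glcm_features(P)
  expect_equal(unname(f["correlation"]), 1)
  expect_equal(unname(f["mcc"]), 1)
  expect_equal(unname(f["joint_entropy"]), 0)

  lev <- matrix(2L, 3, 3)           # single gray level
  f <- glcm_features(glcm_matrix(lev, 4))
  expect_equal(unname(f["correlation"]), 1)
  expect_equal(unname(f["contrast"]), 0)
})

test_that("GLDM of a constant mask matches hand counts", {
  lev <- matrix(1L, 3, 3)
  f <- gldm_features(lev, 1)
  # dependences: 4 corners -> 3, 4 edges -> 5, centre -> 8 (j = dep + 1)
  j <- c(4, 4, 4, 4, 6, 6, 6, 6, 9)
  expect_equal(unname(f["dependence_variance"]), mean((j - mean(j))^2))
  expect_equal(unname(f["large_dependence_emphasis"]), mean(j^2))

  lev1 <- matrix(c(1L, NA, NA, NA), 2, 2)  # single pixel: dependence 0
  f1 <- gldm_features(lev1, 2)
  expect_equal(unname(f1["dependence_variance"]), 0)
  expect_equal(unname(f1["small_dependence_emphasis"]), 1)
  expect_true(f1["dependence_nonuniformity_normalized"] > 0 &&
                f1["dependence_nonuniformity_normalized"] <= 1)
})

test_that("GLRLM runs match hand enumeration", {
  lev <- matrix(3L, 1, 5)  # one row of 5 identical levels
  runs <- pcatomics:::glrlm_runs(lev)
  expect_equal(runs[[1]]$length, 5)           # 0 degrees: one run of 5
  expect_equal(nrow(runs[[3]]), 5)            # 90 degrees: 5 runs of 1
  f <- glrlm_features(lev, 4)
  expect_true(f["long_run_emphasis"] > 1)

  # checkerboard: all runs at 0 degrees have length 1
  lev <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2L) + 1L)
  expect_true(all(pcatomics:::glrlm_runs(lev)[[1]]$length == 1))
  # 4-level tiling: no two equal neighbours in any direction -> SRE = 1
  lev4 <- outer(1:4, 1:4, function(r, c) (r %% 2L) * 2L + (c %% 2L) + 1L)
  f <- glrlm_features(lev4, 4)
  expect_equal(unname(f["short_run_emphasis"]), 1)
  expect_equal(unname(f["run_percentage"]), 1)
})

test_that("GLSZM zones match a flood-fill oracle", {
  lev <- matrix(2L, 4, 4)
  f <- glszm_features(lev, 4)
  expect_equal(unname(f["zone_percentage"]), 1 / 16)

  # 4-level tiling: every pixel is its own 8-connected zone
  lev <- outer(1:4, 1:4, function(r, c) (r %% 2L) * 2L + (c %% 2L) + 1L)
  f <- glszm_features(lev, 4)
  expect_equal(unname(f["small_area_emphasis"]), 1)

  set.seed(42)
  for (i in 1:20) {
    lev <- random_level_matrix(4)
    z <- oracle_zones(lev)
    lab <- pcatomics:::label_zones(lev)
    expect_equal(length(unique(stats::na.omit(as.vector(lab)))), nrow(z))
  }
})

test_that("NGTDM handles constant and toy inputs per the conventions", {
  lev <- matrix(2L, 3, 3)
  f <- ngtdm_features(lev, 4)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["coarseness"]), 1e6)

  lev <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 2L), 3, 3)
  o <- oracle_ngtdm(lev, 2)
  f <- ngtdm_features(lev, 2)
  expect_true(f["busyness"] >= 0)
  # independent recomputation of coarseness from the oracle columns
  nvp <- sum(o$n_i)
  p_i <- o$n_i / nvp
  expect_equal(unname(f["coarseness"]),
               min(1 / sum(p_i * o$s_i), 1e6))
})

test_that("all texture families match brute-force enumeration on random masks", {
  set.seed(20260115)
  n_cases <- 220
  for (case in seq_len(n_cases)) {
    nb <- sample(2:8, 1)
    lev <- random_level_matrix(nb)

    # GLCM: counts exact, features via the oracle matrix
    P_impl <- glcm_matrix(lev, nb)
    cnt <- oracle_glcm(lev, nb)
    expect_equal(attr(P_impl, "n_pairs"), sum(cnt))
    if (sum(cnt) > 0) {
      expect_equal(unclass(P_impl)[seq_along(cnt)], cnt / sum(cnt),
                   tolerance = 1e-12, ignore_attr = TRUE)
      P_or <- cnt / sum(cnt); attr(P_or, "n_pairs") <- sum(cnt)
      expect_equal(glcm_features(P_impl), glcm_features(P_or),
                   tolerance = 1e-9)
    }

    # GLDM
    P_or <- oracle_gldm(lev, nb)
    f_or <- pcatomics:::gldm_features_from_matrix(P_or)
    expect_equal(gldm_features(lev, nb), f_or, tolerance = 1e-9)

    # GLRLM: per-angle matrices and angle-averaged features
    np <- sum(!is.na(lev))
    offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
    f_angles <- vapply(offs, function(o) {
      P <- oracle_glrlm_angle(lev, nb, o[1], o[2])
      pcatomics:::rl_features_from_matrix(
        P, np, pcatomics:::GLRLM_FEATURES, "run")
    }, numeric(16))
    expect_equal(glrlm_features(lev, nb), rowMeans(f_angles),
                 tolerance = 1e-9)

    # GLSZM
    P_or <- oracle_glszm(lev, nb)
    f_or <- pcatomics:::rl_features_from_matrix(
      P_or, np, pcatomics:::GLSZM_FEATURES, "zone")
    expect_equal(glszm_features(lev, nb), f_or, tolerance = 1e-9)

    # NGTDM: features recomputed from oracle n_i / s_i columns
    o <- oracle_ngtdm(lev, nb)
    nvp <- sum(o$n_i)
    f_impl <- ngtdm_features(lev, nb)
    if (nvp > 0) {
      p_i <- o$n_i / nvp
      occ <- which(p_i > 0); ngp <- length(occ)
      coarse <- if (sum(p_i * o$s_i) > 0)
        min(1 / sum(p_i * o$s_i), 1e6) else 1e6
      expect_equal(unname(f_impl["coarseness"]), coarse, tolerance = 1e-9)
      if (ngp > 1) {
        contr <- sum(outer(p_i[occ], p_i[occ]) *
                       outer(occ, occ, "-")^2) / (ngp * (ngp - 1)) *
          sum(o$s_i) / nvp
        expect_equal(unname(f_impl["contrast"]), contr, tolerance = 1e-9)
        compl <- sum(abs(outer(occ, occ, "-")) *
                       outer(p_i[occ] * o$s_i[occ],
                             p_i[occ] * o$s_i[occ], "+") /
                       outer(p_i[occ], p_i[occ], "+")) / nvp
        expect_equal(unname(f_impl["complexity"]), compl, tolerance = 1e-9)
      }
    }
  }
})

test_that("texture matrix normalizations conserve structure counts", {
  set.seed(7)
  for (i in 1:25) {
    nb <- sample(2:6, 1)
    lev <- random_level_matrix(nb)
    P <- glcm_matrix(lev, nb)
    if (attr(P, "n_pairs") > 0) expect_equal(sum(P), 1)
    # GLSZM zone count equals flood-fill component count
    expect_equal(sum(oracle_glszm(lev, nb)), nrow(oracle_zones(lev)))
    # GLDM dependence count equals number of mask pixels
    expect_equal(sum(oracle_gldm(lev, nb)), sum(!is.na(lev)))
    # per-angle run matrices each conserve total pixels when weighted by length
    for (o in list(c(0, 1), c(-1, 1))) {
      P_r <- oracle_glrlm_angle(lev, nb, o[1], o[2])
      expect_equal(sum(P_r %*% seq_len(ncol(P_r))), sum(!is.na(lev)))
    }
  }
})
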