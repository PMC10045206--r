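# Gray-level texture matrices and their derived features (GLCM, GLDM, GLRLM,
# GLSZM, NGTDM), computed in 2D per slice on a discretized, masked image.
# Formulas follow the IBSI definitions. All matrices use distance 1 and, where
# directional, the four 2D angles (0, 45, 90, 135 degrees); zones and
# dependences use 8-connectivity.

GLCM_FEATURES <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "id", "idm", "idmn", "idn",
  "imc1", "imc2", "inverse_variance", "joint_energy", "joint_entropy", "mcc",
  "maximum_probability", "sum_average", "sum_entropy", "sum_squares")

GLDM_FEATURES <- c(
  "small_dependence_emphasis", "large_dependence_emphasis",
  "gray_level_nonuniformity", "dependence_nonuniformity",
  "dependence_nonuniformity_normalized", "gray_level_variance",
  "dependence_variance", "dependence_entropy", "low_gray_level_emphasis",
  "high_gray_level_emphasis", "small_dependence_low_gray_level_emphasis",
  "small_dependence_high_gray_level_emphasis",
  "large_dependence_low_gray_level_emphasis",
  "large_dependence_high_gray_level_emphasis")

GLRLM_FEATURES <- c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "run_length_nonuniformity",
  "run_length_nonuniformity_normalized", "run_percentage",
  "gray_level_variance", "run_variance", "run_entropy",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis")

GLSZM_FEATURES <- c(
  "small_area_emphasis", "large_area_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "size_zone_nonuniformity",
  "size_zone_nonuniformity_normalized", "zone_percentage",
  "gray_level_variance", "zone_variance", "zone_entropy",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_area_low_gray_level_emphasis", "small_area_high_gray_level_emphasis",
  "large_area_low_gray_level_emphasis", "large_area_high_gray_level_emphasis")

NGTDM_FEATURES <- c("coarseness", "contrast", "busyness", "complexity",
                    "strength")

# Offsets for the four 2D angles at distance 1, as (dr, dc).
ANGLE_OFFSETS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
# All eight neighbour offsets.
NEIGH8 <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
               c(1L, -1L), c(1L, 0L), c(1L, 1L))

#' Discretize HU values into equal-width gray levels
#'
#' Values are clamped to `range_hu` and binned into `n_bins` equal-width
#' levels; the lower bound maps to level 1 and the upper bound to level
#' `n_bins`.
#'
#' @param hu_values numeric vector of HU values.
#' @param n_bins number of gray levels (8, 16 or 32 in the standard
#'   pipeline, but any positive integer is accepted).
#' @param range_hu discretization range, default the adipose window
#'   `c(-190, -30)`.
#' @return integer vector of levels in `1..n_bins`.
#' @export
discretize <- function(hu_values, n_bins, range_hu = PCAT_HU_WINDOW) {
  if (length(hu_values) == 0L) return(integer(0))
  lo <- range_hu[1]; hi <- range_hu[2]
  stopifnot(n_bins >= 1, hi > lo)
  x <- pmin(pmax(hu_values, lo), hi)
  width <- (hi - lo) / n_bins
  as.integer(pmin(floor((x - lo) / width) + 1, n_bins))
}

# Build a level matrix (NA outside the mask) from an HU slice.
level_matrix <- function(hu_slice, mask, n_bins, range_hu = PCAT_HU_WINDOW) {
  lev <- matrix(NA_integer_, nrow(hu_slice), ncol(hu_slice))
  lev[mask] <- discretize(hu_slice[mask], n_bins, range_hu)
  lev
}

#' Gray-level co-occurrence matrix
#'
#' Counts distance-1 level pairs over the four 2D angles where both pixels
#' lie in the mask, symmetrized (each pair counted in both directions) and
#' normalized to sum 1. The raw pair count is attached as attribute
#' `n_pairs`; a mask with fewer than two neighbouring in-mask pixels yields
#' an all-zero matrix with `n_pairs = 0`.
#'
#' @param levels integer level matrix with `NA` outside the mask (see
#'   [discretize()]).
#' @param n_bins number of gray levels.
#' @return `n_bins x n_bins` symmetric matrix summing to 1 (or 0 when
#'   degenerate).
#' @export
glcm_matrix <- function(levels, n_bins) {
  counts <- numeric(n_bins * n_bins)
  for (off in ANGLE_OFFSETS) {
    sh <- shift_matrix(levels, off[1], off[2], NA_integer_)
    ok <- !is.na(levels) & !is.na(sh)
    if (!any(ok)) next
    a <- levels[ok]; b <- sh[ok]
    counts <- counts + tabulate(a + n_bins * (b - 1L), n_bins * n_bins) +
      tabulate(b + n_bins * (a - 1L), n_bins * n_bins)
  }
  P <- matrix(counts, n_bins, n_bins)
  tot <- sum(P)
  if (tot > 0) P <- P / tot
  attr(P, "n_pairs") <- tot
  P
}

#' GLCM-derived texture features
#'
#' The 24 standard co-occurrence features. Log terms use base-2 logarithms
#' with the `0 log 0 = 0` convention. For a single-gray-level mask the
#' correlation and maximal-correlation coefficient are set to 1 (perfect
#' correlation convention) and the information measures to 0.
#'
#' @param P normalized symmetric GLCM from [glcm_matrix()].
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(P) {
  ng <- nrow(P)
  out <- stats::setNames(numeric(length(GLCM_FEATURES)), GLCM_FEATURES)
  if (is.null(attr(P, "n_pairs")) || sum(P) == 0) {
    out["correlation"] <- 1; out["mcc"] <- 1
    return(out)
  }
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)  # == colSums by symmetry
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)

  # p_{x+y} over k = 2..2ng and p_{x-y} over k = 0..ng-1
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]),
                    numeric(1))
  k_dif <- 0:(ng - 1)

  out["autocorrelation"] <- sum(i * j * P)
  out["joint_average"] <- mu
  out["cluster_prominence"] <- sum((i + j - 2 * mu)^4 * P)
  out["cluster_shade"] <- sum((i + j - 2 * mu)^3 * P)
  out["cluster_tendency"] <- sum((i + j - 2 * mu)^2 * P)
  out["contrast"] <- sum((i - j)^2 * P)
  out["correlation"] <- if (sig2 > 0)
    (sum(i * j * P) - mu^2) / sig2 else 1
  da <- sum(k_dif * pxy_dif)
  out["difference_average"] <- da
  out["difference_entropy"] <- -sum(xlog2x(pxy_dif))
  out["difference_variance"] <- sum((k_dif - da)^2 * pxy_dif)
  out["id"] <- sum(P / (1 + abs(i - j)))
  out["idm"] <- sum(P / (1 + (i - j)^2))
  out["idmn"] <- sum(P / (1 + (i - j)^2 / ng^2))
  out["idn"] <- sum(P / (1 + abs(i - j) / ng))
  hx <- -sum(xlog2x(px))
  hxy <- -sum(xlog2x(P))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P * ifelse(pxpy > 0, log2(pmax(pxpy, .Machine$double.xmin)), 0))
  hxy2 <- -sum(xlog2x(pxpy))
  out["imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  out["imc2"] <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  off_diag <- abs(i - j) > 0
  out["inverse_variance"] <- sum(P[off_diag] / (i - j)[off_diag]^2)
  out["joint_energy"] <- sum(P^2)
  out["joint_entropy"] <- hxy
  out["mcc"] <- glcm_mcc(P, px)
  out["maximum_probability"] <- max(P)
  out["sum_average"] <- sum(k_sum * pxy_sum)
  out["sum_entropy"] <- -sum(xlog2x(pxy_sum))
  out["sum_squares"] <- sig2
  out
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k)), restricted to occupied levels.
glcm_mcc <- function(P, px) {
  keep <- which(px > 0)
  if (length(keep) < 2L) return(1)
  Psub <- P[keep, keep, drop = FALSE]
  pxs <- px[keep]
  Q <- matrix(0, length(keep), length(keep))
  for (k in seq_along(keep))
    Q <- Q + outer(Psub[, k] / pxs, Psub[, k] / pxs[k])
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}

#' Gray-level dependence matrix features
#'
#' Dependence of a pixel = number of its 8-neighbours inside the mask whose
#' level differs by at most `alpha`. The matrix counts (gray level,
#' dependence + 1) pairs over all mask pixels.
#'
#' @param levels integer level matrix with `NA` outside the mask.
#' @param n_bins number of gray levels.
#' @param alpha dependence tolerance (default 0).
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(levels, n_bins, alpha = 0L) {
  inmask <- !is.na(levels)
  dep <- matrix(0L, nrow(levels), ncol(levels))
  for (off in NEIGH8) {
    sh <- shift_matrix(levels, off[1], off[2], NA_integer_)
    dep <- dep + (inmask & !is.na(sh) & abs(sh - levels) <= alpha)
  }
  g <- levels[inmask]
  d <- dep[inmask] + 1L  # dependence sizes j = dep + 1
  nd <- max(d)
  P <- matrix(tabulate(g + n_bins * (d - 1L), n_bins * nd), n_bins, nd)
  gldm_features_from_matrix(P)
}

gldm_features_from_matrix <- function(P) {
  out <- stats::setNames(numeric(length(GLDM_FEATURES)), GLDM_FEATURES)
  nz <- sum(P)
  if (nz == 0) return(out)
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  p <- P / nz
  pg <- rowSums(P); pd <- colSums(P)
  mu_g <- sum(seq_len(ng) * pg) / nz
  mu_d <- sum(seq_len(nd) * pd) / nz
  out["small_dependence_emphasis"] <- sum(P / j^2) / nz
  out["large_dependence_emphasis"] <- sum(P * j^2) / nz
  out["gray_level_nonuniformity"] <- sum(pg^2) / nz
  out["dependence_nonuniformity"] <- sum(pd^2) / nz
  out["dependence_nonuniformity_normalized"] <- sum(pd^2) / nz^2
  out["gray_level_variance"] <- sum(p * (i - mu_g)^2)
  out["dependence_variance"] <- sum(p * (j - mu_d)^2)
  out["dependence_entropy"] <- -sum(xlog2x(p))
  out["low_gray_level_emphasis"] <- sum(P / i^2) / nz
  out["high_gray_level_emphasis"] <- sum(P * i^2) / nz
  out["small_dependence_low_gray_level_emphasis"] <- sum(P / (i^2 * j^2)) / nz
  out["small_dependence_high_gray_level_emphasis"] <- sum(P * i^2 / j^2) / nz
  out["large_dependence_low_gray_level_emphasis"] <- sum(P * j^2 / i^2) / nz
  out["large_dependence_high_gray_level_emphasis"] <- sum(P * i^2 * j^2) / nz
  out
}

# Extract maximal runs of equal levels along the four angles. Returns a list
# of per-angle data.frames with columns (level, length). Lines are encoded
# into the run key so runs never cross line boundaries.
glrlm_runs <- function(levels) {
  rr <- row(levels); cc <- col(levels)
  lines <- list(rr, rr + cc, cc, rr - cc)      # 0, 45, 90, 135 degrees
  along <- list(cc, cc, rr, cc)                # ordering within a line
  lapply(seq_len(4), function(a) {
    o <- order(lines[[a]], along[[a]])
    v <- as.numeric(levels[o])
    line_id <- lines[[a]][o] - min(lines[[a]]) # nonnegative
    key <- v * 1e6 + line_id                   # NA where v is NA
    r <- rle(key)
    ok <- !is.na(r$values)
    data.frame(level = as.integer(r$values[ok] %/% 1e6),
               length = r$lengths[ok])
  })
}

#' Gray-level run-length matrix features
#'
#' Maximal runs of identical levels along the four 2D angles; the 16
#' standard features are computed per angle and averaged.
#'
#' @inheritParams gldm_features
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(levels, n_bins) {
  np <- sum(!is.na(levels))
  runs <- glrlm_runs(levels)
  feats <- vapply(runs, function(rr) {
    if (nrow(rr) == 0L)
      return(stats::setNames(numeric(length(GLRLM_FEATURES)), GLRLM_FEATURES))
    nl <- max(rr$length)
    P <- matrix(0, n_bins, nl)
    cnt <- tapply(rep(1, nrow(rr)), list(factor(rr$level, levels = 1:n_bins),
                                         factor(rr$length, levels = 1:nl)),
                  sum, default = 0)
    P[] <- cnt
    rl_features_from_matrix(P, np, GLRLM_FEATURES, "run")
  }, numeric(length(GLRLM_FEATURES)))
  rowMeans(feats)
}

# Shared feature formulas for run-length and size-zone matrices: P indexed by
# (gray level i, size/length j); np = number of mask pixels.
rl_features_from_matrix <- function(P, np, feature_names, kind) {
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  ns <- sum(P)  # number of runs / zones
  if (ns == 0) return(out)
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- P / ns
  pg <- rowSums(P); pl <- colSums(P)
  mu_g <- sum(seq_len(ng) * pg) / ns
  mu_l <- sum(seq_len(nl) * pl) / ns
  short <- sum(P / j^2) / ns
  long <- sum(P * j^2) / ns
  vals <- c(
    short, long,
    sum(pg^2) / ns, sum(pg^2) / ns^2,
    sum(pl^2) / ns, sum(pl^2) / ns^2,
    ns / np,
    sum(p * (i - mu_g)^2), sum(p * (j - mu_l)^2),
    -sum(xlog2x(p)),
    sum(P / i^2) / ns, sum(P * i^2) / ns,
    sum(P / (i^2 * j^2)) / ns, sum(P * i^2 / j^2) / ns,
    sum(P * j^2 / i^2) / ns, sum(P * i^2 * j^2) / ns)
  out[] <- vals
  out
}

# 8-connected components of equal-level pixels (zones); NA outside the mask.
# Pixels are graph vertices, edges join adjacent same-level pixels, and zones
# are the connected components. Returns an integer matrix of zone labels.
label_zones <- function(levels) {
  lab <- matrix(NA_integer_, nrow(levels), ncol(levels))
  inmask <- !is.na(levels)
  npix <- sum(inmask)
  if (npix == 0L) return(lab)
  pix <- matrix(NA_integer_, nrow(levels), ncol(levels))
  pix[inmask] <- seq_len(npix)
  a <- integer(0); b <- integer(0)
  for (off in NEIGH8[c(3L, 5L, 7L, 8L)]) {  # NE, E, S, SE: undirected edges
    shp <- shift_matrix(pix, off[1], off[2], NA_integer_)
    shv <- shift_matrix(levels, off[1], off[2], NA_integer_)
    ok <- inmask & !is.na(shp) & shv == levels
    a <- c(a, pix[ok]); b <- c(b, shp[ok])
  }
  g <- igraph::make_graph(rbind(a, b), n = npix, directed = FALSE)
  lab[inmask] <- igraph::components(g)$membership
  lab
}

#' Gray-level size-zone matrix features
#'
#' Zones are 8-connected components of equal gray level; the matrix counts
#' (level, zone size) pairs and the 16 standard features are derived.
#'
#' @inheritParams gldm_features
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(levels, n_bins) {
  np <- sum(!is.na(levels))
  out <- stats::setNames(numeric(length(GLSZM_FEATURES)), GLSZM_FEATURES)
  if (np == 0L) return(out)
  lab <- label_zones(levels)
  zl <- lab[!is.na(lab)]
  gl <- levels[!is.na(lab)]
  sizes <- table(zl)
  zone_level <- gl[match(as.integer(names(sizes)), zl)]
  zone_size <- as.integer(sizes)
  ns_max <- max(zone_size)
  P <- matrix(0, n_bins, ns_max)
  cnt <- tapply(rep(1, length(zone_size)),
                list(factor(zone_level, levels = 1:n_bins),
                     factor(zone_size, levels = 1:ns_max)),
                sum, default = 0)
  P[] <- cnt
  out[] <- rl_features_from_matrix(P, np, GLSZM_FEATURES, "zone")
  out
}

#' Neighbouring gray-tone difference matrix features
#'
#' For each mask pixel with at least one in-mask 8-neighbour, the absolute
#' difference between its level and the mean level of its in-mask neighbours
#' is accumulated per gray level. Coarseness is capped at 1e6 when its
#' denominator vanishes (constant mask); contrast and busyness are 0 for a
#' single occupied gray level.
#'
#' @inheritParams gldm_features
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(levels, n_bins) {
  out <- stats::setNames(numeric(length(NGTDM_FEATURES)), NGTDM_FEATURES)
  inmask <- !is.na(levels)
  nbr_sum <- matrix(0, nrow(levels), ncol(levels))
  nbr_n <- matrix(0L, nrow(levels), ncol(levels))
  for (off in NEIGH8) {
    sh <- shift_matrix(levels, off[1], off[2], NA_integer_)
    valid <- !is.na(sh)
    nbr_sum[valid] <- nbr_sum[valid] + sh[valid]
    nbr_n <- nbr_n + valid
  }
  use <- inmask & nbr_n > 0
  if (!any(use)) return(out)
  diffs <- abs(levels[use] - nbr_sum[use] / nbr_n[use])
  g <- levels[use]
  nvp <- sum(use)
  n_i <- tabulate(g, n_bins)
  s_i <- vapply(seq_len(n_bins), function(k) sum(diffs[g == k]), numeric(1))
  p_i <- n_i / nvp
  occ <- which(p_i > 0)
  ngp <- length(occ)

  denom <- sum(p_i * s_i)
  out["coarseness"] <- if (denom > 0) min(1 / denom, 1e6) else 1e6
  if (ngp > 1) {
    ii <- occ
    pp <- p_i[occ]
    w <- outer(pp, pp) * outer(ii, ii, "-")^2
    out["contrast"] <- sum(w) / (ngp * (ngp - 1)) * sum(s_i) / nvp
    bus_den <- sum(abs(outer(ii * pp, ii * pp, "-")))
    out["busyness"] <- if (bus_den > 0) denom / bus_den else 0
    ssum <- outer(pp * s_i[occ], pp * s_i[occ], "+")
    psum <- outer(pp, pp, "+")
    out["complexity"] <- sum(abs(outer(ii, ii, "-")) * ssum / psum) / nvp
    str_num <- sum(psum * outer(ii, ii, "-")^2)
    out["strength"] <- if (sum(s_i) > 0) str_num / sum(s_i) else 0
  }
  out
}
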