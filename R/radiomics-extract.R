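# Per-slice feature extraction and across-slice aggregation into the
# 1356-value radiomic signature of a vessel range:
# 113 base features (21 shape + 17 first-order + 24 GLCM + 14 GLDM +
# 16 GLRLM + 16 GLSZM + 5 NGTDM), evaluated at 3 gray-level discretizations
# (8, 16, 32 bins over the adipose HU window) and aggregated across slices by
# min, max, mean and sample SD: 113 x 3 x 4 = 1356.

RADIOMIC_BINS <- c(8L, 16L, 32L)
RADIOMIC_STATS <- c("min", "max", "mean", "sd")
FEATURE_FAMILIES <- c("shape", "firstorder", "glcm", "gldm", "glrlm",
                      "glszm", "ngtdm")

base_feature_names <- function() {
  c(paste0("shape_", SHAPE_FEATURES),
    paste0("firstorder_", FIRSTORDER_FEATURES),
    paste0("glcm_", GLCM_FEATURES),
    paste0("gldm_", GLDM_FEATURES),
    paste0("glrlm_", GLRLM_FEATURES),
    paste0("glszm_", GLSZM_FEATURES),
    paste0("ngtdm_", NGTDM_FEATURES))
}

#' Feature family of radiomic feature names
#'
#' Parses the family tag (`shape`, `firstorder`, `glcm`, `gldm`, `glrlm`,
#' `glszm`, `ngtdm`) out of column names of the form
#' `{family}_{feature}_{bins}b` or `{stat}_{family}_{feature}_{bins}b`.
#'
#' @param names character vector of feature names.
#' @return character vector of family tags.
#' @export
feature_family <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  vapply(parts, function(p) {
    if (p[1] %in% FEATURE_FAMILIES) p[1]
    else if (length(p) >= 2 && p[2] %in% FEATURE_FAMILIES) p[2]
    else NA_character_
  }, character(1))
}

#' Extract the 113 base features of one slice at one discretization
#'
#' @param volume_slice numeric HU matrix.
#' @param mask logical PCAT mask for the slice (nonempty).
#' @param spacing_mm in-plane spacing `(dy, dx)` in mm.
#' @param n_bins gray-level count for the texture and histogram features.
#' @param range_hu discretization range, default the adipose window.
#' @return named numeric vector of length 113 (names `{family}_{feature}`).
#' @export
extract_slice_features <- function(volume_slice, mask, spacing_mm, n_bins,
                                   range_hu = PCAT_HU_WINDOW) {
  stopifnot(all(dim(volume_slice) == dim(mask)), any(mask))
  # crop to the mask bounding box (padded) for speed; all features are
  # translation invariant
  bb <- mask_bbox(mask, pad = 1L)
  hu <- volume_slice[bb$rows, bb$cols, drop = FALSE]
  m <- mask[bb$rows, bb$cols, drop = FALSE]
  x <- hu[m]
  lev_vec <- discretize(x, n_bins, range_hu)
  lev <- matrix(NA_integer_, nrow(m), ncol(m))
  lev[m] <- lev_vec

  shp <- shape_features(m, spacing_mm)
  fo <- first_order_features(x, lev_vec)
  glcm <- glcm_features(glcm_matrix(lev, n_bins))
  gldm <- gldm_features(lev, n_bins)
  glrlm <- stats::setNames(glrlm_features(lev, n_bins), GLRLM_FEATURES)
  glszm <- glszm_features(lev, n_bins)
  ngtdm <- ngtdm_features(lev, n_bins)

  stats::setNames(c(shp, fo, glcm, gldm, glrlm, glszm, ngtdm),
                  base_feature_names())
}

#' Per-slice feature matrix of a segmented vessel range
#'
#' Evaluates the 113 base features at each discretization for every retained
#' slice of a PCAT mask. Slices with fewer than `min_fat_voxels` fat voxels
#' are excluded from aggregation (logged).
#'
#' @param volume a [vessel_volume()].
#' @param pcat a `pcat_mask` from [segment_pcat()].
#' @param bins vector of gray-level counts, default `c(8, 16, 32)`.
#' @param min_fat_voxels minimum in-mask voxels for a slice to be retained
#'   (default 10).
#' @return numeric matrix, rows = retained slices, 339 named columns
#'   (`{family}_{feature}_{bins}b`), with attribute `slices`.
#' @export
slice_feature_matrix <- function(volume, pcat, bins = RADIOMIC_BINS,
                                 min_fat_voxels = 10L) {
  stopifnot(inherits(volume, "vessel_volume"), inherits(pcat, "pcat_mask"))
  sp <- volume$spacing_mm[2:3]
  keep <- pcat$n_fat_voxels >= min_fat_voxels
  if (any(!keep))
    msg(sum(!keep), " slice(s) with < ", min_fat_voxels,
        " fat voxels excluded from aggregation")
  slices <- pcat$slices[keep]
  if (length(slices) == 0L) stop("no PCAT in range")
  cols <- as.vector(vapply(bins, function(b)
    paste0(base_feature_names(), "_", b, "b"), character(113L)))
  out <- matrix(NA_real_, length(slices), length(cols),
                dimnames = list(as.character(slices), cols))
  for (k in seq_along(slices)) {
    s <- slices[k]
    m <- pcat$masks[[as.character(s)]]
    sl <- volume$voxels[, , s]
    out[k, ] <- unlist(lapply(bins, function(b)
      extract_slice_features(sl, m, sp, b)), use.names = FALSE)
  }
  attr(out, "slices") <- slices
  out
}

#' Aggregate per-slice features into the 1356-value vessel signature
#'
#' For each of the 339 slice-level columns, emits the minimum, maximum, mean
#' and sample (n-1) standard deviation across slices; the SD is 0 when only
#' one slice is retained. Output names follow
#' `{stat}_{family}_{feature}_{bins}b`.
#'
#' @param mat slice feature matrix from [slice_feature_matrix()].
#' @return named numeric vector of length `4 * ncol(mat)` (1356 for the
#'   standard 339-column matrix).
#' @export
aggregate_features <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  mins <- apply(mat, 2, min)
  maxs <- apply(mat, 2, max)
  means <- colMeans(mat)
  sds <- apply(mat, 2, sd0)
  stats::setNames(
    c(mins, maxs, means, sds),
    as.vector(vapply(RADIOMIC_STATS, function(s)
      paste0(s, "_", colnames(mat)), character(ncol(mat)))))
}

#' Full radiomic signature of one vessel range
#'
#' Convenience wrapper: segments PCAT over the requested range and returns
#' the aggregated 1356-value feature vector.
#'
#' @inheritParams segment_pcat
#' @inheritParams slice_feature_matrix
#' @return named numeric vector of length 1356.
#' @export
extract_features <- function(volume, walls, range_kind = c("LOI", "Vessel"),
                             bins = RADIOMIC_BINS, min_fat_voxels = 10L) {
  range_kind <- match.arg(range_kind)
  pcat <- segment_pcat(volume, walls, range_kind)
  aggregate_features(slice_feature_matrix(volume, pcat, bins,
                                          min_fat_voxels))
}

#' Radiomic feature table of a cohort
#'
#' Extracts the 1356-value signature of every vessel in a phantom cohort for
#' one range kind and assembles the rows into a feature table carrying the
#' vessel labels.
#'
#' @param cohort result of [generate_cohort()].
#' @param range_kind `"LOI"` or `"Vessel"`.
#' @inheritParams slice_feature_matrix
#' @return a `feature_table`: data.frame of features (rows = vessels) with
#'   attributes `labels` (data.frame) and `range_kind`.
#' @export
build_feature_table <- function(cohort, range_kind = c("LOI", "Vessel"),
                                bins = RADIOMIC_BINS, min_fat_voxels = 10L) {
  range_kind <- match.arg(range_kind)
  rows <- lapply(cohort$vessels, function(v)
    extract_features(v$volume, v$walls, range_kind, bins, min_fat_voxels))
  mat <- do.call(rbind, rows)
  rownames(mat) <- cohort$labels$vessel_id
  feature_table(as.data.frame(mat), cohort$labels, range_kind)
}

#' Construct a feature table
#'
#' @param features data.frame or matrix of feature values (rows = vessels,
#'   unique column names, no missing values).
#' @param labels data.frame with logical columns `tcfa`, `mc`, `tcfa_mc`
#'   (one row per vessel).
#' @param range_kind `"LOI"` or `"Vessel"`.
#' @return an object of class `feature_table` (a data.frame).
#' @export
feature_table <- function(features, labels, range_kind = c("LOI", "Vessel")) {
  range_kind <- match.arg(range_kind)
  df <- as.data.frame(features)
  stopifnot(!anyNA(df), !anyDuplicated(colnames(df)),
            nrow(df) == nrow(labels),
            all(c("tcfa", "mc", "tcfa_mc") %in% names(labels)))
  structure(df, labels = labels, range_kind = range_kind,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  labs <- attr(x, "labels")
  cat(sprintf("Feature table (%s range): %d vessels x %d features\n",
              attr(x, "range_kind"), nrow(x), ncol(x)))
  cat(sprintf("  labels: %d TCFA, %d MC, %d TCFA+MC\n",
              sum(labs$tcfa), sum(labs$mc), sum(labs$tcfa_mc)))
  invisible(x)
}

# Restrict a feature table to a column subset, keeping attributes.
ft_subset <- function(table, cols) {
  feature_table(as.data.frame(table)[, cols, drop = FALSE],
                attr(table, "labels"), attr(table, "range_kind"))
}

# Label vector (0/1) for a target.
ft_target <- function(table, target = c("tcfa", "mc", "tcfa_mc")) {
  target <- match.arg(tolower(target), c("tcfa", "mc", "tcfa_mc"))
  as.integer(attr(table, "labels")[[target]])
}
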