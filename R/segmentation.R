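# PCAT segmentation: peri-vessel annulus of radial width equal to the vessel
# diameter, intersected with the adipose Hounsfield window (-190..-30 HU),
# restricted to the LOI or whole-vessel slice range.

PCAT_HU_WINDOW <- c(-190, -30)

#' Per-slice vessel diameter
#'
#' Equivalent-disc diameter `2 * sqrt(area / pi)` of the filled outer-wall
#' region, in mm. Rotation invariant and robust to irregular wall shapes.
#'
#' @param outer_wall_mask logical matrix (filled outer-wall region).
#' @param spacing_mm in-plane spacing `(dy, dx)` in mm.
#' @return vessel diameter in mm.
#' @export
vessel_diameter <- function(outer_wall_mask, spacing_mm) {
  stopifnot(is.matrix(outer_wall_mask), length(spacing_mm) == 2L,
            all(spacing_mm > 0))
  n_vox <- sum(outer_wall_mask)
  if (n_vox == 0L) stop("no wall on slice")
  area <- n_vox * spacing_mm[1] * spacing_mm[2]
  2 * sqrt(area / pi)
}

# 4-connected boundary voxels of a region (voxels with at least one
# non-region 4-neighbour or on the image edge). Distance from any outside
# point to the region is attained at a boundary voxel.
region_boundary <- function(mask) {
  inner <- shift_matrix(mask, 1, 0, FALSE) & shift_matrix(mask, -1, 0, FALSE) &
    shift_matrix(mask, 0, 1, FALSE) & shift_matrix(mask, 0, -1, FALSE)
  mask & !inner
}

#' Candidate PCAT annulus around the vessel wall
#'
#' Voxels strictly outside the filled outer-wall region whose Euclidean
#' distance (in mm, honouring anisotropic in-plane spacing) to the nearest
#' outer-wall voxel centre is at most `diameter_mm`.
#'
#' @param outer_wall_mask logical matrix, nonempty.
#' @param diameter_mm radial width of the annulus (the vessel diameter); a
#'   non-positive value yields an empty mask.
#' @param spacing_mm in-plane spacing `(dy, dx)` in mm.
#' @return logical matrix of annulus membership, disjoint from the wall.
#' @export
pcat_candidate_annulus <- function(outer_wall_mask, diameter_mm, spacing_mm) {
  stopifnot(is.matrix(outer_wall_mask), length(spacing_mm) == 2L,
            all(spacing_mm > 0))
  out <- matrix(FALSE, nrow(outer_wall_mask), ncol(outer_wall_mask))
  if (!any(outer_wall_mask)) stop("no wall on slice")
  if (diameter_mm <= 0) return(out)
  dy <- spacing_mm[1]; dx <- spacing_mm[2]
  # restrict the search to the wall bounding box padded by the annulus width
  pad <- ceiling(diameter_mm / min(dy, dx)) + 1L
  bb <- mask_bbox(outer_wall_mask, pad = pad)
  wall_bb <- outer_wall_mask[bb$rows, bb$cols, drop = FALSE]
  bnd <- which(region_boundary(wall_bb), arr.ind = TRUE)
  cand <- which(!wall_bb, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  # exact min distance to wall boundary voxel centres, vectorised
  d2 <- outer(cand[, 1] * dy, bnd[, 1] * dy, "-")^2 +
    outer(cand[, 2] * dx, bnd[, 2] * dx, "-")^2
  dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
  keep <- dmin <= diameter_mm
  out[cbind(bb$rows[cand[keep, 1]], bb$cols[cand[keep, 2]])] <- TRUE
  out
}

#' Adipose HU-window filter
#'
#' Restricts a candidate mask to voxels whose attenuation lies in
#' `[lo, hi]` HU, inclusive at both endpoints.
#'
#' @param volume_slice numeric HU matrix.
#' @param candidate logical matrix of candidate voxels, same shape.
#' @param lo,hi window bounds in HU (default -190 and -30).
#' @return logical matrix.
#' @export
apply_hu_window <- function(volume_slice, candidate,
                            lo = PCAT_HU_WINDOW[1], hi = PCAT_HU_WINDOW[2]) {
  stopifnot(all(dim(volume_slice) == dim(candidate)))
  candidate & volume_slice >= lo & volume_slice <= hi
}

#' Segment pericoronary adipose tissue
#'
#' Composes, per slice of the selected range, the peri-vessel annulus rule
#' (radial width = vessel diameter) with the adipose HU window. Slices with
#' an empty wall segmentation are skipped with a message. Optionally the
#' first `exclude_proximal_mm` of the range can be dropped (ostial exclusion
#' used for the right coronary artery).
#'
#' @param volume a [vessel_volume()].
#' @param walls a [wall_segmentation()] covering the selected range.
#' @param range_kind `"LOI"` or `"Vessel"`.
#' @param exclude_proximal_mm length (mm) to drop from the start of the
#'   range; default 0.
#' @return an object of class `pcat_mask`: list with `masks` (named list of
#'   logical matrices, names = slice indices), `slices`, `n_fat_voxels`,
#'   `hu_window`, `range_kind`.
#' @export
segment_pcat <- function(volume, walls, range_kind = c("LOI", "Vessel"),
                         exclude_proximal_mm = 0) {
  stopifnot(inherits(volume, "vessel_volume"),
            inherits(walls, "wall_segmentation"))
  range_kind <- match.arg(range_kind)
  rng <- if (range_kind == "LOI") volume$loi_range else volume$vessel_range
  slices <- seq.int(rng[1], rng[2])
  if (exclude_proximal_mm > 0) {
    drop_n <- floor(exclude_proximal_mm / volume$spacing_mm[1])
    slices <- slices[slices > rng[1] + drop_n - 1]
  }
  if (length(slices) == 0L) stop("selected slice range is empty")
  sp <- walls$spacing_mm
  masks <- list(); n_fat <- integer(0); kept <- integer(0)
  for (s in slices) {
    wall <- walls$outer_wall_masks[[s]]
    if (is.null(wall) || !any(wall)) {
      msg("slice ", s, ": empty wall segmentation, skipped")
      next
    }
    d <- walls$diameter_mm[s]
    if (is.na(d)) d <- vessel_diameter(wall, sp)
    ann <- pcat_candidate_annulus(wall, d, sp)
    m <- apply_hu_window(volume$voxels[, , s], ann)
    # hard invariants: fat mask disjoint from wall, HU within window
    stopifnot(!any(m & wall))
    hu <- volume$voxels[, , s][m]
    stopifnot(all(hu >= PCAT_HU_WINDOW[1] & hu <= PCAT_HU_WINDOW[2]))
    masks[[as.character(s)]] <- m
    kept <- c(kept, s)
    n_fat <- c(n_fat, sum(m))
  }
  if (length(masks) == 0L) stop("no PCAT in range")
  structure(list(masks = masks, slices = kept, n_fat_voxels = n_fat,
                 hu_window = PCAT_HU_WINDOW, range_kind = range_kind),
            class = "pcat_mask")
}

#' @export
print.pcat_mask <- function(x, ...) {
  cat(sprintf("PCAT mask (%s range): %d slices, %d fat voxels total, window [%g, %g] HU\n",
              x$range_kind, length(x$slices), sum(x$n_fat_voxels),
              x$hu_window[1], x$hu_window[2]))
  invisible(x)
}
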