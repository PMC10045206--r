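# 2D shape descriptors of a binary slice mask, independent of gray levels.
# All lengths are in mm (anisotropic in-plane spacing honoured).

SHAPE_FEATURES <- c(
  "area", "convex_area", "perimeter", "convex_perimeter",
  "perimeter_area_ratio", "circularity", "compactness",
  "feret_max", "feret_min", "major_axis_length", "minor_axis_length",
  "elongation", "eccentricity", "orientation", "extent", "solidity",
  "equivalent_diameter", "bbox_width", "bbox_height", "euler_number",
  "n_components")

# Convex hull of the four corner points of every mask pixel, in mm.
# Returns a closed polygon matrix (first point repeated last).
mask_hull <- function(mask, spacing_mm) {
  dy <- spacing_mm[1]; dx <- spacing_mm[2]
  idx <- which(mask, arr.ind = TRUE)
  ys <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5) * dy
  xs <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5) * dx
  h <- grDevices::chull(xs, ys)
  cbind(x = xs[c(h, h[1])], y = ys[c(h, h[1])])
}

polygon_area <- function(poly) {
  n <- nrow(poly) - 1L
  if (n < 3L) return(0)
  abs(sum(poly[1:n, 1] * poly[2:(n + 1), 2] -
            poly[2:(n + 1), 1] * poly[1:n, 2])) / 2
}

polygon_perimeter <- function(poly) {
  sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
}

# Minimum width over rotating-caliper directions (edge normals of the hull).
feret_min_width <- function(poly) {
  n <- nrow(poly) - 1L
  if (n < 2L) return(0)
  widths <- vapply(seq_len(n), function(k) {
    e <- poly[k + 1L, ] - poly[k, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nvec <- c(-e[2], e[1]) / len
    pr <- poly[1:n, 1] * nvec[1] + poly[1:n, 2] * nvec[2]
    max(pr) - min(pr)
  }, numeric(1))
  min(widths)
}

# Euler characteristic for 8-connected foreground via 2x2 quad counts.
euler_number_8 <- function(mask) {
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  a <- padded[-nrow(padded), -ncol(padded)]
  b <- padded[-nrow(padded), -1]
  c_ <- padded[-1, -ncol(padded)]
  d <- padded[-1, -1]
  s <- a + b + c_ + d
  q1 <- sum(s == 1)
  q3 <- sum(s == 3)
  qd <- sum(s == 2 & ((a & d & !b & !c_) | (b & c_ & !a & !d)))
  (q1 - q3 - 2L * qd) / 4
}

#' Shape features of a 2D mask
#'
#' Twenty-one geometric descriptors of a binary slice mask, in mm-based
#' units. The perimeter is the total length of exposed pixel edges (exact
#' for axis-aligned rectangles); circularity is the perimeter of the
#' equivalent-area disc divided by the convex-hull perimeter (1 for a disc);
#' compactness is `4 pi area / perimeter^2` using the pixel-edge perimeter.
#' Axis lengths derive from the ellipse with matching second moments (with
#' the 1/12-pixel variance correction), elongation is `minor/major` and
#' eccentricity the corresponding ellipse eccentricity. The Euler number and
#' component count use 8-connectivity.
#'
#' @param mask logical matrix (nonempty).
#' @param spacing_mm in-plane spacing `(dy, dx)` in mm.
#' @return named numeric vector of length 21.
#' @export
shape_features <- function(mask, spacing_mm) {
  stopifnot(any(mask))
  dy <- spacing_mm[1]; dx <- spacing_mm[2]
  out <- stats::setNames(numeric(length(SHAPE_FEATURES)), SHAPE_FEATURES)
  n <- sum(mask)
  area <- n * dy * dx

  # exposed pixel edges
  up <- sum(mask & !shift_matrix(mask, 1, 0, FALSE))
  down <- sum(mask & !shift_matrix(mask, -1, 0, FALSE))
  left <- sum(mask & !shift_matrix(mask, 0, 1, FALSE))
  right <- sum(mask & !shift_matrix(mask, 0, -1, FALSE))
  perim <- (up + down) * dx + (left + right) * dy

  hull <- mask_hull(mask, spacing_mm)
  conv_area <- polygon_area(hull)
  conv_perim <- polygon_perimeter(hull)

  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1] * dy; xs <- idx[, 2] * dx
  mu_y <- mean(ys); mu_x <- mean(xs)
  # second central moments with the 1/12 pixel-variance correction
  myy <- mean((ys - mu_y)^2) + dy^2 / 12
  mxx <- mean((xs - mu_x)^2) + dx^2 / 12
  mxy <- mean((xs - mu_x) * (ys - mu_y))
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - det_))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - det_))
  l2 <- max(l2, 0)

  pts_hull <- hull[-nrow(hull), , drop = FALSE]
  feret_max <- if (nrow(pts_hull) >= 2)
    max(stats::dist(pts_hull)) else sqrt(dx^2 + dy^2)

  bbox_h <- (max(idx[, 1]) - min(idx[, 1]) + 1L) * dy
  bbox_w <- (max(idx[, 2]) - min(idx[, 2]) + 1L) * dx

  binlab <- matrix(NA_integer_, nrow(mask), ncol(mask))
  binlab[mask] <- 1L
  ncomp <- length(unique(stats::na.omit(as.vector(label_zones(binlab)))))

  out["area"] <- area
  out["convex_area"] <- conv_area
  out["perimeter"] <- perim
  out["convex_perimeter"] <- conv_perim
  out["perimeter_area_ratio"] <- perim / area
  out["circularity"] <- if (conv_perim > 0)
    2 * sqrt(pi * area) / conv_perim else 1
  out["compactness"] <- 4 * pi * area / perim^2
  out["feret_max"] <- feret_max
  out["feret_min"] <- feret_min_width(hull)
  out["major_axis_length"] <- 4 * sqrt(l1)
  out["minor_axis_length"] <- 4 * sqrt(l2)
  out["elongation"] <- if (l1 > 0) sqrt(l2 / l1) else 1
  out["eccentricity"] <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  out["orientation"] <- 0.5 * atan2(2 * mxy, mxx - myy)
  out["extent"] <- area / (bbox_w * bbox_h)
  out["solidity"] <- if (conv_area > 0) area / conv_area else 1
  out["equivalent_diameter"] <- 2 * sqrt(area / pi)
  out["bbox_width"] <- bbox_w
  out["bbox_height"] <- bbox_h
  out["euler_number"] <- euler_number_8(mask)
  out["n_components"] <- ncomp
  out
}
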