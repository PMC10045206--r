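# Synthetic straightened-vessel CT phantom.
#
# Emulates the data structure of a straightened coronary CCTA pullback: a
# stack of axial HU slices containing a contrast-bright lumen, a soft-tissue
# wall annulus, and a surrounding adipose field whose mean attenuation and
# spatial texture scale can differ between label classes. Wall masks are
# generated noiselessly so segmentation behaviour is deterministic.

#' Phantom generator configuration
#'
#' Defines the study conditions for a synthetic straightened-vessel cohort.
#' Defaults emulate a small clinical CCTA/IVOCT cohort: 30 vessels, label
#' prevalences of 14/30 (TCFA) and 12/30 (microchannels), 0.5 mm isotropic
#' voxels, adipose attenuation centred at -80 HU with 15 HU spread, and a
#' class effect consisting of a +15 HU attenuation shift plus a doubled
#' texture correlation length in positive vessels (inflamed adipose tissue
#' retains water and changes vascularity, raising attenuation and coarsening
#' texture).
#'
#' @param n_vessels number of vessels in a cohort.
#' @param slices_per_vessel axial slices per vessel.
#' @param grid_size in-plane grid side (pixels).
#' @param spacing_mm voxel spacing `(dz, dy, dx)` in mm, all positive.
#' @param lumen_radius_mm nominal lumen radius (mm); varies +/-15\% along the
#'   vessel.
#' @param wall_thickness_mm radial thickness of the soft-tissue wall (mm).
#' @param fat_mean_hu_neg baseline adipose mean attenuation (HU) in
#'   label-negative vessels; must lie inside (-190, -30).
#' @param fat_mean_shift_hu additive attenuation shift (HU) applied to the
#'   adipose field of label-positive vessels.
#' @param texture_corr_len_neg,texture_corr_len_pos Gaussian correlation
#'   length (mm) of the adipose texture per class.
#' @param fat_sd_hu marginal standard deviation (HU) of the adipose field.
#' @param nonfat_fraction fraction of peri-vessel pixels replaced by
#'   soft-tissue attenuation (> -30 HU) so the HU-window filter is exercised.
#' @param prevalence probability that a vessel carries the TCFA label.
#' @param prevalence_mc probability that a vessel carries the MC label
#'   (drawn independently of TCFA).
#' @param effect_on which label drives the adipose effect: `"tcfa"`, `"mc"`
#'   or `"tcfa_mc"`.
#' @param loi_fraction fraction of the vessel range forming the central
#'   lesion-of-interest (LOI) slice range.
#' @param rng_seed integer seed controlling label draws and per-vessel seeds.
#' @return an object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_vessels = 30L,
                           slices_per_vessel = 40L,
                           grid_size = 64L,
                           spacing_mm = c(0.5, 0.5, 0.5),
                           lumen_radius_mm = 1.5,
                           wall_thickness_mm = 0.75,
                           fat_mean_hu_neg = -80,
                           fat_mean_shift_hu = 15,
                           texture_corr_len_neg = 0.8,
                           texture_corr_len_pos = 1.6,
                           fat_sd_hu = 15,
                           nonfat_fraction = 0.08,
                           prevalence = 14 / 30,
                           prevalence_mc = 12 / 30,
                           effect_on = c("tcfa", "mc", "tcfa_mc"),
                           loi_fraction = 0.2,
                           rng_seed = 20260101L) {
  effect_on <- match.arg(effect_on)
  cfg <- list(
    n_vessels = as.integer(n_vessels),
    slices_per_vessel = as.integer(slices_per_vessel),
    grid_size = as.integer(grid_size),
    spacing_mm = as.numeric(spacing_mm),
    lumen_radius_mm = lumen_radius_mm,
    wall_thickness_mm = wall_thickness_mm,
    fat_mean_hu_neg = fat_mean_hu_neg,
    fat_mean_shift_hu = fat_mean_shift_hu,
    texture_corr_len_neg = texture_corr_len_neg,
    texture_corr_len_pos = texture_corr_len_pos,
    fat_sd_hu = fat_sd_hu,
    nonfat_fraction = nonfat_fraction,
    prevalence = prevalence,
    prevalence_mc = prevalence_mc,
    effect_on = effect_on,
    loi_fraction = loi_fraction,
    rng_seed = as.integer(rng_seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(
    cfg$n_vessels >= 1L,
    cfg$slices_per_vessel >= 1L,
    cfg$grid_size >= 8L,
    length(cfg$spacing_mm) == 3L, all(cfg$spacing_mm > 0),
    cfg$lumen_radius_mm > 0, cfg$wall_thickness_mm > 0,
    cfg$fat_sd_hu > 0,
    cfg$texture_corr_len_neg > 0, cfg$texture_corr_len_pos > 0,
    cfg$nonfat_fraction >= 0, cfg$nonfat_fraction < 1,
    cfg$loi_fraction > 0, cfg$loi_fraction <= 1
  )
  if (!(cfg$fat_mean_hu_neg > -190 && cfg$fat_mean_hu_neg < -30))
    stop("fat_mean_hu_neg must lie inside (-190, -30) HU")
  if (!(cfg$prevalence > 0 && cfg$prevalence <= 1) ||
      !(cfg$prevalence_mc > 0 && cfg$prevalence_mc <= 1))
    stop("prevalence must lie in (0, 1]")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Phantom configuration:", x$n_vessels, "vessels x",
      x$slices_per_vessel, "slices,", x$grid_size, "x", x$grid_size,
      "grid\n")
  cat(sprintf("  adipose: %g HU (sd %g), class shift %+g HU on '%s', texture %g / %g mm\n",
              x$fat_mean_hu_neg, x$fat_sd_hu, x$fat_mean_shift_hu,
              x$effect_on, x$texture_corr_len_neg, x$texture_corr_len_pos))
  cat(sprintf("  prevalence: TCFA %.3f, MC %.3f; seed %d\n",
              x$prevalence, x$prevalence_mc, x$rng_seed))
  invisible(x)
}

#' Vessel-level vulnerability label
#'
#' @param tcfa,mc logicals; `tcfa_mc` is their conjunction.
#' @return an object of class `vessel_label`.
#' @export
vessel_label <- function(tcfa, mc) {
  stopifnot(is.logical(tcfa), is.logical(mc), length(tcfa) == 1L,
            length(mc) == 1L, !is.na(tcfa), !is.na(mc))
  structure(list(tcfa = tcfa, mc = mc, tcfa_mc = tcfa && mc),
            class = "vessel_label")
}

#' Construct a straightened-vessel HU volume
#'
#' @param voxels 3D numeric array of HU values, `dim = c(rows, cols, slices)`.
#' @param spacing_mm voxel spacing `(dz, dy, dx)` in mm.
#' @param loi_range,vessel_range inclusive 1-based slice index ranges
#'   `c(first, last)`; the LOI range must lie inside the vessel range.
#' @param vessel_id identifier string.
#' @return an object of class `vessel_volume`.
#' @export
vessel_volume <- function(voxels, spacing_mm, loi_range, vessel_range,
                          vessel_id = "vessel") {
  stopifnot(length(dim(voxels)) == 3L, all(is.finite(voxels)),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(loi_range) == 2L, length(vessel_range) == 2L)
  n <- dim(voxels)[3]
  if (!(vessel_range[1] >= 1 && vessel_range[2] <= n &&
        vessel_range[1] <= vessel_range[2]))
    stop("vessel_range must lie inside [1, n_slices]")
  if (!(loi_range[1] >= vessel_range[1] && loi_range[2] <= vessel_range[2] &&
        loi_range[1] <= loi_range[2]))
    stop("loi_range must lie inside vessel_range")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 loi_range = as.integer(loi_range),
                 vessel_range = as.integer(vessel_range),
                 vessel_id = as.character(vessel_id)),
            class = "vessel_volume")
}

#' @export
print.vessel_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Vessel volume '%s': %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$vessel_id, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  vessel slices %d..%d, LOI slices %d..%d, HU range [%.0f, %.0f]\n",
              x$vessel_range[1], x$vessel_range[2],
              x$loi_range[1], x$loi_range[2],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a per-slice vessel-wall segmentation
#'
#' @param lumen_masks,outer_wall_masks lists of per-slice logical matrices;
#'   the outer-wall mask is the filled region bounded by the outer wall
#'   contour and must contain the lumen on every slice.
#' @param spacing_mm in-plane spacing `(dy, dx)` in mm.
#' @param diameter_mm optional per-slice vessel diameters; computed as the
#'   equivalent-disc diameter of the outer-wall region when omitted.
#' @return an object of class `wall_segmentation`.
#' @export
wall_segmentation <- function(lumen_masks, outer_wall_masks, spacing_mm,
                              diameter_mm = NULL) {
  stopifnot(length(lumen_masks) == length(outer_wall_masks),
            length(spacing_mm) == 2L, all(spacing_mm > 0))
  for (s in seq_along(lumen_masks)) {
    if (any(lumen_masks[[s]] & !outer_wall_masks[[s]]))
      stop("lumen mask exceeds outer-wall mask on slice ", s)
  }
  if (is.null(diameter_mm)) {
    diameter_mm <- vapply(outer_wall_masks, function(m) {
      if (!any(m)) return(NA_real_)
      vessel_diameter(m, spacing_mm)
    }, numeric(1))
  }
  structure(list(lumen_masks = lumen_masks,
                 outer_wall_masks = outer_wall_masks,
                 spacing_mm = as.numeric(spacing_mm),
                 diameter_mm = diameter_mm),
            class = "wall_segmentation")
}

# Circularly-stationary Gaussian random field with unit marginal variance,
# generated by FFT convolution of white noise with a Gaussian kernel of
# standard deviation `sigma_px` (wrap-around boundary keeps the variance
# exactly stationary so the scaling below is closed-form).
gaussian_field <- function(nr, nc, sigma_px) {
  kr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  kc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  kern <- outer(exp(-kr^2 / (2 * sigma_px^2)), exp(-kc^2 / (2 * sigma_px^2)))
  scale <- sqrt(sum(kern^2))
  e <- matrix(stats::rnorm(nr * nc), nr, nc)
  sm <- Re(stats::fft(stats::fft(e) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  sm / scale
}

#' Generate one synthetic straightened vessel
#'
#' Each axial slice contains a contrast-filled lumen disc (~400 HU), a
#' soft-tissue wall annulus (~50 HU), and a surrounding adipose field drawn
#' as spatially correlated Gaussian noise whose mean is
#' `fat_mean_hu_neg` (plus `fat_mean_shift_hu` when the label selected by
#' `effect_on` is positive) and whose correlation length is class dependent.
#' A fraction of peri-vessel pixels is replaced by soft-tissue attenuation
#' above -30 HU so that the adipose HU window genuinely filters. Wall masks
#' are exact. The output is fully deterministic given `seed`.
#'
#' @param config a [phantom_config()].
#' @param label a [vessel_label()].
#' @param seed integer seed for this vessel.
#' @param vessel_id identifier string.
#' @return a list with elements `volume` ([vessel_volume]) and `walls`
#'   ([wall_segmentation]).
#' @export
generate_vessel <- function(config, label, seed, vessel_id = "vessel") {
  validate_phantom_config(config)
  stopifnot(inherits(label, "vessel_label"))
  n <- config$grid_size
  ns <- config$slices_per_vessel
  dy <- config$spacing_mm[2]; dx <- config$spacing_mm[3]

  positive <- isTRUE(label[[config$effect_on]])
  fat_mean <- config$fat_mean_hu_neg +
    if (positive) config$fat_mean_shift_hu else 0
  corr_len <- if (positive) config$texture_corr_len_pos
              else config$texture_corr_len_neg

  r_out_max <- config$lumen_radius_mm * 1.15 + config$wall_thickness_mm
  # wall plus an annulus of one vessel diameter (~2 r_out) must fit in-plane
  need_mm <- 3 * r_out_max
  if (need_mm > (n / 2 - 1) * dy)
    stop("vessel geometry exceeds slice extent along rows: need ",
         round(need_mm, 2), " mm")
  if (need_mm > (n / 2 - 1) * dx)
    stop("vessel geometry exceeds slice extent along cols: need ",
         round(need_mm, 2), " mm")

  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  ddy <- (seq_len(n) - cy) * dy
  ddx <- (seq_len(n) - cx) * dx
  rad <- sqrt(outer(ddy^2, ddx^2, "+"))

  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    voxels <- array(0, dim = c(n, n, ns))
    lumen_masks <- vector("list", ns)
    wall_masks <- vector("list", ns)
    sigma_px <- corr_len / dx
    for (s in seq_len(ns)) {
      r_lum <- config$lumen_radius_mm *
        (1 + 0.15 * sin(2 * pi * s / ns + phase))
      r_out <- r_lum + config$wall_thickness_mm
      lum <- rad <= r_lum
      wall <- rad <= r_out
      fat <- fat_mean + config$fat_sd_hu * gaussian_field(n, n, sigma_px)
      slice <- fat
      outside <- which(!wall)
      n_nonfat <- round(config$nonfat_fraction * length(outside))
      if (n_nonfat > 0) {
        pick <- sample(outside, n_nonfat)
        slice[pick] <- stats::runif(n_nonfat, 0, 80)
      }
      slice[wall] <- 50 + stats::rnorm(sum(wall), 0, 8)
      slice[lum] <- pmax(100, 400 + stats::rnorm(sum(lum), 0, 10))
      voxels[, , s] <- pmin(pmax(slice, -1000), 1000)
      lumen_masks[[s]] <- lum
      wall_masks[[s]] <- wall
    }
    loi_len <- max(1L, round(config$loi_fraction * ns))
    loi_start <- floor((ns - loi_len) / 2) + 1L
    vol <- vessel_volume(voxels, config$spacing_mm,
                         loi_range = c(loi_start, loi_start + loi_len - 1L),
                         vessel_range = c(1L, ns),
                         vessel_id = vessel_id)
    walls <- wall_segmentation(lumen_masks, wall_masks, c(dy, dx))
    list(volume = vol, walls = walls)
  })
}

#' Generate a labelled cohort of synthetic vessels
#'
#' Draws TCFA and MC labels independently with the configured prevalences,
#' derives one deterministic seed per vessel from `config$rng_seed`, and
#' generates each vessel with [generate_vessel()]. The realised class balance
#' is reported in a message.
#'
#' @param config a [phantom_config()].
#' @return a list with `vessels` (list of `list(volume, walls)`) and
#'   `labels` (data.frame with columns vessel_id, tcfa, mc, tcfa_mc).
#' @export
generate_cohort <- function(config) {
  validate_phantom_config(config)
  if (config$n_vessels < 6L)
    stop("need at least 6 vessels to stratify three folds")
  labs <- with_seed(config$rng_seed, {
    data.frame(
      vessel_id = sprintf("vessel_%03d", seq_len(config$n_vessels)),
      tcfa = stats::runif(config$n_vessels) < config$prevalence,
      mc = stats::runif(config$n_vessels) < config$prevalence_mc,
      stringsAsFactors = FALSE
    )
  })
  labs$tcfa_mc <- labs$tcfa & labs$mc
  eff <- labs[[config$effect_on]]
  if (length(unique(eff)) < 2L)
    warning("single-class cohort on '", config$effect_on,
            "': cannot stratify cross-validation folds")
  vessels <- vector("list", config$n_vessels)
  for (i in seq_len(config$n_vessels)) {
    lab <- vessel_label(labs$tcfa[i], labs$mc[i])
    vessels[[i]] <- generate_vessel(config, lab,
                                    seed = derive_seed(config$rng_seed, i),
                                    vessel_id = labs$vessel_id[i])
  }
  msg(sprintf("cohort of %d vessels: %d TCFA, %d MC, %d TCFA+MC",
              config$n_vessels, sum(labs$tcfa), sum(labs$mc),
              sum(labs$tcfa_mc)))
  list(vessels = vessels, labels = labs)
}
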