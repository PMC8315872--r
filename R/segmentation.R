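#' DRLSE parameters
#'
#' Weights of the distance-regularized level-set evolution
#' `dphi/dt = mu div(d_p(|grad phi|) grad phi)
#'          + lambda delta_eps(phi) div(g grad phi/|grad phi|)
#'          + alpha g delta_eps(phi)`
#' with the double-well regularization potential and the smoothed Dirac
#' `delta_eps`. Spatial derivatives are taken in voxel units. The
#' regularization term is an explicit diffusion: `mu * dt < 0.25` is
#' enforced (the planar bound), and the default `mu = 0.15` respects the
#' stricter three-dimensional limit `mu * dt <= 1/6`.
#'
#' @param mu distance-regularization weight.
#' @param lambda edge-length weight.
#' @param alpha signed area (balloon) weight; negative expands the contour.
#' @param epsilon Heaviside/Dirac smoothing width (voxels).
#' @param dt time step.
#' @param n_iter number of evolution steps (>= 1).
#' @param sigma Gaussian pre-smoothing sd (voxels) used by
#'   [edge_indicator()] when called through the pipelines.
#' @return An object of class `drlse_params`.
#' @export
drlse_params <- function(mu = 0.15, lambda = 5, alpha = -1.5, epsilon = 1.5,
                         dt = 1, n_iter = 300L, sigma = 1.0) {
  if (mu * dt >= 0.25)
    stop("stability requires mu * dt < 0.25")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(mu = mu, lambda = lambda, alpha = alpha, epsilon = epsilon,
                 dt = dt, n_iter = as.integer(n_iter), sigma = sigma),
            class = "drlse_params")
}

#' Level-set field
#'
#' @param phi 3D numeric array; the zero level set is the contour.
#' @param spacing mm per axis.
#' @return An object of class `level_set_field`.
#' @export
level_set_field <- function(phi, spacing = c(1, 1, 1)) {
  phi <- as.array(phi)
  if (length(dim(phi)) != 3L) stop("phi must be a 3D array")
  if (!all(is.finite(phi))) stop("phi must be finite everywhere")
  structure(list(phi = phi, spacing = as.numeric(spacing)),
            class = "level_set_field")
}

#' Edge-indicator image
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)` with the gradient in physical
#' units (1/mm). Values lie in (0, 1] and equal 1 wherever the smoothed
#' gradient vanishes; the evolving contour is slowed where `g` is small
#' (strong edges).
#'
#' @param vol a [volume3d()].
#' @param sigma Gaussian smoothing sd in voxels (0 disables smoothing).
#' @param normalize standardize the gradient magnitude by twice its median
#'   over the volume (a robust noise-floor estimate) before applying the
#'   `1/(1 + s^2)` response. This keeps `g` near 1 in noise-only regions
#'   while true edges still drive it toward 0, making the indicator
#'   insensitive to the intensity scale; the pipelines enable it.
#' @return a [volume3d()] of edge-indicator values.
#' @export
edge_indicator <- function(vol, sigma = 1.0, normalize = FALSE) {
  stopifnot(inherits(vol, "volume3d"))
  if (sigma < 0) stop("sigma must be >= 0")
  sm <- gaussian_smooth(vol$data, sigma)
  g2 <- (axis_gradient(sm, 1L) / vol$spacing[1])^2 +
        (axis_gradient(sm, 2L) / vol$spacing[2])^2 +
        (axis_gradient(sm, 3L) / vol$spacing[3])^2
  if (normalize) {
    q <- 2 * stats::median(sqrt(g2))
    if (q > 0) g2 <- g2 / q^2
  }
  volume3d(1 / (1 + g2), vol$spacing, vol$origin)
}

#' Initialize a level-set field from a registered mean shape
#'
#' Maps the mean-shape landmarks into the ROI through `tf` and rasterizes
#' the region they enclose. The support of the shape is taken as all
#' voxels within `prior_radius_mm` of a mapped landmark (a tube around the
#' landmark surface that respects the concave labyrinth topology, unlike a
#' convex hull). With `intensity_weighted = TRUE` the support is
#' intersected with the bright (fluid) intensity class of the
#' median-filtered ROI, found by Otsu thresholding within the dilated
#' support — this is the "characteristic image" weighting of the
#' registered shape prior. The region is closed morphologically and
#' converted to an initial field: either a signed-distance profile clamped
#' at `+/- c0` (default; a fixed point of the distance regularization, so
#' thin structures survive the early evolution) or a binary step `-c0`
#' inside / `+c0` outside.
#'
#' @param roi a [volume3d()] (the cropped subject ROI).
#' @param mean_shape n x 3 landmark matrix in mm (same world frame as the
#'   ROI after `tf`).
#' @param tf a [rigid_transform()] applied to the landmarks before
#'   rasterization (identity to use them as-is).
#' @param prior_radius_mm radius (mm) of the shape-prior support around
#'   the mapped landmarks.
#' @param intensity_weighted intersect the prior support with the bright
#'   intensity class of the ROI (Otsu threshold on the median-filtered
#'   image).
#' @param profile `"distance"` for a clamped signed-distance field,
#'   `"step"` for a binary step.
#' @param c0 magnitude at which the field is clamped (voxels).
#' @return a [level_set_field()] on the ROI grid.
#' @export
initialize_from_mean_shape <- function(roi, mean_shape, tf = rigid_transform(),
                                       prior_radius_mm = 3.5,
                                       intensity_weighted = TRUE,
                                       profile = c("distance", "step"),
                                       c0 = 3) {
  stopifnot(inherits(roi, "volume3d"))
  profile <- match.arg(profile)
  pts <- apply_rigid(tf, as_points(mean_shape))
  idx <- world_to_index(roi, pts)
  d <- dim(roi$data)
  inb <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
         idx[, 1] <= d[1] - 1 & idx[, 2] <= d[2] - 1 & idx[, 3] <= d[3] - 1
  if (!any(inb))
    stop("initialization failure: all mapped landmarks fall outside the ROI")
  world <- grid_world_coords(roi)
  dists <- cpp_min_dists(world, pts)
  region <- array(dists <= prior_radius_mm, dim = d)
  if (intensity_weighted) {
    # light smoothing keeps the 50% level crossing at the true boundary
    # while suppressing voxel noise before thresholding
    sm <- gaussian_smooth(roi$data, 0.5)
    support <- binary_dilate(region, 2L)
    thr <- otsu_threshold(sm[support])
    region <- region & sm > thr
  } else {
    # a purely geometric prior is a fat tube around the landmark surface;
    # close it so the enclosed interior is filled
    region <- binary_close(region, 1L)
  }
  if (!any(region) || all(region))
    stop("initialization failure: degenerate initial region")
  phi <- if (profile == "step") {
    p <- array(c0, dim = d)
    p[region] <- -c0
    p
  } else signed_distance_field(region, cap = c0)
  level_set_field(phi, roi$spacing)
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance over a fixed-width histogram; the
#' standard two-class threshold used to separate the bright fluid signal
#' from background.
#'
#' @param x numeric vector of intensities.
#' @param bins histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, bins = 256L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  b <- pmin.int(pmax.int(floor((x - lo) / (hi - lo) * bins) + 1L, 1L), bins)
  w <- tabulate(b, bins) / length(x)
  mids <- lo + (seq_len(bins) - 0.5) * (hi - lo) / bins
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[bins]
  w0 <- cw[-bins]; w1 <- 1 - w0
  m0 <- cm[-bins] / pmax(w0, 1e-12)
  m1 <- (mt - cm[-bins]) / pmax(w1, 1e-12)
  lo + which.max(w0 * w1 * (m0 - m1)^2) * (hi - lo) / bins
}

# Signed distance (voxel units) to the region interface, clamped at
# +/- cap; negative inside.  Distances are measured to the inner-boundary
# voxel centers, with the interface taken to lie half a voxel outside
# them, so inner-boundary voxels get -0.5 and adjacent background +0.5.
signed_distance_field <- function(region, cap = 3) {
  d <- dim(region)
  surf <- which(boundary_voxels(region), arr.ind = TRUE) - 1L
  if (!nrow(surf)) {
    p <- array(cap, dim = d)
    p[region] <- -cap
    return(p)
  }
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  dd <- array(cpp_min_dists(idx, surf), dim = d)
  phi <- dd - 0.5
  phi[region] <- -(dd[region] + 0.5)
  pmin(pmax(phi, -cap), cap)
}

# Morphological dilation/erosion with a cubic structuring element of
# half-width r (Chebyshev ball), via separable running max/min.
binary_dilate <- function(mask, r = 1L) {
  a <- mask
  for (ax in 1:3)
    for (s in seq_len(r)) {
      n <- dim(a)[ax]
      ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
      a <- if (ax == 1) a | a[ip, , , drop = FALSE] | a[im, , , drop = FALSE]
      else if (ax == 2) a | a[, ip, , drop = FALSE] | a[, im, , drop = FALSE]
      else a | a[, , ip, drop = FALSE] | a[, , im, drop = FALSE]
    }
  a
}

binary_erode <- function(mask, r = 1L) !binary_dilate(!mask, r)

binary_close <- function(mask, r = 1L) binary_erode(binary_dilate(mask, r), r)

#' Distance-regularized level-set evolution
#'
#' Runs `p$n_iter` explicit-Euler DRLSE updates of `phi0` with edge
#' indicator `g`. Neumann boundary conditions; fully deterministic. A
#' NaN/Inf during evolution raises a numerical-instability error reporting
#' the iteration.
#'
#' @param phi0 a [level_set_field()].
#' @param g a [volume3d()] of edge-indicator values on the same grid.
#' @param p a [drlse_params()].
#' @return the evolved [level_set_field()].
#' @export
drlse_evolve <- function(phi0, g, p = drlse_params()) {
  stopifnot(inherits(phi0, "level_set_field"), inherits(g, "volume3d"),
            inherits(p, "drlse_params"))
  if (!identical(dim(phi0$phi), dim(g$data)))
    stop("phi and g must share the same grid")
  d <- dim(g$data)
  gx <- axis_gradient(g$data, 1L)
  gy <- axis_gradient(g$data, 2L)
  gz <- axis_gradient(g$data, 3L)
  res <- cpp_drlse(as.numeric(phi0$phi), as.numeric(g$data),
                   as.numeric(gx), as.numeric(gy), as.numeric(gz),
                   d, p$mu, p$lambda, p$alpha, p$epsilon, p$dt, p$n_iter)
  if (res$bad_iter > 0)
    stop("numerical instability (NaN/Inf) at DRLSE iteration ", res$bad_iter)
  level_set_field(array(res$phi, dim = d), phi0$spacing)
}

#' Binary mask from a level-set field
#'
#' Thresholds the zero level set: foreground where `phi < 0`. Optionally
#' retains only the largest 26-connected component.
#'
#' @param phi a [level_set_field()].
#' @param largest_component keep only the largest connected component.
#' @param origin world origin to attach to the mask (mm).
#' @return a [binary_mask()].
#' @export
mask_from_levelset <- function(phi, largest_component = FALSE,
                               origin = c(0, 0, 0)) {
  stopifnot(inherits(phi, "level_set_field"))
  m <- phi$phi < 0
  if (largest_component && any(m)) {
    lab <- cpp_label_components(as.logical(m), dim(m), 26L)
    keep <- which.max(tabulate(lab[lab > 0L]))
    m <- array(lab == keep, dim = dim(m))
  }
  binary_mask(m, phi$spacing, origin)
}

#' Seeded region growing
#'
#' Flood fill from the seed voxels, accepting a neighboring voxel when its
#' intensity differs from the current region mean by at most `tolerance`;
#' the region mean is updated incrementally as voxels are added.
#'
#' @param vol a [volume3d()].
#' @param cfg a [region_grow_config()].
#' @return a [binary_mask()].
#' @export
region_growing_segment <- function(vol, cfg) {
  stopifnot(inherits(vol, "volume3d"), inherits(cfg, "region_grow_config"))
  d <- dim(vol$data)
  seeds <- cfg$seeds
  if (any(seeds < 0L) || any(seeds >= matrix(d, nrow(seeds), 3, byrow = TRUE)))
    stop("all seeds must lie inside the grid")
  m <- cpp_region_grow(as.numeric(vol$data), d, seeds, cfg$tolerance,
                       cfg$connectivity)
  binary_mask(array(m, dim = d), vol$spacing, vol$origin)
}

#' Region-growing configuration
#'
#' @param seeds n x 3 matrix of 0-based voxel indices (>= 1 seed).
#' @param tolerance accepted absolute deviation from the region mean
#'   (intensity units, >= 0).
#' @param connectivity 6 or 26.
#' @param curvature_percentile percentile (0-100) used by
#'   [curvature_repair()].
#' @return An object of class `region_grow_config`.
#' @export
region_grow_config <- function(seeds, tolerance, connectivity = 26L,
                               curvature_percentile = 95) {
  seeds <- as_seed_matrix(seeds)
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (curvature_percentile < 0 || curvature_percentile > 100)
    stop("curvature_percentile must be in [0, 100]")
  structure(list(seeds = seeds, tolerance = tolerance,
                 connectivity = as.integer(connectivity),
                 curvature_percentile = curvature_percentile),
            class = "region_grow_config")
}

as_seed_matrix <- function(seeds) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3, byrow = TRUE)
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 3L || nrow(seeds) < 1L)
    stop("seeds must be an n x 3 matrix of voxel indices (n >= 1)")
  storage.mode(seeds) <- "integer"
  seeds
}

#' Adaptive curvature-threshold boundary repair
#'
#' Estimates the mean curvature of the smoothed mask indicator on boundary
#' voxels, flags boundary voxels whose absolute curvature exceeds the given
#' percentile of the boundary-curvature distribution (and is at least twice
#' its median, so a uniformly curved surface is left alone), and smooths
#' the flagged voxels with a local morphological opening/closing rule
#' (spike-like protrusions are removed, pit-like indentations filled). The
#' output differs from the input only on boundary voxels, hence stays
#' within a 2-voxel band of the input boundary.
#'
#' @param mask a nonempty [binary_mask()].
#' @param percentile curvature percentile in \[0, 100\].
#' @return the repaired [binary_mask()].
#' @export
curvature_repair <- function(mask, percentile = 95) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("mask is empty")
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  m <- mask$data
  d <- dim(m)

  u <- gaussian_smooth(m + 0, 0.5)  # light smoothing keeps 1-voxel spikes sharp
  ux <- axis_gradient(u, 1L); uy <- axis_gradient(u, 2L)
  uz <- axis_gradient(u, 3L)
  gn <- sqrt(ux^2 + uy^2 + uz^2) + 1e-10
  curv <- axis_gradient(ux / gn, 1L) + axis_gradient(uy / gn, 2L) +
          axis_gradient(uz / gn, 3L)

  bnd <- boundary_voxels(m) | boundary_voxels(!m) & binary_dilate(m, 1L)
  kb <- abs(curv[bnd])
  if (!length(kb)) return(mask)
  thr <- max(stats::quantile(kb, percentile / 100, names = FALSE),
             2 * stats::median(kb))
  flagged <- bnd & abs(curv) > thr
  if (!any(flagged)) return(mask)

  nb <- neighborhood_count(m)
  out <- m
  out[flagged & m & nb <= 11] <- FALSE  # spike-like: local opening
  out[flagged & !m & nb >= 16] <- TRUE  # pit-like: local closing
  binary_mask(out, mask$spacing, mask$origin)
}

# Foreground voxels with at least one background 6-neighbor (grid border
# counts as background).
boundary_voxels <- function(m) {
  d <- dim(m)
  pad <- function(a, ax, dir) {
    n <- d[ax]
    if (dir > 0) idx <- c(seq_len(n - 1) + 1L, NA) else idx <- c(NA, seq_len(n - 1))
    out <- if (ax == 1) a[ifelse(is.na(idx), 1L, idx), , , drop = FALSE]
    else if (ax == 2) a[, ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    else a[, , ifelse(is.na(idx), 1L, idx), drop = FALSE]
    # mark off-grid neighbors as background
    if (ax == 1) { if (dir > 0) out[n, , ] <- FALSE else out[1, , ] <- FALSE }
    if (ax == 2) { if (dir > 0) out[, n, ] <- FALSE else out[, 1, ] <- FALSE }
    if (ax == 3) { if (dir > 0) out[, , n] <- FALSE else out[, , 1] <- FALSE }
    out
  }
  anybg <- !pad(m, 1, 1) | !pad(m, 1, -1) | !pad(m, 2, 1) | !pad(m, 2, -1) |
           !pad(m, 3, 1) | !pad(m, 3, -1)
  m & anybg
}

# Number of foreground voxels in each 3x3x3 neighborhood (including self).
neighborhood_count <- function(m) {
  d <- dim(m)
  v <- as.numeric(m)
  k <- c(1, 1, 1)
  for (ax in 0:2) v <- cpp_convolve_axis(v, d, k, ax)
  array(v, dim = d)
}

#' Full shape-model level-set segmentation
#'
#' The four-stage pipeline: (1) localize the inner-ear ROI by rigid MI
#' registration of the atlas to the subject; (2) compute the edge-indicator
#' image on the ROI; (3) map the mean shape into the subject through the
#' recovered transform and rasterize it as the initial contour; (4) evolve
#' the contour by DRLSE and threshold the zero level set. The resulting
#' mask is embedded back into the full subject grid.
#'
#' @param subject a [volume3d()].
#' @param model a list with `mean_mm` (mean-shape landmarks in atlas world
#'   mm), `atlas` (a [volume3d()]) and `atlas_roi` (a [roi_box()]); see
#'   [build_shape_model()].
#' @param reg_cfg a [registration_config()].
#' @param drlse a [drlse_params()].
#' @param roi_margin_voxels ROI dilation margin.
#' @return list with `mask` (a [binary_mask()] on the subject grid) and
#'   `provenance` (transform, ROI box, parameters).
#' @export
segment_is3dls <- function(subject, model, reg_cfg = registration_config(),
                           drlse = drlse_params(mu = 0.1, lambda = 3,
                                                alpha = 0, n_iter = 10L),
                           roi_margin_voxels = 3L) {
  stopifnot(inherits(subject, "volume3d"))
  for (f in c("mean_mm", "atlas", "atlas_roi"))
    if (is.null(model[[f]])) stop("model lacks component '", f, "'")

  loc <- tryCatch(
    localize_roi(subject, model$atlas, model$atlas_roi, cfg = reg_cfg,
                 margin_voxels = roi_margin_voxels),
    error = function(e) stop("ROI localization stage failed: ",
                             conditionMessage(e)))
  roi <- crop_volume(subject, loc$roi)
  g <- edge_indicator(roi, drlse$sigma, normalize = TRUE)
  tf_atlas_to_subject <- invert_transform(loc$transform)
  phi0 <- tryCatch(
    initialize_from_mean_shape(roi, model$mean_mm, tf_atlas_to_subject),
    error = function(e) stop("initial-contour stage failed: ",
                             conditionMessage(e)))
  phi <- tryCatch(drlse_evolve(phi0, g, drlse),
                  error = function(e) stop("level-set stage failed: ",
                                           conditionMessage(e)))
  mroi <- mask_from_levelset(phi, largest_component = TRUE,
                             origin = roi$origin)

  full <- array(FALSE, dim = dim(subject$data))
  idx <- Map(function(l, u) (l + 1L):u, loc$roi$lower, loc$roi$upper)
  full[idx[[1]], idx[[2]], idx[[3]]] <- mroi$data
  list(mask = binary_mask(full, subject$spacing, subject$origin),
       provenance = list(
         transform = loc$transform,
         roi = loc$roi,
         registration = unclass(reg_cfg),
         drlse = unclass(drlse),
         n_landmarks = nrow(as_points(model$mean_mm))))
}

#' Region-growing + curvature-repair + DRLSE baseline segmentation
#'
#' The comparator pipeline: seeded region growing determines an initial
#' contour, the adaptive curvature-threshold repair smooths boundary
#' outliers, and DRLSE refines the repaired contour.
#'
#' @param vol a [volume3d()].
#' @param cfg a [region_grow_config()].
#' @param p a [drlse_params()].
#' @return a [binary_mask()] on the input grid.
#' @export
segment_region_growing_baseline <- function(vol, cfg,
                                            p = drlse_params(mu = 0.1,
                                                             lambda = 3,
                                                             alpha = 0,
                                                             n_iter = 10L)) {
  grown <- region_growing_segment(vol, cfg)
  if (!any(grown$data))
    stop("region growing produced an empty mask")
  repaired <- curvature_repair(grown, cfg$curvature_percentile)

  # evolve on the bounding box of the repaired mask (plus margin)
  w <- which(repaired$data, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 6L, 1L)
  hi <- pmin(apply(w, 2, max) + 6L, dim(vol$data))
  box <- roi_box(lo - 1L, hi)
  roi <- crop_volume(vol, box)
  sub <- repaired$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  phi <- signed_distance_field(sub, cap = 3)
  g <- edge_indicator(roi, p$sigma, normalize = TRUE)
  ev <- drlse_evolve(level_set_field(phi, roi$spacing), g, p)
  mroi <- mask_from_levelset(ev, largest_component = TRUE, origin = roi$origin)

  full <- array(FALSE, dim = dim(vol$data))
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- mroi$data
  binary_mask(full, vol$spacing, vol$origin)
}
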