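#' Registration configuration
#'
#' Settings for the mutual-information rigid registration loop: transform ->
#' tricubic resample -> MI -> accept/continue, optimized by coordinate-wise
#' hill climbing on the six rigid parameters (three intrinsic z-y-x Euler
#' angles about the fixed-volume center, three translations) with
#' per-parameter step halving on non-improvement, over an image pyramid.
#'
#' @param bins number of histogram bins per image (>= 2).
#' @param max_iter maximum number of parameter sweeps per pyramid level.
#' @param step_trans_mm initial translation step (mm).
#' @param step_rot_rad initial rotation step (radians).
#' @param tol stop a level when the best MI improvement over a full sweep
#'   falls below this value and steps are at their minimum.
#' @param pyramid_levels number of pyramid levels (1 = full resolution
#'   only; each extra level halves the resolution).
#' @param min_step_trans_mm,min_step_rot_rad smallest steps tried before a
#'   level is declared converged.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(bins = 32L, max_iter = 50L,
                                step_trans_mm = 2.0, step_rot_rad = 0.05,
                                tol = 1e-6, pyramid_levels = 2L,
                                min_step_trans_mm = 0.02,
                                min_step_rot_rad = 0.001) {
  if (bins < 2L) stop("`bins` must be >= 2")
  if (step_trans_mm <= 0 || step_rot_rad <= 0)
    stop("step sizes must be positive")
  if (pyramid_levels < 1L) stop("`pyramid_levels` must be >= 1")
  structure(list(bins = as.integer(bins), max_iter = as.integer(max_iter),
                 step_trans_mm = step_trans_mm, step_rot_rad = step_rot_rad,
                 tol = tol, pyramid_levels = as.integer(pyramid_levels),
                 min_step_trans_mm = min_step_trans_mm,
                 min_step_rot_rad = min_step_rot_rad),
            class = "registration_config")
}

#' Voxel region of interest (half-open box)
#'
#' @param lower,upper integer length-3 0-based voxel indices; the box spans
#'   `[lower, upper)` per axis.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L || anyNA(lower) ||
      anyNA(upper) || any(lower < 0L) || any(lower >= upper))
    stop("roi_box requires 0 <= lower < upper per axis")
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

#' Tricubic interpolation of a volume at world coordinates
#'
#' Separable local cubic polynomial (Lagrange) interpolation, the 3D
#' extension of a bicubic patch `v(x, y) = sum a_ij x^i y^j`. Exactly
#' reproduces grid values at voxel centers and polynomial fields up to
#' degree 3. Coordinates outside the grid return the volume minimum
#' (background fill) and are flagged in the `oob` attribute.
#'
#' @param vol a [volume3d()].
#' @param coords n x 3 matrix of world mm coordinates.
#' @return numeric vector of interpolated values with logical attribute
#'   `oob`.
#' @export
tricubic_interpolate <- function(vol, coords) {
  stopifnot(inherits(vol, "volume3d"))
  coords <- as_points(coords)
  idx <- world_to_index(vol, coords)
  res <- cpp_tricubic(as.numeric(vol$data), dim(vol$data), idx,
                      min(vol$data))
  structure(res$values, oob = res$oob)
}

# Bin assignments over a fixed [lo, hi] range; values outside are clamped.
# A degenerate (constant) range maps everything to bin 1.
intensity_bins <- function(x, bins, lo = min(x), hi = max(x)) {
  if (hi <= lo) return(rep.int(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * bins) + 1L
  pmin.int(pmax.int(b, 1L), bins)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Shared MI computation from bin assignments.
mi_from_bins <- function(bx, by, bins) {
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  n <- length(bx)
  p <- joint / n
  h_xy <- entropy_bits(p)
  px <- rowSums(matrix(p, bins, bins, byrow = TRUE))  # bx marginal
  py <- colSums(matrix(p, bins, bins, byrow = TRUE))
  h_x <- entropy_bits(px)
  h_y <- entropy_bits(py)
  list(mi = h_x + h_y - h_xy, h_x = h_x, h_y = h_y, h_xy = h_xy,
       joint = matrix(joint, bins, bins, byrow = TRUE), n = n)
}

#' Mutual information between two volumes on the same grid
#'
#' Shannon mutual information `MI = H(X) + H(Y) - H(X, Y)` in bits,
#' estimated from a dense `bins x bins` joint histogram with equal-width
#' bins over each image's observed intensity range (`0 log 0 := 0`). The
#' joint entropy always satisfies `H(X, Y) <= H(X) + H(Y)`.
#'
#' @param fixed,moving_resampled [volume3d()] objects with identical grids.
#' @param bins number of bins per image.
#' @return list with `mi`, `h_x`, `h_y`, `h_xy` (bits), the `joint` count
#'   matrix and the sample count `n`.
#' @export
mutual_information <- function(fixed, moving_resampled, bins = 32L) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving_resampled, "volume3d"))
  if (!identical(dim(fixed$data), dim(moving_resampled$data)))
    stop("volumes must share the same grid shape")
  if (bins < 2L) stop("`bins` must be >= 2")
  bx <- intensity_bins(as.numeric(fixed$data), bins)
  by <- intensity_bins(as.numeric(moving_resampled$data), bins)
  mi_from_bins(bx, by, as.integer(bins))
}

# Downsample a volume by block averaging (factor 2 per axis).
downsample2 <- function(vol) {
  d <- dim(vol$data)
  nd <- pmax(1L, d %/% 2L)
  a <- vol$data[seq_len(2 * nd[1]), seq_len(2 * nd[2]), seq_len(2 * nd[3]),
                drop = FALSE]
  i1 <- seq(1L, 2L * nd[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * nd[2], 2L); j2 <- j1 + 1L
  k1 <- seq(1L, 2L * nd[3], 2L); k2 <- k1 + 1L
  out <- (a[i1, j1, k1, drop = FALSE] + a[i2, j1, k1, drop = FALSE] +
          a[i1, j2, k1, drop = FALSE] + a[i2, j2, k1, drop = FALSE] +
          a[i1, j1, k2, drop = FALSE] + a[i2, j1, k2, drop = FALSE] +
          a[i1, j2, k2, drop = FALSE] + a[i2, j2, k2, drop = FALSE]) / 8
  volume3d(out, vol$spacing * 2, vol$origin + vol$spacing / 2)
}

# Intrinsic z-y-x Euler angles of a rotation matrix (inverse of
# euler_to_matrix).
matrix_to_euler <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock; fold everything into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  c(rx, ry, rz)
}

#' Rigid registration by mutual-information hill climbing
#'
#' Maximizes the mutual information between `fixed` and the tricubically
#' resampled `moving` over the six rigid parameters. Rotations are about
#' the physical center of the fixed volume. The optimizer is a
#' coordinate-wise ascent with per-parameter step halving over a
#' multi-resolution pyramid; only MI-improving steps are accepted, so the
#' returned MI trace is non-decreasing.
#'
#' @param fixed,moving [volume3d()] objects.
#' @param init initial [rigid_transform()] mapping fixed world coordinates
#'   to moving world coordinates.
#' @param cfg a [registration_config()].
#' @return list with `transform` (fixed -> moving [rigid_transform()]),
#'   `mi_trace_levels` (one numeric vector per pyramid level: the MI at the
#'   level's starting point and after every accepted step; non-decreasing
#'   within each level), `mi_trace` (the finest level's trace) and `mi`
#'   (final value). Traces are not comparable across levels because each
#'   level estimates MI on a different grid.
#' @export
register_rigid <- function(fixed, moving, init = rigid_transform(),
                           cfg = registration_config()) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"),
            inherits(init, "rigid_transform"),
            inherits(cfg, "registration_config"))
  if (diff(range(fixed$data)) == 0 || diff(range(moving$data)) == 0)
    stop("similarity is undefined for a constant image")

  cf <- volume_center(fixed)
  theta <- c(matrix_to_euler(init$A),
             init$b - cf + as.numeric(init$A %*% cf))

  # pyramid, coarse to fine
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(cfg$pyramid_levels - 1L)) {
    pyr_f <- c(list(downsample2(pyr_f[[1]])), pyr_f)
    pyr_m <- c(list(downsample2(pyr_m[[1]])), pyr_m)
  }

  traces <- vector("list", length(pyr_f))
  for (lev in seq_along(pyr_f)) {
    fx <- pyr_f[[lev]]; mv <- pyr_m[[lev]]
    bfix <- intensity_bins(as.numeric(fx$data), cfg$bins)
    mlo <- min(mv$data); mhi <- max(mv$data)
    mdim <- dim(mv$data); mdat <- as.numeric(mv$data)

    mi_of <- function(th) {
      joint <- cpp_joint_hist_rigid(
        dim(fx$data), fx$spacing, fx$origin, cf,
        euler_to_matrix(th[1], th[2], th[3]), th[4:6],
        mdat, mdim, mv$spacing, mv$origin, mlo, mlo, mhi,
        cfg$bins, bfix)
      p <- joint / sum(joint)
      pm <- matrix(p, cfg$bins, cfg$bins, byrow = TRUE)
      entropy_bits(rowSums(pm)) + entropy_bits(colSums(pm)) - entropy_bits(p)
    }

    fine_shrink <- if (lev == length(pyr_f) && length(pyr_f) > 1L) 4 else 1
    steps <- c(rep(cfg$step_rot_rad, 3), rep(cfg$step_trans_mm, 3)) / fine_shrink
    min_steps <- c(rep(cfg$min_step_rot_rad, 3), rep(cfg$min_step_trans_mm, 3))
    steps <- pmax(steps, min_steps)

    trace <- cur <- mi_of(theta)
    for (sweep_i in seq_len(cfg$max_iter)) {
      improved <- 0
      for (p in 1:6) {
        for (sgn in c(1, -1)) {
          cand <- theta
          cand[p] <- cand[p] + sgn * steps[p]
          v <- mi_of(cand)
          if (v > cur) {
            theta <- cand
            improved <- max(improved, v - cur)
            cur <- v
            trace <- c(trace, cur)
            break
          }
        }
      }
      at_min <- all(steps <= min_steps * (1 + 1e-12))
      if (improved <= cfg$tol) {
        if (at_min) break
        steps <- pmax(steps / 2, min_steps)
      }
    }
    traces[[lev]] <- trace
  }

  A <- euler_to_matrix(theta[1], theta[2], theta[3])
  b <- cf + theta[4:6] - as.numeric(A %*% cf)
  fine <- traces[[length(traces)]]
  list(transform = rigid_transform(A, b), mi_trace_levels = traces,
       mi_trace = fine, mi = fine[length(fine)])
}

#' Resample a moving volume onto the grid of a fixed volume
#'
#' Each fixed voxel center is mapped through `transform` (fixed world ->
#' moving world) and the moving volume is tricubically interpolated there.
#'
#' @param fixed,moving [volume3d()] objects.
#' @param transform a [rigid_transform()].
#' @return a [volume3d()] on the fixed grid.
#' @export
resample_volume <- function(fixed, moving, transform) {
  coords <- apply_rigid(transform, grid_world_coords(fixed))
  vals <- tricubic_interpolate(moving, coords)
  volume3d(array(vals, dim = dim(fixed$data)), fixed$spacing, fixed$origin)
}

#' Automatic ROI localization by atlas registration
#'
#' Registers the atlas to the subject, maps the corners of the atlas ROI
#' box through the recovered transform, and returns the bounding box of the
#' mapped corners in subject voxel indices, dilated by `margin_voxels` and
#' clipped to the subject grid.
#'
#' @param subject,atlas [volume3d()] objects.
#' @param atlas_roi a [roi_box()] in atlas voxel indices.
#' @param cfg a [registration_config()].
#' @param margin_voxels dilation margin (voxels).
#' @param init optional initial [rigid_transform()] (subject -> atlas).
#' @return list with `roi` (a [roi_box()] in subject voxel indices) and
#'   `transform` (the subject -> atlas [rigid_transform()]).
#' @export
localize_roi <- function(subject, atlas, atlas_roi,
                         cfg = registration_config(), margin_voxels = 3L,
                         init = rigid_transform()) {
  stopifnot(inherits(atlas_roi, "roi_box"))
  d <- dim(atlas$data)
  if (any(atlas_roi$upper > d))
    stop("atlas_roi exceeds the atlas grid")
  reg <- register_rigid(subject, atlas, init = init, cfg = cfg)
  inv <- invert_transform(reg$transform)  # atlas -> subject

  corner_idx <- as.matrix(expand.grid(
    c(atlas_roi$lower[1], atlas_roi$upper[1] - 1L),
    c(atlas_roi$lower[2], atlas_roi$upper[2] - 1L),
    c(atlas_roi$lower[3], atlas_roi$upper[3] - 1L)))
  corners_w <- index_to_world(atlas, corner_idx)
  mapped <- apply_rigid(inv, corners_w)
  sub_idx <- world_to_index(subject, mapped)

  lo <- floor(apply(sub_idx, 2, min)) - margin_voxels
  hi <- ceiling(apply(sub_idx, 2, max)) + 1 + margin_voxels
  lo <- pmax(as.integer(lo), 0L)
  hi <- pmin(as.integer(hi), dim(subject$data))
  if (any(lo >= hi))
    stop("localization failure: mapped ROI box is empty after clipping")
  list(roi = roi_box(lo, hi), transform = reg$transform)
}

#' Crop a volume to an ROI box
#'
#' @param vol a [volume3d()] (or [binary_mask()]).
#' @param box a [roi_box()] (0-based, half-open).
#' @return object of the same class on the cropped grid, with the origin
#'   shifted so world coordinates are preserved.
#' @export
crop_volume <- function(vol, box) {
  stopifnot(inherits(box, "roi_box"))
  d <- dim(vol$data)
  if (any(box$upper > d)) stop("roi_box exceeds the grid")
  idx <- Map(function(l, u) (l + 1L):u, box$lower, box$upper)
  data <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  origin <- vol$origin + box$lower * vol$spacing
  if (inherits(vol, "binary_mask")) binary_mask(data, vol$spacing, origin)
  else volume3d(data, vol$spacing, origin)
}
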