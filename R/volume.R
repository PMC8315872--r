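#' 3D scalar volume with voxel spacing
#'
#' Container for a 3D scalar image: a numeric array together with the voxel
#' spacing (mm per axis) and the world-space position of the first voxel
#' center (origin, mm). World coordinates follow the convention
#' `world = origin + index * spacing` with 0-based voxel indices.
#'
#' @param data numeric 3D array of finite values.
#' @param spacing positive numeric length-3 vector, mm per axis.
#' @param origin numeric length-3 vector, mm position of voxel (0,0,0).
#' @return An object of class `volume3d` with elements `data`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("`data` must be a nonempty 3D array")
  if (!all(is.finite(data)))
    stop("`data` must be finite everywhere")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  origin (", paste(signif(x$origin, 4), collapse = ", "),
      ") mm; intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' Binary segmentation mask on a voxel grid
#'
#' @param data logical (or coercible) 3D array.
#' @param spacing,origin grid geometry as in [volume3d()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA")
  v <- volume3d(array(0, dim = dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

# --- grid coordinate helpers (internal) -------------------------------------

# World-space coordinates (mm) of every voxel center, as an n x 3 matrix in
# column-major voxel order.
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  sweep(idx %*% diag(vol$spacing), 2, vol$origin, "+")
}

world_to_index <- function(vol, coords) {
  sweep(coords, 2, vol$origin, "-") %*% diag(1 / vol$spacing)
}

index_to_world <- function(vol, idx) {
  sweep(idx %*% diag(vol$spacing), 2, vol$origin, "+")
}

# Physical center of the grid (mm): midpoint of the voxel-center bounding box.
volume_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) * vol$spacing / 2
}

# Separable Gaussian smoothing with sd `sigma` in voxels (replicate padding).
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  v <- as.numeric(arr)
  for (ax in 0:2)
    v <- cpp_convolve_axis(v, d, k, ax)
  array(v, dim = d)
}

# Central-difference gradient along one axis (1, 2 or 3) in voxel units,
# replicate boundary.
axis_gradient <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  if (axis == 1L) (arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]) / 2
  else if (axis == 2L) (arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE]) / 2
  else (arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE]) / 2
}
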