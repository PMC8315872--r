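# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive results with naive algorithms (explicit
# loops, closed forms) rather than calling the code paths under test.

# --- random fixtures --------------------------------------------------------

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_mask <- function(d = c(16L, 16L, 16L), p = 0.3) {
  binary_mask(array(stats::runif(prod(d)) < p, dim = d))
}

# a blotchy random mask with some spatial structure (not pure salt-and-pepper)
random_blob_mask <- function(d = c(16L, 16L, 16L), n_blobs = 3L) {
  m <- array(FALSE, dim = d)
  ctr <- matrix(stats::runif(3 * n_blobs, 2, d[1] - 2), n_blobs, 3)
  r <- stats::runif(n_blobs, 2, 5)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  for (b in seq_len(n_blobs))
    m[matrix(idx[sqrt(rowSums(sweep(idx, 2, ctr[b, ])^2)) <= r[b], ],
             ncol = 3)] <- TRUE
  binary_mask(m)
}

# --- metric oracles (exhaustive voxel loops / O(n^2) point loops) -----------

oracle_confusion <- function(pred, truth) {
  p <- pred$data; t_ <- truth$data
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (v in seq_along(p)) {
    if (p[v] && t_[v]) tp <- tp + 1L
    else if (p[v] && !t_[v]) fp <- fp + 1L
    else if (!p[v] && t_[v]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_mcc <- function(c) {
  marg <- c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)
  if (any(marg == 0)) return(0)
  (as.numeric(c$tp) * c$tn - as.numeric(c$fp) * c$fn) / sqrt(prod(marg))
}

oracle_pairwise_min <- function(a, b) {
  apply(a, 1, function(x) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((x - b[j, ])^2))
      if (d < best) best <- d
    }
    best
  })
}

oracle_amed <- function(a, b) {
  (mean(oracle_pairwise_min(a, b)) + mean(oracle_pairwise_min(b, a))) / 2
}

oracle_hausdorff <- function(a, b) {
  max(max(oracle_pairwise_min(a, b)), max(oracle_pairwise_min(b, a)))
}

# surface voxels by exhaustive 6-neighbor check
oracle_surface_count <- function(mask) {
  m <- mask$data
  d <- dim(m)
  cnt <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j, k]) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else FALSE,
      if (i < d[1]) m[i + 1, j, k] else FALSE,
      if (j > 1) m[i, j - 1, k] else FALSE,
      if (j < d[2]) m[i, j + 1, k] else FALSE,
      if (k > 1) m[i, j, k - 1] else FALSE,
      if (k < d[3]) m[i, j, k + 1] else FALSE)
    if (any(!nb)) cnt <- cnt + 1L
  }
  cnt
}

# --- phantom geometry oracle (independent inside tests) ---------------------

# Points on / inside the canonical primitives, written against the same
# parameterization the generator documents but re-derived here.
oracle_helix_points <- function(co, n = 600L) {
  tmax <- 2 * pi * co$turns
  t <- seq(0, tmax, length.out = n)
  r <- co$base_radius * (1 - co$taper * t / tmax)
  cbind(co$center[1] + r * cos(t),
        co$center[2] + r * sin(t),
        co$center[3] + co$pitch * t / (2 * pi))
}

oracle_inside <- function(pts, spec, curve = NULL) {
  if (is.null(curve)) curve <- oracle_helix_points(spec$cochlea)
  ins <- rowSums(sweep(pts, 2, spec$vestibule$semi_axes, "/")^2) <= 1
  for (cn in spec$canals) {
    q <- sweep(pts, 2, cn$center, "-")
    # Rodrigues rotation taking (0,0,1) onto the canal normal, re-derived
    # here so the arc cut uses the same documented frame convention.
    Rm <- oracle_axis_rotation(cn$normal)
    qq <- q %*% Rm
    rad <- sqrt(qq[, 1]^2 + qq[, 2]^2)
    u <- atan2(qq[, 2], qq[, 1]) %% (2 * pi)
    ins <- ins | ((rad - cn$major_radius)^2 + qq[, 3]^2 <=
                    cn$minor_radius^2 & u <= cn$arc_deg * pi / 180)
  }
  # cochlea: min distance to the dense helix polyline, chunked
  lo <- apply(curve, 2, min) - spec$cochlea$tube_radius
  hi <- apply(curve, 2, max) + spec$cochlea$tube_radius
  cand <- which(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
                pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
                pts[, 3] >= lo[3] & pts[, 3] <= hi[3] & !ins)
  if (length(cand)) {
    sub <- pts[cand, , drop = FALSE]
    best <- rep(Inf, nrow(sub))
    for (j in seq_len(nrow(curve))) {
      dd <- (sub[, 1] - curve[j, 1])^2 + (sub[, 2] - curve[j, 2])^2 +
        (sub[, 3] - curve[j, 3])^2
      best <- pmin(best, dd)
    }
    ins[cand] <- best <= spec$cochlea$tube_radius^2
  }
  ins
}

oracle_axis_rotation <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2], z[3] * n[1] - z[1] * n[3],
         z[1] * n[2] - z[2] * n[1])
  cth <- sum(z * n)
  if (sum(v^2) < 1e-16) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# dense independent sample of the canonical surface (random parameters)
oracle_surface_cloud <- function(spec, n = 20000L) {
  co <- spec$cochlea
  tmax <- 2 * pi * co$turns
  t <- stats::runif(n, 0, tmax)
  th <- stats::runif(n, 0, 2 * pi)
  r <- co$base_radius * (1 - co$taper * t / tmax)
  p <- cbind(co$center[1] + r * cos(t), co$center[2] + r * sin(t),
             co$center[3] + co$pitch * t / (2 * pi))
  dr <- -co$base_radius * co$taper / tmax
  tang <- cbind(dr * cos(t) - r * sin(t), dr * sin(t) + r * cos(t),
                co$pitch / (2 * pi))
  tang <- tang / sqrt(rowSums(tang^2))
  e1 <- cbind(tang[, 2], -tang[, 1], 0)
  e1 <- e1 / pmax(sqrt(rowSums(e1^2)), 1e-9)
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  coch <- p + co$tube_radius * (e1 * cos(th) + e2 * sin(th))

  u <- stats::rnorm(n); v <- stats::rnorm(n); w <- stats::rnorm(n)
  nn <- sqrt(u^2 + v^2 + w^2)
  ves <- cbind(u / nn * spec$vestibule$semi_axes[1],
               v / nn * spec$vestibule$semi_axes[2],
               w / nn * spec$vestibule$semi_axes[3])

  cloud <- rbind(coch, ves)
  for (cn in spec$canals) {
    uu <- stats::runif(n, 0, cn$arc_deg * pi / 180)
    vv <- stats::runif(n, 0, 2 * pi)
    ring <- cn$major_radius + cn$minor_radius * cos(vv)
    q <- cbind(ring * cos(uu), ring * sin(uu), cn$minor_radius * sin(vv))
    Rm <- oracle_axis_rotation(cn$normal)
    cloud <- rbind(cloud, sweep(q %*% t(Rm), 2, cn$center, "+"))
  }
  cloud
}

# fast-but-small phantom spec for unit tests (same physical extent and the
# same physical pose-translation range as the default grid)
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), spacing = c(0.8, 0.8, 0.8),
               pose_trans_voxels = 2.5, ...)
}
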