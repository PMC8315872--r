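#' Centroid size of a landmark shape
#'
#' The root sum of squared distances of the landmarks from their centroid,
#' the standard scale normalizer of Procrustes shape analysis (the 3D
#' extension of the planar Euclidean-distance size measure).
#'
#' @param shape n x 3 matrix of landmark coordinates (mm), n >= 1.
#' @return nonnegative scalar.
#' @export
centroid_size <- function(shape) {
  shape <- as_points(shape)
  if (nrow(shape) < 1L) stop("shape must contain at least one point")
  if (any(!is.finite(shape))) stop("shape coordinates must be finite")
  sqrt(sum(sweep(shape, 2, colMeans(shape), "-")^2))
}

#' Procrustes (Platts) distance between two corresponding shapes
#'
#' Sum of squared Euclidean distances between corresponding landmarks
#' (point m of `a` corresponds to point m of `b`). Symmetric in its
#' arguments.
#'
#' @param a,b n x 3 landmark matrices with equal n.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  if (nrow(a) != nrow(b))
    stop("shapes must have the same number of corresponding landmarks")
  sum((a - b)^2)
}

#' Align one shape to a reference by translation, scaling and SVD rotation
#'
#' Centers the shape on the reference centroid, scales it to the reference
#' centroid size, and rotates it by the Kabsch (SVD) solution minimizing the
#' Procrustes distance to the reference. Reflections are excluded by
#' sign-flipping the smallest singular direction when needed.
#'
#' @param shape,reference n x 3 landmark matrices with equal n (n >= 3).
#' @return list with `aligned` (n x 3) and `transform` (a
#'   [similarity_transform()] such that
#'   `apply_similarity(transform, shape) == aligned`).
#' @export
align_to_reference <- function(shape, reference) {
  shape <- as_points(shape); reference <- as_points(reference)
  if (nrow(shape) != nrow(reference))
    stop("shapes must have the same number of corresponding landmarks")
  cs_ref <- centroid_size(reference)
  cs_shp <- centroid_size(shape)
  if (cs_ref <= 0) stop("reference has zero centroid size")
  if (cs_shp <= 0) stop("shape has zero centroid size (all points coincide)")
  c_shp <- colMeans(shape); c_ref <- colMeans(reference)
  X <- sweep(shape, 2, c_shp, "-") / cs_shp
  Y <- sweep(reference, 2, c_ref, "-") / cs_ref
  sv <- svd(crossprod(X, Y))            # 3x3 covariance X^T Y = U D V^T
  if (sum(sv$d > 1e-12 * max(sv$d, 1e-300)) < 2L)
    stop("shape is rank-deficient (collinear or coincident landmarks)")
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)           # aligned = X %*% t(R)
  scale <- cs_ref / cs_shp
  aligned <- sweep(scale * (sweep(shape, 2, c_shp, "-") %*% t(R)),
                   2, c_ref, "+")
  tf <- similarity_transform(scale, R, c_ref - scale * as.numeric(R %*% c_shp))
  list(aligned = aligned, transform = tf)
}

#' Generalized Procrustes alignment of a set of corresponding shapes
#'
#' Iterative alignment: all shapes are centered and normalized to unit
#' centroid size, an initial reference is chosen (first shape by default, or
#' a seeded random choice), and then each shape is rotated to the current
#' mean and the mean is recomputed (pointwise average re-normalized to unit
#' centroid size) until the mean moves by less than `tol` or `max_iter` is
#' reached. The renormalized mean is the constrained least-squares optimum
#' over unit-size configurations, so the total Procrustes distance to the
#' mean is non-increasing across iterations.
#'
#' @param shapes list of >= 2 landmark matrices (equal n).
#' @param tol convergence tolerance on the root-squared mean displacement.
#' @param max_iter maximum number of iterations.
#' @param init `"first"` or `"random"` initial reference.
#' @param seed RNG seed used when `init = "random"`.
#' @return An `aligned_shape_set`: list with `shapes` (aligned, centered,
#'   unit size), `mean`, `transforms` (original -> aligned maps),
#'   `converged`, `iterations`, and `objective_trace` (total Procrustes
#'   distance to the mean after each iteration).
#' @export
generalized_procrustes_align <- function(shapes, tol = 1e-7, max_iter = 100L,
                                         init = c("first", "random"),
                                         seed = NULL) {
  init <- match.arg(init)
  if (!is.list(shapes) || length(shapes) < 2L)
    stop("at least two shapes are required")
  shapes <- lapply(shapes, as_points)
  n <- nrow(shapes[[1]])
  if (any(vapply(shapes, nrow, 1L) != n))
    stop("all shapes must have the same number of corresponding landmarks")

  cents <- lapply(shapes, colMeans)
  sizes <- vapply(shapes, centroid_size, 1)
  if (any(sizes <= 0)) stop("every shape must have positive centroid size")
  norm0 <- mapply(function(s, c_, cs) sweep(s, 2, c_, "-") / cs,
                  shapes, cents, sizes, SIMPLIFY = FALSE)

  ref_idx <- 1L
  if (init == "random") {
    old <- get0(".Random.seed", envir = globalenv())
    if (!is.null(seed)) set.seed(seed)
    ref_idx <- sample.int(length(shapes), 1L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  m <- norm0[[ref_idx]]
  rots <- rep(list(diag(3)), length(shapes))
  cur <- norm0
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    for (i in seq_along(cur)) {
      al <- align_to_reference(norm0[[i]], m)
      cur[[i]] <- al$aligned
      rots[[i]] <- al$transform$rotation
    }
    m_new <- Reduce(`+`, cur) / length(cur)
    m_new <- sweep(m_new, 2, colMeans(m_new), "-")
    msize <- sqrt(sum(m_new^2))
    if (msize <= 0) stop("degenerate mean shape (all aligned shapes cancel)")
    m_new <- m_new / msize
    trace <- c(trace, sum(vapply(cur, procrustes_distance, 1, b = m_new)))
    delta <- sqrt(sum((m_new - m)^2))
    m <- m_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes alignment did not converge in ",
            max_iter, " iterations")

  tfs <- mapply(function(R, c_, cs) {
    similarity_transform(1 / cs, R, -as.numeric(R %*% c_) / cs)
  }, rots, cents, sizes, SIMPLIFY = FALSE)

  structure(list(shapes = cur, mean = m, transforms = tfs,
                 converged = converged, iterations = iters,
                 objective_trace = trace),
            class = "aligned_shape_set")
}

#' Mean shape of an aligned shape set
#'
#' Pointwise arithmetic mean of the aligned shapes, re-centered and
#' re-normalized to unit centroid size.
#'
#' @param aligned an `aligned_shape_set` from
#'   [generalized_procrustes_align()], or a plain list of aligned landmark
#'   matrices.
#' @return n x 3 landmark matrix (centered, unit centroid size).
#' @export
compute_mean_shape <- function(aligned) {
  shapes <- if (inherits(aligned, "aligned_shape_set")) aligned$shapes
            else aligned
  if (!is.list(shapes) || length(shapes) < 1L)
    stop("need at least one aligned shape")
  shapes <- lapply(shapes, as_points)
  m <- Reduce(`+`, shapes) / length(shapes)
  m <- sweep(m, 2, colMeans(m), "-")
  cs <- sqrt(sum(m^2))
  if (cs <= 0) stop("degenerate mean shape")
  m / cs
}

#' Build a statistical shape model from a landmark cohort
#'
#' Runs generalized Procrustes alignment on the cohort and returns the mean
#' shape (only the average shape is retained; no variation modes are
#' modelled).
#'
#' @param landmarks list of n x 3 landmark matrices in correspondence.
#' @inheritParams generalized_procrustes_align
#' @return list of class `shape_model` with `mean` (unit-size, centered),
#'   `n_training`, `iterations`, `converged`.
#' @export
build_shape_model <- function(landmarks, tol = 1e-7, max_iter = 100L,
                              init = "first", seed = NULL) {
  gpa <- generalized_procrustes_align(landmarks, tol = tol,
                                      max_iter = max_iter, init = init,
                                      seed = seed)
  structure(list(mean = gpa$mean, n_training = length(landmarks),
                 iterations = gpa$iterations, converged = gpa$converged),
            class = "shape_model")
}

#' Attach an atlas to a shape model for segmentation
#'
#' Maps the normalized mean shape into the atlas world frame by similarity
#' alignment to the atlas's own landmarks, producing the model bundle used
#' by [segment_is3dls()].
#'
#' @param model a `shape_model` from [build_shape_model()].
#' @param atlas_landmarks n x 3 landmarks of the atlas subject (mm, atlas
#'   world frame).
#' @param atlas the atlas [volume3d()].
#' @param atlas_roi a [roi_box()] containing the inner ear in the atlas.
#' @return list with `mean_mm`, `atlas`, `atlas_roi` plus the original
#'   model fields.
#' @export
attach_atlas <- function(model, atlas_landmarks, atlas, atlas_roi) {
  stopifnot(inherits(atlas, "volume3d"), inherits(atlas_roi, "roi_box"))
  mean_mm <- align_to_reference(model$mean, as_points(atlas_landmarks))$aligned
  c(model, list(mean_mm = mean_mm, atlas = atlas, atlas_roi = atlas_roi))
}
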