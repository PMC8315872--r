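#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume3d()]; spacing from the header pixdim, origin from the
#'   xform translation.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file '", path, "': ", conditionMessage(e)))
  data <- as.array(img)
  if (length(dim(data)) != 3L)
    stop("malformed NIfTI file '", path, "': expected 3 dimensions, got ",
         length(dim(data)))
  data <- array(as.numeric(data), dim = dim(data))  # drop header attributes
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  volume3d(data, sp, origin)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' @param vol a [volume3d()] or [binary_mask()] (masks are written as uint8
#'   0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  data <- vol$data
  dt <- "double"
  if (inherits(vol, "binary_mask")) {
    data <- array(as.integer(data), dim = dim(data))
    dt <- "uint8"
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' @param path path to the mask file; nonzero voxels become foreground.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data != 0, v$spacing, v$origin)
}

#' Read ordered landmarks from CSV
#'
#' Expects the dialect `index,x_mm,y_mm,z_mm` with `index` strictly
#' increasing and contiguous from 0.
#'
#' @param path CSV path.
#' @return n x 3 matrix of mm coordinates.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("malformed landmark file '", path, "': ", conditionMessage(e)))
  need <- c("index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("malformed landmark file '", path,
         "': expected header index,x_mm,y_mm,z_mm")
  if (nrow(df) == 0L)
    stop("malformed landmark file '", path, "': no landmark rows")
  expct <- seq_len(nrow(df)) - 1L
  bad <- which(df$index != expct)
  if (length(bad))
    stop("malformed landmark file '", path, "': index ", df$index[bad[1]],
         " at row ", bad[1], " (expected ", expct[bad[1]],
         "; indices must be contiguous from 0)")
  pts <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  if (any(!is.finite(pts)))
    stop("malformed landmark file '", path, "': non-finite coordinates")
  dimnames(pts) <- NULL
  pts
}

#' Write ordered landmarks to CSV
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(points, path) {
  points <- as_points(points)
  df <- data.frame(index = seq_len(nrow(points)) - 1L,
                   x_mm = points[, 1], y_mm = points[, 2], z_mm = points[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' JSON schema: `{"matrix": [9 reals, row-major], "translation_mm": [3]}`.
#'
#' @param t a [rigid_transform()].
#' @param path JSON path.
#' @return `read_transform` returns a [rigid_transform()].
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(list(matrix = as.numeric(t(t$A)),
                            translation_mm = t$b),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$matrix, 3, 3, byrow = TRUE), x$translation_mm)
}

#' Serialize / deserialize an ROI box as JSON
#'
#' JSON schema: `{"lower": [i,j,k], "upper": [i,j,k]}` (0-based,
#' half-open).
#'
#' @param box a [roi_box()].
#' @param path JSON path.
#' @return `read_roi` returns a [roi_box()].
#' @export
write_roi <- function(box, path) {
  stopifnot(inherits(box, "roi_box"))
  jsonlite::write_json(list(lower = box$lower, upper = box$upper), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_box(x$lower, x$upper)
}

#' Serialize / deserialize a statistical shape model as JSON
#'
#' JSON schema: `{n_landmarks, mean_points (flat, row-major), n_training,
#' iterations, converged}`.
#'
#' @param model a shape model from [build_shape_model()].
#' @param path JSON path.
#' @return `read_shape_model` returns the model list.
#' @export
write_shape_model <- function(model, path) {
  jsonlite::write_json(list(
    n_landmarks = nrow(model$mean),
    mean_points = as.numeric(t(model$mean)),
    n_training = model$n_training,
    iterations = model$iterations,
    converged = model$converged), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(mean = matrix(x$mean_points, x$n_landmarks, 3, byrow = TRUE),
       n_training = x$n_training, iterations = x$iterations,
       converged = x$converged)
}

#' Write an evaluation report as JSON
#'
#' Keys: `mcc, dsc, fpr, fnr, tp_pct, fp_pct, amed_mm, hd_mm`.
#'
#' @param report an `evaluation_report` from [evaluate_segmentation()].
#' @param path JSON path.
#' @return `read_report` returns the report as a list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    report[c("mcc", "dsc", "fpr", "fnr", "tp_pct", "fp_pct",
             "amed_mm", "hd_mm")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
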