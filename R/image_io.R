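#' @importFrom stats approx coef lm median sd kruskal.test oneway.test predict rnorm runif setNames quantile
#' @importFrom utils head read.csv write.csv
NULL

#' Gridded image volume
#'
#' A light container for a 3D or 4D scalar image: the voxel array, the 4x4
#' voxel-to-world affine, and the per-axis voxel spacing in mm. For 4D data the
#' varying dimension (b-value or time frame) is the last axis; its physical
#' coordinates (b-values, frame times) travel as separate sidecar inputs.
#'
#' @param data numeric 3D or 4D array.
#' @param affine 4x4 voxel-to-world transform (defaults to identity).
#' @param spacing per-axis voxel size in mm, length 3 (defaults to affine
#'   column norms).
#' @return An object of class `image_volume` with fields `data`, `affine`,
#'   `spacing` and `axis_order` (fixed `"xyz[t]"` tag).
#' @export
image_volume <- function(data, affine = diag(4), spacing = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("image_volume: data must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("image_volume: affine must be 4x4")
  if (is.null(spacing)) {
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("image_volume: spacing entries must be strictly positive")
  }
  structure(list(data = data, affine = unname(affine), spacing = spacing,
                 axis_order = if (nd == 4L) "xyzt" else "xyz"),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

spatial_shape <- function(vol) dim(vol$data)[1:3]

#' Region-of-interest label mask
#'
#' Integer label array on the same grid as a reference volume; 0 is background.
#'
#' @param data integer-valued array (3D) of non-negative labels.
#' @param reference_shape expected spatial shape; defaults to `dim(data)`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, reference_shape = dim(data)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("roi_mask: data must be a 3D array")
  vals <- data[is.finite(data)]
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("roi_mask: labels must be non-negative integers")
  }
  if (!identical(as.integer(dim(data)), as.integer(reference_shape))) {
    stop("roi_mask: mask shape does not match reference_shape")
  }
  structure(list(data = data, reference_shape = as.integer(reference_shape)),
            class = "roi_mask")
}

#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 file (compressed or not) with no resampling.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  d <- dim(img)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # singleton axes dropped
  arr <- array(as.vector(img), dim = d)
  image_volume(arr, affine = aff)
}

#' Write a NIfTI volume
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype; `"double"` preserves values exactly.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' @param path NIfTI file of integer labels.
#' @param reference an optional [image_volume] whose spatial grid the mask must
#'   match exactly (no implicit resampling).
#' @return An [roi_mask].
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  ref_shape <- if (is.null(reference)) dim(vol$data) else spatial_shape(reference)
  m <- roi_mask(round(vol$data), reference_shape = ref_shape)
  if (!is.null(reference) &&
      max(abs(vol$affine - reference$affine)) > 1e-4) {
    stop("read_mask: mask affine does not match the reference volume grid")
  }
  m
}

check_alignment <- function(vol, mask) {
  if (!identical(as.integer(spatial_shape(vol)), as.integer(dim(mask$data)))) {
    stop("mask spatial shape ", paste(dim(mask$data), collapse = "x"),
         " does not match volume ", paste(spatial_shape(vol), collapse = "x"))
  }
  invisible(TRUE)
}

#' Extract per-voxel frame series from an ROI
#'
#' Pulls the full frame series of every voxel carrying `label` out of a 4D
#' volume. Voxels are ordered lexicographically by (column-major) array index —
#' first axis fastest — so the ordering is deterministic and the returned index
#' matrix allows results to be written back with [write_back_roi()].
#'
#' @param volume a 4D [image_volume].
#' @param mask an [roi_mask] on the same spatial grid.
#' @param label positive integer label to extract.
#' @return list with `signals` (n_voxels x n_frames matrix) and `index`
#'   (n_voxels x 3 matrix of 1-based array indices).
#' @export
extract_roi_signals <- function(volume, mask, label = 1L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (length(dim(volume$data)) != 4L) stop("extract_roi_signals: volume must be 4D")
  if (label <= 0) stop("extract_roi_signals: label must be a positive integer")
  check_alignment(volume, mask)
  idx <- which(mask$data == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("extract_roi_signals: label ", label, " absent from mask (empty ROI)")
  nf <- dim(volume$data)[4L]
  flat <- matrix(volume$data, ncol = nf)           # voxels x frames, column-major
  lin <- which(mask$data == label)
  sig <- flat[lin, , drop = FALSE]
  dimnames(idx) <- NULL
  list(signals = sig, index = idx)
}

#' Write per-voxel values back into a 3D map
#'
#' Inverse of the bookkeeping in [extract_roi_signals()]: places `values[i]` at
#' `index[i, ]`, leaving all other voxels untouched.
#'
#' @param map a 3D array (or [image_volume]) to write into.
#' @param index n x 3 matrix of 1-based voxel indices.
#' @param values numeric vector, one per index row.
#' @return The modified array / volume.
#' @export
write_back_roi <- function(map, index, values) {
  is_vol <- inherits(map, "image_volume")
  arr <- if (is_vol) map$data else map
  if (nrow(index) != length(values)) stop("write_back_roi: index/value length mismatch")
  arr[index] <- values
  if (is_vol) { map$data <- arr; map } else arr
}

#' Summarise a parametric map over an ROI
#'
#' Non-finite voxels (failed fits) are excluded and counted, so summaries are
#' the mean +/- SD statistics reported for quantitative imaging biomarkers.
#'
#' @param map 3D [image_volume] (or array) of parameter values.
#' @param mask an [roi_mask].
#' @param label positive integer label.
#' @return list `mean`, `sd` (sample SD), `median`, `n_voxels`, `n_excluded`.
#' @export
summarize_roi <- function(map, mask, label = 1L) {
  arr <- if (inherits(map, "image_volume")) map$data else as.array(map)
  if (length(dim(arr)) != 3L) stop("summarize_roi: map must be 3D")
  check_alignment(image_volume(arr), mask)
  v <- arr[mask$data == label]
  if (length(v) == 0L) stop("summarize_roi: label ", label, " absent from mask")
  keep <- is.finite(v)
  if (!any(keep)) stop("summarize_roi: all masked voxels are non-finite (empty summary)")
  x <- v[keep]
  list(mean = mean(x),
       sd = if (length(x) > 1L) sd(x) else 0,
       median = median(x),
       n_voxels = length(x),
       n_excluded = sum(!keep))
}

#' Rescale image intensities
#'
#' `minmax` maps the range to \[0, 1\]; `zscore` centres to mean 0, SD 1.
#' Constant images are rejected explicitly rather than silently dividing by
#' zero.
#'
#' @param image 2D or 3D numeric array.
#' @param method `"minmax"` or `"zscore"`.
#' @return array of the same shape.
#' @export
normalize_intensity <- function(image, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- as.array(image)
  rng <- range(x, finite = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("normalize_intensity: constant image (degenerate input) — nothing to scale")
  }
  if (method == "minmax") {
    (x - rng[1]) / diff(rng)
  } else {
    s <- sd(x)
    (x - mean(x)) / s
  }
}

#' Resize a 2D image
#'
#' Separable align-corners interpolation: the first and last samples of each
#' axis map onto the first and last samples of the target axis, so an identity
#' resize is exact and bilinear output never leaves the input value range.
#'
#' @param image 2D numeric matrix.
#' @param target integer `(H, W)` output shape.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return `target`-shaped matrix.
#' @export
resize_image <- function(image, target, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  image <- as.matrix(image)
  target <- as.integer(target)
  if (length(target) != 2L || any(target <= 0L)) {
    stop("resize_image: target dimensions must be positive")
  }
  axis_pos <- function(n_in, n_out) {
    if (n_out == 1L) return(if (n_in == 1L) 1 else (1 + n_in) / 2)
    seq(1, n_in, length.out = n_out)
  }
  interp_axis <- function(mat, n_out, along) {
    n_in <- if (along == 1L) nrow(mat) else ncol(mat)
    pos <- axis_pos(n_in, n_out)
    if (interpolation == "nearest") {
      take <- pmin(pmax(round(pos), 1L), n_in)
      if (along == 1L) mat[take, , drop = FALSE] else mat[, take, drop = FALSE]
    } else {
      if (n_in == 1L) {
        take <- rep(1L, n_out)
        return(if (along == 1L) mat[take, , drop = FALSE] else mat[, take, drop = FALSE])
      }
      f <- function(v) approx(seq_len(n_in), v, xout = pos)$y
      if (along == 1L) apply(mat, 2L, f) else t(apply(mat, 1L, f))
    }
  }
  out <- interp_axis(image, target[1L], 1L)
  out <- matrix(out, nrow = target[1L])
  out <- interp_axis(out, target[2L], 2L)
  matrix(out, nrow = target[1L], ncol = target[2L])
}

#' Write an ROI summary table as CSV
#'
#' @param summaries named list of [summarize_roi()] results (names are
#'   parameter names).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_summary <- function(summaries, path) {
  df <- do.call(rbind, lapply(names(summaries), function(p) {
    s <- summaries[[p]]
    data.frame(parameter = p, mean = s$mean, sd = s$sd, median = s$median,
               n_voxels = s$n_voxels, n_excluded = s$n_excluded)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
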