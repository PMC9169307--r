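# Arrays throughout the package are 3D numeric/integer arrays with
# dim = c(ny, nx, nz): readTIFF() pages (y rows, x columns) stacked along z.

.check_stack <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3)
    stop(sprintf("'%s' must be a 3D array", name))
  invisible(dim(x))
}

.check_pair <- function(a, b, na = "raw", nb = "mask") {
  da <- .check_stack(a, na); db <- .check_stack(b, nb)
  if (!identical(da, db))
    stop(sprintf("'%s' and '%s' must have identical dimensions", na, nb))
  invisible(da)
}

.as_binary_mask <- function(mask) {
  m <- array(as.integer(mask != 0), dim = dim(mask))
  if (!any(m == 1L)) stop("mask has no foreground voxels")
  m
}

#' Masked local-contrast enhancement
#'
#' Computes, for every voxel inside the nucleus mask, the Laplacian-style
#' contrast value
#' \deqn{\delta_x = \frac{1}{s} \sum_{y \in N(s)} (v_x - v_y),}
#' where \eqn{N(s)} is the cubic neighborhood of radius `s` voxels
#' (window side `2s + 1`, center excluded). Neighbors outside the image
#' bounds or outside the mask are skipped, so voxels beyond the nuclear
#' envelope never influence the result. Output is 0 outside the mask.
#' Bright compact structures (chromocenters, FISH spots) score high
#' positive values; their surroundings go negative.
#'
#' @param raw 3D numeric array of nonnegative intensities, dim (ny, nx, nz).
#' @param mask Binary 3D array of the same shape; nonzero = nucleus.
#' @param s Neighborhood radius in voxels, integer >= 1.
#' @return 3D numeric array of enhanced values (0 outside the mask).
#' @export
compute_enhanced_image <- function(raw, mask, s) {
  d <- .check_pair(raw, mask)
  if (length(s) != 1 || !is.finite(s) || s < 1 || s != round(s))
    stop("'s' must be a single integer >= 1")
  m <- .as_binary_mask(mask)
  out <- cpp_enhance(as.numeric(raw), m, as.integer(d), as.integer(s))
  array(out, dim = d)
}

#' Gaussian smoothing of the enhanced image
#'
#' Separable 3D Gaussian convolution (reflecting boundary, kernel truncated
#' at 3 sigma and renormalized), applied to the enhanced values and then
#' re-zeroed outside the nucleus mask. `sigma = 0` returns the input
#' unchanged. Sigma is expressed in voxels and is isotropic in voxel space
#' unless three per-axis values `(y, x, z)` are given.
#'
#' @param enhanced 3D numeric array, as from [compute_enhanced_image()].
#' @param sigma Nonnegative smoothing width(s) in voxels; length 1 or 3.
#' @param mask Binary 3D array, same shape.
#' @return Smoothed 3D numeric array, 0 outside the mask.
#' @export
smooth_enhanced <- function(enhanced, sigma, mask) {
  d <- .check_pair(enhanced, mask, "enhanced", "mask")
  if (!length(sigma) %in% c(1L, 3L) || any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be one or three nonnegative values")
  if (all(sigma == 0)) return(enhanced)
  sig <- if (length(sigma) == 1) rep(sigma, 3) else sigma
  out <- cpp_gauss_blur(as.numeric(enhanced), as.integer(d),
                        sig[1], sig[2], sig[3])
  out <- array(out, dim = d)
  out[mask == 0] <- 0
  out
}

#' Adaptive threshold from in-mask statistics
#'
#' The threshold is `t = mean + sd * f_eff`, with mean and population
#' standard deviation (divisor N) taken over the in-mask voxels of the
#' (smoothed) enhanced image only.
#'
#' @param enhanced 3D numeric array of (smoothed) enhanced values.
#' @param mask Binary 3D array, same shape, nonempty.
#' @param f_eff Effective threshold factor (after any large-nucleus
#'   adjustment).
#' @return An object of class `"seg_threshold"`: list with `t`, `mean`,
#'   `stdev`, `f_eff`.
#' @export
compute_threshold <- function(enhanced, mask, f_eff) {
  .check_pair(enhanced, mask, "enhanced", "mask")
  vals <- enhanced[mask != 0]
  if (length(vals) == 0) stop("mask has no foreground voxels")
  m <- mean(vals)
  sdev <- sqrt(mean((vals - m)^2))
  structure(list(t = m + sdev * f_eff, mean = m, stdev = sdev,
                 f_eff = as.numeric(f_eff)),
            class = "seg_threshold")
}

#' @export
print.seg_threshold <- function(x, ...) {
  cat(sprintf("threshold t = %.6g (mean %.6g + stdev %.6g * f %.3g)\n",
              x$t, x$mean, x$stdev, x$f_eff))
  invisible(x)
}

#' Binarize an enhanced image at a threshold
#'
#' A voxel is foreground iff it lies inside the mask and its enhanced
#' value is strictly greater than `t`. The strict comparison guarantees
#' that a constant image (threshold equal to the common value) yields no
#' objects.
#'
#' @param enhanced 3D numeric array.
#' @param t Threshold: a number or a `"seg_threshold"` object.
#' @param mask Binary 3D array, same shape.
#' @return Binary integer 3D array.
#' @export
binarize <- function(enhanced, t, mask) {
  d <- .check_pair(enhanced, mask, "enhanced", "mask")
  tv <- if (inherits(t, "seg_threshold")) t$t else as.numeric(t)
  array(as.integer(mask != 0 & enhanced > tv), dim = d)
}

#' Label connected components in 3D
#'
#' Maximal connected foreground components receive labels `1..n` in
#' first-encounter order of a raster scan (z slowest, then y, then x);
#' background stays 0.
#'
#' @param binary Binary 3D array (values 0/1 or logical).
#' @param connectivity Voxel adjacency: 6 (faces), 18 (faces + edges) or
#'   26 (full cube). Default 26.
#' @return Integer 3D array of labels with attribute `n_objects`.
#' @export
label_components <- function(binary, connectivity = 26) {
  d <- .check_stack(binary, "binary")
  if (!connectivity %in% c(6, 18, 26))
    stop("'connectivity' must be 6, 18 or 26")
  b <- array(as.integer(binary != 0), dim = d)
  lab <- cpp_label_components(b, as.integer(d), as.integer(connectivity))
  n <- attr(lab, "n_objects")
  lab <- array(as.integer(lab), dim = d)
  attr(lab, "n_objects") <- n
  lab
}

#' Number of labeled objects
#' @param labels Integer label array from [label_components()].
#' @return Count of distinct nonzero labels.
#' @export
n_objects <- function(labels) {
  n <- attr(labels, "n_objects")
  if (!is.null(n)) return(as.integer(n))
  as.integer(max(0L, max(labels)))
}

# Drop labeled objects smaller than min_volume um^3 and relabel 1..n
# preserving the original label order.
.filter_small_objects <- function(labels, cal, min_volume) {
  if (min_volume <= 0 || n_objects(labels) == 0) return(labels)
  vv <- voxel_volume(cal)
  counts <- tabulate(labels[labels > 0L], nbins = n_objects(labels))
  keep <- which(counts * vv >= min_volume)
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(labels))
  nz <- labels > 0L
  out[nz] <- remap[labels[nz]]
  attr(out, "n_objects") <- length(keep)
  out
}

#' Segment bright subnuclear objects in one nucleus
#'
#' Full detection pipeline for a single nucleus: compute the calibrated
#' nucleus volume from the mask, adjust `s` and `f` if the nucleus exceeds
#' the volume cutoff, enhance local contrast inside the mask, smooth with
#' a Gaussian, threshold at `mean + sd * f_eff`, binarize (strict `>`) and
#' label connected components. Optionally discards components smaller than
#' `params$min_volume` um^3.
#'
#' @param raw 3D numeric array of raw intensities, dim (ny, nx, nz).
#' @param mask Binary 3D array of the nucleus, same shape.
#' @param cal A [calibration()] object.
#' @param params A [seg_params()] object.
#' @return An object of class `"nucleus_segmentation"`: list with
#'   `labels` (integer array), `n_objects`, `threshold`
#'   (`"seg_threshold"`), `params_eff` (parameters actually used, after
#'   adjustment) and `nucleus_volume` (um^3).
#' @examples
#' # a constant image contains no objects
#' raw <- array(7, dim = c(8, 8, 4))
#' mask <- array(1L, dim = c(8, 8, 4))
#' seg <- segment_nucleus(raw, mask, calibration(1, 1, 1), seg_params())
#' seg$n_objects
#' @export
segment_nucleus <- function(raw, mask, cal = calibration(),
                            params = seg_params()) {
  .check_pair(raw, mask)
  stopifnot(inherits(cal, "calibration"), inherits(params, "seg_params"))
  m <- .as_binary_mask(mask)
  vol <- sum(m) * voxel_volume(cal)
  p <- adjust_parameters(vol, params)
  enh <- compute_enhanced_image(raw, m, p$s)
  if (p$smoothing && any(p$sigma > 0))
    enh <- smooth_enhanced(enh, p$sigma, m)
  thr <- compute_threshold(enh, m, p$f)
  bin <- binarize(enh, thr, m)
  lab <- label_components(bin, p$connectivity)
  lab <- .filter_small_objects(lab, cal, p$min_volume)
  structure(list(labels = lab, n_objects = n_objects(lab), threshold = thr,
                 params_eff = p, nucleus_volume = vol),
            class = "nucleus_segmentation")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf(
    "nucleus segmentation: %d object(s) | nucleus %.3g um^3 | s_eff=%d f_eff=%g t=%.6g\n",
    x$n_objects, x$nucleus_volume, x$params_eff$s, x$params_eff$f,
    x$threshold$t))
  invisible(x)
}
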