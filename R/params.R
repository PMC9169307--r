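#' Voxel calibration
#'
#' Physical edge lengths of a voxel in micrometers. All morphometric
#' quantities (volumes, distances) are derived from these; the voxel
#' volume is `dx * dy * dz` um^3.
#'
#' @param dx,dy,dz Voxel edge lengths along x, y and z, in um. All must be
#'   strictly positive.
#' @return An object of class `"calibration"`: a named list with elements
#'   `dx`, `dy`, `dz`.
#' @examples
#' calibration(0.1, 0.1, 0.2)
#' @export
calibration <- function(dx = 1, dy = 1, dz = 1) {
  if (!all(is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stop("calibration values must be strictly positive and finite")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("voxel calibration: dx=%g dy=%g dz=%g um (voxel volume %g um^3)\n",
              x$dx, x$dy, x$dz, voxel_volume(x)))
  invisible(x)
}

#' Voxel volume in cubic micrometers
#' @param cal A [calibration()] object.
#' @return `dx * dy * dz` in um^3.
#' @export
voxel_volume <- function(cal) cal$dx * cal$dy * cal$dz

#' Segmentation parameters
#'
#' Tunable parameters of the object-detection pipeline. `s` is the radius,
#' in voxels, of the cubic neighborhood used by the local-contrast
#' enhancement (window side `2s + 1`, center excluded). `f` scales the
#' adaptive threshold `t = mean + f * sd` computed over in-mask voxels of
#' the smoothed enhanced image. For nuclei larger than `volume_switch`
#' um^3 both parameters are adjusted automatically (`s <- round(2.5 * s)`,
#' `f <- f + 1`); this compensates for the larger, often endoreduplicated
#' nuclei in which chromocenters are bigger and contrast statistics shift.
#'
#' @param s Neighborhood radius in voxels; integer >= 1.
#' @param f Threshold factor; >= 0.
#' @param sigma Gaussian smoothing width in voxels, isotropic in voxel
#'   space; a single value or one value per (y, x, z) axis; `0` disables
#'   smoothing.
#' @param volume_switch Nucleus-volume cutoff in um^3 above which `s` and
#'   `f` are adjusted (strict `>`). Default 50.
#' @param connectivity Voxel adjacency for component labeling: 6, 18 or 26.
#' @param min_volume Minimum object volume in um^3; smaller components are
#'   discarded after labeling. Default 0 (no filter).
#' @param smoothing Logical; apply the Gaussian smoothing step.
#' @return An object of class `"seg_params"`.
#' @examples
#' seg_params(s = 2, f = 1.5)
#' @export
seg_params <- function(s = 2, f = 1.5, sigma = 1.0, volume_switch = 50,
                       connectivity = 26, min_volume = 0, smoothing = TRUE) {
  if (length(s) != 1 || !is.finite(s) || s < 1 || s != round(s))
    stop("'s' must be a single integer >= 1")
  if (length(f) != 1 || !is.finite(f) || f < 0)
    stop("'f' must be a single value >= 0")
  if (!length(sigma) %in% c(1L, 3L) || any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be one or three values >= 0")
  if (length(volume_switch) != 1 || !is.finite(volume_switch) || volume_switch <= 0)
    stop("'volume_switch' must be a single positive value")
  if (!connectivity %in% c(6, 18, 26))
    stop("'connectivity' must be 6, 18 or 26")
  if (min_volume < 0) stop("'min_volume' must be >= 0")
  structure(list(s = as.integer(s), f = as.numeric(f), sigma = as.numeric(sigma),
                 volume_switch = as.numeric(volume_switch),
                 connectivity = as.integer(connectivity),
                 min_volume = as.numeric(min_volume),
                 smoothing = isTRUE(smoothing)),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat(sprintf(
    "segmentation parameters: s=%d f=%g sigma=%s volume_switch=%g um^3\n  connectivity=%d min_volume=%g um^3 smoothing=%s\n",
    x$s, x$f, paste(x$sigma, collapse = "/"), x$volume_switch,
    x$connectivity, x$min_volume, x$smoothing))
  invisible(x)
}

#' Adjust segmentation parameters for large nuclei
#'
#' Nuclei whose calibrated volume exceeds `params$volume_switch` (default
#' 50 um^3) get an enlarged enhancement neighborhood, `s <- round(2.5 * s)`
#' (round half up, floored at 1), and a raised threshold factor,
#' `f <- f + 1`. Both adjustments trigger together, are applied exactly
#' once per nucleus, and a volume of exactly `volume_switch` counts as
#' small (strict `>`).
#'
#' @param nucleus_volume Calibrated nucleus volume in um^3; must be > 0.
#' @param params A [seg_params()] object.
#' @return A `seg_params` object, adjusted if the nucleus is large.
#' @examples
#' adjust_parameters(60, seg_params(s = 2, f = 1.5)) # s = 5, f = 2.5
#' adjust_parameters(40, seg_params(s = 2, f = 1.5)) # unchanged
#' @export
adjust_parameters <- function(nucleus_volume, params = seg_params()) {
  if (length(nucleus_volume) != 1 || !is.finite(nucleus_volume) ||
      nucleus_volume <= 0)
    stop("'nucleus_volume' must be a single positive value")
  stopifnot(inherits(params, "seg_params"))
  if (nucleus_volume > params$volume_switch) {
    params$s <- max(1L, as.integer(floor(2.5 * params$s + 0.5)))
    params$f <- params$f + 1
  }
  params
}
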