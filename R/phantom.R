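# Ground-truthed ellipsoidal nucleus phantoms and the salt-and-pepper
# noise-robustness experiment.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic nucleus phantom
#'
#' Describes an ellipsoidal nucleus containing bright spherical
#' chromocenters at controlled number, size and position, imaged at three
#' constant intensity levels (background < nucleoplasm < chromocenter)
#' with optional mild Gaussian texture. Defaults emulate a small
#' Arabidopsis-like nucleus (semi-axes 2.2 x 2.5 x 2.0 um, about 46 um^3)
#' sampled at 0.1 um isotropic voxels, carrying 6-10 chromocenters of
#' radius 0.3-0.5 um.
#'
#' @param shape Image dimensions (ny, nx, nz) in voxels.
#' @param semi_axes Nucleus ellipsoid semi-axes (y, x, z) in um.
#' @param n_chromocenters Number of planted objects; a single count or a
#'   length-2 range sampled uniformly (inclusive) per phantom.
#' @param cc_radius_range Chromocenter radius range (min, max) in um.
#' @param min_gap_envelope Minimum clearance between a chromocenter
#'   surface and the nuclear envelope, in um.
#' @param min_gap_objects Minimum surface-to-surface clearance between
#'   chromocenters, in um.
#' @param intensities Named or positional vector
#'   (background, nucleoplasm, chromocenter), strictly increasing, on the
#'   8-bit scale.
#' @param texture_sd Standard deviation of additive Gaussian texture
#'   (0 = three flat levels).
#' @param cal A [calibration()] object.
#' @param seed Integer seed; the phantom is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(50, 56, 46),
                         semi_axes = c(2.2, 2.5, 2.0),
                         n_chromocenters = c(6, 10),
                         cc_radius_range = c(0.3, 0.5),
                         min_gap_envelope = 0.25,
                         min_gap_objects = 0.2,
                         intensities = c(background = 10, nucleoplasm = 90,
                                         chromocenter = 200),
                         texture_sd = 0,
                         cal = calibration(0.1, 0.1, 0.1),
                         seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 4),
            length(semi_axes) == 3, all(semi_axes > 0),
            length(n_chromocenters) %in% c(1L, 2L), all(n_chromocenters >= 0),
            length(cc_radius_range) == 2,
            cc_radius_range[1] > 0, diff(cc_radius_range) >= 0,
            min_gap_envelope >= 0, min_gap_objects >= 0,
            length(intensities) == 3, all(diff(intensities) > 0),
            texture_sd >= 0, inherits(cal, "calibration"))
  structure(list(shape = as.integer(shape), semi_axes = as.numeric(semi_axes),
                 n_chromocenters = as.integer(n_chromocenters),
                 cc_radius_range = as.numeric(cc_radius_range),
                 min_gap_envelope = min_gap_envelope,
                 min_gap_objects = min_gap_objects,
                 intensities = unname(as.numeric(intensities)),
                 texture_sd = texture_sd, cal = cal,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate field for voxel centers,
# relative to centers cy/cx/cz (um) and semi-axes a (um)
.ellipsoid_field <- function(coords, center, a) {
  y2 <- ((coords$y - center[1]) / a[1])^2
  x2 <- ((coords$x - center[2]) / a[2])^2
  z2 <- ((coords$z - center[3]) / a[3])^2
  outer(outer(y2, x2, "+"), z2, "+")
}

.voxel_coords <- function(shape, cal) {
  list(y = (seq_len(shape[1]) - (shape[1] + 1) / 2) * cal$dy,
       x = (seq_len(shape[2]) - (shape[2] + 1) / 2) * cal$dx,
       z = (seq_len(shape[3]) - (shape[3] + 1) / 2) * cal$dz)
}

#' Generate a ground-truthed nucleus phantom
#'
#' Builds the (raw, mask, truth) triplet for one synthetic nucleus:
#' an ellipsoidal binary mask, a raw image at the three intensity levels
#' of the spec (plus optional Gaussian texture, clamped to the 8-bit
#' range), and a label stack of the planted chromocenters. Chromocenter
#' centers are rejection-sampled so that every object keeps the required
#' clearance from the envelope and from the other objects; an infeasible
#' spec errors out after a bounded number of attempts. The result is a
#' deterministic function of the spec (including its seed).
#'
#' @param spec A [phantom_spec()] object.
#' @return An object of class `"ground_truth"`: list with `raw`, `mask`,
#'   `truth` (label array), `cal`, `spec` and `objects` (data.frame with
#'   per-object center, radius, true volume and radial envelope
#'   clearance).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    shape <- spec$shape; cal <- spec$cal; a <- spec$semi_axes
    coords <- .voxel_coords(shape, cal)
    mask <- array(as.integer(.ellipsoid_field(coords, c(0, 0, 0), a) <= 1),
                  dim = shape)
    if (!any(mask == 1L))
      stop("nucleus ellipsoid does not cover any voxel; enlarge the shape")

    n <- if (length(spec$n_chromocenters) == 2)
      sample(spec$n_chromocenters[1]:spec$n_chromocenters[2], 1)
    else spec$n_chromocenters

    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    max_attempts <- 2000L * max(1L, n)
    attempts <- 0L
    while (length(radii) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place all chromocenters; spec appears infeasible")
      r <- runif(1, spec$cc_radius_range[1], spec$cc_radius_range[2])
      shrink <- a - r - spec$min_gap_envelope
      if (any(shrink <= 0)) next
      p <- runif(3, -shrink, shrink)
      if (sum((p / shrink)^2) > 1) next
      if (length(radii) > 0) {
        dists <- sqrt(colSums((t(centers) - p)^2))
        if (any(dists < radii + r + spec$min_gap_objects)) next
      }
      centers <- rbind(centers, p)
      radii <- c(radii, r)
    }

    lev <- spec$intensities
    raw <- array(lev[1], dim = shape)
    raw[mask == 1L] <- lev[2]
    truth <- array(0L, dim = shape)
    env_dist <- numeric(n)
    if (n > 0) for (k in seq_len(n)) {
      p <- centers[k, ]
      inside <- .ellipsoid_field(coords, p, rep(radii[k], 3)) <= 1
      raw[inside] <- lev[3]
      truth[inside] <- k
      rho <- sqrt(sum((p / a)^2))
      env_dist[k] <- if (rho > 0) (1 - rho) * sqrt(sum(p^2)) / rho - radii[k]
                     else min(a) - radii[k]
    }
    if (spec$texture_sd > 0) {
      raw <- raw + rnorm(length(raw), 0, spec$texture_sd)
      raw <- round(pmin(pmax(raw, 0), 255))
    }

    objects <- data.frame(
      label = seq_len(n),
      center_y = if (n > 0) centers[, 1] else numeric(0),
      center_x = if (n > 0) centers[, 2] else numeric(0),
      center_z = if (n > 0) centers[, 3] else numeric(0),
      radius = radii,
      true_volume = 4 / 3 * pi * radii^3,
      true_envelope_distance = env_dist
    )
    structure(list(raw = raw, mask = mask, truth = truth, cal = cal,
                   spec = spec, objects = objects),
              class = "ground_truth")
  })
}

#' Add salt-and-pepper noise
#'
#' Replaces exactly `round(fraction * n_voxels)` distinct voxels, sampled
#' without replacement over the whole image (background included), with
#' the intensity minimum or maximum, each with probability 1/2.
#' Deterministic for a given seed.
#'
#' @param raw 3D numeric array.
#' @param fraction Fraction of voxels to corrupt, in `[0, 1]`.
#' @param seed Integer seed.
#' @param lo,hi Replacement intensities (dtype extremes); default 0 and
#'   255 for 8-bit data.
#' @return Corrupted copy of `raw`.
#' @export
add_salt_pepper <- function(raw, fraction, seed, lo = 0, hi = 255) {
  .check_stack(raw, "raw")
  if (length(fraction) != 1 || !is.finite(fraction) ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be a single value in [0, 1]")
  k <- round(fraction * length(raw))
  if (k == 0) return(raw)
  .with_seed(seed, {
    idx <- sample.int(length(raw), k)
    salt <- runif(k) < 0.5
    raw[idx] <- ifelse(salt, hi, lo)
    raw
  })
}

#' Voxel-overlap score of a segmentation against ground truth
#'
#' Both stacks are binarized (any nonzero label = foreground) and
#' compared voxel-wise, normalized by the truth foreground count:
#' `tp = |pred & truth| / |truth|`, `fn = |truth \ pred| / |truth|`,
#' `fp = |pred \ truth| / |truth|`. By construction `tp + fn = 1`
#' exactly; `fp` may exceed 1 if the prediction spills far outside the
#' truth.
#'
#' @param pred Predicted label (or binary) 3D array.
#' @param truth Ground-truth label (or binary) 3D array, same shape,
#'   nonempty foreground.
#' @return List with `tp_fraction`, `fn_fraction`, `fp_fraction`.
#' @export
overlap_stats <- function(pred, truth) {
  .check_pair(pred, truth, "pred", "truth")
  p <- pred != 0
  t <- truth != 0
  nt <- sum(t)
  if (nt == 0) stop("truth has no foreground voxels")
  tp <- sum(p & t)
  list(tp_fraction = tp / nt,
       fn_fraction = (nt - tp) / nt,
       fp_fraction = sum(p & !t) / nt)
}

# fixed arithmetic for reproducible child seeds (kept below 2^31)
.child_seed <- function(master, i, j = 0L) {
  as.integer((as.double(master) * 100003 + i * 7919 + j * 131) %% 2147483629)
}

#' Noise-robustness experiment on synthetic phantoms
#'
#' For each of `n_phantoms` seeded phantoms, segments the noiseless image
#' and each salt-and-pepper corrupted version, scores voxel overlap and
#' records the morphometric read-outs (object count, mean object volume,
#' mean border distance to the envelope). With `reference = "truth"`
#' every segmentation is scored against the planted chromocenters; with
#' `reference = "noiseless"` the noisy segmentations are scored against
#' the segmentation of the noiseless image instead (the noiseless row is
#' always scored against truth).
#'
#' @param n_phantoms Number of phantoms (>= 1).
#' @param noise_levels Salt-and-pepper fractions; default
#'   `c(0.05, 0.10, 0.25, 0.50, 0.75)`.
#' @param spec A [phantom_spec()] template; its seed is replaced by a
#'   per-phantom child seed derived from `seed`.
#' @param params A [seg_params()] object used for every image.
#' @param seed Master seed; child seeds for phantoms and noise draws are
#'   derived by fixed arithmetic so subsets are reproducible.
#' @param reference `"truth"` or `"noiseless"` (see above).
#' @return data.frame with one row per processed image
#'   (`n_phantoms * (1 + length(noise_levels))` rows): phantom index,
#'   noise level (0 = noiseless), overlap fractions, object counts and
#'   morphometrics.
#' @export
run_noise_experiment <- function(n_phantoms, noise_levels = c(0.05, 0.10, 0.25,
                                                              0.50, 0.75),
                                 spec = phantom_spec(), params = seg_params(),
                                 seed = 1,
                                 reference = c("truth", "noiseless")) {
  stopifnot(n_phantoms >= 1, all(noise_levels > 0), all(noise_levels <= 1))
  reference <- match.arg(reference)
  rows <- vector("list", n_phantoms * (1 + length(noise_levels)))
  ri <- 0L
  for (i in seq_len(n_phantoms)) {
    sp <- spec
    sp$seed <- .child_seed(seed, i)
    gt <- generate_phantom(sp)
    ref_labels <- gt$truth
    for (j in seq_along(c(0, noise_levels))) {
      level <- c(0, noise_levels)[j]
      img <- if (level > 0)
        add_salt_pepper(gt$raw, level, seed = .child_seed(seed, i, j))
      else gt$raw
      seg <- segment_nucleus(img, gt$mask, gt$cal, params)
      if (level == 0 && reference == "noiseless") ref_labels <- seg$labels
      score_ref <- if (level == 0) gt$truth else ref_labels
      ov <- overlap_stats(seg$labels, score_ref)
      tab <- summarize_nucleus(seg$labels, gt$mask, gt$cal,
                               nucleus_id = sprintf("phantom_%04d", i),
                               provenance = seg)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        phantom = i, phantom_seed = sp$seed, noise_level = level,
        n_true = nrow(gt$objects),
        n_objects = seg$n_objects,
        tp_fraction = ov$tp_fraction, fn_fraction = ov$fn_fraction,
        fp_fraction = ov$fp_fraction,
        mean_object_volume = tab$summary$mean_object_volume,
        mean_border_distance = tab$summary$mean_border_distance,
        threshold = seg$threshold$t
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
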