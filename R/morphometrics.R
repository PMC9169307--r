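#' Calibrated nucleus volume
#'
#' @param mask Binary 3D array of the nucleus (nonzero = foreground).
#' @param cal A [calibration()] object.
#' @return Foreground voxel count times the voxel volume, in um^3.
#' @export
nucleus_volume <- function(mask, cal) {
  .check_stack(mask, "mask")
  m <- .as_binary_mask(mask)
  sum(m) * voxel_volume(cal)
}

#' Distance map to the nuclear envelope
#'
#' Euclidean distance transform of the nucleus mask with anisotropic
#' voxel spacing `(dy, dx, dz)`: each in-mask voxel carries its distance
#' in um to the nearest voxel outside the mask. The image boundary counts
#' as background (the mask is padded with a one-voxel background shell
#' before the transform), so a mask that touches the image edge still
#' gets finite distances. Background voxels are 0.
#'
#' @param mask Binary 3D array, nonempty.
#' @param cal A [calibration()] object.
#' @return 3D numeric array of distances in um.
#' @export
envelope_distance_map <- function(mask, cal) {
  d <- .check_stack(mask, "mask")
  m <- .as_binary_mask(mask)
  stopifnot(inherits(cal, "calibration"))
  dp <- d + 2L
  padded <- array(0L, dim = dp)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  dist <- cpp_edt(padded, as.integer(dp), c(cal$dy, cal$dx, cal$dz))
  dist <- array(dist, dim = dp)
  dist[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Border voxels of every object at once: a foreground voxel is border if
# any 6-neighbor carries a different label (background and the image
# boundary both count as different). One shifted comparison per face.
.border_mask_all <- function(labeled) {
  d <- dim(labeled)
  border <- array(FALSE, dim = d)
  fg <- labeled > 0L
  for (axis in 1:3) for (by in c(1L, -1L)) {
    nb <- array(-1L, dim = d)  # out-of-bounds sentinel, never a label
    if (d[axis] > 1L) {
      idx_to <- lapply(d, seq_len)
      idx_from <- idx_to
      n <- d[axis]
      if (by == 1L) { idx_to[[axis]] <- 2:n; idx_from[[axis]] <- 1:(n - 1) }
      else          { idx_to[[axis]] <- 1:(n - 1); idx_from[[axis]] <- 2:n }
      nb[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
        labeled[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    }
    border <- border | (fg & (nb != labeled))
  }
  border
}

# Minimum envelope distance per label over that label's border voxels.
.border_distances <- function(labeled, dmap, n) {
  border <- .border_mask_all(labeled)
  labs <- factor(labeled[border], levels = seq_len(n))
  as.numeric(tapply(dmap[border], labs, min))
}

#' Distance from an object's border to the nuclear envelope
#'
#' Minimum of the envelope distance map over the object's border voxels.
#' A border voxel is an object voxel with at least one 6-neighbor not in
#' the object; a single-voxel object is its own border. This measures how
#' close a chromocenter surface comes to the nuclear periphery.
#'
#' @param labeled Integer label array from [label_components()].
#' @param label Label of the object of interest (>= 1).
#' @param dmap Distance map from [envelope_distance_map()], same shape.
#' @return Distance in um (nonnegative scalar).
#' @export
object_border_distance <- function(labeled, label, dmap) {
  .check_pair(labeled, dmap, "labeled", "dmap")
  if (!any(labeled == label))
    stop(sprintf("label %s not present in the label stack", label))
  border <- .border_mask_all(array(as.integer(labeled == label),
                                   dim = dim(labeled)))
  min(dmap[border])
}

#' Per-object and per-nucleus morphometrics
#'
#' Builds one record per labeled object (voxel count, calibrated volume,
#' barycenter in um, border distance to the nuclear envelope) and a
#' one-row summary for the nucleus (volume, object count, mean/total
#' object volume, mean border distance, plus segmentation provenance).
#' Objects are ordered by label; with zero objects the summary's mean
#' fields are `NA`.
#'
#' @param labeled Integer label array.
#' @param mask Binary 3D nucleus mask, same shape.
#' @param cal A [calibration()] object.
#' @param nucleus_id Identifier recorded in both tables.
#' @param provenance Optional `"nucleus_segmentation"` result; its
#'   threshold and effective parameters are copied into the summary.
#' @return List with `summary` (1-row data.frame) and `objects`
#'   (data.frame, one row per object).
#' @export
summarize_nucleus <- function(labeled, mask, cal, nucleus_id = "nucleus",
                              provenance = NULL) {
  d <- .check_pair(labeled, mask, "labeled", "mask")
  stopifnot(inherits(cal, "calibration"))
  vv <- voxel_volume(cal)
  nuc_vol <- nucleus_volume(mask, cal)
  n <- n_objects(labeled)

  if (n > 0) {
    dmap <- envelope_distance_map(mask, cal)
    idx <- which(labeled > 0L, arr.ind = TRUE)
    labs <- factor(labeled[labeled > 0L], levels = seq_len(n))
    counts <- tabulate(labeled[labeled > 0L], nbins = n)
    # barycenters: 0-based voxel indices scaled by the pitch, order (z,y,x)
    bz <- tapply((idx[, 3] - 1) * cal$dz, labs, mean)
    by <- tapply((idx[, 1] - 1) * cal$dy, labs, mean)
    bx <- tapply((idx[, 2] - 1) * cal$dx, labs, mean)
    bdist <- .border_distances(labeled, dmap, n)
    objects <- data.frame(
      nucleus_id = nucleus_id,
      label = seq_len(n),
      voxel_count = counts,
      volume = counts * vv,
      barycenter_z = as.numeric(bz),
      barycenter_y = as.numeric(by),
      barycenter_x = as.numeric(bx),
      border_distance_to_envelope = bdist,
      stringsAsFactors = FALSE
    )
  } else {
    objects <- data.frame(
      nucleus_id = character(0), label = integer(0), voxel_count = integer(0),
      volume = numeric(0), barycenter_z = numeric(0), barycenter_y = numeric(0),
      barycenter_x = numeric(0), border_distance_to_envelope = numeric(0),
      stringsAsFactors = FALSE
    )
  }

  summary <- data.frame(
    nucleus_id = nucleus_id,
    nucleus_volume = nuc_vol,
    n_objects = n,
    mean_object_volume = if (n > 0) mean(objects$volume) else NA_real_,
    total_object_volume = if (n > 0) sum(objects$volume) else 0,
    mean_border_distance = if (n > 0) mean(objects$border_distance_to_envelope)
                           else NA_real_,
    threshold_used = if (!is.null(provenance)) provenance$threshold$t else NA_real_,
    s_eff = if (!is.null(provenance)) provenance$params_eff$s else NA_integer_,
    f_eff = if (!is.null(provenance)) provenance$params_eff$f else NA_real_,
    stringsAsFactors = FALSE
  )
  list(summary = summary, objects = objects)
}

#' Write the per-nucleus and per-object tables
#'
#' Tab-delimited UTF-8 tables with a header row and `NA` for missing
#' values: `NucAndCcParameters3D.tab` (one row per nucleus) and
#' `CcParameters.tab` (one row per detected object).
#'
#' @param summaries data.frame of per-nucleus rows (as from
#'   [summarize_nucleus()], row-bound).
#' @param objects data.frame of per-object rows.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_result_tables <- function(summaries, objects, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "NucAndCcParameters3D.tab")
  f2 <- file.path(dir, "CcParameters.tab")
  write.table(summaries, f1, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  write.table(objects, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(c(f1, f2))
}
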