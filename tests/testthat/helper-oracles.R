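# Independent reference implementations used to validate the compiled
# kernels on small inputs. Deliberately naive: nested loops, exhaustive
# searches, queue-based flood fill.

# masked local-contrast enhancement, seven nested loops
oracle_enhance <- function(raw, mask, s) {
  d <- dim(raw)
  out <- array(0, dim = d)
  for (z in 1:d[3]) for (x in 1:d[2]) for (y in 1:d[1]) {
    if (mask[y, x, z] == 0) next
    acc <- 0
    for (dz in -s:s) for (dx in -s:s) for (dy in -s:s) {
      if (dy == 0 && dx == 0 && dz == 0) next
      yy <- y + dy; xx <- x + dx; zz <- z + dz
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
        next
      if (mask[yy, xx, zz] == 0) next
      acc <- acc + raw[y, x, z] - raw[yy, xx, zz]
    }
    out[y, x, z] <- acc / s
  }
  out
}

# neighbor offsets for a connectivity
oracle_offsets <- function(connectivity) {
  off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  ord <- abs(off$dy) + abs(off$dx) + abs(off$dz)
  keep <- ord > 0 & switch(as.character(connectivity),
                           "6" = ord <= 1, "18" = ord <= 2, "26" = ord <= 3)
  off[keep, , drop = FALSE]
}

# queue-based flood fill from one seed; returns logical array of the
# component containing the seed, restricted to foreground
oracle_flood <- function(binary, seed_idx, connectivity) {
  d <- dim(binary)
  off <- oracle_offsets(connectivity)
  visited <- array(FALSE, dim = d)
  queue <- list(seed_idx)
  visited[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(off))) {
      yy <- cur[1] + off$dy[k]; xx <- cur[2] + off$dx[k]; zz <- cur[3] + off$dz[k]
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
        next
      if (binary[yy, xx, zz] != 0 && !visited[yy, xx, zz]) {
        visited[yy, xx, zz] <- TRUE
        queue <- c(queue, list(c(yy, xx, zz)))
      }
    }
  }
  visited
}

# exhaustive anisotropic nearest-background distance; the image boundary
# counts as background (one-voxel shell)
oracle_envelope_distance <- function(mask, cal) {
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(0L, dim = dp)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  bg <- which(padded == 0L, arr.ind = TRUE)
  out <- array(0, dim = d)
  for (z in 1:d[3]) for (x in 1:d[2]) for (y in 1:d[1]) {
    if (mask[y, x, z] == 0) next
    dy <- (bg[, 1] - (y + 1)) * cal$dy
    dx <- (bg[, 2] - (x + 1)) * cal$dx
    dz <- (bg[, 3] - (z + 1)) * cal$dz
    out[y, x, z] <- sqrt(min(dy^2 + dx^2 + dz^2))
  }
  out
}

# random raw/mask pair on a small grid; mask is a random blob plus noise
random_stack_pair <- function(dims, mask_prob = 0.6) {
  raw <- array(runif(prod(dims), 0, 255), dim = dims)
  mask <- array(as.integer(runif(prod(dims)) < mask_prob), dim = dims)
  if (!any(mask == 1L)) mask[1, 1, 1] <- 1L
  list(raw = raw, mask = mask)
}

# spherical mask of radius R um with a concentric spherical object of
# radius r um, isotropic calibration
sphere_in_sphere <- function(R, r, pitch) {
  n <- 2L * ceiling(R / pitch) + 5L
  cal <- calibration(pitch, pitch, pitch)
  ctr <- (n + 1) / 2
  g <- seq_len(n)
  d2 <- outer(outer((g - ctr)^2, (g - ctr)^2, "+"), (g - ctr)^2, "+") * pitch^2
  mask <- array(as.integer(d2 <= R^2), dim = c(n, n, n))
  obj <- array(as.integer(d2 <= r^2), dim = c(n, n, n))
  list(mask = mask, obj = obj, cal = cal)
}

# match detected objects to planted ones by maximal voxel overlap and
# return per-matched-object relative volume errors
match_volume_errors <- function(pred, truth, cal) {
  vv <- voxel_volume(cal)
  nt <- n_objects(truth)
  errs <- rep(NA_real_, nt)
  for (k in seq_len(nt)) {
    tv <- truth == k
    labs <- pred[tv]
    labs <- labs[labs > 0]
    if (length(labs) == 0) next
    best <- as.integer(names(which.max(table(labs))))
    pred_vol <- sum(pred == best) * vv
    true_vol <- sum(tv) * vv
    errs[k] <- abs(pred_vol - true_vol) / true_vol
  }
  errs
}
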