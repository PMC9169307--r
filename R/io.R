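# TIFF stack I/O. The `tiff` package exposes resolution tags and the
# ImageJ-style description on read but cannot write them, so label stacks
# written by this package carry their calibration in a plain-text sidecar
# file "<stack>.calibration.tsv" which read_stack() also understands.

.sidecar_path <- function(path) paste0(path, ".calibration.tsv")

.parse_imagej_description <- function(desc) {
  # ImageJ writes e.g. "ImageJ=1.53\nspacing=0.2\nunit=micron"
  out <- list(spacing = NA_real_, unit = NA_character_)
  if (is.null(desc) || !nzchar(desc)) return(out)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  for (p in kv) {
    if (length(p) != 2) next
    if (p[1] == "spacing") out$spacing <- suppressWarnings(as.numeric(p[2]))
    if (p[1] == "unit") out$unit <- p[2]
  }
  out
}

.unit_to_um <- function(unit) {
  switch(tolower(unit %||% ""),
         "micron" = 1, "um" = 1, "µm" = 1, "micrometer" = 1,
         "mm" = 1000, "cm" = 10000, "inch" = 25400, NA_real_)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

.cal_from_metadata <- function(first_page, path) {
  xres <- attr(first_page, "x.resolution")
  yres <- attr(first_page, "y.resolution")
  runit <- attr(first_page, "resolution.unit")
  desc <- .parse_imagej_description(attr(first_page, "description"))
  scale <- .unit_to_um(runit %||% desc$unit %||% "micron")
  dx <- dy <- dz <- NA_real_
  if (!is.na(scale)) {
    if (!is.null(xres) && is.finite(xres) && xres > 0) dx <- scale / xres
    if (!is.null(yres) && is.finite(yres) && yres > 0) dy <- scale / yres
  }
  if (is.finite(desc$spacing) && desc$spacing > 0) dz <- desc$spacing
  side <- .sidecar_path(path)
  if (file.exists(side)) {
    sc <- read.table(side, header = TRUE, sep = "\t")
    if (all(c("dx", "dy", "dz") %in% names(sc)))
      return(calibration(sc$dx[1], sc$dy[1], sc$dz[1]))
  }
  if (all(is.finite(c(dx, dy, dz)))) return(calibration(dx, dy, dz))
  NULL
}

#' Read a multi-page grayscale TIFF stack
#'
#' Pages are stacked along z giving a numeric array of dim (ny, nx, nz)
#' with intensities rescaled back to integer counts (`tiff` reads samples
#' as fractions of the dtype maximum). Calibration is taken from, in
#' order: a plain-text sidecar `<path>.calibration.tsv` (written by
#' [write_stack()]), TIFF x/y resolution tags plus the ImageJ `spacing`
#' field, the `cal` override, or `(1, 1, 1)` um with a warning.
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param cal Optional [calibration()] used when the file has no
#'   calibration metadata.
#' @return List with `voxels` (numeric array, integer counts), `cal`
#'   (a `"calibration"`), and `bits` (8, 16 or 32).
#' @export
read_stack <- function(path, cal = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop(sprintf("not a grayscale stack: %s", path))
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16
  arr <- simplify2array(lapply(pages, function(p) round(p * (2^bits - 1))))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  found <- .cal_from_metadata(pages[[1]], path)
  if (is.null(found)) {
    if (!is.null(cal)) {
      stopifnot(inherits(cal, "calibration"))
      found <- cal
    } else {
      warning(sprintf("no calibration metadata in %s; assuming 1x1x1 um", path))
      found <- calibration(1, 1, 1)
    }
  }
  list(voxels = arr, cal = found, bits = as.integer(bits))
}

#' Write a 3D stack as a multi-page grayscale TIFF
#'
#' Values must be nonnegative integers representable at the requested bit
#' depth. Calibration is recorded in a plain-text sidecar
#' `<path>.calibration.tsv` so that a later [read_stack()] recovers it.
#'
#' @param voxels 3D numeric/integer array, dim (ny, nx, nz).
#' @param path Output file path.
#' @param cal A [calibration()] object.
#' @param bits Bits per sample: 8, 16 or 32.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(voxels, path, cal = calibration(), bits = 16) {
  d <- .check_stack(voxels, "voxels")
  maxv <- 2^bits - 1
  if (min(voxels) < 0 || max(voxels) > maxv)
    stop(sprintf("values must lie in [0, %d] for %d-bit output", maxv, bits))
  pages <- lapply(seq_len(d[3]), function(z) voxels[, , z] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  write.table(data.frame(dx = cal$dx, dy = cal$dy, dz = cal$dz),
              .sidecar_path(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a label stack as a 16-bit TIFF
#'
#' @param labels Integer label array (0 background, 1..n objects); at most
#'   65535 labels.
#' @param path Output file path.
#' @param cal A [calibration()] object, recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_label_stack <- function(labels, path, cal = calibration()) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be written as 16-bit")
  write_stack(labels, path, cal = cal, bits = 16)
}

#' Pair raw and mask files of a dataset
#'
#' Raw stacks and nucleus masks are matched by identical base filename
#' (extension-insensitive: `.tif`/`.tiff`). Unmatched files on either side
#' are reported, not fatal; an empty intersection is an error.
#'
#' @param raw_dir Directory of raw grayscale stacks.
#' @param mask_dir Directory of binary nucleus masks.
#' @return List with `entries` (data.frame: `nucleus_id`, `raw_path`,
#'   `mask_path`) and `unmatched` (character vector of paths).
#' @export
pair_inputs <- function(raw_dir, mask_dir) {
  if (!dir.exists(raw_dir)) stop(sprintf("raw directory not found: %s", raw_dir))
  if (!dir.exists(mask_dir)) stop(sprintf("mask directory not found: %s", mask_dir))
  list_tiffs <- function(d) {
    f <- list.files(d, pattern = "\\.tiff?$", ignore.case = TRUE)
    stats::setNames(file.path(d, f), sub("\\.tiff?$", "", f, ignore.case = TRUE))
  }
  raws <- list_tiffs(raw_dir)
  masks <- list_tiffs(mask_dir)
  ids <- sort(intersect(names(raws), names(masks)))
  if (length(ids) == 0) stop("no raw/mask file pairs share a base filename")
  unmatched <- c(unname(raws[setdiff(names(raws), ids)]),
                 unname(masks[setdiff(names(masks), ids)]))
  list(entries = data.frame(nucleus_id = ids,
                            raw_path = unname(raws[ids]),
                            mask_path = unname(masks[ids]),
                            stringsAsFactors = FALSE),
       unmatched = unmatched)
}

#' Batch configuration
#'
#' @param params A [seg_params()] object applied to every nucleus.
#' @param cal Optional [calibration()] override used when a file carries
#'   no calibration metadata.
#' @param out_dir Output directory for label stacks, tables and the log.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(params = seg_params(), cal = NULL, out_dir = ".") {
  stopifnot(inherits(params, "seg_params"))
  if (!is.null(cal)) stopifnot(inherits(cal, "calibration"))
  structure(list(params = params, cal = cal, out_dir = out_dir),
            class = "run_config")
}

#' Run segmentation and morphometry over a paired dataset
#'
#' Processes every manifest entry independently: reads the raw/mask pair,
#' segments, summarizes, and writes a 16-bit label TIFF per nucleus plus
#' the two result tables (`NucAndCcParameters3D.tab`, `CcParameters.tab`)
#' and a plain-text log recording `s_eff`, `f_eff`, the threshold and the
#' object count per nucleus. A failing nucleus (e.g. raw/mask shape
#' mismatch) is skipped and logged; it does not abort the batch.
#'
#' @param manifest Result of [pair_inputs()], or a compatible list.
#' @param config A [run_config()] object.
#' @return Invisibly, a list with `summaries`, `objects` (data.frames),
#'   `failed` (character vector of nucleus ids) and `log_path`.
#' @export
run_batch <- function(manifest, config = run_config()) {
  entries <- manifest$entries
  if (is.null(entries) || nrow(entries) == 0) stop("empty manifest")
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  label_dir <- file.path(out_dir, "labels")
  if (!dir.exists(label_dir)) dir.create(label_dir)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)

  # deterministic order regardless of manifest ordering
  entries <- entries[order(entries$nucleus_id), , drop = FALSE]

  summaries <- list(); objects <- list(); failed <- character(0)
  for (i in seq_len(nrow(entries))) {
    id <- entries$nucleus_id[i]
    res <- tryCatch({
      raw <- read_stack(entries$raw_path[i], cal = config$cal)
      msk <- read_stack(entries$mask_path[i], cal = config$cal)
      if (!identical(dim(raw$voxels), dim(msk$voxels)))
        stop("raw and mask dimensions differ")
      seg <- segment_nucleus(raw$voxels, msk$voxels, raw$cal, config$params)
      tab <- summarize_nucleus(seg$labels, msk$voxels, raw$cal,
                               nucleus_id = id, provenance = seg)
      write_label_stack(seg$labels, file.path(label_dir, paste0(id, ".tif")),
                        cal = raw$cal)
      log_lines <- c(log_lines, sprintf(
        "OK %s s_eff=%d f_eff=%g t=%.6g n_objects=%d",
        id, seg$params_eff$s, seg$params_eff$f, seg$threshold$t, seg$n_objects))
      tab
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf("FAIL %s: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, id)
    else { summaries[[id]] <- res$summary; objects[[id]] <- res$objects }
  }

  empty <- summarize_nucleus(array(0L, c(1, 1, 1)), array(1L, c(1, 1, 1)),
                             calibration())
  all_summaries <- if (length(summaries))
    do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  else empty$summary[0, ]
  all_objects <- if (length(objects))
    do.call(rbind, c(objects, list(make.row.names = FALSE)))
  else empty$objects
  write_result_tables(all_summaries, all_objects, out_dir)
  writeLines(log_lines, log_path)
  invisible(list(summaries = all_summaries, objects = all_objects,
                 failed = failed, log_path = log_path))
}
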