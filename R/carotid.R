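#' Dynamic PET image container
#'
#' @param voxels 4-D numeric array (x, y, z, frame), kBq/mL.
#' @param voxel_size Numeric length-3 vector, mm per axis.
#' @param schedule A [frame_schedule()] matching the 4th dimension.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, voxel_size, schedule) {
  d <- dim(voxels)
  if (length(d) != 4L) stop("voxels must be a 4-D array (x, y, z, frame)")
  if (d[4] != n_frames(schedule))
    stop("4th dimension does not match the frame schedule")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("dynamic_image: %dx%dx%d voxels x %d frames, %.1fx%.1fx%.1f mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Interior search volume for carotid segmentation
#'
#' Reconstructed edge slices and the transaxial periphery carry noise and
#' artefacts; the carotid search is restricted to the interior obtained by
#' trimming `xy_trim` voxels from each side in x and y and `z_trim` slices
#' from each end in z.
#'
#' @param img A [dynamic_image()] (or a length-3 spatial dim vector).
#' @param xy_trim Voxels trimmed per side in x and y (default 20).
#' @param z_trim Slices trimmed per end in z (default 5).
#' @return A 3-D logical mask, TRUE in the interior.
#' @export
trim_search_volume <- function(img, xy_trim = 20, z_trim = 5) {
  d <- if (inherits(img, "dynamic_image")) dim(img$voxels)[1:3] else img
  if (d[1] <= 2 * xy_trim || d[2] <= 2 * xy_trim || d[3] <= 2 * z_trim)
    stop("trim exceeds image extent")
  m <- array(FALSE, dim = d)
  m[(xy_trim + 1):(d[1] - xy_trim),
    (xy_trim + 1):(d[2] - xy_trim),
    (z_trim + 1):(d[3] - z_trim)] <- TRUE
  m
}

#' Select the thresholding frame from the grey-matter intensity graph
#'
#' Builds the frame-wise graph of summed grey-matter intensity and returns
#' the first frame whose sum is strictly larger than 25% (by default) of the
#' graph maximum — an early-bolus frame where the carotids are bright against
#' tissue.
#'
#' @param img A [dynamic_image()].
#' @param gm_mask 3-D logical grey-matter mask.
#' @param fraction Threshold fraction of the graph maximum (default 0.25).
#' @return Frame index (1-based).
#' @export
select_threshold_frame <- function(img, gm_mask, fraction = 0.25) {
  if (!any(gm_mask)) stop("empty grey-matter mask")
  nf <- dim(img$voxels)[4]
  sums <- vapply(seq_len(nf),
                 function(f) sum(img$voxels[, , , f][gm_mask]), numeric(1))
  m <- max(sums)
  if (m <= 0) stop("all-zero image: threshold graph has no maximum")
  which(sums > fraction * m)[1]
}

#' Extract the three carotid VOIs by top-intensity thresholding
#'
#' Within the search volume, the 10, 100 and 1000 highest-intensity voxels of
#' the chosen frame form three volumes of interest with increasing partial
#' volume dilution. Intensity ties at a cutoff are broken by ascending linear
#' voxel index, making the selection deterministic. With distinct intensities
#' the VOIs are nested by construction.
#'
#' @param img A [dynamic_image()].
#' @param frame Frame index used for thresholding.
#' @param search 3-D logical search mask (>= max(sizes) TRUE voxels).
#' @param sizes Voxel counts of the VOIs (default `c(10, 100, 1000)`).
#' @return Named list of 3-D logical masks (`voi10`, `voi100`, `voi1000` for
#'   the default sizes).
#' @export
extract_carotid_vois <- function(img, frame, search, sizes = c(10, 100, 1000)) {
  idx <- which(search)
  if (length(idx) < max(sizes))
    stop("search region smaller than the largest VOI")
  v <- img$voxels[, , , frame][idx]
  ord <- idx[order(-v, idx)]
  out <- lapply(sizes, function(k) {
    m <- array(FALSE, dim = dim(search))
    m[ord[seq_len(k)]] <- TRUE
    m
  })
  names(out) <- paste0("voi", sizes)
  out
}

#' Median time-activity curve over a VOI
#'
#' The per-frame median over the VOI voxels; the median (even-count: mean of
#' the two central values) is robust to the extreme values that top-intensity
#' voxel sets contain.
#'
#' @param img A [dynamic_image()].
#' @param voi 3-D logical mask, non-empty.
#' @return A frame-based `tac` at frame midpoints.
#' @export
extract_idif <- function(img, voi) {
  if (!any(voi)) stop("empty VOI")
  nf <- dim(img$voxels)[4]
  v <- vapply(seq_len(nf),
              function(f) stats::median(img$voxels[, , , f][voi]), numeric(1))
  new_tac(frame_midpoints(img$schedule), v, grid_kind = "frame")
}

#' Mean time-activity curve over a mask
#'
#' @param img A [dynamic_image()].
#' @param mask 3-D logical mask, non-empty.
#' @return A frame-based `tac`.
#' @export
extract_mean_tac <- function(img, mask) {
  if (!any(mask)) stop("empty mask")
  nf <- dim(img$voxels)[4]
  v <- vapply(seq_len(nf),
              function(f) mean(img$voxels[, , , f][mask]), numeric(1))
  new_tac(frame_midpoints(img$schedule), v, grid_kind = "frame")
}

#' Full image-derived input function pipeline
#'
#' Trims the search volume, picks the thresholding frame from the
#' grey-matter intensity graph, extracts the 10/100/1000-voxel carotid VOIs,
#' takes per-frame median curves, interpolates them to a uniform 1-s grid and
#' windows them to the analysis interval.
#'
#' @param img A [dynamic_image()].
#' @param gm_mask 3-D logical grey-matter mask.
#' @param config A configuration list, see [default_config()].
#' @return An object of class `idif_set`: `idif10`, `idif100`, `idif1000`
#'   (uniform 1-s `tac`s on \[0, window\]), `threshold_frame`, and `vois`.
#' @export
run_idif_pipeline <- function(img, gm_mask, config = default_config()) {
  search <- trim_search_volume(img, config$xy_trim, config$z_trim)
  fr <- select_threshold_frame(img, gm_mask, config$threshold_fraction)
  vois <- extract_carotid_vois(img, fr, search, config$voi_sizes)
  curves <- lapply(vois, function(v)
    tac_window(resample_to_1s(extract_idif(img, v), img$schedule),
               config$window_s))
  structure(list(idif10 = curves[[1]], idif100 = curves[[2]],
                 idif1000 = curves[[3]], threshold_frame = fr, vois = vois),
            class = "idif_set")
}

#' @export
print.idif_set <- function(x, ...) {
  cat(sprintf(paste0("idif_set: threshold frame %d; peaks %.3g / %.3g / ",
                     "%.3g kBq/mL (10/100/1000 voxels)\n"),
              x$threshold_frame, max(x$idif10$value), max(x$idif100$value),
              max(x$idif1000$value)))
  invisible(x)
}
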