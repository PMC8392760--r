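#' Derive a reproducible substream seed
#'
#' All phantom randomness flows from one top-level seed; each stage draws
#' from a named substream so that regenerating any piece is deterministic.
#'
#' @param seed Integer top-level seed.
#' @param name Substream name.
#' @return An integer seed < 2^31.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) * 131))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw a phantom subject
#'
#' Ground-truth physiology for one simulated subject-scan: gamma-variate
#' bolus parameters with a recirculation tail, condition-dependent CBF
#' (baseline ~ Normal(0.45, 0.05), acetazolamide ~ Normal(0.60, 0.07)
#' mL/min/g, truncated above 0.2), k2 = CBF / 0.9 (partition coefficient
#' 0.9 mL/g), V_A = 0, a brain arrival delay (3 s shorter under
#' acetazolamide, emulating the increased blood velocity), a longer wrist
#' delay, wrist dispersion tau = 15 s, and a 15% larger brain-local bolus
#' area under acetazolamide while the wrist curve shape is unchanged.
#'
#' @param seed Integer seed; the draw is deterministic given it.
#' @param condition `"baseline"` or `"acz"`.
#' @return An object of class `phantom_subject`.
#' @export
sample_subject <- function(seed, condition = c("baseline", "acz")) {
  condition <- match.arg(condition)
  with_seed(seed, {
    cbf <- -1
    while (cbf <= 0.2)
      cbf <- if (condition == "baseline") stats::rnorm(1, 0.45, 0.05)
             else stats::rnorm(1, 0.60, 0.07)
    delay <- stats::runif(1, 6, 10) - if (condition == "acz") 3 else 0
    structure(list(
      amplitude = stats::runif(1, 40, 70),      # kBq/mL peak scale
      alpha = stats::runif(1, 2.5, 3.5),        # gamma-variate shape
      beta = stats::runif(1, 5, 8),             # gamma-variate scale, s
      recirc_frac = stats::runif(1, 0.08, 0.15),
      recirc_decay = stats::runif(1, 150, 250), # s
      cbf_true = cbf,
      k2_true = cbf / 0.9,
      va_true = 0,
      brain_delay = delay,
      wrist_delay = delay + stats::runif(1, 8, 14),
      wrist_tau = 15,
      detector_scale = stats::runif(1, 0.6, 1.8),
      area_boost = if (condition == "acz") 1.15 else 1,
      condition = condition, seed = seed),
      class = "phantom_subject")
  })
}

#' Generate a subject's arterial bolus curve
#'
#' Gamma-variate first pass plus an exponential recirculation tail:
#' b(u) = A (u/tp)^alpha exp(alpha (1 - u/tp)) +
#'        frac * A * (1 - exp(-u/60)) exp(-u/decay), u = t - delay,
#' zero before arrival. tp = alpha * beta is the peak time after arrival.
#'
#' @param subject A [sample_subject()].
#' @param t Time grid in seconds (default 0..600 at 1 s).
#' @param delay Arrival delay in seconds (default 0: the undelayed shape).
#' @param scale Amplitude scale factor.
#' @return A uniform `tac`.
#' @export
generate_aif <- function(subject, t = 0:600, delay = 0, scale = 1) {
  u <- pmax(t - delay, 0)
  tp <- subject$alpha * subject$beta
  A <- subject$amplitude * scale
  first <- A * (u / tp)^subject$alpha * exp(subject$alpha * (1 - u / tp))
  first[u == 0] <- 0
  tail <- subject$recirc_frac * A * (1 - exp(-u / 60)) *
    exp(-u / subject$recirc_decay)
  new_tac(t, first + tail, grid_kind = "uniform")
}

#' Brain-local arterial input function of a subject
#'
#' The bolus at the carotids: delayed by the brain arrival time and, under
#' acetazolamide, boosted in area by the subject's `area_boost`.
#'
#' @inheritParams generate_aif
#' @return A uniform `tac`.
#' @export
local_aif <- function(subject, t = 0:600) {
  generate_aif(subject, t, delay = subject$brain_delay,
               scale = subject$area_boost)
}

#' Phantom image geometry
#'
#' A compact digital head: two parallel carotid tubes running the full
#' z-extent and a grey-matter ellipsoid shell, mutually disjoint, on a
#' 44 x 44 x 22 grid of 2 mm voxels with a 5 mm FWHM Gaussian point-spread
#' function.
#'
#' @param shape Grid dimensions (voxels).
#' @param voxel_size mm per axis.
#' @param carotid_radius Tube radius in voxels.
#' @param psf_fwhm_mm PSF full width at half maximum, mm.
#' @return An object of class `phantom_geometry` with `carotid_mask` and
#'   `gm_mask` 3-D logical arrays.
#' @export
phantom_geometry <- function(shape = c(44, 44, 22), voxel_size = c(2, 2, 2),
                             carotid_radius = 2.2, psf_fwhm_mm = 5) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  xi <- slice.index(array(0, shape), 1)
  yi <- slice.index(array(0, shape), 2)
  zi <- slice.index(array(0, shape), 3)
  tube <- function(x0, y0)
    (xi - x0)^2 + (yi - y0)^2 <= carotid_radius^2
  carotid <- tube(cx - 6, cy - 8) | tube(cx + 6, cy - 8)
  ell <- ((xi - cx) / (nx * 0.36))^2 + ((yi - cy - 2) / (ny * 0.30))^2 +
    ((zi - cz) / (nz * 0.40))^2
  gm <- ell <= 1
  # keep GM clear of the carotids and their PSF skirt
  dil <- (xi - (cx - 6))^2 + (yi - (cy - 8))^2 <= (carotid_radius + 2.5)^2 |
    (xi - (cx + 6))^2 + (yi - (cy - 8))^2 <= (carotid_radius + 2.5)^2
  gm <- gm & !dil
  structure(list(shape = shape, voxel_size = voxel_size,
                 carotid_mask = carotid & !gm, gm_mask = gm,
                 psf_fwhm_mm = psf_fwhm_mm),
            class = "phantom_geometry")
}

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

shift_array <- function(a, s, axis) {
  # shift along `axis` by s voxels, zero-filling
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (s > 0) { idx_dst[[axis]] <- (s + 1):n; idx_src[[axis]] <- 1:(n - s) }
  else { idx_dst[[axis]] <- 1:(n + s); idx_src[[axis]] <- (1 - s):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Separable 3-D Gaussian blur (shift-and-add)
#'
#' Zero-padded separable convolution used as the scanner point-spread
#' function. Kernel per axis is normalised to unit sum.
#'
#' @param a 3-D array.
#' @param sigma_vox Gaussian sigma per axis, voxels (length 1 or 3).
#' @return Blurred array of the same shape.
#' @export
gauss_blur3d <- function(a, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (axis in 1:3) {
    k <- gauss_kernel1d(sigma_vox[axis])
    if (length(k) == 1) next
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim(a))
    for (j in seq_along(k))
      acc <- acc + k[j] * shift_array(a, j - r - 1L, axis)
    a <- acc
  }
  a
}

#' Render a dynamic phantom image
#'
#' Carotid voxels carry the brain-local arterial curve; grey-matter voxels
#' carry the one-tissue-compartment tissue curve driven by it with the
#' subject's true CBF. Frame values are frame-averages of the underlying
#' 1-s curves. Each frame is blurred with the Gaussian PSF (partial volume)
#' and Gaussian noise with variance noise_scale * signal / frame_duration is
#' added, approximating reconstructed-PET frame statistics (short early
#' frames are noisiest).
#'
#' @param subject A [sample_subject()].
#' @param geom A [phantom_geometry()].
#' @param schedule A [frame_schedule()].
#' @param noise_scale Noise variance scale (default 0.5; 0 = noiseless).
#' @param seed Integer seed for the noise.
#' @return List with `image` (a [dynamic_image()]) and `gm_mask`.
#' @export
render_dynamic_image <- function(subject, geom,
                                 schedule = default_frame_schedule(),
                                 noise_scale = 0.5, seed = 1) {
  la <- local_aif(subject, t = 0:total_duration(schedule))
  tis <- simulate_tissue(la, subject$cbf_true, subject$k2_true,
                         subject$va_true)
  a_frames <- rebin_to_schedule(la, schedule)$value
  t_frames <- rebin_to_schedule(tis, schedule)$value
  sigma <- geom$psf_fwhm_mm / 2.3548 / geom$voxel_size
  nf <- n_frames(schedule)
  vox <- array(0, c(geom$shape, nf))
  car <- geom$carotid_mask * 1.0
  gmv <- geom$gm_mask * 1.0
  with_seed(seed, {
    for (f in seq_len(nf)) {
      vol <- car * a_frames[f] + gmv * t_frames[f]
      if (geom$psf_fwhm_mm > 0) vol <- gauss_blur3d(vol, sigma)
      if (noise_scale > 0) {
        sd <- sqrt(noise_scale * pmax(vol, 0) / schedule$duration[f])
        vol <- vol + array(stats::rnorm(length(vol), 0, 1), dim(vol)) * sd
      }
      vox[, , , f] <- vol
    }
  })
  list(image = dynamic_image(vox, geom$voxel_size, schedule),
       gm_mask = geom$gm_mask)
}

#' Simulate the wrist blood measurement
#'
#' The continuously sampled wrist signal is a delayed, dispersed, noisy and
#' uncalibrated copy of the subject's bolus: the undelayed arterial shape is
#' shifted by the wrist delay, convolved with the mono-exponential
#' dispersion kernel (tau = 15 s), scaled by an arbitrary detector factor
#' and perturbed with Gaussian noise. The single calibration sample is the
#' true (unscaled, noise-free) concentration at t = 300 s. The wrist shape
#' carries no acetazolamide area boost — the wrist does not see the local
#' cerebrovascular change.
#'
#' @param subject A [sample_subject()].
#' @param noise_scale Relative noise level (0 = noiseless).
#' @param seed Integer seed.
#' @param t Time grid, seconds.
#' @return A [blood_measurement()]; attribute `"truth"` holds the
#'   noise-free wrist concentration curve.
#' @export
generate_wrist_measurement <- function(subject, noise_scale = 0.5, seed = 1,
                                       t = 0:600) {
  wr_true <- apply_dispersion(
    generate_aif(subject, t, delay = subject$wrist_delay, scale = 1),
    subject$wrist_tau)
  counts <- with_seed(seed, {
    sd <- noise_scale * 0.01 * max(wr_true$value)
    wr_true$value * subject$detector_scale +
      stats::rnorm(length(t), 0, sd)
  })
  meas <- blood_measurement(new_tac(t, counts, grid_kind = "uniform"),
                            cal_time = 300,
                            cal_value = wr_true$value[which(t == 300)])
  attr(meas, "truth") <- wr_true
  meas
}

#' Generate a paired ground-truthed phantom cohort
#'
#' Each subject receives a paired baseline and acetazolamide scan: a dynamic
#' image with carotid and grey-matter structures, the grey-matter mask, and
#' a wrist blood measurement. Ground truth (the subject draw and the local
#' arterial curve) is kept in a separate `truth` element that no pipeline
#' function reads — it exists only for validation.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param seed Top-level integer seed.
#' @param conditions Conditions to simulate per subject.
#' @param geom A [phantom_geometry()].
#' @param noise_scale Image/blood noise scale (default 0.5).
#' @param schedule Frame schedule.
#' @return An object of class `phantom_cohort`: a list of subjects, each a
#'   named list of scans (`baseline`, `acz`); every scan has `image`,
#'   `gm_mask`, `blood` and `truth`.
#' @export
generate_cohort <- function(n_subjects = 22, seed = 1,
                            conditions = c("baseline", "acz"),
                            geom = phantom_geometry(), noise_scale = 0.5,
                            schedule = default_frame_schedule()) {
  if (n_subjects < 3) stop("need >= 3 subjects")
  subjects <- lapply(seq_len(n_subjects), function(i) {
    scans <- lapply(conditions, function(cond) {
      sseed <- substream_seed(seed, paste0("subj", i, "-", cond))
      subj <- sample_subject(sseed, cond)
      img <- render_dynamic_image(subj, geom, schedule, noise_scale,
                                  seed = substream_seed(sseed, "image"))
      blood <- generate_wrist_measurement(subj, noise_scale,
                                          seed = substream_seed(sseed, "blood"))
      list(image = img$image, gm_mask = img$gm_mask, blood = blood,
           truth = list(subject = subj,
                        local_aif = local_aif(subj)))
    })
    names(scans) <- conditions
    scans
  })
  structure(list(subjects = subjects, seed = seed, geom = geom,
                 noise_scale = noise_scale),
            class = "phantom_cohort")
}

#' Configuration adapted to the phantom geometry
#'
#' The clinical trim defaults (20 voxels in-plane, 5 slices axially) assume
#' a full-size reconstruction grid; the phantom grid is 44 x 44 x 22, so its
#' search volume uses proportionally smaller trims.
#'
#' @return A configuration list, see [default_config()].
#' @export
phantom_config <- function() {
  cfg <- default_config()
  cfg$xy_trim <- 6
  cfg$z_trim <- 2
  cfg
}

#' Process one phantom scan into an evaluation record
#'
#' Runs the carotid IDIF pipeline on the image, extracts the windowed
#' grey-matter tissue curve, and recovers the arterial input function from
#' the wrist measurement (dispersion correction, calibration, delay
#' alignment to IDIF10). Reads nothing from the scan's `truth` element.
#'
#' @param scan One scan from a [generate_cohort()] cohort.
#' @param config Configuration list.
#' @return A record list with `idifs`, `aif`, `tissue`, `shift`.
#' @export
process_scan <- function(scan, config = phantom_config()) {
  idifs <- run_idif_pipeline(scan$image, scan$gm_mask, config)
  tissue <- tac_window(resample_to_1s(extract_mean_tac(scan$image,
                                                       scan$gm_mask),
                                      scan$image$schedule), config$window_s)
  rec <- recover_aif(scan$blood, idifs$idif10, tau = config$tau_s,
                     max_shift = config$max_shift_s,
                     window_end = config$window_s)
  list(idifs = idifs, aif = rec$aif, tissue = tissue, shift = rec$shift)
}

#' Process every scan of a cohort
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param config Configuration list.
#' @return List with `baseline` and `acz` lists of records (subject order).
#' @export
process_cohort <- function(cohort, config = phantom_config()) {
  conds <- names(cohort$subjects[[1]])
  out <- lapply(conds, function(cond)
    lapply(cohort$subjects, function(s) process_scan(s[[cond]], config)))
  names(out) <- conds
  out
}
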