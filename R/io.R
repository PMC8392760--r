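#' Default run configuration
#'
#' All pipeline constants in one place. The dispersion constant (15 s), the
#' analysis window (0-360 s), the VOI sizes (10/100/1000 voxels), the 25%
#' threshold-frame rule and the 20-voxel / 5-slice search trims are the
#' standard values for this acquisition protocol; the delay search range,
#' GP initialisation and fit bounds are package defaults. Every consumer
#' echoes the configuration into its output sidecar.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    tau_s = 15,
    max_shift_s = 30,
    window_s = 360,
    voi_sizes = c(10, 100, 1000),
    threshold_fraction = 0.25,
    xy_trim = 20,
    z_trim = 5,
    gp_init = NULL,
    fit_init = c(K1 = 0.5, k2 = 1.0, va = 0.05),
    fit_lower = c(0, 0, 0),
    fit_upper = c(5, 10, 1),
    noise_scale = 0.5,
    seed = 1)
}

#' Read and write time-activity curves as TSV
#'
#' Two columns: `time_s`, `activity_kBq_per_mL`.
#'
#' @param path File path.
#' @param tac A `tac` object.
#' @param grid_kind Grid kind to assign on read.
#' @return `read_tac_tsv` returns a `tac`; `write_tac_tsv` returns the path
#'   invisibly.
#' @export
read_tac_tsv <- function(path, grid_kind = "uniform") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_tac(d$time_s, d$activity_kBq_per_mL, grid_kind = grid_kind)
}

#' @rdname read_tac_tsv
#' @export
write_tac_tsv <- function(tac, path) {
  utils::write.table(
    data.frame(time_s = tac$t, activity_kBq_per_mL = tac$value),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 4-D dynamic PET image with its frame-schedule sidecar
#'
#' The NIfTI voxel grid is used as-is; the affine is consulted only for
#' voxel sizes. The JSON sidecar (same path with extension `.json`)
#' must list `frame_duration_s`; its length must match the 4th image
#' dimension.
#'
#' @param path Path to a 4-D NIfTI file.
#' @param sidecar Optional explicit sidecar path.
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  nii <- RNifti::readNifti(path)
  a <- as.array(nii)
  if (length(dim(a)) != 4L) stop("expected a 4-D NIfTI image")
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (!file.exists(sidecar)) stop("missing frame-schedule sidecar: ", sidecar)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sched <- frame_schedule(sc$frame_duration_s)
  if (n_frames(sched) != dim(a)[4])
    stop("sidecar frame count does not match the image")
  dynamic_image(a, RNifti::pixdim(nii)[1:3], sched)
}

#' @rdname read_dynamic_image
#' @param img A [dynamic_image()] to write.
#' @export
write_dynamic_image <- function(img, path) {
  nii <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nii) <- c(img$voxel_size, 1)
  RNifti::writeNifti(nii, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(list(frame_duration_s = img$schedule$duration),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read and write a 3-D mask as NIfTI
#'
#' @param path File path.
#' @param mask 3-D logical array.
#' @return `read_mask` returns a logical array.
#' @export
read_mask <- function(path) as.array(RNifti::readNifti(path)) > 0.5

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(mask * 1L), path)
  invisible(path)
}

#' Serialise / restore a trained MLIF model as JSON
#'
#' Hyperparameters, normalisation constants and training matrices are stored
#' as plain JSON arrays; the Cholesky factor is rebuilt on load.
#'
#' @param model A `gp_mlif` model.
#' @param path File path.
#' @return `read_gp_model` returns a `gp_mlif`.
#' @export
write_gp_model <- function(model, path) {
  jsonlite::write_json(list(
    ell = model$ell, sf2 = model$sf2, sn2 = model$sn2,
    norm = as.list(model$norm),
    X = model$X, Y = model$Y), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(j$X); Y <- as.matrix(j$Y)
  K <- matern52(cross_dist2(X, X), j$ell, j$sf2) +
    (j$sn2 + 1e-10 * j$sf2) * diag(nrow(X))
  L <- chol(K)
  structure(list(ell = j$ell, sf2 = j$sf2, sn2 = j$sn2,
                 norm = unlist(j$norm), X = X, Y = Y, L = L,
                 alpha = backsolve(L, forwardsolve(t(L), Y))),
            class = "gp_mlif")
}

#' Write a phantom cohort to disk
#'
#' Lays out one directory per scan with the NIfTI image + schedule sidecar,
#' grey-matter mask, blood TSV and calibration JSON; a top-level
#' `manifest.tsv` lists the pipeline inputs. Ground truth goes under a
#' separate `truth/` directory that the manifest never references, so the
#' pipeline cannot read it by construction.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    for (cond in names(cohort$subjects[[i]])) {
      scan <- cohort$subjects[[i]][[cond]]
      base <- sprintf("sub%02d_%s", i, cond)
      pet <- file.path(dir, paste0(base, "_pet.nii.gz"))
      gm <- file.path(dir, paste0(base, "_gm.nii.gz"))
      blood <- file.path(dir, paste0(base, "_blood.tsv"))
      cal <- file.path(dir, paste0(base, "_cal.json"))
      write_dynamic_image(scan$image, pet)
      write_mask(scan$gm_mask, gm)
      utils::write.table(
        data.frame(time_s = scan$blood$counts$t,
                   counts = scan$blood$counts$value),
        blood, sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(list(time_s = scan$blood$cal_time,
                                value_kBq_per_mL = scan$blood$cal_value),
                           cal, auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(
        list(condition = cond, seed = scan$truth$subject$seed,
             cbf_true = scan$truth$subject$cbf_true,
             k2_true = scan$truth$subject$k2_true,
             brain_delay = scan$truth$subject$brain_delay),
        file.path(dir, "truth", paste0(base, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = i, condition = cond, pet = pet, gm = gm,
                   blood = blood, cal = cal)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = cohort$seed,
                            noise_scale = cohort$noise_scale,
                            package_version =
                              as.character(utils::packageVersion("mlifpet"))),
                       file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.tsv`.
#' @return A list of scans (image, gm_mask, blood) grouped by subject and
#'   condition; ground truth is not read.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  subjects <- lapply(sort(unique(man$subject)), function(i) {
    rows <- man[man$subject == i, ]
    scans <- lapply(seq_len(nrow(rows)), function(r) {
      row <- rows[r, ]
      bl <- utils::read.table(row$blood, header = TRUE, sep = "\t")
      cal <- jsonlite::read_json(row$cal, simplifyVector = TRUE)
      list(image = read_dynamic_image(row$pet),
           gm_mask = read_mask(row$gm),
           blood = blood_measurement(
             new_tac(bl$time_s, bl$counts, grid_kind = "uniform"),
             cal$time_s, cal$value_kBq_per_mL))
    })
    names(scans) <- rows$condition
    scans
  })
  structure(list(subjects = subjects), class = "phantom_cohort")
}

parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    out[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

cli_log <- function(event, ...) {
  msg <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event,
              version = as.character(utils::packageVersion("mlifpet")), ...)
  cat(jsonlite::toJSON(msg, auto_unbox = TRUE), "\n")
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `extract-idif`, `blood-correct`, `train`,
#' `predict`, `fit-cbf`, `evaluate`. Invoked by the `inst/cli/mlifpet.R`
#' wrapper script; each emits a JSON-lines log with the configuration used.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit code (0 on success), invisibly.
#' @export
cli_main <- function(argv) {
  code <- tryCatch({
    if (length(argv) == 0L) stop("usage: mlifpet <subcommand> [--args]")
    cmd <- argv[1]
    opts <- parse_cli_args(argv[-1])
    num <- function(key, default) if (is.null(opts[[key]])) default
      else as.numeric(opts[[key]])
    switch(cmd,
      "simulate" = {
        co <- generate_cohort(n_subjects = num("n", 22),
                              seed = as.integer(num("seed", 1)),
                              noise_scale = num("noise_scale", 0.5))
        man <- write_cohort(co, opts$out)
        cli_log("simulate", n = num("n", 22), seed = num("seed", 1),
                manifest = man)
      },
      "extract-idif" = {
        cfg <- default_config()
        cfg$xy_trim <- num("xy_trim", cfg$xy_trim)
        cfg$z_trim <- num("z_trim", cfg$z_trim)
        img <- read_dynamic_image(opts$pet)
        idifs <- run_idif_pipeline(img, read_mask(opts$gm), cfg)
        utils::write.table(
          data.frame(time_s = idifs$idif10$t, idif10 = idifs$idif10$value,
                     idif100 = idifs$idif100$value,
                     idif1000 = idifs$idif1000$value),
          opts$out, sep = "\t", row.names = FALSE, quote = FALSE)
        jsonlite::write_json(
          list(threshold_frame = idifs$threshold_frame, config = cfg),
          paste0(opts$out, ".json"), auto_unbox = TRUE, digits = NA)
        cli_log("extract-idif", pet = opts$pet, out = opts$out,
                threshold_frame = idifs$threshold_frame)
      },
      "blood-correct" = {
        bl <- utils::read.table(opts$blood, header = TRUE, sep = "\t")
        cal <- jsonlite::read_json(opts$cal, simplifyVector = TRUE)
        meas <- blood_measurement(
          new_tac(bl$time_s, bl$counts, grid_kind = "uniform"),
          cal$time_s, cal$value_kBq_per_mL)
        idif <- utils::read.table(opts$idif, header = TRUE, sep = "\t")
        rec <- recover_aif(meas,
                           new_tac(idif$time_s, idif$idif10,
                                   grid_kind = "uniform"),
                           tau = num("tau", 15),
                           max_shift = num("max_shift", 30))
        write_tac_tsv(rec$aif, opts$out)
        cli_log("blood-correct", shift = rec$shift, tau = num("tau", 15),
                out = opts$out)
      },
      "train" = {
        cohort <- read_cohort(opts$cohort)
        cond <- if (is.null(opts$condition)) "baseline" else opts$condition
        recs <- lapply(cohort$subjects,
                       function(s) process_scan(s[[cond]], phantom_config()))
        model <- gp_train_cohort(recs)
        write_gp_model(model, opts$out)
        cli_log("train", n = length(recs), condition = cond,
                ell = model$ell, out = opts$out)
      },
      "predict" = {
        model <- read_gp_model(opts$model)
        idif <- utils::read.table(opts$idif, header = TRUE, sep = "\t")
        idifs <- list(
          idif10 = new_tac(idif$time_s, idif$idif10, grid_kind = "uniform"),
          idif100 = new_tac(idif$time_s, idif$idif100, grid_kind = "uniform"),
          idif1000 = new_tac(idif$time_s, idif$idif1000,
                             grid_kind = "uniform"))
        class(idifs) <- "idif_set"
        pred <- gp_predict(model, idifs, t = idif$time_s)
        write_tac_tsv(pred$mean, opts$out)
        cli_log("predict", variance = pred$variance[1], out = opts$out)
      },
      "fit-cbf" = {
        img <- read_dynamic_image(opts$pet)
        fit <- region_cbf(img, read_mask(opts$gm),
                          read_tac_tsv(opts$input),
                          config = if (is.null(opts$xy_trim))
                            default_config() else phantom_config())
        jsonlite::write_json(
          list(K1 = fit$params[["K1"]], k2 = fit$params[["k2"]],
               va = fit$params[["va"]], cbf = fit$cbf,
               converged = fit$converged),
          opts$out, auto_unbox = TRUE, digits = NA)
        cli_log("fit-cbf", cbf = fit$cbf, out = opts$out)
      },
      "evaluate" = {
        cohort <- read_cohort(opts$cohort)
        recs <- process_cohort(cohort, phantom_config())
        rep <- run_case(as.integer(num("case", 1)), recs$baseline,
                        recs$acz, phantom_config())
        jsonlite::write_json(rep, opts$out, auto_unbox = TRUE, digits = NA,
                             force = TRUE)
        cli_log("evaluate", case = num("case", 1), out = opts$out)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("mlifpet error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
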