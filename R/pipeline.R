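#' Run the end-to-end workflow from a YAML config
#'
#' Stages (each optional, run in this order): `phantom` (generate a
#' cohort of phantom volume/truth pairs), `label` (semi-automatic
#' labeling of the phantom volumes), `train` (cross-validated U-Net
#' training with best-fold selection), `segment` (segment volumes with
#' the selected model), `evaluate` (per-class DSC against truth),
#' `thickness` (cohort layer-thickness statistics). All randomness
#' derives from the single manifest seed via named sub-seeds. A manifest
#' (JSON) recording configs, seeds, package version and per-stage output
#' digests is written to the output directory; when outputs already
#' exist with matching digests a stage is skipped.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Top-level keys: `out_dir`, `seed`, and one section per stage.
#' @param verbose Log stage progress.
#' @return The manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required",
                                 call. = FALSE)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  log_ <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("octseg")),
                   config = cfg, stages = list(), timestamp =
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  digest_files <- function(paths)
    as.list(tools::md5sum(paths[file.exists(paths)]))

  phantoms <- NULL
  load_phantoms <- function() {
    if (!is.null(phantoms)) return(phantoms)
    n <- cfg$phantom$n_volumes %||% 1L
    paths <- file.path(out, sprintf("phantom_%02d.nii", seq_len(n)))
    lapply(seq_len(n), function(i) list(
      volume = read_volume(paths[i], kind = "intensity"),
      truth = read_volume(sub("\\.nii", "_truth.nii", paths[i]),
                          kind = "label")))
  }

  if (!is.null(cfg$phantom)) {
    pc <- cfg$phantom
    n <- pc$n_volumes %||% 1L
    g <- voxel_geometry(pc$n_z %||% 256L, pc$n_y %||% 512L,
                        pc$n_x %||% 256L,
                        pc$extent_z_mm %||% (1.2 * (pc$n_z %||% 256L) / 256),
                        pc$extent_y_mm %||% (3.0 * (pc$n_y %||% 512L) / 512),
                        pc$extent_x_mm %||% (3.0 * (pc$n_x %||% 256L) / 512))
    lt <- unlist(pc$layer_thickness_um %||% c(`2` = 20, `3` = 153,
                                              `4` = 137))
    names(lt) <- as.character(2:4)
    pp <- phantom_params(geometry = g,
                         gap_depth_vox = pc$gap_depth_vox %||% 15,
                         layer_thickness_um = lt,
                         undulation_amplitude_vox =
                           pc$undulation_amplitude_vox %||% 3,
                         undulation_period_vox =
                           pc$undulation_period_vox %||% 40,
                         speckle_shape = pc$speckle_shape %||% 4,
                         seed = seed + 1000L)
    paths <- file.path(out, sprintf("phantom_%02d.nii", seq_len(n)))
    tpaths <- sub("\\.nii$", "_truth.nii", paths)
    if (all(file.exists(c(paths, tpaths))) && !isTRUE(pc$overwrite)) {
      log_("phantom: outputs exist, skipping")
    } else {
      log_("phantom: generating %d volumes", n)
      ph <- make_dataset(n, pp, seed = seed + 1000L)
      for (i in seq_len(n)) {
        write_volume(ph[[i]]$volume, paths[i])
        write_volume(ph[[i]]$truth, tpaths[i])
      }
      phantoms <- lapply(ph, function(p) list(volume = p$volume,
                                              truth = p$truth))
    }
    manifest$stages$phantom <- list(n_volumes = n, seed = seed + 1000L,
                                    files = digest_files(c(paths, tpaths)))
  }

  if (!is.null(cfg$label)) {
    lc <- cfg$label
    ph <- load_phantoms()
    sp <- semiauto_params(
      alpha = lc$alpha %||% c(1.5, -1.5, 1.0, -3),
      w = lc$w %||% 11L,
      despeckle_window = lc$despeckle_window %||% 3L)
    lpaths <- file.path(out, sprintf("label_%02d.nii", seq_along(ph)))
    for (i in seq_along(ph)) {
      rois <- label_rois(ph[[i]]$truth)
      res <- run_semiauto(ph[[i]]$volume, rois, sp)
      write_volume(res$labels, lpaths[i])
    }
    manifest$stages$label <- list(files = digest_files(lpaths))
    log_("label: %d volumes labeled", length(ph))
  }

  best <- NULL
  if (!is.null(cfg$train)) {
    tc <- cfg$train
    ph <- load_phantoms()
    ids <- as.character(seq_along(ph))
    names(ph) <- ids
    plan <- make_cv_plan(ids, tc$n_test %||% 2L, seed = seed + 2000L)
    mc <- unet_config(dims = tc$model %||% 2L,
                      width_multiplier = tc$width_multiplier %||% 1)
    cfg_t <- train_config(epochs = tc$epochs %||% 40L,
                          batch_size = tc$batch_size,
                          blocks_per_epoch = tc$blocks_per_epoch,
                          seed = seed + 3000L)
    folds <- lapply(seq_along(plan$folds), function(i) {
      log_("train: fold %d/%d", i, length(plan$folds))
      train_fold(plan$folds[[i]], mc, cfg_t, ph, fold_id = i)
    })
    best <- select_best(folds)
    manifest$stages$train <- list(
      test_ids = plan$test_ids, n_folds = length(plan$folds),
      fold_dsc = vapply(folds, function(f) f$mean_fg_dsc, numeric(1)),
      best_fold = best$fold_id)
    log_("train: best fold %d (mean tissue DSC %.3f)", best$fold_id,
         best$mean_fg_dsc)
  }

  if (!is.null(cfg$segment)) {
    if (is.null(best)) stop("segment stage requires the train stage",
                            call. = FALSE)
    ph <- load_phantoms()
    test_ids <- manifest$stages$train$test_ids
    preds <- lapply(test_ids, function(id) {
      p <- predict(best, ph[[as.integer(id)]]$volume)
      write_volume(p, file.path(out, sprintf("segm_%s.nii", id)))
      p
    })
    if (best$model_config$dims == 3L) {
      g3 <- split_3d_overlap(ph[[as.integer(test_ids[1])]]$volume)
      manifest$stages$segment$min_coverage <- min(coverage_count(g3))
    }
    manifest$stages$segment$files <-
      digest_files(file.path(out, sprintf("segm_%s.nii", test_ids)))
    names(preds) <- test_ids

    if (!is.null(cfg$evaluate)) {
      reps <- lapply(test_ids, function(id)
        dice(ph[[as.integer(id)]]$truth, preds[[id]]))
      manifest$stages$evaluate <- list(
        dsc = lapply(reps, function(r) r$dsc),
        mean_fg = vapply(reps, function(r) mean(r$dsc[2:5]), numeric(1)))
    }
    if (!is.null(cfg$thickness)) {
      layers <- cfg$thickness$layers %||% c(3L, 4L)
      manifest$stages$thickness <- lapply(layers, function(l) {
        tr <- cohort_thickness(preds, l,
                               cfg$thickness$n_refr %||% 1.4)
        list(layer = l, mean_um = tr$mean_um, sd_um = tr$sd_um)
      })
    }
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}
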