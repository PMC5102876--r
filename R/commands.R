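#' Simulate a synthetic dataset to disk
#'
#' Writes PNG frames, the annotation CSV (with state labels) and the effective
#' configuration (YAML, seed included) into `out_dir`. Reruns with the same
#' configuration produce byte-identical annotations.
#'
#' @param config partial configuration (see [load_config()]).
#' @param out_dir output directory (created if needed).
#' @param n_images number of images; defaults to `config$synth$n_train`.
#' @param absent_frac fraction of frames rendered without the instrument.
#' @param seed overrides `config$seed` when given.
#' @return invisibly, the dataset list from [sample_training_set()].
#' @export
cmd_simulate <- function(config = NULL, out_dir, n_images = NULL,
                         absent_frac = 0, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(n_images)) n_images <- cfg$synth$n_train
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("out_dir is not writable: ", out_dir)
  sc <- scene_config(cfg$synth$image_size, cfg$synth$background_kind,
                     cfg$synth$illumination_gain, cfg$synth$blur_sigma,
                     cfg$synth$noise_sigma, rng_seed = cfg$seed)
  ds <- sample_training_set(n_images, sc, seed = cfg$seed,
                            closed_frac = cfg$synth$closed_frac,
                            closed_threshold = cfg$synth$closed_threshold)
  if (absent_frac > 0) {
    absent <- withr::with_seed(cfg$seed + 1L, {
      which(stats::runif(n_images) < absent_frac)
    })
    for (i in absent) {
      sc_i <- sc; sc_i$rng_seed <- (sc$rng_seed + 7919L * i) %% .Machine$integer.max
      ds$images[[i]] <- render_frame(ds$geometries[[i]], sc_i, frame_id = i - 1L,
                                     instrument_present = FALSE)$image
      ds$annotations[i, ] <- dplyr::mutate(empty_annotation(i - 1L),
                                           state = NA_character_)
    }
  }
  for (i in seq_along(ds$images)) {
    png::writePNG(ds$images[[i]],
                  file.path(out_dir, sprintf("frame_%05d.png", i - 1L)))
  }
  write_annotations(ds$annotations, file.path(out_dir, "annotations.csv"))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(ds)
}

read_frames_dir <- function(frames_dir) {
  files <- sort(list.files(frames_dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", frames_dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    img
  })
}

#' Train detector and priors from an annotated dataset
#'
#' Mines HOG patches from the dataset, trains the part-detection forest, fits
#' the relative-length and rotation priors from the annotations, and writes
#' the models (`forest.rds`, `priors.yaml`) plus the effective configuration
#' to `model_dir`.
#'
#' @param dataset_dir directory produced by [cmd_simulate()] (or any directory
#'   of PNG frames plus `annotations.csv` with a `state` column).
#' @param config partial configuration.
#' @param model_dir output directory.
#' @return invisibly, list with `forest` and `priors`.
#' @export
cmd_train <- function(dataset_dir, config = NULL, model_dir) {
  cfg <- load_config(config)
  ann_path <- file.path(dataset_dir, "annotations.csv")
  if (!file.exists(ann_path)) stop("missing annotations.csv in ", dataset_dir)
  ann <- read_annotations(ann_path)
  if (!"state" %in% names(ann)) stop("annotations lack the state column")
  images <- read_frames_dir(dataset_dir)
  d <- cfg$detector
  tp <- mine_training_patches(images, ann, d$patch_size, d$bins, d$n_cells,
                              d$r_pos, d$n_jitter, d$n_neg, seed = cfg$seed)
  forest <- train_forest(tp$features, tp$labels, d$n_trees, d$max_depth,
                         seed = cfg$seed, patch_size = d$patch_size,
                         bins = d$bins, n_cells = d$n_cells)
  rlen <- fit_rlen_model(ann)
  rotation <- fit_rotation_model(ann, lambda = cfg$potentials$lambda)
  dir.create(model_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(forest, file.path(model_dir, "forest.rds"))
  write_priors(rlen, rotation, file.path(model_dir, "priors.yaml"),
               eps = cfg$potentials$eps)
  yaml::write_yaml(cfg, file.path(model_dir, "config.yaml"))
  invisible(list(forest = forest, priors = list(rlen = rlen, rotation = rotation)))
}

#' Track a sequence of frames with trained models
#'
#' @param frames_dir directory of PNG frames (lexicographic frame order), or a
#'   list of image matrices.
#' @param model_dir directory written by [cmd_train()].
#' @param config partial configuration.
#' @param out_csv tracking output CSV (one row per frame).
#' @return invisibly, the `track_result` tibble.
#' @export
cmd_track <- function(frames_dir, model_dir, config = NULL, out_csv) {
  cfg <- load_config(config)
  forest <- readRDS(file.path(model_dir, "forest.rds"))
  pri <- read_priors(file.path(model_dir, "priors.yaml"))
  frames <- if (is.character(frames_dir)) read_frames_dir(frames_dir) else frames_dir
  tr <- track_sequence(frames, forest, pri, config = c(
    cfg$track[!vapply(cfg$track, is.null, TRUE)],
    list(stride = cfg$detector$stride, min_conf = cfg$detector$min_conf,
         max_per_part = cfg$detector$max_per_part,
         grad_threshold = cfg$potentials$grad_threshold,
         eps = cfg$potentials$eps, temporal_sigma = cfg$potentials$temporal_sigma,
         pop_size = cfg$ga$pop_size, n_iter = cfg$ga$n_iter,
         mutation_rate = cfg$ga$mutation_rate,
         neighborhood_radius = cfg$ga$neighborhood_radius,
         elite_frac = cfg$ga$elite_frac,
         tournament_size = cfg$ga$tournament_size, seed = cfg$seed)))
  utils::write.csv(as.data.frame(tr), out_csv, row.names = FALSE, quote = FALSE)
  invisible(tr)
}

#' Evaluate tracking output against ground truth
#'
#' Writes the accuracy-threshold curves (per joint), the strict PCP table and
#' the angular-threshold curve as CSV files plus a JSON summary to `out_dir`.
#'
#' @param tracking_csv tracking CSV from [cmd_track()] (or a tibble).
#' @param ground_truth_csv annotation CSV (or a tibble).
#' @param config partial configuration.
#' @param out_dir output directory.
#' @return invisibly, list with `errors`, `accuracy`, `pcp`, `angular`.
#' @export
cmd_evaluate <- function(tracking_csv, ground_truth_csv, config = NULL, out_dir) {
  cfg <- load_config(config)
  pred <- if (is.character(tracking_csv)) {
    tibble::as_tibble(utils::read.csv(tracking_csv))
  } else tracking_csv
  gt <- if (is.character(ground_truth_csv)) read_annotations(ground_truth_csv) else ground_truth_csv
  errors <- joint_error_table(pred, gt)
  acc <- dplyr::bind_rows(lapply(c("left", "right", "center"), function(j)
    accuracy_threshold_curve(errors, j, cfg$eval$acc_thresholds)))
  pcp <- strict_pcp(pred, gt, alpha = cfg$eval$alpha)
  ang <- angular_threshold_curve(errors, cfg$eval$ang_thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(acc, file.path(out_dir, "accuracy_threshold.csv"), row.names = FALSE)
  utils::write.csv(pcp, file.path(out_dir, "strict_pcp.csv"), row.names = FALSE)
  utils::write.csv(ang, file.path(out_dir, "angular_threshold.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pcp = pcp, accuracy = acc, angular = ang,
         n_frames = nrow(errors), n_excluded = sum(!errors$evaluable)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(errors = errors, accuracy = acc, pcp = pcp, angular = ang))
}
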