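#' Default run configuration
#'
#' One nested list holding every tunable of the pipeline, grouped by stage.
#' Detector defaults follow the published setting (50 trees, depth 25, 9 HOG
#' bins, 50x50 patches, GA population 1000, PCP alpha 0.5); the remaining
#' values are the package's documented engineering choices.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synth = list(
      image_size = c(240L, 320L), background_kind = "textured",
      illumination_gain = 1, blur_sigma = 1, noise_sigma = 0.02,
      n_train = 200L, closed_frac = 0.35, closed_threshold = 0.1
    ),
    detector = list(
      n_trees = 50L, max_depth = 25L, patch_size = 50L, bins = 9L,
      n_cells = 5L, stride = 4L, min_conf = 0.5, max_per_part = 25L,
      r_pos = 5, n_jitter = 4L, n_neg = 16L
    ),
    potentials = list(
      eps = 1e-6, n_dp = 7L, dp_frac = 0.35, grad_threshold = "otsu",
      lambda = 1e-4, temporal_sigma = 20
    ),
    ga = list(
      pop_size = 1000L, n_iter = 50L, mutation_rate = 0.1,
      neighborhood_radius = 20, elite_frac = 0.05, tournament_size = 4L
    ),
    track = list(
      base_side = NULL, growth = 1.5, rel_rot_threshold = 0.01, max_passes = 3L
    ),
    eval = list(
      acc_thresholds = seq(20, 80, by = 10), alpha = 0.5,
      ang_thresholds = seq(3, 24, by = 3)
    )
  )
}

# reject keys absent from the defaults, recursively
check_config_keys <- function(cfg, defaults, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(defaults)) {
      stop("unknown config key: ", paste0(path, nm))
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
          is.list(cfg[[nm]])) {
      check_config_keys(cfg[[nm]], defaults[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Merges a (possibly partial) configuration into [default_config()],
#' rejecting unknown keys.
#'
#' @param config named list or path to a YAML file; `NULL` gives the defaults.
#' @return validated nested list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  check_config_keys(config, defaults)
  utils::modifyList(defaults, config)
}

annotation_columns <- function() {
  c("frame_id", "left_x", "left_y", "right_x", "right_y",
    "center_x", "center_y", "shaft_x", "shaft_y", "present", "state")
}

#' Write annotations to the interchange CSV schema
#' @param annotations annotation tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- intersect(c(annotation_columns(), "clipped", "opening_angle",
                      "log_fitness", "confident", "roi_side"),
                    names(annotations))
  utils::write.csv(annotations[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation CSV
#' @param path CSV path.
#' @return annotation tibble.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(annotation_columns(), "state"), names(df))
  if (length(missing)) {
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df)
}
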