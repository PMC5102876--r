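#' Square search region of interest
#'
#' @param center `(x, y)` center in px.
#' @param side side length in px (> 0); the ROI is clipped to the image when
#'   used.
#' @param expansion_level number of growth steps applied since the last
#'   confident pose.
#' @return object of class `roi`.
#' @export
roi <- function(center, side, expansion_level = 0L) {
  stopifnot(side > 0, length(center) == 2)
  structure(list(center = as.numeric(center), side = side,
                 expansion_level = as.integer(expansion_level)),
            class = "roi")
}

#' Full-frame ROI for detection mode
#'
#' Used on the first frame and after a full reset: the whole frame is
#' searched, side `max(H, W)` centered on the image.
#'
#' @param image_size `(H, W)` in px.
#' @return a [roi()].
#' @export
init_roi <- function(image_size) {
  h <- image_size[1]; w <- image_size[2]
  roi(c((w - 1) / 2, (h - 1) / 2), side = max(h, w), expansion_level = 0L)
}

#' Confidence assessment of an inferred pose
#'
#' A pose is rejected when (1) the consistency potential collapsed to the
#' floor `eps` (gripper longer than half the ROI side), or (2) the rotation
#' mixture density at the pose's angle triple falls below
#' `rel_rot_threshold` times the larger of the two component mode densities.
#' The relative threshold makes the check independent of the prior's scale.
#'
#' @param pose a `pose_estimate`.
#' @param rotation a [rotation_model()].
#' @param roi the [roi()] used for detection.
#' @param rel_rot_threshold relative density threshold in `(0, 1]`.
#' @param eps probability floor.
#' @return `TRUE` when the pose is trustworthy.
#' @export
assess_confidence <- function(pose, rotation, roi, rel_rot_threshold = 0.01,
                              eps = 1e-6) {
  stopifnot(inherits(pose, "pose_estimate"))
  pts <- pose$configuration
  p <- function(part) c(pts$x[pts$part == part], pts$y[pts$part == part])
  left <- p("left"); center <- p("center"); right <- p("right"); shaft <- p("shaft")
  if (consistency_potential(center, left, right, roi, eps) == eps) return(FALSE)
  th <- tryCatch(angle_triple(left, center, right, shaft), error = function(e) NULL)
  if (is.null(th)) return(FALSE)
  dens <- rotation_potential(th, rotation)
  dens >= rel_rot_threshold * max(rotation_mode_density(rotation))
}

#' Update the ROI after one frame
#'
#' A confident pose recenters the ROI on the inferred center point and resets
#' it to the base side; a missing part or low-confidence pose grows the side
#' geometrically (capped at the full frame), implementing gradual automatic
#' reinitialization.
#'
#' @param current the [roi()] used this frame.
#' @param pose a `pose_estimate` or `NULL` when inference had missing parts.
#' @param confident logical confidence verdict.
#' @param base_side reset side in px.
#' @param growth multiplicative growth factor per failed frame.
#' @param image_size `(H, W)`.
#' @return the next frame's [roi()].
#' @export
update_roi <- function(current, pose, confident, base_side, growth = 1.5,
                       image_size) {
  max_side <- max(image_size)
  if (isTRUE(confident) && !is.null(pose)) {
    ctr <- unlist(pose$configuration[pose$configuration$part == "center", c("x", "y")])
    return(roi(ctr, min(base_side, max_side), expansion_level = 0L))
  }
  roi(current$center, min(current$side * growth, max_side),
      expansion_level = current$expansion_level + 1L)
}

track_defaults <- function() {
  list(stride = 4L, min_conf = 0.5, max_per_part = 25L,
       grad_threshold = "otsu", eps = 1e-6, temporal_sigma = 20,
       base_side = NULL, growth = 1.5, rel_rot_threshold = 0.01,
       max_passes = 3L, dp_grid = NULL,
       pop_size = 1000L, n_iter = 50L, mutation_rate = 0.1,
       neighborhood_radius = 20, elite_frac = 0.05, tournament_size = 4L,
       seed = 1L)
}

#' Track a forceps through a frame sequence
#'
#' Tracking by detection: per frame, part hypotheses are detected inside the
#' current ROI, the MAP configuration is inferred by the genetic algorithm,
#' its confidence is assessed, and the ROI is recentered (confident) or grown
#' (failure). When a part has no hypothesis the ROI is expanded and detection
#' retried up to `max_passes` times within the same frame; frames that stay
#' incomplete after expansion to the full frame are reported missing. No
#' manual input is ever required: reinitialization is automatic.
#'
#' @param frames list of image matrices.
#' @param forest a trained `forest_model`.
#' @param priors list with elements `rlen` ([rlen_model()]) and `rotation`
#'   ([rotation_model()]); as returned by [read_priors()] or [cmd_train()].
#' @param config named list overriding entries of the tracking defaults
#'   (stride, min_conf, max_per_part, grad_threshold, eps, temporal_sigma,
#'   base_side, growth, rel_rot_threshold, max_passes, GA settings, seed).
#'   `base_side = NULL` defaults to 4x the fitted mean gripper length.
#' @return object of class `track_result`: a tibble with one row per frame
#'   (`frame_id, present, left_x, ..., shaft_y, log_fitness, confident,
#'   roi_side, roi_side_end, n_passes`), with the per-frame `pose_estimate`
#'   objects in the `"poses"` attribute.
#' @export
track_sequence <- function(frames, forest, priors, config = list()) {
  cfg <- utils::modifyList(track_defaults(), config)
  stopifnot(inherits(forest, "forest_model"),
            inherits(priors$rlen, "rlen_model"),
            inherits(priors$rotation, "rotation_model"))
  if (is.null(cfg$base_side)) cfg$base_side <- 4 * mean(priors$rlen$mu)
  image_size <- dim(frames[[1]])
  state <- list(prev_pose = NULL, roi = init_roi(image_size))
  rows <- vector("list", length(frames))
  poses <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fid <- fi - 1L
    img <- frames[[fi]]
    edges <- edge_map(img, cfg$grad_threshold)
    current_roi <- state$roi
    roi_start <- current_roi$side
    hyps <- NULL
    passes <- 0L
    repeat {
      passes <- passes + 1L
      hyps <- detect_hypotheses(img, current_roi, forest, cfg$stride,
                                cfg$min_conf, cfg$max_per_part)
      missing <- setdiff(instrument_parts(), unique(hyps$label))
      if (!length(missing)) break
      at_full <- current_roi$side >= max(image_size)
      if (passes >= cfg$max_passes || at_full) break
      current_roi <- update_roi(current_roi, NULL, FALSE, cfg$base_side,
                                cfg$growth, image_size)
    }
    missing <- setdiff(instrument_parts(), unique(hyps$label))
    if (length(missing)) {
      state$roi <- update_roi(current_roi, NULL, FALSE, cfg$base_side,
                              cfg$growth, image_size)
      rows[[fi]] <- tibble::tibble(
        frame_id = fid, present = 0L,
        left_x = NA_real_, left_y = NA_real_, right_x = NA_real_,
        right_y = NA_real_, center_x = NA_real_, center_y = NA_real_,
        shaft_x = NA_real_, shaft_y = NA_real_,
        log_fitness = NA_real_, confident = FALSE,
        roi_side = roi_start, roi_side_end = state$roi$side,
        n_passes = passes)
      next
    }
    ctx <- fitness_context(hyps, edges, priors$rlen, priors$rotation,
                           current_roi, prev_pose = state$prev_pose,
                           eps = cfg$eps, dp_grid = cfg$dp_grid,
                           temporal_sigma = cfg$temporal_sigma)
    pose <- ga_infer(ctx, pop_size = cfg$pop_size, n_iter = cfg$n_iter,
                     mutation_rate = cfg$mutation_rate,
                     neighborhood_radius = cfg$neighborhood_radius,
                     elite_frac = cfg$elite_frac,
                     tournament_size = cfg$tournament_size,
                     seed = (cfg$seed + 31L * fid) %% .Machine$integer.max)
    confident <- assess_confidence(pose, priors$rotation, current_roi,
                                   cfg$rel_rot_threshold, cfg$eps)
    pose$confidence_ok <- confident
    poses[[fi]] <- pose
    if (confident) {
      cc <- pose$configuration
      state$prev_pose <- lapply(stats::setNames(instrument_parts(),
                                                instrument_parts()),
                                function(p) c(cc$x[cc$part == p], cc$y[cc$part == p]))
    }
    state$roi <- update_roi(current_roi, pose, confident, cfg$base_side,
                            cfg$growth, image_size)
    cc <- pose$configuration
    g <- function(p, a) cc[[a]][cc$part == p]
    rows[[fi]] <- tibble::tibble(
      frame_id = fid, present = 1L,
      left_x = g("left", "x"), left_y = g("left", "y"),
      right_x = g("right", "x"), right_y = g("right", "y"),
      center_x = g("center", "x"), center_y = g("center", "y"),
      shaft_x = g("shaft", "x"), shaft_y = g("shaft", "y"),
      log_fitness = pose$log_fitness, confident = confident,
      roi_side = roi_start, roi_side_end = state$roi$side,
      n_passes = passes)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "poses") <- poses
  class(out) <- c("track_result", class(out))
  out
}

#' @export
glance.track_result <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x),
                 n_present = sum(x$present),
                 n_confident = sum(x$confident),
                 mean_roi_side = mean(x$roi_side))
}
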