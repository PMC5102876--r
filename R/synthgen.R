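#' Scene configuration for the synthetic renderer
#'
#' Describes everything about a rendered frame except the instrument itself.
#' Identical `(scene_config, forceps_geometry)` pairs render bit-identical
#' images.
#'
#' @param image_size integer length-2 `(H, W)` in px.
#' @param background_kind one of `"flat"`, `"textured"`, `"vessels"`.
#'   `"vessels"` adds random smooth dark curvilinear strokes over the textured
#'   background, emulating retinal vasculature that produces plausible false
#'   part detections.
#' @param illumination_gain scalar multiplier on the rendered intensities.
#' @param blur_sigma Gaussian blur sigma in px (0 disables).
#' @param noise_sigma additive Gaussian noise sd in intensity units (0 disables).
#' @param rng_seed integer seed controlling all stochastic scene content.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(240, 320),
                         background_kind = c("textured", "flat", "vessels"),
                         illumination_gain = 1,
                         blur_sigma = 1,
                         noise_sigma = 0.02,
                         rng_seed = 1L) {
  background_kind <- match.arg(background_kind)
  stopifnot(length(image_size) == 2, image_size >= 32,
            illumination_gain > 0, blur_sigma >= 0, noise_sigma >= 0)
  structure(
    list(image_size = as.integer(image_size), background_kind = background_kind,
         illumination_gain = illumination_gain, blur_sigma = blur_sigma,
         noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)),
    class = "scene_config"
  )
}

# Evaluate a quadratic Bezier at n parameter values; returns n x 2 (x, y)
bezier_samples <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

# Control point for a quadratic Bezier: chord midpoint displaced by `offset`
# px along the unit orthogonal of (p0 -> p2).
bezier_control <- function(p0, p2, offset) {
  d <- p2 - p0
  len <- vnorm(d)
  if (len == 0) stop("coincident endpoints do not define a curve")
  n_hat <- c(-d[2], d[1]) / len
  (p0 + p2) / 2 + offset * n_hat
}

# Stamp a stroke of the given width along float sample points onto the image.
# mode "set" paints `value`; "darken" lowers intensity by `value` (floored).
stamp_stroke <- function(img, pts, width, value, mode = "set") {
  h <- nrow(img); w <- ncol(img)
  r <- max(width / 2, 0.5)
  ir <- ceiling(r)
  off <- expand.grid(dx = -ir:ir, dy = -ir:ir)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.25, , drop = FALSE]
  cx <- round(rep(pts[, 1], each = nrow(off)) + off$dx)
  cy <- round(rep(pts[, 2], each = nrow(off)) + off$dy)
  keep <- cx >= 0 & cx < w & cy >= 0 & cy < h
  idx <- cbind(cy[keep] + 1L, cx[keep] + 1L)
  if (mode == "set") {
    img[idx] <- value
  } else {
    img[idx] <- pmax(img[idx] - value, 0.05)
  }
  img
}

render_background <- function(scene) {
  h <- scene$image_size[1]; w <- scene$image_size[2]
  withr::with_seed(scene$rng_seed, {
    if (scene$background_kind == "flat") {
      img <- matrix(0.35, h, w)
    } else {
      z <- matrix(stats::runif(h * w), h, w)
      z <- EBImage::gblur(z, sigma = 8)
      rng <- range(z)
      img <- 0.28 + 0.18 * (z - rng[1]) / max(rng[2] - rng[1], 1e-12)
      if (scene$background_kind == "vessels") {
        n_vessels <- 6L
        for (i in seq_len(n_vessels)) {
          p0 <- c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1))
          ang <- stats::runif(1, 0, 2 * pi)
          len <- stats::runif(1, 0.3, 0.8) * min(h, w)
          p2 <- p0 + len * c(cos(ang), sin(ang))
          ctrl <- bezier_control(p0, p2, stats::runif(1, -0.3, 0.3) * len)
          pts <- bezier_samples(p0, ctrl, p2, n = max(8, ceiling(2 * len)))
          img <- stamp_stroke(img, pts, width = stats::runif(1, 2, 4),
                              value = stats::runif(1, 0.12, 0.2), mode = "darken")
        }
      }
    }
    img
  })
}

stamp_instrument <- function(img, geometry, intensity = 0.85) {
  j <- forceps_joints(geometry)
  # shaft: straight thick stroke from base to center
  n_sh <- max(2, ceiling(2 * geometry$shaft_length))
  t <- seq(0, 1, length.out = n_sh)
  sh_pts <- cbind(j$shaft_base[1] + t * (j$center[1] - j$shaft_base[1]),
                  j$shaft_base[2] + t * (j$center[2] - j$shaft_base[2]))
  img <- stamp_stroke(img, sh_pts, geometry$shaft_width, intensity)
  # arms: quadratic Bezier strokes, bows mirrored about each chord
  for (s in c(+1, -1)) {
    tip <- if (s > 0) j$left else j$right
    chord <- vnorm(tip - j$center)
    if (chord == 0) { # closed instrument: arms coincide with the axis
      ctrl <- (j$center + tip) / 2
      pts <- matrix(rep(j$center, 2), 2, byrow = TRUE)
      img <- stamp_stroke(img, pts, geometry$arm_width, intensity)
      next
    }
    ctrl <- bezier_control(j$center, tip,
                           s * geometry$arm_curvature * geometry$arm_length)
    pts <- bezier_samples(j$center, ctrl, tip, n = max(4, ceiling(3 * chord)))
    img <- stamp_stroke(img, pts, geometry$arm_width, intensity)
  }
  img
}

empty_annotation <- function(frame_id) {
  tibble::tibble(frame_id = as.integer(frame_id),
                 left_x = NA_real_, left_y = NA_real_,
                 right_x = NA_real_, right_y = NA_real_,
                 center_x = NA_real_, center_y = NA_real_,
                 shaft_x = NA_real_, shaft_y = NA_real_,
                 present = 0L, state = NA_character_)
}

geometry_annotation <- function(geometry, frame_id, closed_threshold = 0.1) {
  j <- forceps_joints(geometry)
  tibble::tibble(frame_id = as.integer(frame_id),
                 left_x = j$left[1], left_y = j$left[2],
                 right_x = j$right[1], right_y = j$right[2],
                 center_x = j$center[1], center_y = j$center[2],
                 shaft_x = j$shaft[1], shaft_y = j$shaft[2],
                 present = 1L,
                 state = if (geometry$opening_angle > closed_threshold) "open" else "closed")
}

#' Render one synthetic forceps frame with exact ground truth
#'
#' Draws the instrument (bright shaft plus two gripper arms rendered as
#' quadratic Bezier strokes) over the configured background, applies
#' illumination gain, Gaussian blur and additive noise, and returns the exact
#' joint coordinates used for drawing.
#'
#' @param geometry a [forceps_geometry()]; must fit inside the image.
#' @param scene a [scene_config()].
#' @param frame_id integer id stored in the annotation; also decorrelates the
#'   per-frame noise draw so a sequence shares its background but not its noise.
#' @param instrument_present if `FALSE`, renders background only and flags the
#'   annotation as missing.
#' @param closed_threshold opening angle (rad) at or below which the state
#'   label is `"closed"`.
#' @return A list with `image` (H x W matrix in `[0, 1]`) and `annotation`
#'   (one-row tibble: `frame_id, left_x, ..., shaft_y, present, state`).
#' @export
render_frame <- function(geometry, scene, frame_id = 0L,
                         instrument_present = TRUE, closed_threshold = 0.1) {
  stopifnot(inherits(geometry, "forceps_geometry"), inherits(scene, "scene_config"))
  if (instrument_present && !geometry_in_bounds(geometry, scene$image_size)) {
    stop("forceps geometry does not fit inside the ", scene$image_size[1], "x",
         scene$image_size[2], " image (joints or stroke margin out of bounds)")
  }
  img <- render_background(scene)
  if (instrument_present) img <- stamp_instrument(img, geometry)
  img <- img * scene$illumination_gain
  if (scene$blur_sigma > 0) img <- EBImage::gblur(img, sigma = scene$blur_sigma)
  if (scene$noise_sigma > 0) {
    noise_seed <- (scene$rng_seed + 104729L * (as.integer(frame_id) + 1L)) %% .Machine$integer.max
    img <- img + withr::with_seed(noise_seed,
      matrix(stats::rnorm(length(img), sd = scene$noise_sigma), nrow(img)))
  }
  img <- pmin(pmax(img, 0), 1)
  ann <- if (instrument_present) {
    geometry_annotation(geometry, frame_id, closed_threshold)
  } else {
    empty_annotation(frame_id)
  }
  list(image = img, annotation = ann)
}

apply_motion <- function(geometry, motion) {
  g <- unclass(geometry)
  for (nm in names(motion)) {
    if (!nm %in% names(g)) stop("unknown geometry field in motion: ", nm)
    g[[nm]] <- g[[nm]] + motion[[nm]]
  }
  g$opening_angle <- min(max(g$opening_angle, 0), pi / 2)
  do.call(forceps_geometry, g[c("center", "shaft_angle", "shaft_length",
                                "arm_length", "opening_angle", "arm_curvature",
                                "shaft_width", "arm_width", "shaft_point_dist")])
}

# Clamp the center so the geometry fits; returns list(geometry, clipped)
clamp_geometry <- function(geometry, image_size) {
  if (geometry_in_bounds(geometry, image_size)) {
    return(list(geometry = geometry, clipped = FALSE))
  }
  reach <- max(geometry$shaft_length, geometry$arm_length) +
    max(geometry$shaft_width, geometry$arm_width) / 2 + 2
  g <- unclass(geometry)
  g$center <- c(min(max(g$center[1], reach), image_size[2] - 1 - reach),
                min(max(g$center[2], reach), image_size[1] - 1 - reach))
  list(geometry = do.call(forceps_geometry, g), clipped = TRUE)
}

#' Generate a synthetic video sequence
#'
#' Frames share the background style (same background seed) while the
#' instrument evolves under a constant per-frame motion model. Frames listed
#' in `absent_frames` contain no instrument and are flagged missing, which
#' exercises the tracker's automatic reinitialization.
#'
#' @param geometry initial [forceps_geometry()].
#' @param scene a [scene_config()].
#' @param n_frames number of frames (>= 1).
#' @param motion named list of per-frame additive deltas on geometry fields,
#'   e.g. `list(center = c(2, 0), opening_angle = 0.01)`.
#' @param absent_frames integer vector of 0-based frame ids rendered without
#'   the instrument.
#' @param closed_threshold passed to [render_frame()].
#' @return A list with `frames` (list of image matrices) and `annotations`
#'   (tibble, one row per frame, plus a `clipped` flag where the motion had to
#'   be clamped to keep the instrument in frame).
#' @export
generate_sequence <- function(geometry, scene, n_frames,
                              motion = list(), absent_frames = integer(0),
                              closed_threshold = 0.1) {
  stopifnot(n_frames >= 1)
  frames <- vector("list", n_frames)
  anns <- vector("list", n_frames)
  g <- geometry
  for (i in seq_len(n_frames)) {
    fid <- i - 1L
    if (i > 1 && length(motion)) g <- apply_motion(g, motion)
    cl <- clamp_geometry(g, scene$image_size)
    g <- cl$geometry
    fr <- render_frame(g, scene, frame_id = fid,
                       instrument_present = !(fid %in% absent_frames),
                       closed_threshold = closed_threshold)
    frames[[i]] <- fr$image
    anns[[i]] <- dplyr::mutate(fr$annotation, clipped = cl$clipped)
  }
  list(frames = frames, annotations = dplyr::bind_rows(anns))
}

default_geometry_ranges <- function() {
  # shaft angles span a bounded arc: the instrument enters through a fixed
  # scleral port, so its orientation varies moderately around the approach axis
  list(shaft_angle = c(-0.6, 0.6),
       arm_length = c(52, 58),
       shaft_length = c(88, 92),
       arm_curvature = c(0.05, 0.2),
       opening_closed = c(0, 0.08),
       opening_open = c(0.25, 0.9))
}

# Draw one geometry uniformly from the ranges; centers keep the whole
# instrument strictly inside the image.
sample_geometry <- function(image_size, ranges, closed_frac = 0.35) {
  r <- utils::modifyList(default_geometry_ranges(), ranges)
  for (nm in names(r)) {
    if (length(r[[nm]]) != 2 || r[[nm]][1] > r[[nm]][2]) {
      stop("empty or invalid range for ", nm)
    }
  }
  shaft_length <- stats::runif(1, r$shaft_length[1], r$shaft_length[2])
  reach <- shaft_length + 8
  lo <- c(reach, reach); hi <- c(image_size[2] - 1 - reach, image_size[1] - 1 - reach)
  if (any(hi < lo)) stop("image too small for the geometry ranges")
  opening <- if (stats::runif(1) < closed_frac) {
    stats::runif(1, r$opening_closed[1], r$opening_closed[2])
  } else {
    stats::runif(1, r$opening_open[1], r$opening_open[2])
  }
  forceps_geometry(
    center = c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2])),
    shaft_angle = stats::runif(1, r$shaft_angle[1], r$shaft_angle[2]),
    shaft_length = shaft_length,
    arm_length = stats::runif(1, r$arm_length[1], r$arm_length[2]),
    opening_angle = opening,
    arm_curvature = stats::runif(1, r$arm_curvature[1], r$arm_curvature[2])
  )
}

#' Sample a labelled synthetic training set
#'
#' Draws independent forceps geometries over fresh scenes and emits, for each
#' image, the exact joint annotation and an open/closed state label derived
#' from the generating opening angle (`opening_angle > closed_threshold` means
#' open). Opening angles are drawn from a two-regime mixture (closed near 0,
#' open well above the threshold) so both components of the rotation prior are
#' covered by construction.
#'
#' @param n_images number of images (>= 1).
#' @param scene base [scene_config()]; each image gets a derived seed.
#' @param seed master integer seed.
#' @param ranges named list overriding [default_geometry_ranges()] entries.
#' @param closed_frac fraction of draws from the closed regime.
#' @param closed_threshold state-label threshold in radians.
#' @return list with `images` (list of matrices), `annotations` (tibble with
#'   `state` column) and `geometries` (list of [forceps_geometry()]).
#' @export
sample_training_set <- function(n_images, scene = scene_config(), seed = 1L,
                                ranges = list(), closed_frac = 0.35,
                                closed_threshold = 0.1) {
  stopifnot(n_images >= 1)
  geoms <- withr::with_seed(seed, {
    lapply(seq_len(n_images), function(i)
      sample_geometry(scene$image_size, ranges, closed_frac))
  })
  images <- vector("list", n_images)
  anns <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- scene
    sc$rng_seed <- (scene$rng_seed + 7919L * i) %% .Machine$integer.max
    fr <- render_frame(geoms[[i]], sc, frame_id = i - 1L,
                       closed_threshold = closed_threshold)
    images[[i]] <- fr$image
    anns[[i]] <- fr$annotation
  }
  list(images = images, annotations = dplyr::bind_rows(anns), geometries = geoms)
}

#' Sample annotations only (no rendering)
#'
#' Fast path for fitting and testing the kinematic priors: draws geometries as
#' [sample_training_set()] does but skips image synthesis.
#'
#' @inheritParams sample_training_set
#' @param image_size `(H, W)` bounds for center placement.
#' @return tibble of annotations with a `state` column and an
#'   `opening_angle` column carrying the generating angle.
#' @export
sample_annotations <- function(n_images, image_size = c(240, 320), seed = 1L,
                               ranges = list(), closed_frac = 0.35,
                               closed_threshold = 0.1) {
  stopifnot(n_images >= 1)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_images), function(i) {
      g <- sample_geometry(image_size, ranges, closed_frac)
      dplyr::mutate(geometry_annotation(g, i - 1L, closed_threshold),
                    opening_angle = g$opening_angle)
    })
    dplyr::bind_rows(rows)
  })
}
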