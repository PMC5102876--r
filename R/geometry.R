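#' Forceps geometry
#'
#' Parametric description of a two-armed forceps in the image plane. The
#' instrument is a straight shaft whose distal end (the center joint) splits
#' into two gripper arms. All coordinates follow the package-wide convention:
#' `(x, y)` with the origin at the top-left pixel center, 0-based, x rightward,
#' y downward; angles in radians.
#'
#' @param center numeric length-2, `(x, y)` position of the center joint (px).
#' @param shaft_angle direction from the shaft base toward the center, radians.
#' @param shaft_length shaft length in px (> 0).
#' @param arm_length length of each gripper arm in px (> 0).
#' @param opening_angle full angle between the two arms, radians in `[0, pi/2]`.
#' @param arm_curvature dimensionless bow factor (>= 0): each arm is rendered as
#'   a quadratic Bezier whose control point sits `arm_curvature * arm_length`
#'   off the chord midpoint, orthogonally, mirrored between the two arms. The
#'   tip positions themselves are unaffected.
#' @param shaft_width,arm_width stroke widths in px used by the renderer.
#' @param shaft_point_dist distance (px) from the center to the annotated shaft
#'   point along the shaft centerline. The annotation protocol does not pin
#'   this down, so it is an explicit parameter.
#'
#' @return An object of class `forceps_geometry`.
#' @seealso [forceps_joints()], [render_frame()]
#' @export
forceps_geometry <- function(center = c(160, 120),
                             shaft_angle = 0,
                             shaft_length = 90,
                             arm_length = 55,
                             opening_angle = 0.5,
                             arm_curvature = 0.12,
                             shaft_width = 10,
                             arm_width = 5,
                             shaft_point_dist = 60) {
  stopifnot(length(center) == 2, is.finite(center))
  if (shaft_length <= 0 || arm_length <= 0) {
    stop("shaft_length and arm_length must be positive")
  }
  if (opening_angle < 0 || opening_angle > pi / 2 + 1e-12) {
    stop("opening_angle must lie in [0, pi/2]")
  }
  if (arm_curvature < 0) stop("arm_curvature must be >= 0")
  if (shaft_point_dist <= 0 || shaft_point_dist > shaft_length) {
    stop("shaft_point_dist must be in (0, shaft_length]")
  }
  structure(
    list(center = as.numeric(center), shaft_angle = as.numeric(shaft_angle),
         shaft_length = shaft_length, arm_length = arm_length,
         opening_angle = opening_angle, arm_curvature = arm_curvature,
         shaft_width = shaft_width, arm_width = arm_width,
         shaft_point_dist = shaft_point_dist),
    class = "forceps_geometry"
  )
}

rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Joint positions implied by a forceps geometry
#'
#' Derives the four annotated joints (left tip, right tip, center, shaft
#' point) plus the shaft base deterministically from the geometry fields.
#' For straight or bowed arms alike, the angle between `(left - center)` and
#' `(right - center)` equals `opening_angle` exactly.
#'
#' @param geometry a [forceps_geometry()].
#' @return A list with numeric `(x, y)` elements `left`, `right`, `center`,
#'   `shaft` (the annotated shaft point) and `shaft_base`.
#' @export
forceps_joints <- function(geometry) {
  stopifnot(inherits(geometry, "forceps_geometry"))
  u <- c(cos(geometry$shaft_angle), sin(geometry$shaft_angle))
  half <- geometry$opening_angle / 2
  list(
    left = geometry$center + geometry$arm_length * rot2(u, +half),
    right = geometry$center + geometry$arm_length * rot2(u, -half),
    center = geometry$center,
    shaft = geometry$center - geometry$shaft_point_dist * u,
    shaft_base = geometry$center - geometry$shaft_length * u
  )
}

# TRUE iff every rendered stroke (with half-width margin) stays inside the image
geometry_in_bounds <- function(geometry, image_size) {
  j <- forceps_joints(geometry)
  margin <- max(geometry$shaft_width, geometry$arm_width) / 2 + 1
  pts <- rbind(j$left, j$right, j$center, j$shaft_base)
  all(pts[, 1] >= margin & pts[, 1] <= image_size[2] - 1 - margin &
        pts[, 2] >= margin & pts[, 2] <= image_size[1] - 1 - margin)
}

#' Unsigned angle between two 2D vectors, in [0, pi]
#' @param a,b numeric length-2 vectors (must be non-zero).
#' @return angle in radians.
#' @export
angle_between <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na == 0 || nb == 0) stop("angle undefined for a zero-length vector")
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}
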