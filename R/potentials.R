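#' Binary edge map by gradient thresholding
#'
#' Sobel gradient magnitude thresholded into a binary edge image. The
#' connectivity potential tolerates 1 px of rasterization slack, so the map
#' also carries a 3x3 box dilation of itself.
#'
#' @param image numeric H x W matrix.
#' @param grad_threshold numeric threshold on Sobel magnitude, or `"otsu"` for
#'   an automatic threshold.
#' @return object of class `edge_map`: `mask` (0/1 matrix), `dilated` (logical
#'   matrix) and `threshold` used.
#' @export
edge_map <- function(image, grad_threshold = "otsu") {
  h <- nrow(image); w <- ncol(image)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- EBImage::filter2(image, kx, boundary = "replicate")
  gy <- EBImage::filter2(image, t(kx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  thr <- if (identical(grad_threshold, "otsu")) {
    mx <- max(mag)
    if (mx <= 0) 0 else EBImage::otsu(EBImage::Image(mag / mx)) * mx
  } else {
    stopifnot(is.numeric(grad_threshold), grad_threshold >= 0)
    grad_threshold
  }
  mask <- (mag > thr) * 1L
  dil <- EBImage::dilate(mask, EBImage::makeBrush(3, "box")) > 0
  structure(list(mask = mask, dilated = dil, threshold = thr),
            class = "edge_map")
}

#' Quadratic Bezier curve specification between two part hypotheses
#'
#' The curve joins `y_i` and `y_j` exactly at its endpoints; its control point
#' sits `control_offset` px along the unit orthogonal of the chord, anchored at
#' the chord midpoint. Zero offset degenerates to the straight segment.
#'
#' @param p0,p2 endpoints `(x, y)`; must be distinct.
#' @param control_offset signed offset in px.
#' @param density sample points per px of estimated arc length.
#' @return object of class `bezier_spec`.
#' @export
bezier_spec <- function(p0, p2, control_offset = 0, density = 3) {
  if (all(p0 == p2)) stop("coincident endpoints do not define a curve")
  structure(list(p0 = as.numeric(p0), p2 = as.numeric(p2),
                 control_offset = control_offset, density = density),
            class = "bezier_spec")
}

#' Rasterize a quadratic Bezier into an ordered pixel chain
#'
#' Dense parameter sampling followed by rounding and consecutive
#' de-duplication; adjacent chain pixels are 8-connected. With zero control
#' offset the result is the straight rasterized segment.
#'
#' @param spec a [bezier_spec()].
#' @return m x 2 integer matrix of `(x, y)` pixels ordered from `p0` to `p2`.
#' @export
trace_curve <- function(spec) {
  stopifnot(inherits(spec, "bezier_spec"))
  ctrl <- bezier_control(spec$p0, spec$p2, spec$control_offset)
  arc <- vnorm(ctrl - spec$p0) + vnorm(spec$p2 - ctrl)
  n <- max(2, ceiling(spec$density * arc))
  pts <- round(bezier_samples(spec$p0, ctrl, spec$p2, n))
  keep <- c(TRUE, diff(pts[, 1]) != 0 | diff(pts[, 2]) != 0)
  pts[keep, , drop = FALSE]
}

#' Edge connectivity along a traced curve
#'
#' Splits the curve's pixel chain into maximal runs of edge pixels (segments)
#' and scores `sum(|s_j|^2) / k^2` where `k` is the total number of curve
#' pixels. Fully connected curves score 1; fragmentation is penalized
#' quadratically (two half-curve runs score 0.5); a curve touching no edge
#' pixel scores the floor `eps`. A curve pixel counts as "on an edge" if it
#' falls inside the 1-px dilation of the edge map.
#'
#' @param edges an [edge_map()].
#' @param curve m x 2 pixel matrix from [trace_curve()].
#' @param eps probability floor.
#' @return probability in `[eps, 1]`.
#' @export
curve_connectivity <- function(edges, curve, eps = 1e-6) {
  stopifnot(inherits(edges, "edge_map"), nrow(curve) >= 1)
  h <- nrow(edges$mask); w <- ncol(edges$mask)
  x <- curve[, 1]; y <- curve[, 2]
  inside <- x >= 0 & x < w & y >= 0 & y < h
  on_edge <- logical(nrow(curve))
  on_edge[inside] <- edges$dilated[cbind(y[inside] + 1L, x[inside] + 1L)]
  r <- rle(on_edge)
  segs <- r$lengths[r$values]
  if (!length(segs)) return(eps)
  max(sum(segs^2) / nrow(curve)^2, eps)
}

default_dp_grid <- function(p0, p2, n_dp = 7L, dp_frac = 0.35) {
  seq(-dp_frac, dp_frac, length.out = n_dp) * vnorm(p2 - p0)
}

#' Translation (connectivity) potential between two parts
#'
#' Maximizes the curve connectivity over a family of quadratic Bezier curves
#' whose control-point offsets sweep `dp_grid`, so the potential adapts to
#' gripper arms of varying curvature.
#'
#' @param y_i,y_j part hypothesis positions `(x, y)`.
#' @param edges an [edge_map()].
#' @param dp_grid numeric vector of signed control offsets in px; `NULL` uses
#'   7 offsets spanning +/- 0.35 of the chord length.
#' @param eps probability floor.
#' @return max connectivity over the curve family, in `[eps, 1]`.
#' @export
translation_potential <- function(y_i, y_j, edges, dp_grid = NULL, eps = 1e-6) {
  if (all(y_i == y_j)) return(eps)
  if (is.null(dp_grid)) dp_grid <- default_dp_grid(y_i, y_j)
  stopifnot(length(dp_grid) >= 1)
  best <- eps
  for (dp in dp_grid) {
    v <- curve_connectivity(edges, trace_curve(bezier_spec(y_i, y_j, dp)), eps)
    if (v > best) best <- v
  }
  best
}

#' Relative-length model of the two gripper arms
#'
#' @param mu length-2 mean `(mu_left, mu_right)` of the center-to-tip
#'   distances, px.
#' @param sigma shared isotropic spread, px (> 0).
#' @return object of class `rlen_model`.
#' @export
rlen_model <- function(mu, sigma) {
  stopifnot(length(mu) == 2, sigma > 0)
  structure(list(mu = as.numeric(mu), sigma = sigma), class = "rlen_model")
}

#' Relative-length potential
#'
#' Peak-normalized isotropic bivariate Gaussian over the pair of gripper
#' lengths `(|center-left|, |center-right|)`; equals 1 exactly at the fitted
#' mean pair. Penalizes configurations whose arms were snapped to nearby
#' vessel-like false detections.
#'
#' @param center,left,right `(x, y)` points.
#' @param model an [rlen_model()].
#' @return score in `(0, 1]`.
#' @export
relative_length_potential <- function(center, left, right, model) {
  stopifnot(inherits(model, "rlen_model"))
  d_l <- vnorm(left - center); d_r <- vnorm(right - center)
  exp(-((d_l - model$mu[1])^2 + (d_r - model$mu[2])^2) / (2 * model$sigma^2))
}

#' Consistency potential
#'
#' Binary factor tying the gripper scale to the search region: 1 iff both
#' gripper lengths are strictly less than half the ROI side, else the floor
#' `eps`.
#'
#' @param center,left,right `(x, y)` points.
#' @param roi a [roi()] (only `side` is used).
#' @param eps probability floor.
#' @return 1 or `eps`.
#' @export
consistency_potential <- function(center, left, right, roi, eps = 1e-6) {
  stopifnot(roi$side > 0)
  if (max(vnorm(left - center), vnorm(right - center)) < roi$side / 2) 1 else eps
}

#' Angle triple of a configuration
#'
#' Three unsigned angles in `[0, pi]` characterizing the articulation:
#' `theta1` between (left - center) and (shaft - center), `theta2` between
#' (right - center) and (shaft - center), `theta3` between (left - center) and
#' (right - center) (the gripper opening).
#'
#' @param left,center,right,shaft `(x, y)` points; `center` must be distinct
#'   from the other three.
#' @return numeric length-3 vector `(theta1, theta2, theta3)`.
#' @export
angle_triple <- function(left, center, right, shaft) {
  v_l <- left - center; v_r <- right - center; v_s <- shaft - center
  if (vnorm(v_l) == 0 || vnorm(v_r) == 0 || vnorm(v_s) == 0) {
    stop("degenerate configuration: a joint coincides with the center")
  }
  c(angle_between(v_l, v_s), angle_between(v_r, v_s), angle_between(v_l, v_r))
}

#' Two-state rotation model over angle triples
#'
#' One trivariate Gaussian for the (nearly) closed instrument, one for the
#' open instrument. Following the factor definition the two densities are
#' summed without mixture weights.
#'
#' @param mu_closed,mu_open length-3 mean angle triples (radians).
#' @param sigma_closed,sigma_open 3 x 3 positive-definite covariances.
#' @return object of class `rotation_model`.
#' @export
rotation_model <- function(mu_closed, sigma_closed, mu_open, sigma_open) {
  for (s in list(sigma_closed, sigma_open)) {
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("rotation covariance is not positive definite")
  }
  structure(list(mu = list(closed = as.numeric(mu_closed), open = as.numeric(mu_open)),
                 sigma = list(closed = sigma_closed, open = sigma_open)),
            class = "rotation_model")
}

# density of each component at its own mode (used by the confidence check)
rotation_mode_density <- function(model) {
  vapply(c("closed", "open"), function(nm)
    mclust::dmvnorm(matrix(model$mu[[nm]], 1), model$mu[[nm]], model$sigma[[nm]]),
    numeric(1))
}

#' Rotation potential
#'
#' Unweighted sum of the two component densities evaluated at the
#' configuration's angle triple.
#'
#' @param theta length-3 angle triple, or an n x 3 matrix of triples.
#' @param model a [rotation_model()].
#' @return non-negative density value(s).
#' @export
rotation_potential <- function(theta, model) {
  stopifnot(inherits(model, "rotation_model"))
  theta <- matrix(theta, ncol = 3)
  mclust::dmvnorm(theta, model$mu$closed, model$sigma$closed) +
    mclust::dmvnorm(theta, model$mu$open, model$sigma$open)
}

annotation_gripper_lengths <- function(annotations) {
  ann <- dplyr::filter(annotations, .data$present == 1L)
  tibble::tibble(
    d_left = sqrt((ann$left_x - ann$center_x)^2 + (ann$left_y - ann$center_y)^2),
    d_right = sqrt((ann$right_x - ann$center_x)^2 + (ann$right_y - ann$center_y)^2)
  )
}

annotation_angle_triples <- function(annotations) {
  ann <- dplyr::filter(annotations, .data$present == 1L)
  t(vapply(seq_len(nrow(ann)), function(i) {
    angle_triple(c(ann$left_x[i], ann$left_y[i]),
                 c(ann$center_x[i], ann$center_y[i]),
                 c(ann$right_x[i], ann$right_y[i]),
                 c(ann$shaft_x[i], ann$shaft_y[i]))
  }, numeric(3)))
}

#' Fit the relative-length model from annotations
#'
#' Sample means of the two gripper lengths and a pooled sample standard
#' deviation (shared across the two dimensions), floored at 1 px so
#' degenerate annotation sets stay usable.
#'
#' @param annotations annotation tibble (>= 2 present rows).
#' @return an [rlen_model()].
#' @export
fit_rlen_model <- function(annotations) {
  d <- annotation_gripper_lengths(annotations)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 annotations to fit the length model")
  mu <- c(mean(d$d_left), mean(d$d_right))
  pooled_var <- (sum((d$d_left - mu[1])^2) + sum((d$d_right - mu[2])^2)) /
    max(2 * n - 2, 1)
  rlen_model(mu, max(sqrt(pooled_var), 1))
}

#' Fit the two-state rotation model from labelled annotations
#'
#' Per-state sample mean and covariance of the angle triples, with a `lambda *
#' I` ridge on each covariance to guarantee positive definiteness.
#'
#' @param annotations annotation tibble with a `state` column (`"open"` /
#'   `"closed"`); at least 4 present rows per state.
#' @param lambda covariance ridge.
#' @return a [rotation_model()].
#' @export
fit_rotation_model <- function(annotations, lambda = 1e-4) {
  ann <- dplyr::filter(annotations, .data$present == 1L)
  fit_state <- function(state) {
    sub <- dplyr::filter(ann, .data$state == !!state)
    if (nrow(sub) < 4) {
      stop("need at least 4 annotations in state '", state, "' (have ",
           nrow(sub), ")")
    }
    th <- annotation_angle_triples(sub)
    list(mu = colMeans(th), sigma = stats::cov(th) + lambda * diag(3))
  }
  cl <- fit_state("closed"); op <- fit_state("open")
  rotation_model(cl$mu, cl$sigma, op$mu, op$sigma)
}

#' @export
tidy.rlen_model <- function(x, ...) {
  tibble::tibble(term = c("mu_left", "mu_right", "sigma"),
                 estimate = c(x$mu, x$sigma), unit = "px")
}

#' @export
tidy.rotation_model <- function(x, ...) {
  dplyr::bind_rows(lapply(c("closed", "open"), function(nm) {
    tibble::tibble(component = nm,
                   term = c("theta1", "theta2", "theta3"),
                   mean = x$mu[[nm]],
                   sd = sqrt(diag(x$sigma[[nm]])),
                   unit = "rad")
  }))
}

#' Serialize fitted priors to a YAML file
#'
#' Writes the relative-length and rotation models (units: px and radians) plus
#' the numerical-floor setting to a plain-text priors file; [read_priors()]
#' restores them.
#'
#' @param rlen an [rlen_model()].
#' @param rotation a [rotation_model()].
#' @param path output file.
#' @param eps probability floor recorded with the models.
#' @return `path`, invisibly.
#' @export
write_priors <- function(rlen, rotation, path, eps = 1e-6) {
  obj <- list(
    version = 1L, units = list(length = "px", angle = "rad"), eps = eps,
    rlen = list(mu = rlen$mu, sigma = rlen$sigma),
    rotation = list(
      closed = list(mu = rotation$mu$closed,
                    sigma = as.vector(rotation$sigma$closed)),
      open = list(mu = rotation$mu$open,
                  sigma = as.vector(rotation$sigma$open))
    )
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a priors file written by [write_priors()]
#' @param path priors YAML file.
#' @return list with `rlen`, `rotation`, `eps`.
#' @export
read_priors <- function(path) {
  obj <- yaml::read_yaml(path)
  list(
    rlen = rlen_model(unlist(obj$rlen$mu), obj$rlen$sigma),
    rotation = rotation_model(
      unlist(obj$rotation$closed$mu), matrix(unlist(obj$rotation$closed$sigma), 3),
      unlist(obj$rotation$open$mu), matrix(unlist(obj$rotation$open$sigma), 3)),
    eps = obj$eps
  )
}
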