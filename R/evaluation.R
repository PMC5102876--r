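#' Per-frame, per-joint error table
#'
#' Joins predictions and ground truth on `frame_id` and computes the Euclidean
#' error of each joint (px) plus the undirected shaft-orientation error in
#' degrees (the angle between the predicted and true center-to-shaft lines,
#' folded into `[0, 90]`). Frames the tracker reported missing while the
#' instrument was present count as failures (infinite error) so that
#' abstaining cannot inflate the scores; frames without ground truth are
#' marked not evaluable.
#'
#' @param predictions,ground_truth tibbles in the annotation schema
#'   (`frame_id, left_x, ..., shaft_y, present`).
#' @return tibble of class `joint_error_table`: `frame_id, evaluable,
#'   pred_present, left_err, right_err, center_err, shaft_err, angular_err_deg`.
#' @export
joint_error_table <- function(predictions, ground_truth) {
  common <- intersect(predictions$frame_id, ground_truth$frame_id)
  if (!length(common)) stop("predictions and ground truth share no frame_id")
  pr <- dplyr::arrange(dplyr::filter(predictions, .data$frame_id %in% common), .data$frame_id)
  gt <- dplyr::arrange(dplyr::filter(ground_truth, .data$frame_id %in% common), .data$frame_id)
  stopifnot(nrow(pr) == nrow(gt))
  jerr <- function(j) {
    e <- sqrt((pr[[paste0(j, "_x")]] - gt[[paste0(j, "_x")]])^2 +
                (pr[[paste0(j, "_y")]] - gt[[paste0(j, "_y")]])^2)
    ifelse(gt$present == 1L & pr$present == 0L, Inf, e)
  }
  ang <- vapply(seq_len(nrow(pr)), function(i) {
    if (gt$present[i] == 0L) return(NA_real_)
    if (pr$present[i] == 0L) return(Inf)
    vg <- c(gt$shaft_x[i] - gt$center_x[i], gt$shaft_y[i] - gt$center_y[i])
    vp <- c(pr$shaft_x[i] - pr$center_x[i], pr$shaft_y[i] - pr$center_y[i])
    if (vnorm(vg) == 0 || vnorm(vp) == 0) return(NA_real_)
    a <- angle_between(vg, vp) * 180 / pi
    min(a, 180 - a)   # undirected line orientation
  }, numeric(1))
  out <- tibble::tibble(
    frame_id = pr$frame_id,
    evaluable = gt$present == 1L,
    pred_present = pr$present == 1L,
    left_err = jerr("left"), right_err = jerr("right"),
    center_err = jerr("center"), shaft_err = jerr("shaft"),
    angular_err_deg = ang)
  class(out) <- c("joint_error_table", class(out))
  out
}

#' Accuracy-threshold curve for one joint
#'
#' Fraction of evaluable frames whose joint error is strictly below each
#' threshold; monotone non-decreasing in the threshold. The default grid
#' spans 20-80 px (the evaluation range used when the shaft is about 50 px
#' wide).
#'
#' @param errors a [joint_error_table()].
#' @param joint one of `"left"`, `"right"`, `"center"`, `"shaft"`.
#' @param thresholds px thresholds.
#' @return tibble of class `threshold_curve`: `joint, threshold, fraction`,
#'   with the number of excluded (non-evaluable) frames in the
#'   `"n_excluded"` attribute.
#' @export
accuracy_threshold_curve <- function(errors, joint = "center",
                                     thresholds = seq(20, 80, by = 10)) {
  joint <- match.arg(joint, c("left", "right", "center", "shaft"))
  ev <- dplyr::filter(errors, .data$evaluable)
  if (!nrow(ev)) stop("no evaluable frames")
  e <- ev[[paste0(joint, "_err")]]
  out <- tibble::tibble(joint = joint, threshold = thresholds,
                        fraction = vapply(thresholds, function(t) mean(e < t),
                                          numeric(1)))
  attr(out, "n_excluded") <- sum(!errors$evaluable)
  class(out) <- c("threshold_curve", class(out))
  out
}

#' Strict percentage of correct parts (PCP)
#'
#' A gripper part (center-to-left-tip or center-to-right-tip) is correct iff
#' BOTH its predicted endpoints lie within `alpha` times the ground-truth part
#' length of their true positions. Frames with a zero-length ground-truth part
#' are excluded and counted; missing predictions count as incorrect.
#'
#' @param predictions,ground_truth annotation-schema tibbles.
#' @param alpha relative tolerance (0.5 is the standard setting).
#' @return tibble `part, pcp, n_used, n_excluded` with `pcp` in `[0, 100]`.
#' @export
strict_pcp <- function(predictions, ground_truth, alpha = 0.5) {
  common <- intersect(predictions$frame_id, ground_truth$frame_id)
  if (!length(common)) stop("predictions and ground truth share no frame_id")
  pr <- dplyr::arrange(dplyr::filter(predictions, .data$frame_id %in% common), .data$frame_id)
  gt <- dplyr::arrange(dplyr::filter(ground_truth, .data$frame_id %in% common), .data$frame_id)
  gt_ev <- gt$present == 1L
  res <- lapply(c("left", "right"), function(tip) {
    len <- sqrt((gt[[paste0(tip, "_x")]] - gt$center_x)^2 +
                  (gt[[paste0(tip, "_y")]] - gt$center_y)^2)
    usable <- gt_ev & len > 0
    tol <- alpha * len
    e_tip <- sqrt((pr[[paste0(tip, "_x")]] - gt[[paste0(tip, "_x")]])^2 +
                    (pr[[paste0(tip, "_y")]] - gt[[paste0(tip, "_y")]])^2)
    e_ctr <- sqrt((pr$center_x - gt$center_x)^2 + (pr$center_y - gt$center_y)^2)
    correct <- pr$present == 1L & e_tip <= tol & e_ctr <= tol
    correct[is.na(correct)] <- FALSE
    tibble::tibble(part = tip,
                   pcp = 100 * sum(correct[usable]) / max(sum(usable), 1),
                   n_used = sum(usable),
                   n_excluded = sum(gt_ev & len == 0))
  })
  dplyr::bind_rows(res)
}

#' Angular-threshold curve for shaft orientation
#'
#' Fraction of evaluable frames whose undirected shaft-orientation deviation
#' is strictly below each threshold; default grid 3-24 degrees.
#'
#' @param errors a [joint_error_table()].
#' @param thresholds degree thresholds.
#' @return tibble of class `threshold_curve`: `joint = "shaft_orientation",
#'   threshold, fraction`.
#' @export
angular_threshold_curve <- function(errors, thresholds = seq(3, 24, by = 3)) {
  ev <- dplyr::filter(errors, .data$evaluable, !is.na(.data$angular_err_deg) |
                        !.data$pred_present)
  if (!nrow(ev)) stop("no evaluable frames with a defined shaft direction")
  a <- ev$angular_err_deg
  a[!ev$pred_present] <- Inf
  n_deg <- sum(is.na(a))
  a <- a[!is.na(a)]
  out <- tibble::tibble(joint = "shaft_orientation", threshold = thresholds,
                        fraction = vapply(thresholds, function(t) mean(a < t),
                                          numeric(1)))
  attr(out, "n_excluded") <- n_deg
  class(out) <- c("threshold_curve", class(out))
  out
}
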