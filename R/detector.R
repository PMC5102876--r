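#' Part labels
#'
#' The CRF has one random variable per instrument part; the detector adds one
#' background class, so the classifier always sees exactly five labels.
#' @return character vector of the five class labels in canonical order.
#' @export
part_labels <- function() c("left", "right", "center", "shaft", "background")

# canonical gene/part order used by every configuration-indexed structure
instrument_parts <- function() c("left", "center", "right", "shaft")

#' Mine HOG training patches from annotated frames
#'
#' Positives are patches centered within `r_pos` px of an annotated joint
#' (the exact joint plus jittered replicas); background negatives are sampled
#' uniformly at least `2 * r_pos` px away from every joint.
#'
#' @param images list of image matrices.
#' @param annotations tibble in the annotation schema (one row per image, in
#'   the same order); rows with `present == 0` contribute negatives only.
#' @param patch_size,bins,n_cells HOG parameters, see [extract_hog()].
#' @param r_pos positive-mining radius in px.
#' @param n_jitter jittered positive replicas per joint.
#' @param n_neg background patches per image.
#' @param seed integer seed for the jitter and negative draws.
#' @return list with `features` (matrix) and `labels` (factor over
#'   [part_labels()]).
#' @export
mine_training_patches <- function(images, annotations, patch_size = 50L,
                                  bins = 9L, n_cells = 5L, r_pos = 5,
                                  n_jitter = 4L, n_neg = 16L, seed = 1L) {
  stopifnot(length(images) == nrow(annotations))
  joints <- instrument_parts()
  withr::with_seed(seed, {
    feats <- list(); labs <- character(0)
    for (i in seq_along(images)) {
      img <- images[[i]]
      ctx <- hog_context(img, bins = bins, patch_size = patch_size)
      h <- nrow(img); w <- ncol(img)
      ann <- annotations[i, ]
      centers <- NULL; lab_i <- character(0)
      jpts <- NULL
      if (ann$present == 1L) {
        for (jn in joints) {
          p <- c(ann[[paste0(jn, "_x")]], ann[[paste0(jn, "_y")]])
          jpts <- rbind(jpts, p)
          reps <- rbind(p, matrix(p, n_jitter, 2, byrow = TRUE) +
                          matrix(stats::runif(2 * n_jitter, -r_pos, r_pos), n_jitter, 2))
          reps[, 1] <- pmin(pmax(reps[, 1], 0), w - 1)
          reps[, 2] <- pmin(pmax(reps[, 2], 0), h - 1)
          centers <- rbind(centers, reps)
          lab_i <- c(lab_i, rep(jn, nrow(reps)))
        }
      }
      # negatives: uniform, rejected if within 2*r_pos of any joint
      neg <- matrix(stats::runif(4 * n_neg * 2), ncol = 2) *
        matrix(c(w - 1, h - 1), 4 * n_neg, 2, byrow = TRUE)
      if (!is.null(jpts)) {
        d2min <- apply(neg, 1, function(p) min(colSums((t(jpts) - p)^2)))
        neg <- neg[d2min >= (2 * r_pos)^2, , drop = FALSE]
      }
      neg <- neg[seq_len(min(n_neg, nrow(neg))), , drop = FALSE]
      centers <- rbind(centers, neg)
      lab_i <- c(lab_i, rep("background", nrow(neg)))
      feats[[i]] <- hog_features_at(ctx, centers, patch_size, bins, n_cells)
      labs <- c(labs, lab_i)
    }
    list(features = do.call(rbind, feats),
         labels = factor(labs, levels = part_labels()))
  })
}

#' Train the multi-class part detection forest
#'
#' A probability random forest over HOG descriptors with one class per
#' instrument part plus background. Per-tree class probabilities are exposed so
#' the unary confidence is exactly the mean over trees.
#'
#' @param features numeric matrix, one descriptor per row.
#' @param labels factor with levels [part_labels()]; every class must occur.
#' @param n_trees number of trees `T`.
#' @param max_depth maximum tree depth.
#' @param seed integer seed for reproducible training.
#' @param patch_size,bins,n_cells HOG parameters embedded in the model so
#'   detection uses the same descriptor.
#' @return object of class `forest_model`.
#' @export
train_forest <- function(features, labels, n_trees = 50L, max_depth = 25L,
                         seed = 1L, patch_size = 50L, bins = 9L, n_cells = 5L) {
  stopifnot(n_trees >= 1)
  labels <- factor(labels, levels = part_labels())
  missing <- setdiff(part_labels(), levels(droplevels(labels)))
  if (length(missing)) {
    stop("training data lacks class(es): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(features)
  df$.class <- labels
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, max.depth = max_depth, probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(
    list(forest = fit, n_trees = n_trees, max_depth = max_depth,
         patch_size = patch_size, bins = bins, n_cells = n_cells,
         classes = part_labels(), feature_length = ncol(features),
         version = 1L),
    class = "forest_model"
  )
}

#' Average per-tree class probabilities
#'
#' The unary confidence of a hypothesis is the arithmetic mean over trees of
#' the per-tree class probabilities: `(1/T) * sum_j pi_j(x)`.
#'
#' @param per_tree_probs `T x C` matrix (or `n x C x T` array) of per-tree
#'   class probabilities.
#' @return named probability vector over classes (or `n x C` matrix), summing
#'   to 1.
#' @export
unary_confidence <- function(per_tree_probs) {
  if (is.matrix(per_tree_probs)) return(colMeans(per_tree_probs))
  stopifnot(length(dim(per_tree_probs)) == 3)
  apply(per_tree_probs, c(1, 2), mean)
}

#' Per-class probabilities from a trained forest
#'
#' @param model a `forest_model`.
#' @param features descriptor matrix (rows) or single descriptor vector.
#' @param per_tree if `TRUE`, also return the raw `n x C x T` per-tree array.
#' @return `n x C` probability matrix (columns in [part_labels()] order), or a
#'   list with `probs` and `per_tree` when `per_tree = TRUE`.
#' @export
forest_confidence <- function(model, features, per_tree = FALSE) {
  stopifnot(inherits(model, "forest_model"))
  if (is.vector(features)) features <- matrix(features, 1)
  if (ncol(features) != model$feature_length) {
    stop("feature length ", ncol(features), " does not match model (",
         model$feature_length, ")")
  }
  df <- as.data.frame(features)
  if (per_tree) {
    pr <- stats::predict(model$forest, df, predict.all = TRUE,
                         num.threads = 1)$predictions
    probs <- unary_confidence(pr)
    colnames(probs) <- dimnames(pr)[[2]]
    probs <- probs[, part_labels(), drop = FALSE]
    return(list(probs = probs, per_tree = pr))
  }
  probs <- stats::predict(model$forest, df, num.threads = 1)$predictions
  probs[, part_labels(), drop = FALSE]
}

#' Temporal proximity prior
#'
#' Scores a hypothesis by its distance to the corresponding part of the
#' previous pose: `exp(-d^2 / (2 * sigma^2))`, strictly decreasing in the
#' distance and 1 only at zero distance. `sigma = 1` gives the literal
#' unit-variance kernel `exp(-d^2 / 2)`; the default `sigma = 20` px keeps the
#' prior informative at video resolution.
#'
#' @param position,previous `(x, y)` points, or n x 2 matrices.
#' @param sigma distance scale in px.
#' @return probability in `(0, 1]` (vectorized over rows).
#' @export
temporal_score <- function(position, previous, sigma = 20) {
  position <- matrix(position, ncol = 2)
  previous <- matrix(previous, ncol = 2)
  stopifnot(all(is.finite(position)), all(is.finite(previous)), sigma > 0)
  d2 <- (position[, 1] - previous[, 1])^2 + (position[, 2] - previous[, 2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Scan a region of interest for part hypotheses
#'
#' Evaluates the forest on a stride grid inside the ROI and keeps every grid
#' position whose probability for a non-background class reaches `min_conf`.
#' Empty groups are legal and meaningful: the tracker reacts to them by
#' expanding the ROI.
#'
#' @param image image matrix.
#' @param roi a [roi()] (clipped to the image when used).
#' @param model a `forest_model`.
#' @param stride grid step in px.
#' @param min_conf minimum class probability to keep a hypothesis.
#' @param max_per_part keep at most this many highest-confidence hypotheses
#'   per part (caps the inference search space).
#' @return tibble `label, x, y, confidence`, grouped conceptually by label;
#'   zero rows for a part mean no detection.
#' @export
detect_hypotheses <- function(image, roi, model, stride = 4L, min_conf = 0.5,
                              max_per_part = 25L) {
  stopifnot(inherits(model, "forest_model"), stride >= 1)
  h <- nrow(image); w <- ncol(image)
  half <- roi$side / 2
  x0 <- max(0, ceiling(roi$center[1] - half)); x1 <- min(w - 1, floor(roi$center[1] + half))
  y0 <- max(0, ceiling(roi$center[2] - half)); y1 <- min(h - 1, floor(roi$center[2] + half))
  if (x0 > x1 || y0 > y1) stop("ROI does not intersect the image")
  gx <- seq(x0, x1, by = stride); gy <- seq(y0, y1, by = stride)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  ctx <- hog_context(image, bins = model$bins, patch_size = model$patch_size)
  feats <- hog_features_at(ctx, grid, model$patch_size, model$bins, model$n_cells)
  probs <- forest_confidence(model, feats)
  out <- lapply(instrument_parts(), function(lb) {
    p <- probs[, lb]
    keep <- which(p >= min_conf)
    if (!length(keep)) return(NULL)
    keep <- keep[order(p[keep], decreasing = TRUE)]
    keep <- keep[seq_len(min(max_per_part, length(keep)))]
    tibble::tibble(label = lb, x = grid[keep, 1], y = grid[keep, 2],
                   confidence = p[keep])
  })
  empty <- tibble::tibble(label = character(0), x = numeric(0),
                          y = numeric(0), confidence = numeric(0))
  dplyr::bind_rows(c(list(empty), out))
}

#' @export
glance.forest_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, max_depth = x$max_depth,
                 patch_size = x$patch_size, hog_bins = x$bins,
                 n_cells = x$n_cells, feature_length = x$feature_length,
                 oob_error = x$forest$prediction.error)
}
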