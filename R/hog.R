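#' @title Histogram-of-oriented-gradients patch descriptors
#' @description
#' Patch descriptor used by the part detector: gradient orientations (unsigned,
#' `[0, pi)`) are hard-binned into `bins` orientation bins, per-bin gradient
#' magnitude is summed over an `n_cells x n_cells` grid covering the square
#' patch, and the concatenated histogram is L2-normalized. Constant patches
#' yield the all-zero descriptor. Dense scanning uses one integral image per
#' orientation bin so extracting thousands of patch descriptors per frame costs
#' a handful of rectangle sums each.
#' @name hog
NULL

# Reflect-pad a matrix by `pad` pixels on every side.
reflect_pad <- function(m, pad) {
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(pad) + 1L), seq_len(h), h - seq_len(pad))
  cidx <- c(rev(seq_len(pad) + 1L), seq_len(w), w - seq_len(pad))
  m[ridx, cidx, drop = FALSE]
}

# Central-difference gradients; replicated borders.
image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  xr <- img[, c(2:w, w), drop = FALSE]; xl <- img[, c(1, 1:(w - 1)), drop = FALSE]
  yd <- img[c(2:h, h), , drop = FALSE]; yu <- img[c(1, 1:(h - 1)), , drop = FALSE]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

# Precompute per-orientation-bin integral images over the reflect-padded frame.
# extract_hog()/hog_features_at() read cell sums from these in O(1).
hog_context <- function(image, bins = 9L, patch_size = 50L) {
  stopifnot(bins >= 2)
  pad <- ceiling(patch_size / 2) + 1L
  pimg <- reflect_pad(image, pad)
  g <- image_gradients(pimg)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ori <- atan2(g$gy, g$gx) %% pi            # unsigned orientation in [0, pi)
  bin <- pmin(floor(ori / (pi / bins)), bins - 1L) + 1L
  h <- nrow(pimg); w <- ncol(pimg)
  integrals <- vector("list", bins)
  for (b in seq_len(bins)) {
    ch <- mag * (bin == b)
    ii <- apply(apply(ch, 2, cumsum), 1, cumsum)  # transposed double cumsum
    ii <- t(ii)
    integrals[[b]] <- rbind(0, cbind(0, ii))      # zero-padded for rect sums
  }
  list(integrals = integrals, bins = bins, pad = pad,
       image_size = dim(image))
}

# Rectangle sums from a zero-padded integral image. r1/c1/r2/c2 are 1-based
# inclusive bounds into the original (padded) matrix; all vectorized.
rect_sum <- function(ii, r1, c1, r2, c2) {
  n <- nrow(ii)
  ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
    ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
}

#' Extract HOG descriptors at many patch centers
#'
#' @param ctx context from `hog_context()` (internal) or an image matrix, in
#'   which case the context is built on the fly.
#' @param centers n x 2 matrix of `(x, y)` patch centers, 0-based pixel
#'   coordinates inside the image.
#' @param patch_size square patch side in px.
#' @param bins orientation bins.
#' @param n_cells cells per patch side; descriptor length is
#'   `n_cells^2 * bins`.
#' @return n x (n_cells^2 * bins) matrix, each row an L2-normalized descriptor.
#' @export
hog_features_at <- function(ctx, centers, patch_size = 50L, bins = 9L,
                            n_cells = 5L) {
  if (is.matrix(ctx)) {
    ctx <- hog_context(ctx, bins = bins, patch_size = patch_size)
  }
  stopifnot(bins == ctx$bins)
  centers <- matrix(centers, ncol = 2)
  h <- ctx$image_size[1]; w <- ctx$image_size[2]
  if (any(centers[, 1] < 0 | centers[, 1] > w - 1 |
            centers[, 2] < 0 | centers[, 2] > h - 1)) {
    stop("patch center outside image bounds")
  }
  pad <- ctx$pad
  half <- floor(patch_size / 2)
  # top-left of patch in padded 1-based coordinates
  tlc <- round(centers[, 1]) - half + pad + 1L
  tlr <- round(centers[, 2]) - half + pad + 1L
  edges <- round(seq(0, patch_size, length.out = n_cells + 1))
  n <- nrow(centers)
  feat <- matrix(0, n, n_cells^2 * ctx$bins)
  k <- 0L
  for (cy in seq_len(n_cells)) {
    for (cx in seq_len(n_cells)) {
      r1 <- tlr + edges[cy]; r2 <- tlr + edges[cy + 1] - 1L
      c1 <- tlc + edges[cx]; c2 <- tlc + edges[cx + 1] - 1L
      for (b in seq_len(ctx$bins)) {
        k <- k + 1L
        feat[, k] <- rect_sum(ctx$integrals[[b]], r1, c1, r2, c2)
      }
    }
  }
  nrm <- sqrt(rowSums(feat^2))
  nz <- nrm > 1e-12
  feat[nz, ] <- feat[nz, , drop = FALSE] / nrm[nz]
  feat
}

#' Extract a single HOG descriptor
#'
#' @param image numeric H x W matrix in `[0, 1]`.
#' @param center `(x, y)` patch center, 0-based, inside the image.
#' @inheritParams hog_features_at
#' @return numeric descriptor of length `n_cells^2 * bins`, entries >= 0.
#' @export
extract_hog <- function(image, center, patch_size = 50L, bins = 9L,
                        n_cells = 5L) {
  ctx <- hog_context(image, bins = bins, patch_size = patch_size)
  drop(hog_features_at(ctx, matrix(center, 1), patch_size, bins, n_cells))
}
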