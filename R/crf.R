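#' Fitness context for CRF inference
#'
#' Bundles everything one inference call needs: per-part hypothesis sets with
#' unary confidences, the optional previous pose (temporal prior), the binary
#' edge map, the fitted kinematic priors, the ROI and the numerical floor.
#' Connectivity values and configuration fitnesses are memoized inside the
#' context, so repeated evaluation of the same pair or configuration is free.
#'
#' @param hypotheses tibble `label, x, y, confidence` (see
#'   [detect_hypotheses()]); every instrument part should have at least one
#'   row for inference to run.
#' @param edges an [edge_map()] of the current frame.
#' @param rlen an [rlen_model()].
#' @param rotation a [rotation_model()].
#' @param roi the [roi()] the hypotheses were detected in.
#' @param prev_pose optional named list of `(x, y)` points
#'   (`left`, `center`, `right`, `shaft`) from the last confident frame; when
#'   `NULL` (first frame) the temporal factor is 1 for every hypothesis.
#' @param eps probability floor shared by all factors.
#' @param dp_grid control-offset grid for the connectivity potential (`NULL`
#'   uses the chord-proportional default).
#' @param temporal_sigma scale of the temporal prior, px.
#' @param use named list of logical flags (`conf`, `temp`, `conn`, `rlen`,
#'   `cons`, `rot`) enabling factor families; disabled families contribute
#'   log(1) = 0 (ablation support).
#' @return object of class `fitness_context`.
#' @export
fitness_context <- function(hypotheses, edges, rlen, rotation, roi,
                            prev_pose = NULL, eps = 1e-6, dp_grid = NULL,
                            temporal_sigma = 20, use = list()) {
  use <- utils::modifyList(
    list(conf = TRUE, temp = TRUE, conn = TRUE, rlen = TRUE, cons = TRUE,
         rot = TRUE), use)
  parts <- instrument_parts()
  pos <- list(); conf <- list(); temp <- list()
  for (p in parts) {
    sub <- hypotheses[hypotheses$label == p, , drop = FALSE]
    pos[[p]] <- cbind(sub$x, sub$y)
    conf[[p]] <- sub$confidence
    temp[[p]] <- if (is.null(prev_pose) || nrow(sub) == 0) {
      rep(1, nrow(sub))
    } else {
      temporal_score(pos[[p]], matrix(prev_pose[[p]], nrow(sub), 2, byrow = TRUE),
                     sigma = temporal_sigma)
    }
  }
  memo <- new.env(parent = emptyenv())
  n_l <- nrow(pos$left); n_c <- nrow(pos$center); n_r <- nrow(pos$right)
  memo$conn_lc <- matrix(NA_real_, max(n_l, 1), max(n_c, 1))
  memo$conn_rc <- matrix(NA_real_, max(n_r, 1), max(n_c, 1))
  memo$fitness <- new.env(parent = emptyenv(), size = 4096L)
  structure(
    list(pos = pos, conf = conf, temp = temp, sizes = vapply(pos, nrow, 1L),
         edges = edges, rlen = rlen, rotation = rotation, roi = roi,
         prev_pose = prev_pose, eps = eps, dp_grid = dp_grid,
         temporal_sigma = temporal_sigma, use = use, memo = memo),
    class = "fitness_context"
  )
}

# fill and read the memoized connectivity between left/right tips and center
ctx_connectivity <- function(ctx, side, i_tip, i_center) {
  slot <- if (side == "left") "conn_lc" else "conn_rc"
  m <- ctx$memo[[slot]]
  key <- cbind(i_tip, i_center)
  todo <- which(is.na(m[key]))
  if (length(todo)) {
    tip_pos <- ctx$pos[[side]]; c_pos <- ctx$pos$center
    for (j in todo) {
      it <- i_tip[j]; ic <- i_center[j]
      if (!is.na(m[it, ic])) next
      yi <- tip_pos[it, ]; yj <- c_pos[ic, ]
      m[it, ic] <- if (all(yi == yj)) ctx$eps else
        translation_potential(yi, yj, ctx$edges, ctx$dp_grid, ctx$eps)
    }
    ctx$memo[[slot]] <- m
  }
  m[key]
}

factor_names <- function() {
  c("conf_left", "conf_center", "conf_right", "conf_shaft",
    "temp_left", "temp_center", "temp_right", "temp_shaft",
    "conn_left_center", "conn_right_center", "rlen", "cons", "rot")
}

# Vectorized log-posterior over an n x 4 index matrix (left, center, right,
# shaft). Returns list(total, logs) where logs is n x 13 per-factor log
# scores. Single source of truth for the fitness; log_posterior(),
# exhaustive_infer() and ga_infer() all route through here.
ctx_fitness_batch <- function(ctx, idx) {
  idx <- matrix(as.integer(idx), ncol = 4)
  n <- nrow(idx)
  parts <- instrument_parts()
  for (k in seq_len(4)) {
    p <- c("left", "center", "right", "shaft")[k]
    col <- idx[, k]
    if (any(col < 1 | col > ctx$sizes[[p]])) {
      stop("configuration refers to a ", p,
           " hypothesis outside the context's hypothesis set")
    }
  }
  eps <- ctx$eps
  logs <- matrix(0, n, length(factor_names()),
                 dimnames = list(NULL, factor_names()))
  L <- ctx$pos$left[idx[, 1], , drop = FALSE]
  C <- ctx$pos$center[idx[, 2], , drop = FALSE]
  R <- ctx$pos$right[idx[, 3], , drop = FALSE]
  S <- ctx$pos$shaft[idx[, 4], , drop = FALSE]
  if (ctx$use$conf) {
    logs[, "conf_left"] <- log(pmax(ctx$conf$left[idx[, 1]], eps))
    logs[, "conf_center"] <- log(pmax(ctx$conf$center[idx[, 2]], eps))
    logs[, "conf_right"] <- log(pmax(ctx$conf$right[idx[, 3]], eps))
    logs[, "conf_shaft"] <- log(pmax(ctx$conf$shaft[idx[, 4]], eps))
  }
  if (ctx$use$temp) {
    logs[, "temp_left"] <- log(pmax(ctx$temp$left[idx[, 1]], eps))
    logs[, "temp_center"] <- log(pmax(ctx$temp$center[idx[, 2]], eps))
    logs[, "temp_right"] <- log(pmax(ctx$temp$right[idx[, 3]], eps))
    logs[, "temp_shaft"] <- log(pmax(ctx$temp$shaft[idx[, 4]], eps))
  }
  if (ctx$use$conn) {
    logs[, "conn_left_center"] <- log(ctx_connectivity(ctx, "left", idx[, 1], idx[, 2]))
    logs[, "conn_right_center"] <- log(ctx_connectivity(ctx, "right", idx[, 3], idx[, 2]))
  }
  d_l <- sqrt(rowSums((L - C)^2)); d_r <- sqrt(rowSums((R - C)^2))
  if (ctx$use$rlen) {
    v <- exp(-((d_l - ctx$rlen$mu[1])^2 + (d_r - ctx$rlen$mu[2])^2) /
               (2 * ctx$rlen$sigma^2))
    logs[, "rlen"] <- log(pmax(v, eps))
  }
  if (ctx$use$cons) {
    ok <- pmax(d_l, d_r) < ctx$roi$side / 2
    logs[, "cons"] <- log(ifelse(ok, 1, eps))
  }
  if (ctx$use$rot) {
    d_s <- sqrt(rowSums((S - C)^2))
    ok <- d_l > 0 & d_r > 0 & d_s > 0
    rotv <- rep(eps, n)
    if (any(ok)) {
      cl <- function(z) pmin(pmax(z, -1), 1)
      vl <- L - C; vr <- R - C; vs <- S - C
      th <- cbind(acos(cl(rowSums(vl * vs)[ok] / (d_l[ok] * d_s[ok]))),
                  acos(cl(rowSums(vr * vs)[ok] / (d_r[ok] * d_s[ok]))),
                  acos(cl(rowSums(vl * vr)[ok] / (d_l[ok] * d_r[ok]))))
      rotv[ok] <- pmax(rotation_potential(th, ctx$rotation), eps)
    }
    logs[, "rot"] <- log(rotv)
  }
  list(total = rowSums(logs), logs = logs)
}

# cached per-configuration fitness (scalar per row)
ctx_fitness_cached <- function(ctx, idx) {
  idx <- matrix(as.integer(idx), ncol = 4)
  keys <- paste(idx[, 1], idx[, 2], idx[, 3], idx[, 4], sep = "_")
  cache <- ctx$memo$fitness
  vals <- vapply(keys, function(k) {
    v <- cache[[k]]; if (is.null(v)) NA_real_ else v
  }, numeric(1), USE.NAMES = FALSE)
  miss <- which(is.na(vals))
  if (length(miss)) {
    um <- !duplicated(keys[miss])
    ui <- miss[um]
    tot <- ctx_fitness_batch(ctx, idx[ui, , drop = FALSE])$total
    for (j in seq_along(ui)) cache[[keys[ui[j]]]] <- tot[j]
    vals[miss] <- vapply(keys[miss], function(k) cache[[k]], numeric(1),
                         USE.NAMES = FALSE)
  }
  vals
}

config_coord_vector <- function(ctx, idx) {
  c(ctx$pos$left[idx[1], ], ctx$pos$center[idx[2], ],
    ctx$pos$right[idx[3], ], ctx$pos$shaft[idx[4], ])
}

# TRUE if coordinate vector of a is lexicographically before b
lex_before <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Unnormalized log posterior of a configuration
#'
#' Sum of the logs of every active factor: per-part forest confidence and
#' temporal prior, the two tip-to-center connectivity potentials, the
#' relative-length, consistency and rotation potentials. The partition
#' function is constant in the configuration and omitted; every factor is
#' floored at the context's `eps`, so the result is always finite.
#'
#' @param config named integer vector or list with elements `left`, `center`,
#'   `right`, `shaft` indexing the context's hypothesis sets.
#' @param ctx a [fitness_context()].
#' @param breakdown if `TRUE`, attach the per-factor log scores as the
#'   `"factor_logs"` attribute.
#' @return scalar log posterior (up to the constant `log Z`).
#' @export
log_posterior <- function(config, ctx, breakdown = FALSE) {
  idx <- config_indices(config)
  res <- ctx_fitness_batch(ctx, matrix(idx, 1))
  out <- res$total
  if (breakdown) attr(out, "factor_logs") <- res$logs[1, ]
  out
}

config_indices <- function(config) {
  if (is.list(config)) config <- unlist(config[c("left", "center", "right", "shaft")])
  if (!is.null(names(config))) config <- config[c("left", "center", "right", "shaft")]
  if (length(config) != 4 || any(is.na(config))) {
    stop("a configuration needs integer indices for left, center, right, shaft")
  }
  as.integer(config)
}

pose_estimate <- function(ctx, idx, trace = NULL, converged = NA) {
  res <- ctx_fitness_batch(ctx, matrix(idx, 1))
  pts <- rbind(ctx$pos$left[idx[1], ], ctx$pos$center[idx[2], ],
               ctx$pos$right[idx[3], ], ctx$pos$shaft[idx[4], ])
  structure(
    list(
      configuration = tibble::tibble(
        part = c("left", "center", "right", "shaft"),
        x = pts[, 1], y = pts[, 2],
        confidence = c(ctx$conf$left[idx[1]], ctx$conf$center[idx[2]],
                       ctx$conf$right[idx[3]], ctx$conf$shaft[idx[4]])),
      indices = stats::setNames(idx, c("left", "center", "right", "shaft")),
      log_fitness = res$total,
      factor_logs = res$logs[1, ],
      confidence_ok = NA,
      trace = trace, converged = converged
    ),
    class = "pose_estimate"
  )
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat("<pose_estimate> log fitness", format(x$log_fitness, digits = 6),
      if (isTRUE(x$confidence_ok)) "(confident)" else
        if (isFALSE(x$confidence_ok)) "(low confidence)" else "", "\n")
  print(x$configuration)
  invisible(x)
}

#' @export
tidy.pose_estimate <- function(x, ...) x$configuration

#' @export
glance.pose_estimate <- function(x, ...) {
  tibble::tibble(log_fitness = x$log_fitness,
                 confidence_ok = x$confidence_ok,
                 converged = x$converged,
                 generations = if (is.null(x$trace)) NA_integer_ else nrow(x$trace))
}

#' Exhaustive MAP inference (test oracle)
#'
#' Enumerates every configuration in the hypothesis product space and returns
#' the global maximizer of [log_posterior()]. Ties are broken
#' lexicographically on the coordinate vector
#' `(left_x, left_y, center_x, ..., shaft_y)`.
#'
#' @param ctx a [fitness_context()].
#' @param max_space refuse product spaces larger than this.
#' @return a `pose_estimate`.
#' @export
exhaustive_infer <- function(ctx, max_space = 200000L) {
  sizes <- ctx$sizes
  if (any(sizes == 0)) {
    return(missing_parts_result(names(sizes)[sizes == 0]))
  }
  space <- prod(as.numeric(sizes))
  if (space > max_space) {
    stop("configuration space of size ", space, " exceeds max_space (",
         max_space, "); use ga_infer() instead")
  }
  idx <- as.matrix(expand.grid(left = seq_len(sizes["left"]),
                               center = seq_len(sizes["center"]),
                               right = seq_len(sizes["right"]),
                               shaft = seq_len(sizes["shaft"])))
  tot <- ctx_fitness_batch(ctx, idx)$total
  cand <- which(tot == max(tot))
  if (length(cand) > 1) {
    coords <- t(vapply(cand, function(i) config_coord_vector(ctx, idx[i, ]),
                       numeric(8)))
    cand <- cand[do.call(order, as.data.frame(coords))[1]]
  }
  pose_estimate(ctx, idx[cand, ])
}

missing_parts_result <- function(parts) {
  structure(list(missing = parts), class = "missing_parts")
}

#' Single-cut crossover over the gene order (left, center, right, shaft)
#'
#' Offspring swap the gene suffix after `cut_index`; applying the same
#' crossover twice recovers the parents.
#'
#' @param parent_a,parent_b length-4 integer configurations (named or in gene
#'   order).
#' @param cut_index integer in 1..3.
#' @return list of two offspring configurations (named integer vectors).
#' @export
crossover <- function(parent_a, parent_b, cut_index) {
  stopifnot(cut_index %in% 1:3)
  a <- config_indices(parent_a); b <- config_indices(parent_b)
  head_idx <- seq_len(cut_index); tail_idx <- (cut_index + 1):4
  nm <- c("left", "center", "right", "shaft")
  list(stats::setNames(c(a[head_idx], b[tail_idx]), nm),
       stats::setNames(c(b[head_idx], a[tail_idx]), nm))
}

# per-label neighbor lists within the mutation radius (self excluded)
build_neighborhoods <- function(ctx, radius) {
  lapply(instrument_parts(), function(p) {
    pos <- ctx$pos[[p]]
    n <- nrow(pos)
    lapply(seq_len(n), function(i) {
      d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
      setdiff(which(d2 <= radius^2), i)
    })
  }) |> stats::setNames(instrument_parts())
}

#' Mutate a configuration
#'
#' Each gene is independently replaced, with probability `rate`, by another
#' same-label hypothesis within `neighborhood_radius` px of its current
#' position (falling back to any other same-label hypothesis when the
#' neighborhood is empty; genes with no alternative stay put). Uses the
#' current RNG stream.
#'
#' @param config length-4 integer configuration.
#' @param ctx a [fitness_context()].
#' @param rate per-gene mutation probability in `[0, 1]`.
#' @param neighborhood_radius radius in px.
#' @return mutated configuration (named integer vector).
#' @export
mutate_config <- function(config, ctx, rate = 0.1, neighborhood_radius = 20) {
  stopifnot(rate >= 0, rate <= 1)
  idx <- config_indices(config)
  nbh <- build_neighborhoods(ctx, neighborhood_radius)
  for (k in seq_len(4)) {
    p <- instrument_parts()[k]
    if (stats::runif(1) < rate) {
      cand <- nbh[[p]][[idx[k]]]
      if (!length(cand)) cand <- setdiff(seq_len(ctx$sizes[[p]]), idx[k])
      if (length(cand)) idx[k] <- cand[sample.int(length(cand), 1)]
    }
  }
  stats::setNames(idx, instrument_parts())
}

#' Simulate a random small fitness context
#'
#' Draws a random inference problem: a smooth random image thresholded into an
#' edge map, `n_per_part` random hypotheses per part with random confidences,
#' randomized kinematic priors and (half the time) a random previous pose.
#' Used to exercise MAP inference against the exhaustive oracle on spaces
#' small enough to enumerate.
#'
#' @param seed integer seed; the context is a pure function of it.
#' @param n_per_part hypotheses per part (scalar or length-4, gene order).
#' @param image_size `(H, W)` of the synthetic edge image.
#' @return a [fitness_context()].
#' @export
simulate_fitness_context <- function(seed, n_per_part = 4L,
                                     image_size = c(80, 80)) {
  n <- rep(n_per_part, length.out = 4)
  withr::with_seed(seed, {
    img <- EBImage::gblur(matrix(stats::runif(prod(image_size)),
                                 image_size[1]), sigma = 3)
    edges <- edge_map(img, "otsu")
    parts <- instrument_parts()
    hyps <- dplyr::bind_rows(lapply(seq_len(4), function(k) {
      tibble::tibble(label = parts[k],
                     x = stats::runif(n[k], 5, image_size[2] - 6),
                     y = stats::runif(n[k], 5, image_size[1] - 6),
                     confidence = stats::runif(n[k], 0.05, 1))
    }))
    rlen <- rlen_model(stats::runif(2, 10, 25), stats::runif(1, 2, 8))
    rot <- rotation_model(
      c(pi, pi, 0.05) + stats::rnorm(3, 0, 0.02), diag(3) * stats::runif(1, 0.02, 0.1)^2,
      c(pi - 0.3, pi - 0.3, 0.6) + stats::rnorm(3, 0, 0.05), diag(3) * stats::runif(1, 0.05, 0.2)^2)
    prev <- if (stats::runif(1) < 0.5) {
      lapply(stats::setNames(parts, parts), function(p)
        c(stats::runif(1, 5, image_size[2] - 6), stats::runif(1, 5, image_size[1] - 6)))
    } else NULL
    fitness_context(hyps, edges, rlen, rot, init_roi(image_size),
                    prev_pose = prev)
  })
}

#' Genetic-algorithm MAP inference
#'
#' Maximizes [log_posterior()] over the hypothesis product space: a random
#' initial population, pairwise single-cut crossover, neighborhood mutation,
#' tournament selection with elitism, and an elitist memory that always
#' retains the best configuration ever evaluated. Terminates after `n_iter`
#' generations or as soon as the best fitness has not improved over two
#' successive generations.
#'
#' @param ctx a [fitness_context()].
#' @param pop_size population size.
#' @param n_iter maximum generations.
#' @param mutation_rate per-gene mutation probability.
#' @param neighborhood_radius mutation neighborhood, px.
#' @param elite_frac fraction of the population carried over unchanged.
#' @param tournament_size tournament size for parent selection.
#' @param seed integer seed; the result is a pure function of (context, seed).
#' @return a `pose_estimate` (with a per-generation best-fitness `trace`), or
#'   a `missing_parts` object when some part has no hypothesis — a typed
#'   outcome the tracker consumes, not an error.
#' @export
ga_infer <- function(ctx, pop_size = 1000L, n_iter = 50L, mutation_rate = 0.1,
                     neighborhood_radius = 20, elite_frac = 0.05,
                     tournament_size = 4L, seed = 1L) {
  sizes <- ctx$sizes
  if (any(sizes == 0)) {
    return(missing_parts_result(names(sizes)[sizes == 0]))
  }
  if (all(sizes == 1)) {
    return(pose_estimate(ctx, rep(1L, 4),
                         trace = tibble::tibble(generation = 0L,
                                                best = ctx_fitness_cached(ctx, matrix(1L, 1, 4))),
                         converged = TRUE))
  }
  nbh <- build_neighborhoods(ctx, neighborhood_radius)
  parts <- instrument_parts()
  withr::with_seed(seed, {
    pop <- vapply(parts, function(p) sample.int(sizes[[p]], pop_size, replace = TRUE),
                  integer(pop_size))
    fit <- ctx_fitness_cached(ctx, pop)
    best_i <- which.max(fit)
    best_idx <- pop[best_i, ]
    best_fit <- fit[best_i]
    trace <- list(tibble::tibble(generation = 0L, best = best_fit))
    stall <- 0L
    converged <- FALSE
    n_elite <- max(1L, ceiling(elite_frac * pop_size))
    for (gen in seq_len(n_iter)) {
      ord <- order(fit, decreasing = TRUE)
      elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      n_children <- pop_size - n_elite
      n_pairs <- ceiling(n_children / 2)
      pick <- function() {
        cand <- sample.int(pop_size, tournament_size, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      children <- matrix(0L, 2 * n_pairs, 4)
      for (pr in seq_len(n_pairs)) {
        pa <- pop[pick(), ]; pb <- pop[pick(), ]
        off <- crossover(pa, pb, sample.int(3, 1))
        children[2 * pr - 1, ] <- off[[1]]
        children[2 * pr, ] <- off[[2]]
      }
      children <- children[seq_len(n_children), , drop = FALSE]
      # neighborhood mutation, vectorized per gene column
      for (k in seq_len(4)) {
        p <- parts[k]
        hit <- which(stats::runif(n_children) < mutation_rate)
        for (i in hit) {
          cand <- nbh[[p]][[children[i, k]]]
          if (!length(cand)) cand <- setdiff(seq_len(sizes[[p]]), children[i, k])
          if (length(cand)) children[i, k] <- cand[sample.int(length(cand), 1)]
        }
      }
      pop <- rbind(elites, children)
      fit <- ctx_fitness_cached(ctx, pop)
      gi <- which.max(fit)
      improved <- fit[gi] > best_fit + 1e-12
      if (improved) {
        best_fit <- fit[gi]; best_idx <- pop[gi, ]; stall <- 0L
      } else {
        if (fit[gi] >= best_fit - 1e-12) {
          # equal-fitness tie: prefer the lexicographically smaller coordinates
          ca <- config_coord_vector(ctx, pop[gi, ])
          cb <- config_coord_vector(ctx, best_idx)
          if (lex_before(ca, cb)) best_idx <- pop[gi, ]
        }
        stall <- stall + 1L
      }
      trace[[gen + 1L]] <- tibble::tibble(generation = gen, best = best_fit)
      if (stall >= 2L) { converged <- TRUE; break }
    }
    pose_estimate(ctx, best_idx, trace = dplyr::bind_rows(trace),
                  converged = converged)
  })
}
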