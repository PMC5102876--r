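test_that("edge maps threshold the gradient magnitude", {
  flat <- matrix(0.4, 50, 50)
  em <- edge_map(flat, 0)
  expect_true(all(em$mask == 0))

  img <- matrix(0.4, 50, 50); img[20, 20] <- 0.9
  expect_gt(sum(edge_map(img, 0)$mask), 0)

  # vertical step of height h: Sobel x-response is 4h in the two columns
  # flanking the step and 0 elsewhere
  step <- matrix(0, 40, 40); step[, 21:40] <- 0.5
  em2 <- edge_map(step, 4 * 0.5 * 0.9)
  on <- which(em2$mask == 1, arr.ind = TRUE)
  expect_true(all(on[, 2] %in% c(20, 21)))
  expect_gt(nrow(on), 0)
})

test_that("curve tracing matches the quadratic Bezier closed form", {
  # straight horizontal segment rasterizes to exactly its 11 pixels
  tc <- trace_curve(bezier_spec(c(0, 0), c(10, 0), 0))
  expect_equal(tc, cbind(0:10, rep(0, 11)), ignore_attr = TRUE)

  # curve midpoint lies at (p0 + 2P + p2) / 4
  p0 <- c(5, 5); p2 <- c(45, 15); dp <- 8
  ctrl <- forcepspose:::bezier_control(p0, p2, dp)
  mid <- (p0 + 2 * ctrl + p2) / 4
  tc2 <- trace_curve(bezier_spec(p0, p2, dp))
  d <- sqrt((tc2[, 1] - mid[1])^2 + (tc2[, 2] - mid[2])^2)
  expect_lt(min(d), 1)

  # mirrored offset mirrors the curve across the chord (here the x-axis)
  up <- trace_curve(bezier_spec(c(0, 10), c(40, 10), 6))
  dn <- trace_curve(bezier_spec(c(0, 10), c(40, 10), -6))
  expect_equal(up[, 1], dn[, 1])
  expect_equal(up[, 2] - 10, -(dn[, 2] - 10))

  expect_error(trace_curve(bezier_spec(c(1, 1), c(1, 1), 0)), "coincident")
})

test_that("connectivity scores follow the segment-square algebra", {
  eps <- 1e-6
  k <- 21
  curve <- cbind(0:(k - 1), rep(5, k))
  full <- edge_fixture(matrix(1, 20, 40))
  expect_equal(curve_connectivity(full, curve, eps), 1)

  blank <- edge_fixture(matrix(0, 20, 40))
  expect_equal(curve_connectivity(blank, curve, eps), eps)

  # two runs of 8 separated by gaps: (8^2 + 8^2) / 21^2
  mask <- matrix(0, 20, 40)
  mask[6, 1:8] <- 1; mask[6, 12:19] <- 1
  two <- edge_fixture(mask)
  expect_equal(curve_connectivity(two, curve, eps), (64 + 64) / k^2)

  # a single long run beats the same pixels fragmented
  mask2 <- matrix(0, 20, 40)
  mask2[6, 1:16] <- 1
  expect_gt(curve_connectivity(edge_fixture(mask2), curve, eps),
            curve_connectivity(two, curve, eps))
})

test_that("merging adjacent runs never decreases connectivity", {
  set.seed(31)
  k <- 40
  curve <- cbind(0:(k - 1), rep(3, k))
  for (rep in 1:20) {
    on <- runif(k) < 0.5
    mask <- matrix(0, 10, k)
    mask[4, which(on)] <- 1
    base <- curve_connectivity(edge_fixture(mask), curve)
    # fill one random gap -> merges (or extends) runs
    gaps <- which(!on)
    if (!length(gaps)) next
    mask[4, sample(gaps, 1)] <- 1
    expect_gte(curve_connectivity(edge_fixture(mask), curve), base)
  }
})

test_that("translation potential maximizes over the curve family", {
  mask <- matrix(0, 30, 60)
  mask[15, 6:55] <- 1
  edges <- edge_fixture(mask)
  yi <- c(5, 14); yj <- c(55, 14)
  straight <- curve_connectivity(edges, trace_curve(bezier_spec(yi, yj, 0)))
  expect_equal(translation_potential(yi, yj, edges, dp_grid = 0), straight)

  # monotone under grid inclusion
  g1 <- translation_potential(yi, yj, edges, dp_grid = c(-5, 0))
  g2 <- translation_potential(yi, yj, edges, dp_grid = c(-5, 0, 5))
  expect_gte(g2, g1)
  expect_gte(g2, straight)

  blank <- edge_fixture(matrix(0, 30, 60))
  expect_equal(translation_potential(yi, yj, blank, dp_grid = c(-3, 0, 3)), 1e-6)
})

test_that("a bowed synthetic arm is best matched by its own curvature", {
  g <- forceps_geometry(center = c(160, 120), shaft_angle = 0, opening_angle = 0.8,
                        arm_curvature = 0.25)
  sc <- scene_config(background_kind = "flat", blur_sigma = 0, noise_sigma = 0,
                     rng_seed = 1)
  fr <- render_frame(g, sc)
  edges <- edge_map(fr$image, 0.05)
  j <- forceps_joints(g)
  # the renderer bows the left arm by +curvature * arm_length along the
  # chord orthogonal; that offset should beat the mirrored one
  dp <- g$arm_curvature * g$arm_length
  conn_match <- curve_connectivity(edges, trace_curve(bezier_spec(j$center, j$left, dp)))
  conn_mirror <- curve_connectivity(edges, trace_curve(bezier_spec(j$center, j$left, -dp)))
  expect_gt(conn_match, conn_mirror)
  best <- translation_potential(j$center, j$left, edges, dp_grid = c(-dp, 0, dp))
  expect_equal(best, conn_match)
})

test_that("relative-length potential peaks at the fitted mean", {
  m <- rlen_model(c(20, 25), 4)
  ctr <- c(0, 0)
  expect_equal(relative_length_potential(ctr, c(20, 0), c(0, 25), m), 1)
  expect_equal(relative_length_potential(ctr, c(24, 0), c(0, 25), m),
               exp(-1 / 2))
  # symmetric model is invariant under swapping the tips
  ms <- rlen_model(c(22, 22), 3)
  a <- c(18, 0); b <- c(0, 27)
  expect_equal(relative_length_potential(ctr, a, b, ms),
               relative_length_potential(ctr, b, a, ms))
})

test_that("consistency potential enforces the strict half-side cutoff", {
  r <- roi(c(50, 50), side = 40)
  eps <- 1e-6
  ctr <- c(50, 50)
  expect_equal(consistency_potential(ctr, ctr + c(10, 0), ctr + c(0, 10), r, eps), 1)
  expect_equal(consistency_potential(ctr, ctr + c(40, 0), ctr + c(0, 10), r, eps), eps)
  # exactly side/2 fails the strict inequality
  expect_equal(consistency_potential(ctr, ctr + c(20, 0), ctr + c(0, 10), r, eps), eps)
})

test_that("angle triples follow planar trigonometry", {
  ctr <- c(0, 0); shaft <- c(-40, 0)
  left <- 50 * c(cos(0.3), sin(0.3))
  right <- 50 * c(cos(-0.3), sin(-0.3))
  th <- angle_triple(left, ctr, right, shaft)
  expect_equal(th, c(pi - 0.3, pi - 0.3, 0.6), tolerance = 1e-12)

  # near-closed forceps: tiny opening angle
  th2 <- angle_triple(c(50, 0.5), ctr, c(50, -0.5), shaft)
  expect_lt(th2[3], 0.05)

  # mirroring across the shaft axis leaves the unsigned triple unchanged
  mirror <- function(p) c(p[1], -p[2])
  th3 <- angle_triple(mirror(left), ctr, mirror(right), mirror(shaft))
  expect_equal(sort(th3[1:2]), sort(th[1:2]), tolerance = 1e-12)
  expect_equal(th3[3], th[3], tolerance = 1e-12)

  expect_error(angle_triple(ctr, ctr, right, shaft), "degenerate")
})

test_that("rotation potential is the unweighted two-component density sum", {
  s <- 0.1
  m <- rotation_model(c(pi, pi, 0.02), diag(3) * s^2,
                      c(2, 2, 1.2), diag(3) * s^2)
  # at a component mean with the other far away: (2*pi)^(-3/2) * s^(-3)
  v <- rotation_potential(c(pi, pi, 0.02), m)
  expect_equal(v, (2 * pi)^(-3 / 2) / s^3, tolerance = 1e-6)
  # value at a mode is at least the single-component mode density
  expect_gte(v, (2 * pi)^(-3 / 2) / s^3 - 1e-9)
  # identical components double the density
  m2 <- rotation_model(c(2, 2, 1), diag(3) * s^2, c(2, 2, 1), diag(3) * s^2)
  expect_equal(rotation_potential(c(2.05, 2, 1), m2),
               2 * mclust::dmvnorm(matrix(c(2.05, 2, 1), 1), c(2, 2, 1),
                                   diag(3) * s^2),
               tolerance = 1e-12)
  expect_error(rotation_model(c(0, 0, 0), matrix(0, 3, 3), c(1, 1, 1), diag(3)),
               "positive definite")
})

test_that("length-model fitting recovers generator parameters", {
  # two annotations with d_left 10 and 14 -> mu_left 12
  ann <- tibble::tibble(
    frame_id = 0:1, center_x = 0, center_y = 0,
    left_x = c(10, 14), left_y = 0, right_x = 0, right_y = c(11, 13),
    shaft_x = -20, shaft_y = 0, present = 1L, state = "open")
  m <- fit_rlen_model(ann)
  expect_equal(m$mu, c(12, 12))
  expect_error(fit_rlen_model(ann[1, ]), "at least 2")

  # identical annotations: mu exact, sigma at the 1 px floor
  m2 <- fit_rlen_model(ann[c(1, 1), ])
  expect_equal(m2$mu, c(10, 11))
  expect_equal(m2$sigma, 1)

  # parameter recovery on simulated annotations (arm length 60 +/- jitter)
  ann3 <- sample_annotations(150, seed = 31, ranges = list(arm_length = c(59, 61)))
  m3 <- fit_rlen_model(ann3)
  expect_lt(max(abs(m3$mu - 60)), 2)
})

test_that("rotation-model fitting recovers per-state angle clusters", {
  ann <- sample_annotations(200, seed = 33)
  m <- fit_rotation_model(ann)
  # generator opening angles: closed ~ U(0, 0.08), open ~ U(0.25, 0.9);
  # theta3 equals the opening angle, theta1 = theta2 = pi - opening/2
  expect_lt(abs(m$mu$closed[3] - 0.04), 0.05)
  expect_lt(abs(m$mu$open[3] - 0.575), 0.05)
  expect_lt(abs(m$mu$open[1] - (pi - 0.575 / 2)), 0.05)

  # all-identical closed samples: exact mean, ridge-only covariance
  one <- ann[ann$state == "open", ][1, ]
  same <- dplyr::bind_rows(one, one, one, one)
  same$state <- "closed"
  both <- dplyr::bind_rows(same, ann[ann$state == "open", ][1:10, ])
  mf <- fit_rotation_model(both)
  th <- forcepspose:::annotation_angle_triples(same)
  expect_equal(mf$mu$closed, colMeans(th), tolerance = 1e-12)
  expect_equal(mf$sigma$closed, 1e-4 * diag(3), ignore_attr = TRUE)

  # swapping the state labels swaps components; the density sum is unchanged
  flipped <- dplyr::mutate(ann, state = ifelse(state == "open", "closed", "open"))
  m2 <- fit_rotation_model(flipped)
  expect_equal(m2$mu$closed, m$mu$open)
  expect_equal(m2$mu$open, m$mu$closed)
  th0 <- c(3, 3, 0.3)
  expect_equal(rotation_potential(th0, m2), rotation_potential(th0, m), tolerance = 1e-12)

  expect_error(fit_rotation_model(ann[ann$state == "open", ]), "closed")
})

test_that("priors round-trip through the YAML file", {
  ann <- sample_annotations(60, seed = 41)
  rl <- fit_rlen_model(ann); rot <- fit_rotation_model(ann)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_priors(rl, rot, path, eps = 1e-6)
  back <- read_priors(path)
  expect_equal(back$rlen$mu, rl$mu)
  expect_equal(back$rlen$sigma, rl$sigma)
  expect_equal(back$rotation$mu$open, rot$mu$open)
  expect_equal(back$rotation$sigma$closed, rot$sigma$closed, ignore_attr = TRUE)
  expect_equal(back$eps, 1e-6)
})
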