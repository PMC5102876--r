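test_that("log posterior is the sum of the per-factor logs", {
  eps <- 1e-6
  # all factors at 1: full edge coverage, lengths at the model mean, angles at
  # a rotation mode rescaled to contribute its mode value, no previous pose
  ctr <- c(30, 30); left <- c(50, 36); right <- c(50, 24); shaft <- c(10, 30)
  d <- forcepspose:::vnorm(left - ctr)
  th <- angle_triple(left, ctr, right, shaft)
  rot <- rotation_model(th, diag(3) * 0.1^2, c(0.5, 0.5, 2), diag(3) * 0.1^2)
  ctx <- simple_context(
    hyp(c("left", "center", "right", "shaft"),
        c(left[1], ctr[1], right[1], shaft[1]),
        c(left[2], ctr[2], right[2], shaft[2])),
    rlen = rlen_model(c(d, d), 5), rotation = rot)
  lp <- log_posterior(c(left = 1, center = 1, right = 1, shaft = 1), ctx,
                      breakdown = TRUE)
  logs <- attr(lp, "factor_logs")
  expect_equal(as.numeric(lp), sum(logs), tolerance = 1e-9)
  # conf/temp/conn/rlen/cons all exactly 1 -> zero logs
  zero_names <- setdiff(names(logs), "rot")
  expect_equal(unname(logs[zero_names]), rep(0, length(zero_names)), tolerance = 1e-9)
  expect_equal(logs[["rot"]], log(rotation_potential(th, rot)), tolerance = 1e-9)

  # single factor at eps: blank edge map drives both connectivity factors to eps
  ctx2 <- simple_context(
    hyp(c("left", "center", "right", "shaft"),
        c(left[1], ctr[1], right[1], shaft[1]),
        c(left[2], ctr[2], right[2], shaft[2])),
    rlen = rlen_model(c(d, d), 5), rotation = rot,
    edges = edge_fixture(matrix(0, 60, 60)))
  lp2 <- log_posterior(c(left = 1, center = 1, right = 1, shaft = 1), ctx2,
                       breakdown = TRUE)
  expect_equal(attr(lp2, "factor_logs")[["conn_left_center"]], log(1e-6))
  expect_equal(as.numeric(lp2 - lp), 2 * log(1e-6), tolerance = 1e-9)
})

test_that("the posterior matches factor-by-factor hand computation", {
  set.seed(19)
  ctx <- simulate_fitness_context(19, n_per_part = 2)
  idx <- c(left = 2L, center = 1L, right = 2L, shaft = 1L)
  lp <- log_posterior(idx, ctx, breakdown = TRUE)
  pt <- function(p, i) ctx$pos[[p]][i, ]
  left <- pt("left", 2); ctr <- pt("center", 1)
  right <- pt("right", 2); shaft <- pt("shaft", 1)
  hand <- log(ctx$conf$left[2]) + log(ctx$conf$center[1]) +
    log(ctx$conf$right[2]) + log(ctx$conf$shaft[1]) +
    sum(log(pmax(c(
      if (is.null(ctx$prev_pose)) rep(1, 4) else c(
        temporal_score(left, ctx$prev_pose$left),
        temporal_score(ctr, ctx$prev_pose$center),
        temporal_score(right, ctx$prev_pose$right),
        temporal_score(shaft, ctx$prev_pose$shaft))), 1e-6))) +
    log(translation_potential(left, ctr, ctx$edges)) +
    log(translation_potential(right, ctr, ctx$edges)) +
    log(max(relative_length_potential(ctr, left, right, ctx$rlen), 1e-6)) +
    log(consistency_potential(ctr, left, right, ctx$roi)) +
    log(max(rotation_potential(angle_triple(left, ctr, right, shaft),
                               ctx$rotation), 1e-6))
  expect_equal(as.numeric(lp), hand, tolerance = 1e-9)
})

test_that("disabling a factor family changes the score by its stored log", {
  ctx_all <- simulate_fitness_context(23, n_per_part = 3)
  idx <- c(left = 1L, center = 2L, right = 3L, shaft = 1L)
  lp_all <- log_posterior(idx, ctx_all, breakdown = TRUE)
  logs <- attr(lp_all, "factor_logs")
  for (fam in c("rot", "rlen", "cons")) {
    ctx_off <- simulate_fitness_context(23, n_per_part = 3)
    ctx_off$use[[fam]] <- FALSE
    lp_off <- log_posterior(idx, ctx_off)
    expect_equal(as.numeric(lp_all - lp_off), logs[[fam]], tolerance = 1e-9)
  }
})

test_that("configurations outside the hypothesis sets are rejected", {
  ctx <- simulate_fitness_context(3, n_per_part = 2)
  expect_error(log_posterior(c(left = 3L, center = 1L, right = 1L, shaft = 1L), ctx),
               "left")
})

test_that("exhaustive inference matches a naive quadruple loop", {
  ctx <- simulate_fitness_context(29, n_per_part = 3)
  best <- -Inf; best_idx <- NULL
  for (l in 1:3) for (c in 1:3) for (r in 1:3) for (s in 1:3) {
    v <- log_posterior(c(left = l, center = c, right = r, shaft = s), ctx)
    if (v > best) { best <- v; best_idx <- c(l, c, r, s) }
  }
  pe <- exhaustive_infer(ctx)
  expect_equal(pe$log_fitness, best, tolerance = 1e-12)
  expect_error(exhaustive_infer(ctx, max_space = 10), "ga_infer")
})

test_that("exhaustive inference picks the larger of two configurations", {
  # two near-identical left candidates differing essentially in confidence
  h <- hyp(c("left", "left", "center", "right", "shaft"),
           c(10, 10.5, 30, 50, 5), c(30, 30.5, 30, 30, 30),
           c(0.9, 0.2, 1, 1, 1))
  ctx <- simple_context(h)
  pe <- exhaustive_infer(ctx)
  expect_identical(unname(pe$indices["left"]), 1L)
})

test_that("crossover interleaves gene suffixes and is an involution", {
  a <- c(left = 1L, center = 2L, right = 3L, shaft = 4L)
  b <- c(left = 5L, center = 6L, right = 7L, shaft = 8L)
  off <- crossover(a, b, 2)
  expect_identical(off[[1]], c(left = 1L, center = 2L, right = 7L, shaft = 8L))
  expect_identical(off[[2]], c(left = 5L, center = 6L, right = 3L, shaft = 4L))
  # cut at 3 swaps only the shaft gene
  off3 <- crossover(a, b, 3)
  expect_identical(off3[[1]], c(left = 1L, center = 2L, right = 3L, shaft = 8L))
  # identical parents are fixed points
  same <- crossover(a, a, 1)
  expect_identical(same[[1]], a)
  # applying the same crossover twice recovers the parents
  back <- crossover(off[[1]], off[[2]], 2)
  expect_identical(back[[1]], a)
  expect_identical(back[[2]], b)
})

test_that("mutation respects rate, radius and availability", {
  ctx <- simulate_fitness_context(31, n_per_part = 2)
  cfg <- c(left = 1L, center = 1L, right = 1L, shaft = 1L)
  expect_identical(withr::with_seed(1, mutate_config(cfg, ctx, rate = 0)), cfg)
  # rate 1 with a single hypothesis per part cannot move
  ctx1 <- simulate_fitness_context(31, n_per_part = 1)
  one <- c(left = 1L, center = 1L, right = 1L, shaft = 1L)
  expect_identical(withr::with_seed(1, mutate_config(one, ctx1, rate = 1)), one)
  # rate 1, infinite radius, two hypotheses per part: every gene flips
  flipped <- withr::with_seed(1, mutate_config(cfg, ctx, rate = 1,
                                               neighborhood_radius = Inf))
  expect_identical(unname(flipped), rep(2L, 4))
})

test_that("GA returns the single configuration of a singleton space", {
  ctx <- simulate_fitness_context(37, n_per_part = 1)
  pe <- ga_infer(ctx, seed = 1)
  expect_s3_class(pe, "pose_estimate")
  expect_equal(pe$log_fitness,
               log_posterior(c(left = 1L, center = 1L, right = 1L, shaft = 1L), ctx))
})

test_that("an empty hypothesis set yields a typed missing-parts outcome", {
  ctx <- simulate_fitness_context(41, n_per_part = c(2, 0, 2, 2))
  out <- ga_infer(ctx, seed = 1)
  expect_s3_class(out, "missing_parts")
  expect_identical(out$missing, "center")
  out2 <- exhaustive_infer(ctx)
  expect_s3_class(out2, "missing_parts")
})

test_that("GA best fitness is monotone across generations and never beats the oracle", {
  for (seed in 1:10) {
    ctx <- simulate_fitness_context(100 + seed, n_per_part = 3)
    pe <- ga_infer(ctx, pop_size = 60, n_iter = 15, seed = seed)
    expect_true(all(diff(pe$trace$best) >= 0))
    opt <- exhaustive_infer(simulate_fitness_context(100 + seed, n_per_part = 3))
    expect_lte(pe$log_fitness, opt$log_fitness + 1e-9)
  }
})

test_that("GA is deterministic under a fixed seed and invariant to hypothesis order", {
  ctx_a <- simulate_fitness_context(55, n_per_part = 3)
  ctx_b <- simulate_fitness_context(55, n_per_part = 3)
  p1 <- ga_infer(ctx_a, pop_size = 80, seed = 7)
  p2 <- ga_infer(ctx_b, pop_size = 80, seed = 7)
  expect_identical(p1$indices, p2$indices)
  expect_equal(p1$log_fitness, p2$log_fitness)

  # permuting each part's hypothesis list leaves the attained optimum
  # unchanged (small space: GA reaches the global optimum; ties broken
  # lexicographically on coordinates)
  ctx <- simulate_fitness_context(56, n_per_part = 3)
  hyps <- dplyr::bind_rows(lapply(instrument_labels <- c("left", "center", "right", "shaft"),
    function(p) {
      pos <- ctx$pos[[p]]
      tibble::tibble(label = p, x = pos[, 1], y = pos[, 2],
                     confidence = ctx$conf[[p]])
    }))
  perm <- dplyr::arrange(hyps, dplyr::desc(x))
  ctx_perm <- fitness_context(perm, ctx$edges, ctx$rlen, ctx$rotation, ctx$roi,
                              prev_pose = ctx$prev_pose)
  f1 <- ga_infer(ctx, pop_size = 120, seed = 3)$log_fitness
  f2 <- ga_infer(ctx_perm, pop_size = 120, seed = 3)$log_fitness
  expect_equal(f1, f2, tolerance = 1e-9)
})
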