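# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Moderate-size trained detector + priors for module-level tests.
trained_models <- function() {
  fixture("models", function() {
    sc <- scene_config(rng_seed = 11)
    ds <- sample_training_set(80, sc, seed = 3)
    tp <- mine_training_patches(ds$images, ds$annotations, seed = 5)
    forest <- train_forest(tp$features, tp$labels, seed = 9)
    list(forest = forest,
         rlen = fit_rlen_model(ds$annotations),
         rotation = fit_rotation_model(ds$annotations),
         dataset = ds)
  })
}

# Full-size models under the default study conditions (acceptance tests).
acceptance_models <- function() {
  fixture("acc_models", function() {
    cfg <- default_config()
    sc <- scene_config(cfg$synth$image_size, cfg$synth$background_kind,
                       cfg$synth$illumination_gain, cfg$synth$blur_sigma,
                       cfg$synth$noise_sigma, rng_seed = 101)
    ds <- sample_training_set(cfg$synth$n_train, sc, seed = 103,
                              closed_frac = cfg$synth$closed_frac)
    tp <- mine_training_patches(ds$images, ds$annotations, seed = 107)
    forest <- train_forest(tp$features, tp$labels,
                           n_trees = cfg$detector$n_trees,
                           max_depth = cfg$detector$max_depth, seed = 109)
    list(forest = forest,
         rlen = fit_rlen_model(ds$annotations),
         rotation = fit_rotation_model(ds$annotations))
  })
}

# Edge-map fixture with an exactly known mask (no dilation slack), for the
# connectivity algebra tests.
edge_fixture <- function(mask) {
  structure(list(mask = mask * 1L, dilated = mask > 0, threshold = 0),
            class = "edge_map")
}

# Hypothesis tibble helper
hyp <- function(label, x, y, confidence = 1) {
  tibble::tibble(label = label, x = x, y = y, confidence = confidence)
}

# A minimal rotation model with isotropic covariances
iso_rotation_model <- function(mu1 = c(pi - 0.3, pi - 0.3, 0.6),
                               mu2 = c(pi, pi, 0.02), s = 0.1) {
  rotation_model(mu2, diag(3) * s^2, mu1, diag(3) * s^2)
}

# Context over explicit hypothesis sets with permissive models: flat priors
# unless overridden, an all-edge map, full-frame ROI.
simple_context <- function(hyps, image_size = c(60, 60), rlen = NULL,
                           rotation = NULL, edges = NULL, roi_side = NULL,
                           prev_pose = NULL, use = list(), eps = 1e-6) {
  if (is.null(rlen)) rlen <- rlen_model(c(20, 20), 5)
  if (is.null(rotation)) rotation <- iso_rotation_model(s = 0.3)
  if (is.null(edges)) edges <- edge_fixture(matrix(1, image_size[1], image_size[2]))
  r <- if (is.null(roi_side)) init_roi(image_size) else
    roi(c(image_size[2] / 2, image_size[1] / 2), roi_side)
  fitness_context(hyps, edges, rlen, rotation, r, prev_pose = prev_pose,
                  eps = eps, use = use)
}
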