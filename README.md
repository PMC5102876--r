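# forcepspose

Detection, tracking and pose estimation of a two-armed surgical forceps in
video frames, for researchers building instrument-aware imaging pipelines
(e.g. steering OCT scan lines to the instrument tips during retinal
microsurgery) and for anyone who needs a fully reproducible, synthetic-data
testbed for part-based instrument pose estimation.

## The model

The instrument pose is a configuration **y** = (y_L, y_C, y_R, y_S) — left
tip, center joint, right tip and a point on the shaft centerline — where each
part position is drawn from a discrete hypothesis set Λ_i proposed by a
part detector. Pose estimation is MAP inference in a conditional random
field:

    p(y | x, P) ∝ ∏_i Φ^Conf(y_i, x) · Φ^Temp(y_i, P_i)
                 · Ψ^Conn(y_L, y_C) · Ψ^Conn(y_R, y_C)
                 · Ψ^RLen(y_C, y_L, y_R) · Ψ^Cons(y_C, y_L, y_R)
                 · Ψ^Rot(y_L, y_C, y_R, y_S)

* **Φ^Conf** — probability random forest (50 trees, depth 25) on HOG
  descriptors of 50×50 patches; five classes (four parts + background); the
  confidence is the mean of the per-tree class probabilities.
* **Φ^Temp** = exp(−‖y_i − P_i‖² / 2σ_t²) — proximity to the previous pose.
* **Ψ^Conn** — edge connectivity along a family of quadratic Bézier curves
  joining tip and center hypotheses: each rasterized curve scores
  Σ_j |s_j|² / k² over its maximal edge-pixel runs s_j (k = curve length) on a
  thresholded Sobel edge map, and the potential takes the best curve.
* **Ψ^RLen** — peak-normalized bivariate Gaussian on the two gripper lengths,
  fitted from annotations.
* **Ψ^Cons** — 1 if both gripper lengths are strictly under half the
  search-region side, else a small floor ε.
* **Ψ^Rot** — sum of two trivariate Gaussians over the configuration's angle
  triple (closed-state and open-state components, fitted from labelled
  annotations).

Inference is a seeded genetic algorithm over the hypothesis product space
(population 1000, single-cut crossover, neighborhood mutation, elitism),
with `exhaustive_infer()` as an exact oracle on small spaces. Tracking runs
detection inside a square ROI that recenters on confident poses and grows
geometrically on failure, so the tracker recovers from instrument
disappearance without any manual reinitialization.

Everything is trainable and testable without external data: a synthetic scene
generator renders a bright shaft splitting into two Bézier gripper arms over
flat / textured / vessel-cluttered backgrounds and emits exact ground-truth
joints. See `vignettes/forcepspose-methods.Rmd` for the full account.

## Worked example

```r
library(forcepspose)

# render a labelled training set and fit detector + kinematic priors
scene <- scene_config(rng_seed = 11)
train <- sample_training_set(120, scene, seed = 3)
patches <- mine_training_patches(train$images, train$annotations, seed = 5)
forest <- train_forest(patches$features, patches$labels, seed = 9)
priors <- list(rlen = fit_rlen_model(train$annotations),
               rotation = fit_rotation_model(train$annotations))
tidy(priors$rlen)
#> # A tibble: 3 × 3
#>   term     estimate unit
#>   <chr>       <dbl> <chr>
#> 1 mu_left     55.0  px
#> 2 mu_right    55.0  px
#> 3 sigma        1.73 px

# track a fresh 20-frame sequence
geom <- forceps_geometry(center = c(130, 120), shaft_angle = 0.2, opening_angle = 0.4)
seq <- generate_sequence(geom, scene_config(rng_seed = 321), n_frames = 20,
                         motion = list(center = c(2, 0.5), opening_angle = 0.005))
track <- track_sequence(seq$frames, forest, priors, config = list(seed = 5))
glance(track)
#> # A tibble: 1 × 4
#>   n_frames n_present n_confident mean_roi_side
#>      <int>     <int>       <int>         <dbl>
#> 1       20        20          20          225.

# evaluate against the exact ground truth
errors <- joint_error_table(track, seq$annotations)
strict_pcp(track, seq$annotations, alpha = 0.5)
#> # A tibble: 2 × 4
#>   part    pcp n_used n_excluded
#>   <chr> <dbl>  <int>      <int>
#> 1 left    100     20          0
#> 2 right   100     20          0
accuracy_threshold_curve(errors, "center", c(5, 10, 20))
#> # A tibble: 3 × 3
#>   joint  threshold fraction
#>   <chr>      <dbl>    <dbl>
#> 1 center         5        1
#> 2 center        10        1
#> 3 center        20        1
angular_threshold_curve(errors, c(3, 6, 12))
#> # A tibble: 3 × 3
#>   joint             threshold fraction
#>   <chr>                 <dbl>    <dbl>
#> 1 shaft_orientation         3     0.85
#> 2 shaft_orientation         6     1
#> 3 shaft_orientation        12     1
```

The fitted mean gripper length (55 px) matches the generator's 52–58 px arm
range; every frame is tracked confidently, both gripper parts score a strict
PCP of 100 at α = 0.5, the center joint is always within 5 px, and the shaft
orientation is within 3° in 85% of frames (within 6° in all of them).
`autoplot()` methods visualize threshold curves and tracking traces, and
`plot_pose()` overlays a pose on a frame.

There is also a command-line wrapper (`inst/cli/forcepspose.R`) exposing
`simulate`, `train`, `track` and `evaluate` subcommands over the same
functions, plus `cmd_simulate()` / `cmd_train()` / `cmd_track()` /
`cmd_evaluate()` in R.

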