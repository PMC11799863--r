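# Shared fixtures, cached per test run.  Coarse polygonization (4.5 mm)
# keeps mesh sizes desk-scale; geometric assertions hold at this
# resolution.
.fixture_cache <- new.env(parent = emptyenv())

test_femur <- function(seed = 7, resolution_mm = 4.5) {
  key <- sprintf("femur_%d_%g", seed, resolution_mm)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_femur(seed = seed,
                                            resolution_mm = resolution_mm)
  .fixture_cache[[key]]
}

# axis-aligned landmark set used across frame/planning tests:
# epicondyles on +/-x, shaft along +z, trochlea anterior (+y)
axis_aligned_landmarks <- function() {
  landmark_set(
    medial_epicondyle = c(-40, 0, 0),
    lateral_epicondyle = c(40, 0, 0),
    shaft_axis_point_distal = c(0, 0, 0),
    shaft_axis_point_proximal = c(0, 0, 100),
    most_anterior_trochlea = c(0, 30, 0)
  )
}

axis_aligned_frame <- function(side = "lateral") {
  build_frame(axis_aligned_landmarks(), side, "right")
}

random_rigid <- function() {
  rigid_transform(rotation_about_axis(rnorm(3), runif(1, -180, 180)),
                  rnorm(3, sd = 20))
}

# independent brute-force oracle for segment-segment distance:
# evaluates |p1 + s d1 - p2 - t d2| on an n x n parameter grid via outer
# sums of the quadratic's separable terms
segment_distance_bruteforce <- function(p1, d1, L1, p2, d2, L2, n = 2000) {
  s <- seq(0, L1, length.out = n)
  t <- seq(0, L2, length.out = n)
  r <- p1 - p2
  A <- sum(r * r) + 2 * s * sum(r * d1) + s^2          # n-vector in s
  B <- -2 * t * sum(r * d2) + t^2                      # n-vector in t
  Cst <- -2 * sum(d1 * d2) * outer(s, t)               # cross term
  sqrt(min(outer(A, B, "+") + Cst))
}

unitize_test <- function(v) v / sqrt(sum(v^2))

# cached small noiseless end-to-end run shared by several tests
test_sim_small <- function() {
  if (is.null(.fixture_cache$sim_small))
    .fixture_cache$sim_small <- simulate_study(
      n_knees_per_group = 1, seed = 19, noise_sd = 0, resolution_mm = 4.5)
  .fixture_cache$sim_small
}

transform_landmarks <- function(landmarks, transform) {
  lm <- lapply(unclass(landmarks), function(p) apply_transform(transform, p))
  do.call(landmark_set, lm)
}
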