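test_that("axis-aligned landmark sets give the canonical frame axes", {
  fr_lat <- axis_aligned_frame("lateral")
  expect_equal(fr_lat$ml, c(-1, 0, 0))
  expect_equal(fr_lat$ap, c(0, 1, 0))
  expect_equal(fr_lat$si, c(0, 0, 1))
  expect_equal(fr_lat$origin, c(40, 0, 0))

  # medial frame flips only the ML sense and the origin
  fr_med <- axis_aligned_frame("medial")
  expect_equal(fr_med$ml, c(1, 0, 0))
  expect_equal(fr_med$ap, c(0, 1, 0))
  expect_equal(fr_med$origin, c(-40, 0, 0))
})

test_that("frames are orthonormal with |det| = 1 on jittered anatomy", {
  set.seed(21)
  for (i in 1:20) {
    lm <- landmark_set(
      medial_epicondyle = c(-40, 0, 0) + rnorm(3, sd = 5),
      lateral_epicondyle = c(40, 0, 0) + rnorm(3, sd = 5),
      shaft_axis_point_distal = rnorm(3, sd = 3),
      shaft_axis_point_proximal = c(0, 0, 100) + rnorm(3, sd = 5),
      most_anterior_trochlea = c(0, 30, 0) + rnorm(3, sd = 5)
    )
    for (side in c("lateral", "medial")) {
      fr <- build_frame(lm, side, "right")
      M <- cbind(fr$ml, fr$ap, fr$si)
      expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
      expect_equal(abs(det(M)), 1, tolerance = 1e-9)
      # anterior trochlea must sit anterior of the origin
      expect_gt(sum(fr$ap * (lm$most_anterior_trochlea - fr$origin)), 0)
    }
  }
})

test_that("ML axis is the Gram-Schmidt orthogonalization of the epicondylar direction", {
  # epicondylar direction tilted 10 degrees toward SI
  th <- 10 * pi / 180
  lm <- landmark_set(
    medial_epicondyle = -40 * c(cos(th), 0, sin(th)),
    lateral_epicondyle = 40 * c(cos(th), 0, sin(th)),
    shaft_axis_point_distal = c(0, 0, 0),
    shaft_axis_point_proximal = c(0, 0, 100),
    most_anterior_trochlea = c(0, 30, 0)
  )
  fr <- build_frame(lm, "lateral", "right")
  # explicit Gram-Schmidt oracle
  v <- lm$medial_epicondyle - lm$lateral_epicondyle
  si <- c(0, 0, 1)
  gs <- v - sum(v * si) * si
  gs <- gs / sqrt(sum(gs^2))
  expect_equal(fr$ml, gs, tolerance = 1e-12)
  expect_equal(sum(fr$ml * fr$si), 0, tolerance = 1e-12)
})

test_that("frame construction is equivariant under rigid transforms", {
  set.seed(33)
  lm <- axis_aligned_landmarks()
  fr0 <- build_frame(lm, "lateral", "right")
  for (i in 1:10) {
    tr <- random_rigid()
    fr1 <- build_frame(transform_landmarks(lm, tr), "lateral", "right")
    expect_equal(fr1$origin, apply_transform(tr, fr0$origin),
                 tolerance = 1e-9)
    for (ax in c("ml", "ap", "si"))
      expect_equal(fr1[[ax]], as.numeric(tr$rotation %*% fr0[[ax]]),
                   tolerance = 1e-9)
  }
})

test_that("mirrored landmarks give unchanged tunnel angles", {
  set.seed(8)
  lm <- axis_aligned_landmarks()
  tr <- random_rigid() # work in a generic pose, not the canonical one
  lm <- transform_landmarks(lm, tr)
  fr_r <- build_frame(lm, "lateral", "right")
  lm_l <- mirror_landmarks(lm)
  fr_l <- build_frame(lm_l, "lateral", "left")

  # sagittal mirror of a direction vector
  si <- unitize_test(lm$shaft_axis_point_proximal - lm$shaft_axis_point_distal)
  v <- lm$medial_epicondyle - lm$lateral_epicondyle
  n <- unitize_test(v - sum(v * si) * si)
  for (ang in list(c(30, 0), c(30, 30), c(-20, 10))) {
    d_r <- direction_from_angles(fr_r, ang[1], ang[2])
    d_l <- d_r - 2 * sum(d_r * n) * n
    expect_equal(as.numeric(angles_from_direction(fr_l, d_l)), ang,
                 tolerance = 1e-9)
  }
})

test_that("degenerate epicondylar geometry is an explicit failure", {
  lm <- landmark_set(
    medial_epicondyle = c(0, 0, -40),
    lateral_epicondyle = c(0, 0, 40), # parallel to the shaft
    shaft_axis_point_distal = c(0, 0, 0),
    shaft_axis_point_proximal = c(0, 0, 100),
    most_anterior_trochlea = c(0, 30, 0)
  )
  expect_error(build_frame(lm, "lateral", "right"), "degenerate")
})

test_that("landmark/footprint JSON sidecar round-trips", {
  lm <- axis_aligned_landmarks()
  fp <- list(LCL = c(40, -7, 8), PT = c(40, 8, -12))
  path <- withr::local_tempfile(fileext = ".json")
  write_sidecar(lm, fp, path)
  back <- read_sidecar(path)
  expect_equal(unclass(back$landmarks), unclass(lm))
  expect_equal(back$footprints, fp)
})
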