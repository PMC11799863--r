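test_that("direction_from_angles reproduces the closed-form prescriptions", {
  fr <- axis_aligned_frame("medial") # ml = +x, ap = +y, si = +z
  expect_equal(direction_from_angles(fr, 0, 0), c(1, 0, 0))
  # 30 deg anterior in the axial plane, 0 coronal (the LCL prescription)
  expect_equal(direction_from_angles(fr, 30, 0),
               c(0.8660, 0.5000, 0), tolerance = 1e-4)
  # 30/30 (PT, MCL, POL): normalize(1, tan30, tan30)
  expect_equal(direction_from_angles(fr, 30, 30),
               c(0.7746, 0.4472, 0.4472), tolerance = 1e-4)
})

test_that("angles_from_direction inverts direction_from_angles to 1e-9 on a grid", {
  fr <- axis_aligned_frame("lateral")
  for (ax in seq(-55, 55, by = 13.75)) {
    for (co in seq(-55, 55, by = 13.75)) {
      d <- direction_from_angles(fr, ax, co)
      expect_equal(as.numeric(angles_from_direction(fr, d)), c(ax, co),
                   tolerance = 1e-9)
    }
  }
  expect_equal(as.numeric(angles_from_direction(fr, fr$ml)), c(0, 0))
  expect_error(angles_from_direction(fr, -fr$ml), "into the bone")
})

test_that("the two angle-composition conventions agree at 0 and differ ~2 deg at 30/30", {
  fr <- axis_aligned_frame("medial")
  expect_equal(direction_from_angles(fr, 30, 0, convention = "sequential"),
               direction_from_angles(fr, 30, 0, convention = "projection"),
               tolerance = 1e-12)
  dev <- angular_deviation(
    direction_from_angles(fr, 30, 30, convention = "projection"),
    direction_from_angles(fr, 30, 30, convention = "sequential"))
  expect_gt(dev, 1)
  expect_lt(dev, 5) # measured: 3.4 deg at 30/30
})

test_that("plan_knee produces the study's four tunnels with protocol dimensions", {
  f <- test_femur()
  pl <- plan_knee(f, frames = knee_frames(f))
  expect_length(pl, 4)
  expect_equal(vapply(pl, `[[`, "", "ligament"), c("LCL", "PT", "MCL", "POL"))
  expect_equal(vapply(pl, `[[`, 0, "diameter_mm"), c(8, 8, 7, 7))
  expect_equal(vapply(pl, `[[`, 0, "depth_mm"), rep(25, 4))
  for (tn in pl) expect_equal(sqrt(sum(tn$direction^2)), 1, tolerance = 1e-9)
  # entries are the footprints
  expect_equal(pl[[1]]$entry, f$footprints$LCL)
  # empty spec list -> empty plan
  expect_length(plan_knee(f, specs = list(), frames = knee_frames(f)), 0)
  # missing footprint names the ligament
  f2 <- f
  f2$footprints$POL <- NULL
  expect_error(plan_knee(f2, frames = knee_frames(f2)), "POL")
})

test_that("planned LCL and PT trajectories subtend the closed-form angle", {
  # frozen from the dot product of normalize(1, tan30, 0) and
  # normalize(1, tan30, tan30): acos(2/sqrt(5)) = 26.565 deg
  f <- test_femur()
  pl <- plan_knee(f, frames = knee_frames(f))
  expect_equal(angular_deviation(pl[[1]], pl[[2]]), 26.565, tolerance = 0.1)
})

test_that("planned angles are invariant under rigid motion of the whole knee", {
  set.seed(14)
  lm <- axis_aligned_landmarks()
  fr <- build_frame(lm, "lateral", "right")
  for (i in 1:8) {
    tr <- random_rigid()
    fr2 <- build_frame(transform_landmarks(lm, tr), "lateral", "right")
    for (ang in list(c(30, 0), c(30, 30), c(-10, 25))) {
      d <- direction_from_angles(fr, ang[1], ang[2])
      d2 <- as.numeric(tr$rotation %*% d)
      expect_equal(as.numeric(angles_from_direction(fr2, d2)), ang,
                   tolerance = 1e-9)
    }
  }
})

test_that("tunnel prescriptions validate their ranges", {
  expect_error(tunnel_spec("LCL", 95, 0, 8, 25))
  expect_error(tunnel_spec("LCL", 30, 0, -1, 25))
  expect_error(tunnel_spec("XCL", 30, 0, 8, 25))
  sp <- tunnel_spec("PT", 30, 30, 8, 25)
  expect_s3_class(sp, "tunnel_spec")
})

test_that("guide parameters derive the cannula inner diameter", {
  g <- psi_guide_params()
  expect_equal(g$cannula_inner_diameter_mm, 3.1)
  expect_equal(g$mean_thickness_mm, 3.3)
})

test_that("tunnel plans round-trip through JSON", {
  f <- test_femur()
  pl <- plan_knee(f, frames = knee_frames(f))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(pl, path)
  back <- read_plan(path)
  expect_length(back, 4)
  for (i in seq_along(pl)) {
    expect_equal(back[[i]]$entry, pl[[i]]$entry)
    expect_equal(back[[i]]$direction, pl[[i]]$direction)
    expect_equal(back[[i]]$ligament, pl[[i]]$ligament)
  }
})
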