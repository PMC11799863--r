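test_that("log-normal calibration matches the closed form", {
  # PSI pooled angular quartiles: mu = ln(5.7), sigma = ln(8.2/4.0)/1.349
  p <- calibrate_lognormal(quartile_spec(5.7, 4.0, 8.2))
  expect_equal(p[["mu"]], 1.7405, tolerance = 1e-3)
  expect_equal(p[["sigma"]], 0.5321, tolerance = 1e-3)

  # fitted distribution reproduces the median and quartile ratio exactly
  expect_equal(exp(p[["mu"]]), 5.7)
  expect_equal(exp(2 * p[["sigma"]] * qnorm(0.75)), 8.2 / 4.0,
               tolerance = 1e-12)

  # degenerate spec: point mass
  p0 <- calibrate_lognormal(quartile_spec(3, 3, 3))
  expect_equal(p0[["sigma"]], 0)
  expect_equal(draw_error_magnitudes(quartile_spec(3, 3, 3), 5), rep(3, 5))
  expect_equal(draw_error_magnitudes(quartile_spec(0, 0, 0), 5), rep(0, 5))

  expect_error(quartile_spec(2, 3, 4)) # q1 > median
  expect_error(calibrate_lognormal(quartile_spec(1, 0, 2)), "q1 > 0")
})

test_that("empirical quartiles of calibrated draws match every shipped spec", {
  model <- default_error_model()
  set.seed(71)
  for (group in c("freehand", "psi")) {
    for (lig in c("LCL", "PT", "MCL", "POL")) {
      for (outcome in c("angular", "entry")) {
        spec <- model[[group]][[lig]][[outcome]]
        x <- draw_error_magnitudes(spec, 2e5)
        q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        expect_equal(q[2], spec$median, tolerance = 0.02)
        # IQR ratio is the calibrated quantity; check the fitted quartiles
        fit_q1 <- spec$median / sqrt(spec$q3 / spec$q1)
        fit_q3 <- spec$median * sqrt(spec$q3 / spec$q1)
        expect_equal(q[1], fit_q1, tolerance = 0.02)
        expect_equal(q[3], fit_q3, tolerance = 0.02)
      }
    }
  }
})

test_that("perturb_tunnel injects exactly the drawn magnitudes", {
  f <- test_femur()
  planned <- plan_knee(f, frames = knee_frames(f))

  # fixed 10-degree angular draw at random azimuth
  model <- default_error_model()
  fixed <- model
  for (lig in c("LCL", "PT", "MCL", "POL")) {
    fixed$psi[[lig]]$angular <- quartile_spec(10, 10, 10)
    fixed$psi[[lig]]$entry <- quartile_spec(0, 0, 0)
  }
  set.seed(72)
  for (tn in planned) {
    a <- perturb_tunnel(tn, fixed, "psi", mesh = f$mesh)
    expect_equal(angular_deviation(tn, a), 10, tolerance = 1e-6)
    expect_equal(entry_distance(tn, a), 0)
    expect_equal(a$diameter_mm, tn$diameter_mm)
  }

  # fixed entry draw: on-surface displacement equals the drawn magnitude
  fixed2 <- model
  for (lig in c("LCL", "PT", "MCL", "POL")) {
    fixed2$psi[[lig]]$angular <- quartile_spec(0, 0, 0)
    fixed2$psi[[lig]]$entry <- quartile_spec(4, 4, 4)
  }
  set.seed(73)
  for (tn in planned) {
    a <- perturb_tunnel(tn, fixed2, "psi", mesh = f$mesh)
    expect_equal(entry_distance(tn, a), 4, tolerance = 0.05)
    # new entry still on the bone surface
    expect_lt(mesh_closest_points(a$entry, f$mesh)$distance, 0.05)
    expect_equal(angular_deviation(tn, a), 0, tolerance = 1e-9)
  }

  # all-zero model: achieved = planned
  zero <- model
  for (g in c("freehand", "psi")) for (lig in c("LCL", "PT", "MCL", "POL")) {
    zero[[g]][[lig]]$angular <- quartile_spec(0, 0, 0)
    zero[[g]][[lig]]$entry <- quartile_spec(0, 0, 0)
  }
  a0 <- perturb_tunnel(planned[[1]], zero, "freehand", mesh = f$mesh)
  expect_equal(a0$entry, planned[[1]]$entry)
  expect_equal(a0$direction, planned[[1]]$direction)
})

test_that("measured deviations of perturbed tunnels recover the configured quartiles", {
  # parameter recovery at n = 500 per cell, 3% tolerance (angular and entry)
  f <- test_femur()
  planned <- plan_knee(f, frames = knee_frames(f))
  model <- default_error_model()
  set.seed(74)
  for (lig in c("MCL", "LCL")) {
    tn <- planned[[match(lig, c("LCL", "PT", "MCL", "POL"))]]
    spec_a <- model$psi[[lig]]$angular
    devs <- replicate(500, {
      a <- perturb_tunnel(tn, model, "psi", mesh = f$mesh)
      angular_deviation(tn, a)
    })
    q <- quantile(devs, c(0.25, 0.5, 0.75), names = FALSE)
    expect_equal(q[2], spec_a$median, tolerance = 0.03 + 3 / sqrt(500))
  }
})

test_that("PSI-calibrated MCL deviations have median near the configured 7.5 deg", {
  model <- default_error_model()
  set.seed(75)
  x <- draw_error_magnitudes(model$psi$MCL$angular, 1e4)
  expect_gt(median(x), 7.0)
  expect_lt(median(x), 8.0)
})

test_that("freehand angular error stochastically dominates PSI error per ligament", {
  model <- default_error_model()
  set.seed(76)
  probs <- seq(0.05, 0.95, by = 0.05)
  for (lig in c("LCL", "PT", "MCL", "POL")) {
    qf <- quantile(draw_error_magnitudes(model$freehand[[lig]]$angular, 2e4),
                   probs)
    qp <- quantile(draw_error_magnitudes(model$psi[[lig]]$angular, 2e4),
                   probs)
    expect_true(all(qf >= qp))
  }
})

test_that("simulate_study is deterministic and recovers injected errors at zero noise", {
  rec1 <- test_sim_small()
  rec2 <- simulate_study(n_knees_per_group = 1, seed = 19, noise_sd = 0,
                         resolution_mm = 4.5)
  attr(rec1, "registrations") <- NULL
  attr(rec2, "registrations") <- NULL
  expect_identical(rec1, rec2)

  expect_equal(nrow(rec1), 8) # 2 groups x 1 knee x 4 tunnels
  expect_setequal(unique(rec1$group), c("psi", "freehand"))
  # measured vs injected: the registration must be exactly invertible
  expect_lt(max(abs(rec1$angular_deviation_deg - rec1$injected_angular_deg)),
            0.05)
  expect_lt(max(abs(rec1$entry_distance_mm - rec1$injected_entry_mm)), 0.05)
})
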