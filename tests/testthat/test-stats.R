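test_that("median_iqr follows the requested quantile convention", {
  mi <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(mi$q1, mi$median, mi$q3), c(2, 3, 4))
  mi1 <- median_iqr(7)
  expect_equal(c(mi1$q1, mi1$median, mi1$q3), c(7, 7, 7))
  expect_error(median_iqr(numeric(0)), "empty")

  # hinges and interpolation agree when n = 4k + 1
  set.seed(81)
  for (i in 1:10) {
    x <- rnorm(5)
    a <- median_iqr(x, "linear")
    b <- median_iqr(x, "hinges")
    expect_equal(c(a$q1, a$median, a$q3), c(b$q1, b$median, b$q3))
  }
})

test_that("exact Mann-Whitney reproduces the study's printed p-values", {
  # complete separation at n = 5 vs 5: p = 2/252, printed as 0.008
  sep <- mannwhitney_exact(1:5, 11:15)
  expect_true(sep$exact)
  expect_equal(sep$p, 2 / 252)
  expect_equal(round(sep$p, 3), 0.008)

  # U = 6 -> p = 0.222 and U = 7 -> p = 0.310 (the entry-distance rows)
  # construct 5v5 data with exactly those U values
  a6 <- c(1, 2, 3, 4, 10)   # ranks 1,2,3,4,10 -> U = 20 - 15 + ... check below
  b6 <- c(5, 6, 7, 8, 9)
  r6 <- mannwhitney_exact(a6, b6)
  expect_equal(r6$U, 5) # rank sum 20 - 15
  u6 <- mannwhitney_exact(c(1, 2, 3, 5, 10), c(4, 6, 7, 8, 9))
  expect_equal(u6$U, 6)
  expect_equal(round(u6$p, 3), 0.222)
  u7 <- mannwhitney_exact(c(1, 2, 3, 6, 10), c(4, 5, 7, 8, 9))
  expect_equal(u7$U, 7)
  expect_equal(round(u7$p, 3), 0.310)

  # identical samples: no evidence
  expect_equal(mannwhitney_exact(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("exact enumeration matches the independent distribution oracle", {
  # cross-check the enumerated two-sided p against R's exact Wilcoxon
  # distribution (pwilcox) on random tie-free samples
  set.seed(82)
  for (i in 1:20) {
    na <- sample(3:8, 1)
    nb <- sample(3:8, 1)
    a <- rnorm(na)
    b <- rnorm(nb, mean = runif(1, -1, 1))
    res <- mannwhitney_exact(a, b)
    expect_true(res$exact)
    oracle <- min(1, 2 * min(pwilcox(res$U, na, nb),
                             1 - pwilcox(res$U - 1, na, nb)))
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }
})

test_that("exact p-values are invariant under relabeling and monotone transforms", {
  set.seed(83)
  a <- rnorm(6)
  b <- rnorm(7, mean = 0.8)
  p0 <- mannwhitney_exact(a, b)$p
  expect_equal(mannwhitney_exact(b, a)$p, p0)
  expect_equal(mannwhitney_exact(exp(a), exp(b))$p, p0)
  expect_equal(mannwhitney_exact(a * 100 - 7, b * 100 - 7)$p, p0)
})

test_that("enumeration and the normal approximation agree for n = 10 vs 10", {
  set.seed(84)
  for (i in 1:10) {
    a <- rnorm(10)
    b <- rnorm(10, mean = runif(1, 0, 1.5))
    ex <- mannwhitney_exact(a, b)
    ap <- mannwhitney_exact(a, b, enum_limit = 1)
    expect_true(ex$exact)
    expect_false(ap$exact)
    expect_lt(abs(ex$p - ap$p), 0.02)
  }
})

test_that("Levene test detects spread differences and handles degeneracy", {
  # identical groups: no spread difference
  x <- c(1, 3, 5, 7)
  expect_equal(levene_test(x, x)$p, 1)
  expect_equal(levene_test(x, x)$W, 0)

  # perfect separation of spreads: undefined, explicit failure
  expect_error(levene_test(c(0, 10), c(4, 6)), "undefined")

  # power: sigma ratio 3 at n = 20/20 rejects > 80% of the time
  set.seed(85)
  rej <- mean(replicate(2000,
    levene_test(rnorm(20, sd = 3), rnorm(20, sd = 1))$p < 0.05))
  expect_gt(rej, 0.8)

  # cross-check against the classic formula on a fixed dataset
  a <- c(2, 4, 9, 12, 7)
  b <- c(5, 6, 5.5, 6.2, 5.8)
  lv <- levene_test(a, b)
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  zb_all <- mean(c(za, zb))
  W <- (length(za) * (mean(za) - zb_all)^2 + length(zb) * (mean(zb) - zb_all)^2) /
    ((sum((za - mean(za))^2) + sum((zb - mean(zb))^2)) / (length(c(za, zb)) - 2))
  expect_equal(lv$W, W, tolerance = 1e-12)
  expect_equal(lv$p, pf(W, 1, 8, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("compare_study emits the full pooled + per-ligament table", {
  set.seed(86)
  model <- default_error_model()
  records <- do.call(rbind, lapply(c("freehand", "psi"), function(g)
    do.call(rbind, lapply(c("LCL", "PT", "MCL", "POL"), function(lig)
      data.frame(knee_id = paste0(g, 1:5), group = g, ligament = lig,
                 angular_deviation_deg =
                   draw_error_magnitudes(model[[g]][[lig]]$angular, 5),
                 entry_distance_mm =
                   draw_error_magnitudes(model[[g]][[lig]]$entry, 5))))))
  tab <- compare_study(records)
  expect_equal(nrow(tab), 10) # 2 pooled + 8 per-ligament rows
  expect_setequal(unique(tab$stratum), c("pooled", "LCL", "PT", "MCL", "POL"))
  pooled <- tab[tab$stratum == "pooled", ]
  expect_equal(pooled$n_control, c(20, 20))
  # per-ligament rows (5v5, no ties) ran the exact path
  expect_true(all(tab$mw_exact[tab$stratum != "pooled"]))
  # calibrated angular separation is overwhelming
  expect_lt(tab$p_mannwhitney[tab$outcome == "angular" &
                                tab$stratum == "pooled"], 0.001)

  # PSI = control exactly -> all MW p = 1
  recs_eq <- records
  recs_eq$angular_deviation_deg <- rep(records$angular_deviation_deg[1:20], 2)
  recs_eq$entry_distance_mm <- rep(records$entry_distance_mm[1:20], 2)
  tab_eq <- compare_study(recs_eq)
  expect_true(all(tab_eq$p_mannwhitney == 1))
})

test_that("understrength strata are omitted with a warning", {
  records <- data.frame(
    knee_id = rep(c("a", "b"), each = 4),
    group = rep(c("freehand", "psi"), each = 4),
    ligament = rep(c("LCL", "PT", "MCL", "POL"), 2),
    angular_deviation_deg = c(20, 21, 22, 23, 5, 6, 7, 8),
    entry_distance_mm = c(5, 6, 7, 8, 4, 4.5, 5, 5.5)
  )
  w <- capture_warnings(tab <- compare_study(records))
  expect_true(any(grepl("omitted", w)))
  expect_setequal(unique(tab$stratum), "pooled")
})
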