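test_that("interface samples land in their printed layers", {
  expect_identical(assign_layer(1000), "UIF")
  expect_identical(assign_layer(2500), "MIF")
  expect_identical(assign_layer(1800), "GAP")
  expect_identical(assign_layer(10), "SEAWATER")
  expect_identical(assign_layer(2900), "GAP")
  expect_identical(assign_layer(3500), "LIF")
  expect_identical(assign_layer(4500), "BRINE")
  expect_error(assign_layer(-1), ">= 0")
})

test_that("every printed layer bound maps to its own (inclusive) layer", {
  expect_identical(assign_layer(c(70, 1500)), c("UIF", "UIF"))
  expect_identical(assign_layer(c(2080, 2800)), c("MIF", "MIF"))
  expect_identical(assign_layer(c(3050, 4120)), c("LIF", "LIF"))
  # layers partition [0, 4720]: every point gets exactly one label
  mg <- seq(0, 4720, by = 0.5)
  labs <- assign_layer(mg)
  expect_false(anyNA(labs))
  expect_setequal(unique(labs),
                  c("SEAWATER", "UIF", "GAP", "MIF", "LIF", "BRINE"))
  # boundaries between consecutive classes are consistent (no overlap):
  # a half-open seam everywhere except at the inclusive printed endpoints
  expect_identical(assign_layer(c(69.999, 70)), c("SEAWATER", "UIF"))
  expect_identical(assign_layer(c(1500, 1500.001)), c("UIF", "GAP"))
  expect_identical(assign_layer(c(2079.999, 2080)), c("GAP", "MIF"))
  expect_identical(assign_layer(c(4120, 4120.001)), c("LIF", "BRINE"))
})

test_that("activity curves pass through anchors exactly and decrease monotonically", {
  cv <- fit_activity_curve(hephaestus_anchors())
  expect_equal(predict_aw(cv, c(0.061, 2.97, 4.72)),
               c(0.980, 0.653, 0.395), tolerance = 1e-12)
  grid <- seq(0.061, 4.72, length.out = 2000)
  aw <- predict_aw(cv, grid)
  expect_true(all(diff(aw) < 0))
  expect_true(all(aw >= 0.395 - 1e-9 & aw <= 0.980 + 1e-9))
})

test_that("anchor-exactness and monotonicity hold for random accepted anchor sets", {
  for (s in 1:20) {
    anc <- withr::with_seed(s, {
      k <- sample(3:6, 1)
      conc <- sort(runif(k, 0, 5))
      aw <- sort(runif(k, 0.3, 1), decreasing = TRUE)
      while (any(diff(aw) >= 0)) aw <- sort(runif(k, 0.3, 1), decreasing = TRUE)
      activity_anchors(conc, aw)
    })
    cv <- fit_activity_curve(anc)
    expect_equal(predict_aw(cv, anc$conc), anc$aw, tolerance = 1e-12)
    g <- seq(min(anc$conc), max(anc$conc), length.out = 500)
    expect_true(all(diff(predict_aw(cv, g)) <= 0))
  }
})

test_that("degenerate or inconsistent anchor sets are rejected", {
  expect_error(fit_activity_curve(data.frame(conc = 1, aw = 0.9)),
               "at least 2")
  expect_error(fit_activity_curve(activity_anchors(c(1, 2, 3), c(0.9, 0.95, 0.5))),
               "strictly decreasing")
  expect_error(fit_activity_curve(data.frame(conc = c(1, 1), aw = c(0.9, 0.8))),
               "distinct|decreasing")
  mixed <- rbind(activity_anchors(c(0.1, 2.27), c(0.98, 0.747), "kryos"),
                 activity_anchors(2.3, 0.790, "discovery"))
  expect_error(fit_activity_curve(mixed), "mix brine systems")
  cv <- fit_activity_curve(hephaestus_anchors())
  expect_error(predict_aw(cv, 5.5), "outside anchored range")
})

test_that("threshold depth is exact for a symmetric linear construction", {
  # linear Mg ramp 70 -> 4720 mM over 3 m against a linear a_w curve
  # 0.980 -> 0.395: the a_w midpoint 0.6875 falls exactly mid-interface
  prof <- make_interface_profile(n = 2, shape = "linear",
                                 noise = noise_spec(sigma = 0))
  lin <- fit_activity_curve(activity_anchors(c(0.070, 4.72), c(0.980, 0.395)))
  hit <- locate_threshold_depth(prof, lin, aw_threshold = 0.6875)
  expect_identical(hit$status, "crossed")
  expect_equal(hit$depth_m, 1.5, tolerance = 1e-9)
  # a threshold above the whole profile is reported, not extrapolated
  miss <- locate_threshold_depth(prof, lin, aw_threshold = 0.99)
  expect_identical(miss$status, "not-crossed")
  expect_true(is.na(miss$depth_m))
})

test_that("threshold depth matches a dense-grid scan for random sigmoidal haloclines", {
  cv <- fit_activity_curve(hephaestus_anchors())
  for (s in 1:10) {
    k <- withr::with_seed(s, runif(1, 1.5, 6))
    prof <- make_interface_profile(top_mg = 70, bottom_mg = 4720,
                                   thickness = 3, shape = "logistic",
                                   n = 61, k = k,
                                   noise = noise_spec(sigma = 0))
    hit <- locate_threshold_depth(prof, cv, aw_threshold = 0.585)
    expect_identical(hit$status, "crossed")
    # brute force: 1-mm depth grid over the sample-interpolated a_w profile
    zg <- seq(0, 3, by = 0.001)
    aws <- predict_aw(cv, prof$value / 1000)
    awg <- approx(prof$depth_m, aws, xout = zg)$y
    zscan <- zg[which(awg <= 0.585)[1]]
    expect_lt(abs(hit$depth_m - zscan), 0.0011)
  }
})

test_that("habitability classification reports both criteria", {
  cv <- fit_activity_curve(hephaestus_anchors())
  up <- classify_habitability(1000, cv)
  expect_identical(up$status, "active-window")
  expect_false(up$below_observed_limit)
  low <- classify_habitability(3500, cv)
  expect_identical(low$status, "below-observed-limit")
  expect_true(low$below_observed_limit)
  # a curve constructed so a_w drops under 0.585 inside the observed window
  steep <- fit_activity_curve(activity_anchors(c(0.05, 1.0, 3.0),
                                               c(0.90, 0.50, 0.40)))
  mid <- classify_habitability(1500, steep)
  expect_identical(mid$status, "below-aw-limit")
  expect_true(mid$below_aw_limit)
  expect_false(mid$below_observed_limit)
  # reported a_w matches the curve
  expect_equal(up$aw, predict_aw(cv, 1.0), tolerance = 1e-12)
})
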