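test_that("noise-free profiles return the generating time to optimizer precision", {
  p <- hephaestus_mg_params()
  for (t_true in c(1e10, 2.2e10, 63.1e9)) {
    prof <- profile_curve(seq(0.1, 3.2, by = 0.25), t_true, p, tracer = "Mg")
    est <- fit_age(prof, p)
    expect_equal(est$t_seconds, t_true, tolerance = 1e-3)
    expect_lt(est$rss, 1e-10)
    expect_equal(est$n_obs, nrow(prof))
  }
})

test_that("noisy magnesium profile from the brine-lake parameter set dates to ~700 yr", {
  prof <- make_pore_profile("hephaestus_mg", seed = 42)
  p <- transport_preset("hephaestus_mg")$params
  est <- fit_age(prof, p)
  expect_lt(abs(est$t_years - 700) / 700, 0.10)
})

test_that("age recovery under 2% noise: median relative error over replicates <= 5%", {
  p <- transport_preset("hephaestus_mg")$params
  t_true <- 2.2e10
  errs <- vapply(1:100, function(s) {
    prof <- make_pore_profile("hephaestus_mg", seed = s)
    abs(fit_age(prof, p)$t_seconds - t_true) / t_true
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("joint two-tracer fits agree with single-tracer fits at a common time", {
  t_true <- 1.5e10
  pmg <- transport_preset("hephaestus_mg")$params
  pcl <- transport_preset("hephaestus_cl")$params
  mg <- profile_curve(seq(0.1, 3.2, by = 0.25), t_true, pmg, tracer = "Mg")
  cl <- profile_curve(seq(0.1, 3.2, by = 0.25), t_true, pcl, tracer = "Cl")
  joint <- fit_age(list(mg, cl), list(pmg, pcl))
  alone <- fit_age(mg, pmg)
  expect_equal(joint$t_seconds, alone$t_seconds, tolerance = 5e-3)
  expect_equal(joint$t_seconds, t_true, tolerance = 5e-3)
  expect_named(joint$per_tracer_rss, c("Mg", "Cl"))
})

test_that("the fitted time is a genuine objective minimum", {
  prof <- make_pore_profile("hephaestus_mg", seed = 11)
  p <- transport_preset("hephaestus_mg")$params
  est <- fit_age(prof, p)
  obj <- function(t) sum((prof$value -
    analytic_concentration(prof$depth_m, t, p))^2)
  expect_lte(obj(est$t_seconds), obj(0.5 * est$t_seconds))
  expect_lte(obj(est$t_seconds), obj(2 * est$t_seconds))
})

test_that("single free parameters are recovered from noise-free and noisy profiles", {
  z <- seq(0.1, 3.2, by = 0.25)
  pd <- transport_preset("hephaestus_dD")$params
  t_fix <- 2.2e10
  # deuterium diffusivity, noise-free: recovered within 0.1%
  clean <- profile_curve(z, t_fix, pd, tracer = "dD", units = "permil")
  fd <- fit_free_parameter(clean, pd, free = "Ds", t = t_fix,
                           bounds = c(1e-11, 1e-9))
  expect_equal(fd$value, 2.96e-10, tolerance = 1e-3)
  # with instrument noise: within 5%
  noisy <- make_pore_profile("hephaestus_dD", seed = 5, depths = z)
  fn <- fit_free_parameter(noisy, pd, free = "Ds", t = t_fix,
                           bounds = c(1e-11, 1e-9))
  expect_equal(fn$value, 2.96e-10, tolerance = 0.05)
  # boundary value C0, noise-free: exact
  pmg <- hephaestus_mg_params()
  mg <- profile_curve(z, t_fix, pmg, tracer = "Mg")
  fc <- fit_free_parameter(mg, pmg, free = "C0", t = t_fix,
                           bounds = c(1000, 10000))
  expect_equal(fc$value, 4720, tolerance = 1e-6)
  # advection velocity generated at zero recovers zero
  p0 <- transport_params(Ds = 2.4e-10, Vs = 0, C0 = 4720, Cbg = 61)
  mg0 <- profile_curve(z, t_fix, p0, tracer = "Mg")
  fv <- fit_free_parameter(mg0, p0, free = "Vs", t = t_fix,
                           bounds = c(0, 1e-9))
  expect_lt(abs(fv$value), 1e-12)
})

test_that("jointly freeing t and Ds is refused as unidentifiable", {
  p <- hephaestus_mg_params()
  prof <- profile_curve(seq(0.1, 3.2, by = 0.25), 2.2e10, p, tracer = "Mg")
  expect_error(fit_free_parameter(prof, p, free = c("t", "Ds"),
                                  bounds = c(1e8, 1e12)),
               "not jointly identifiable")
})

test_that("bootstrap intervals are reproducible, contain the estimate, and shrink without noise", {
  p <- transport_preset("hephaestus_mg")$params
  prof <- make_pore_profile("hephaestus_mg", seed = 3)
  b1 <- bootstrap_age_ci(prof, p, n_boot = 150, seed = 9)
  b2 <- bootstrap_age_ci(prof, p, n_boot = 150, seed = 9)
  expect_identical(b1$ci_years, b2$ci_years)
  expect_lte(b1$ci_years[1], b1$t_years)
  expect_gte(b1$ci_years[2], b1$t_years)
  # different seed -> different resamples
  b3 <- bootstrap_age_ci(prof, p, n_boot = 150, seed = 10)
  expect_false(identical(b1$ci_years, b3$ci_years))
  # noise-free data: interval collapses onto the estimate
  clean <- profile_curve(seq(0.1, 3.2, by = 0.25), 2.2e10, p, tracer = "Mg")
  b0 <- bootstrap_age_ci(clean, p, n_boot = 100, seed = 1)
  expect_lt(diff(b0$ci_years) / b0$t_years, 1e-3)
  expect_error(bootstrap_age_ci(prof, p, n_boot = 1), "n_boot")
})

test_that("bootstrap nominal-95% coverage of the generating age is at least 90%", {
  p <- transport_preset("hephaestus_mg")$params
  t_true_years <- seconds_to_years(2.2e10)
  hits <- vapply(1:50, function(s) {
    prof <- make_pore_profile("hephaestus_mg", seed = 1000 + s)
    ci <- bootstrap_age_ci(prof, p, n_boot = 200, seed = s)$ci_years
    ci[1] <= t_true_years && t_true_years <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("age differences are signed and reproduce the printed 1,300-yr gap", {
  expect_identical(compare_ages(700, 2000), 1300)
  expect_identical(compare_ages(2000, 2000), 0)
  # from the caption second->year pairs
  d <- compare_ages(seconds_to_years(31.55e9), seconds_to_years(63.1e9))
  expect_equal(d, 999.7, tolerance = 1e-3)
  a <- age_estimate(2.2e10, rss = 0, n_obs = 10)
  b <- age_estimate(63.1e9, rss = 0, n_obs = 10)
  expect_equal(compare_ages(a, b), 1302.4, tolerance = 1e-3)
})

test_that("degenerate fit inputs fail loudly", {
  p <- hephaestus_mg_params()
  prof <- profile_curve(seq(0.1, 3.2, by = 0.25), 2.2e10, p, tracer = "Mg")
  expect_error(fit_age(list(), p), "at least one")
  expect_error(fit_age(prof, p, t_bounds = c(1e12, 1e8)), "lower < upper")
  expect_error(fit_age(prof, p, t_bounds = c(-1, 1e8)), "positive")
  short <- tracer_profile(c(0, 1), c(4720, 3000))
  expect_error(fit_age(short, p), "at least 3")
})
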