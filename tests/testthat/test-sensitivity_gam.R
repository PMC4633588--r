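# Latin-hypercube scenario sampling, the sensitivity sweep, and the
# GCV-selected smoothing spline.

test_that("latin hypercube stratifies every margin", {
  tab <- sample_scenarios(n = 100, seed = 1)
  expect_equal(nrow(tab), 100)
  for (v in platypopdyn:::SCENARIO_DIMS) {
    # exactly one value in each decile band
    expect_equal(as.integer(table(cut(tab[[v]], seq(0, 1, 0.1)))),
                 rep(10L, 10))
  }
  expect_identical(sample_scenarios(n = 20, seed = 2),
                   sample_scenarios(n = 20, seed = 2))
  expect_warning(
    cons <- sample_scenarios(list(s_disp = c(0.5, 0.5)), n = 12, seed = 3),
    "held constant")
  expect_true(all(cons$s_disp == 0.5))
})

test_that("sensitivity sweep handles certain-death and immortal rows", {
  base <- pva_scenario("adjusted", n0 = 30, K = 100, years = 15,
                       iterations = 10)
  tab <- sample_scenarios(n = 2, seed = 4)
  tab[1, 1:5] <- 1   # all mortalities 1 -> extinction in year 1
  tab[2, 1:5] <- 0   # immortal -> censored at the horizon
  out <- run_sensitivity(tab, base, iterations = 10)
  expect_equal(out$time_to_extinction[1], 1)
  expect_false(out$censored[1])
  expect_equal(out$time_to_extinction[2], 15)
  expect_true(out$censored[2])
})

test_that("time to extinction falls along an adult-female-mortality slice", {
  base <- pva_scenario("adjusted", n0 = 40, K = 150, years = 40,
                       iterations = 150)
  ms <- c(0.05, 0.3, 0.5, 0.7, 0.9)
  tab <- data.frame(female_juvenile_mortality = 0.71,
                    female_adult_mortality = ms,
                    male_juvenile_mortality = 0.77,
                    male_subadult_mortality = 0.43,
                    male_adult_mortality = 0.23,
                    s_disp = 1, seed = 11:15)
  out <- run_sensitivity(tab, base, iterations = 150)
  tte <- ifelse(out$censored, base$years + 1, out$time_to_extinction)
  expect_true(all(diff(tte) <= 0))
  expect_gt(tte[1], tte[5])
})

test_that("an exactly linear signal is fit with two effective degrees of freedom", {
  x <- seq(0, 1, length.out = 50)
  y <- 2 + 3 * x
  fit <- fit_gcv_spline(x, y)
  expect_equal(fit$edf, 2, tolerance = 0.1)
  expect_lt(max(abs(fit$fitted - y)), 1e-6)
})

test_that("a smooth signal is recovered from noise", {
  set.seed(5)
  x <- runif(200)
  y <- sin(2 * pi * x) + rnorm(200, 0, 0.1)
  fit <- fit_gcv_spline(x, y)
  expect_lt(sqrt(mean((fit$fitted - sin(2 * pi * sort(x)))^2)), 0.1)
  # prediction interpolates the same curve
  xs <- seq(0.05, 0.95, length.out = 30)
  expect_lt(max(abs(predict(fit, xs) - sin(2 * pi * xs))), 0.25)
})

test_that("the GCV minimum matches an exhaustive grid search", {
  set.seed(6)
  x <- runif(120)
  y <- cos(3 * x) + rnorm(120, 0, 0.2)
  fit <- fit_gcv_spline(x, y)
  grid <- 10^seq(-9, 9, length.out = 1000)
  scores <- spline_gcv(x, y, grid)
  best <- scores$lambda[which.min(scores$gcv)]
  # agreement to the resolution of the 1000-point grid
  step <- 18 / 999
  expect_lt(abs(log10(fit$lambda) - log10(best)), 2 * step)
  expect_lte(fit$gcv, min(scores$gcv) * (1 + 1e-6))
})

test_that("the smoother is affine-equivariant and edf decreases with lambda", {
  set.seed(7)
  x <- runif(60)
  y <- x^2 + rnorm(60, 0.05)
  # at fixed penalty the hat matrix is linear, so a constant shift of y
  # shifts the fit by exactly that constant
  f1 <- fit_gcv_spline(x, y, lambda = 10)
  f2 <- fit_gcv_spline(x, y + 10, lambda = 10)
  expect_equal(f2$fitted, f1$fitted + 10, tolerance = 1e-8)
  lams <- 10^seq(-8, 4, length.out = 20)
  edfs <- spline_gcv(x, y, lams)$edf
  expect_true(all(diff(edfs) < 1e-8))
  expect_error(fit_gcv_spline(rep(1:5, 4), rnorm(20)), "distinct")
})

test_that("smoothing spline agrees with an independent smoother", {
  # cross-check against the reference GCV smoothing spline in stats
  set.seed(8)
  x <- sort(runif(150))
  y <- exp(-2 * x) * sin(4 * x) + rnorm(150, 0, 0.05)
  ours <- fit_gcv_spline(x, y)
  ref <- stats::smooth.spline(x, y, cv = FALSE)
  expect_lt(sqrt(mean((ours$fitted - predict(ref, x)$y)^2)), 0.03)
})

test_that("threshold reporting finds crossings and degenerate cases", {
  x <- seq(0.3, 0.9, length.out = 80)
  set.seed(9)
  y <- 4 * (x - 0.6) + rnorm(80, 0, 0.05)   # crosses zero at 0.6
  fit <- fit_gcv_spline(x, y)
  rep0 <- threshold_report(fit, 0)
  expect_equal(rep0$status, "ok")
  expect_gt(rep0$threshold, 0.55)
  expect_lt(rep0$threshold, 0.65)
  never <- threshold_report(fit, 10)
  expect_equal(never$status, "none within range")
  expect_true(is.na(never$threshold))
  always <- threshold_report(fit, -10)
  expect_equal(always$status, "met everywhere")
  expect_equal(always$threshold, 0.3, tolerance = 1e-6)
})
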