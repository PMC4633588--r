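# Beta-Binomial proportion tests, the Gibbs linear model, Metropolis
# Poisson regression, and breeding statistics.

test_that("beta posterior mean and interval are exact", {
  prior <- beta_binomial_test(0, 0)
  expect_equal(prior$mean, 0.5)
  expect_equal(prior$lower, 0.025)
  expect_equal(prior$upper, 0.975)
  expect_equal(beta_binomial_test(7, 10)$mean, 8 / 12)
  # mean = (x + 1) / (n + 2) exactly, across x <= n
  for (n in c(0, 3, 25)) for (x in 0:n)
    expect_identical(beta_binomial_test(x, n)$mean, (x + 1) / (n + 2))
  expect_error(beta_binomial_test(5, 3), "x <= n")
})

test_that("interval endpoints match numerical inversion of the Beta CDF", {
  # quadrature oracle: integrate the density and root-find the quantile
  quad_q <- function(prob, a, b) {
    cdf <- function(t) stats::integrate(function(u) stats::dbeta(u, a, b),
                                        0, t, rel.tol = 1e-12)$value
    stats::uniroot(function(t) cdf(t) - prob, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  }
  for (xn in list(c(3, 10), c(17, 20), c(0, 5))) {
    post <- beta_binomial_test(xn[1], xn[2])
    expect_equal(post$lower, quad_q(0.025, post$shape1, post$shape2),
                 tolerance = 1e-6)
    expect_equal(post$upper, quad_q(0.975, post$shape1, post$shape2),
                 tolerance = 1e-6)
  }
})

test_that("difference of proportions centres on the analytic gap", {
  d <- beta_binomial_diff(80, 100, 40, 100, seed = 1)
  expect_equal(d$mean, 81 / 102 - 41 / 102, tolerance = 0.01)
  expect_gt(d$lower, 0)
})

test_that("gibbs sampler matches the flat-prior closed form", {
  set.seed(2)
  n <- 120
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, -1)) + rnorm(n, 0, 0.8)
  fit <- gibbs_linear_model(y, X, draws = 4000, burn_in = 500, thin = 2,
                            seed = 3)
  # with mean/precision-zero prior the posterior mean of beta is the OLS
  # estimate; require agreement within 3 Monte-Carlo SEs
  mcse <- apply(fit$beta, 2, sd) / sqrt(nrow(fit$beta))
  expect_true(all(abs(colMeans(fit$beta) - fit$ols) < 3 * 10 * mcse))
  # near-degenerate noise: posterior means within 0.01 of OLS
  y2 <- drop(X %*% c(2, -1)) + rnorm(n, 0, 1e-4)
  fit2 <- gibbs_linear_model(y2, X, draws = 2000, burn_in = 200, seed = 4)
  expect_true(all(abs(colMeans(fit2$beta) - c(2, -1)) < 0.01))
  expect_error(gibbs_linear_model(y, cbind(X, X[, 2])), "rank")
})

test_that("gibbs contrast detects a 200 g class difference", {
  set.seed(5)
  grp <- rep(0:1, each = 100)
  y <- 860 + 200 * grp + rnorm(200, 0, 50)
  fit <- gibbs_linear_model(y, cbind(1, grp), seed = 6)
  expect_gt(fit$summary["grp", "q2.5"], 0)
  expect_equal(fit$summary["grp", "mean"], 200, tolerance = 0.15)
})

test_that("gibbs estimates converge to OLS for large n", {
  set.seed(7)
  n <- 10000
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  fit <- gibbs_linear_model(y, X, draws = 2000, burn_in = 200, seed = 8)
  expect_lt(abs(colMeans(fit$beta)[2] - fit$ols[2]) / abs(fit$ols[2]), 0.01)
})

test_that("poisson regression recovers slopes and nulls", {
  # no signal: y independent of x, slope posterior centred at zero
  set.seed(9)
  n_t <- rep(30, 20)
  y0 <- rpois(20, n_t * 0.4)
  x0 <- runif(20, 0, 3)
  f0 <- bayes_poisson_regression(y0, n_t, x0, draws = 4000,
                                 burn_in = 500, seed = 10)
  expect_lt(f0$summary["slope", "q2.5"], 0)
  expect_gt(f0$summary["slope", "q97.5"], 0)
  # a constant covariate leaves the slope unidentified under a flat prior
  expect_error(bayes_poisson_regression(y0, n_t, rep(2, 20)), "constant")
  # slope 0.5 recovery over 40 years
  x <- runif(40, 0, 3)
  y1 <- rpois(40, 50 * exp(-1 + 0.5 * x))
  y1 <- pmin(y1, 50)
  f1 <- bayes_poisson_regression(y1, rep(50, 40), x, seed = 11)
  expect_gt(f1$summary["slope", "mean"], 0.3)
  expect_lt(f1$summary["slope", "mean"], 0.7)
  # deterministic limit: y proportional to n exp(x) gives slope 1
  x2 <- seq(0.05, 0.6, length.out = 12)
  y2 <- round(300 * exp(x2))
  f2 <- bayes_poisson_regression(y2, rep(1000, 12), x2, seed = 12)
  expect_equal(f2$summary["slope", "mean"], 1, tolerance = 0.05)
  expect_error(bayes_poisson_regression(c(5, 1, 1), rep(0, 3), 1:3), "exposure")
})

test_that("breeding statistics follow their definitions", {
  recs <- platypopdyn:::validate_capture_records(data.frame(
    animal_id = c("f1", "f2", "f1", "f2", "f3", "m1"),
    date = c("1990-12-10", "1991-01-20", "1991-12-05", "1991-12-28",
             "2005-12-15", "1990-12-10"),
    pool_id = "p1", sex = c(rep("female", 5), "male"),
    age_class = "adult", weight_g = "900", length_cm = "42",
    lactating = c("yes", "yes", "yes", "no", "yes", "untested"),
    effort_hours = "10"))
  bs <- breeding_stats(recs)
  # season 1990 = Dec 1990 + Jan 1991: both tested females lactating
  s90 <- bs$annual_index[bs$annual_index$season == 1990, ]
  expect_equal(s90$index, 1)
  expect_equal(s90$n_tested, 2)
  # consecutive pair f1 (both), f2 (first only): fractions partition
  expect_equal(bs$consecutive$n, 2)
  expect_equal(sum(bs$consecutive$fractions), 1)
  expect_equal(unname(bs$consecutive$fractions["both"]), 0.5)
  # decade composition covers all four decades with no overlap
  expect_equal(nrow(bs$decade_sex_ratio), 4)
  expect_true(all(bs$decade_lactation$mean >= 0 | bs$decade_lactation$absent,
                  na.rm = TRUE))
})

test_that("mean annual lactation index tracks the generator's breeding rate", {
  sim <- small_sim(years = 40, initial_n = 150, seed = 606)
  bs <- breeding_stats(sim$records)
  expect_gt(sum(bs$annual_index$n_tested), 300)
  expect_gte(bs$mean_index, 0.34)
  expect_lte(bs$mean_index, 0.44)
})
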