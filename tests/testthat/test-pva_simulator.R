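# Survival adjustment, Leslie oracles and the stochastic two-sex simulator.

flat5 <- function(v) setNames(rep(v, 5), platypopdyn:::CLASS_LEVELS)

test_that("survival adjustment reproduces the published adult mortalities", {
  rates <- shoalhaven_class_rates()
  vr <- derive_vital_rates(setNames(rates$phi, rates$class),
                           setNames(rates$residency, rates$class))
  m <- setNames(vr$mortality, vr$class)
  # adult female: phi 0.76, dispersal 14.5% -> 11% mortality
  expect_equal(round(100 * m[["female_adult"]]), 11)
  # adult male: phi 0.57, residency 0.74 -> 23% mortality
  expect_equal(round(100 * m[["male_adult"]]), 23)
  # r = 1 leaves survival untouched
  vr1 <- derive_vital_rates(flat5(0.63), flat5(1))
  expect_equal(vr1$survival, rep(0.63, 5))
  expect_equal(vr1$dispersal, rep(0, 5))
  # phi > r is capped at 1 with a warning; zero residency is an error
  expect_warning(vr2 <- derive_vital_rates(flat5(0.9), flat5(0.8)), "capped")
  expect_equal(vr2$survival, rep(1, 5))
  expect_error(derive_vital_rates(flat5(0.5), flat5(0)), "residency")
})

test_that("leslie eigenvalue matches the Euler-Lotka bisection oracle", {
  cfg <- pva_config(survival = c(female_juvenile = 0.29, female_adult = 0.89,
                                 male_juvenile = 0.23, male_subadult = 0.57,
                                 male_adult = 0.77))
  ll <- leslie_lambda(cfg)
  # independent oracle: root of the renewal equation
  f <- 0.62 * 1.5 * 0.5 * 0.29
  lam_el <- euler_lotka_lambda(f, 0.89)
  expect_equal(ll$lambda, lam_el, tolerance = 1e-8)
  expect_gt(ll$lambda, 0.97)
  expect_lt(ll$lambda, 1.03)
  # pure persistence: survival 1 with recruitment exactly replacing the
  # max-age die-off (f = 1/20 per breeding-age female) -> lambda = 1
  cfg1 <- pva_config(survival = flat5(1), breeding_female = 0.1,
                     litter_mean = 1)
  expect_equal(leslie_lambda(cfg1)$lambda, 1, tolerance = 1e-8)
  # lambda strictly increasing in adult female survival
  lams <- sapply(seq(0.7, 0.95, length.out = 5), function(s) {
    sv <- cfg$survival; sv["female_adult"] <- s
    leslie_lambda(pva_config(survival = sv))$lambda
  })
  expect_true(all(diff(lams) > 0))
})

test_that("stable stage integerizes exactly and matches eigenvector shares", {
  cfg <- pva_scenario("adjusted", n0 = 73)
  ss <- stable_stage(cfg)
  expect_equal(sum(ss$Nf) + sum(ss$Nm), 73)
  expect_true(all(abs(c(ss$Nf, ss$Nm) - ss$proportions * 73) <= 1))
})

test_that("degenerate mortalities behave exactly", {
  dead <- pva_config(survival = flat5(0), years = 5, iterations = 20,
                     n0 = 40, seed = 1)
  res <- run_pva(dead)
  expect_true(all(res$extinction_year == 1))
  s <- summarize_pva(res, c(1, 5))
  expect_equal(unname(s$extinction_prob), c(1, 1))
  expect_equal(s$median_time_to_extinction, 1)
  # immortal, non-breeding, K = Inf: constant until the max-age die-off
  # (uniform-age cohort far from the maximum age over the horizon)
  frozen <- pva_config(survival = flat5(1), breeding_female = 0, K = Inf,
                       years = 8, iterations = 3, n0 = 30, max_age = 400,
                       seed = 2)
  resf <- run_pva(frozen)
  expect_true(all(resf$N == 30))
})

test_that("identical seeds reproduce the simulation exactly", {
  cfg <- pva_scenario("adjusted", years = 30, iterations = 30, seed = 3)
  a <- run_pva(cfg); b <- run_pva(cfg)
  expect_identical(a$N, b$N)
  expect_identical(a$r_values, b$r_values)
  expect_identical(a$extinction_year, b$extinction_year)
})

test_that("neutral dispersal leaves growth unchanged and lossy dispersal recovers apparent survival", {
  surv <- c(female_juvenile = 0.4, female_adult = 0.85,
            male_juvenile = 0.4, male_subadult = 0.6, male_adult = 0.75)
  disp <- flat5(0.3)
  base <- pva_config(survival = surv, dispersal = flat5(0), s_disp = 1,
                     n0 = 2000, K = Inf, years = 20, iterations = 30,
                     seed = 4)
  with_d <- pva_config(survival = surv, dispersal = disp, s_disp = 1,
                       n0 = 2000, K = Inf, years = 20, iterations = 30,
                       seed = 5)
  r0 <- run_pva(base)$r_mean
  r1 <- run_pva(with_d)$r_mean
  expect_equal(r0, r1, tolerance = 0.01)
  # s_disp = 0: realized survival of a non-breeding cohort falls to
  # S * (1 - d) = phi (the apparent-survival decomposition)
  cohort <- pva_config(survival = flat5(0.85), dispersal = flat5(0.3),
                       s_disp = 0, breeding_female = 0, n0 = 10000,
                       K = Inf, years = 2, iterations = 8,
                       max_age = 200, max_disperse_age = 200, seed = 6)
  res <- run_pva(cohort)
  realized <- mean(res$N[, 2] / res$N[, 1])
  expect_equal(realized, 0.85 * 0.7, tolerance = 0.01)
})

test_that("mean log growth matches the Leslie log-lambda at large N", {
  cfg <- pva_scenario("adjusted", n0 = 5000, K = Inf, years = 25,
                      iterations = 15, seed = 7)
  res <- run_pva(cfg)
  expect_equal(res$r_mean, leslie_lambda(cfg)$log_lambda, tolerance = 0.02)
})

test_that("carrying capacity truncates to K and extinction risk is monotone in horizon", {
  cfg <- pva_scenario("adjusted", n0 = 150, K = 120, years = 25,
                      iterations = 40, seed = 8)
  res <- run_pva(cfg)
  expect_true(all(res$N <= 150))
  expect_true(all(res$N[, -1] <= 120))
  s <- summarize_pva(res, c(10, 20, 25))
  expect_true(all(diff(s$extinction_prob) >= 0))
})

test_that("extinction probability falls with adult female survival and dispersal success", {
  ext_at <- function(s_af, s_disp) {
    sv <- c(female_juvenile = 0.29, female_adult = s_af,
            male_juvenile = 0.23, male_subadult = 0.57, male_adult = 0.77)
    cfg <- pva_config(survival = sv, dispersal = flat5(0.3),
                      s_disp = s_disp, n0 = 50, K = 200, years = 60,
                      iterations = 150, seed = 9)
    mean(!is.na(run_pva(cfg)$extinction_year))
  }
  # 5-point grid in adult female survival (dispersal success fixed)
  grid_af <- sapply(c(0.5, 0.65, 0.8, 0.9, 0.97), ext_at, s_disp = 1)
  expect_true(all(diff(grid_af) <= 0))
  expect_gt(grid_af[1], grid_af[5])
  # 5-point grid in dispersal success (survival fixed mid-range)
  grid_sd <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(sd)
    ext_at(0.85, sd))
  expect_true(all(diff(grid_sd) <= 0.05))  # monotone up to MC noise
  expect_gt(grid_sd[1], grid_sd[5])
})
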