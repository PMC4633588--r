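# CJS likelihood, fitting, AICc ranking/averaging, prediction and
# abundance adjustment.

test_that("likelihood matches hand results for two-occasion histories", {
  d <- cjs_design(~1, ~1)
  ch <- make_ch(matrix(c(1, 1), 1, 2))
  # phi = p = 0.5: P(11) = phi * p = 0.25
  expect_equal(cjs_negloglik(c(0, 0), ch, d), -log(0.25))
  ch10 <- make_ch(matrix(c(1, 0), 1, 2))
  # P(10) = (1 - phi) + phi (1 - p) = 0.75
  expect_equal(cjs_negloglik(c(0, 0), ch10, d), -log(0.75))
  expect_error(cjs_negloglik(c(NaN, 0), ch, d), "non-finite")
})

test_that("likelihood equals the enumeration oracle for T <= 4", {
  d <- cjs_design(~1, ~1)
  set.seed(31)
  for (T in 2:4) {
    phi <- stats::runif(T - 1, 0.2, 0.9)
    p <- c(NA, stats::runif(T - 1, 0.2, 0.9))
    pars <- c(stats::qlogis(phi), stats::qlogis(p[-1]))
    mats <- per_occasion_mats(1, T)
    # all histories starting with a release at occasion 1
    tails <- as.matrix(expand.grid(rep(list(0:1), T - 1)))
    for (r in seq_len(nrow(tails))) {
      h <- c(1L, tails[r, ])
      ch <- make_ch(matrix(h, 1, T))
      expect_equal(cjs_negloglik(pars, ch, d, mats = mats),
                   -log(enum_history_prob(h, phi, p)), tolerance = 1e-10)
    }
  }
})

test_that("post-release history probabilities sum to one", {
  d <- cjs_design(~1, ~1)
  set.seed(77)
  for (T in 2:4) {
    phi <- stats::runif(T - 1)
    p <- stats::runif(T - 1)
    pars <- c(stats::qlogis(phi), stats::qlogis(p))
    mats <- per_occasion_mats(1, T)
    tails <- as.matrix(expand.grid(rep(list(0:1), T - 1)))
    probs <- apply(tails, 1, function(tail) {
      ch <- make_ch(matrix(c(1L, tail), 1, T))
      exp(-cjs_negloglik(pars, ch, d, mats = mats))
    })
    expect_equal(sum(probs), 1, tolerance = 1e-10)
  }
})

test_that("aicc implements the small-sample correction", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-1120.22, 13, 868), 2 * 1120.22 + 26 + 364 / 854)
  # monotone decreasing in ess, converging to AIC
  k <- 5; ll <- -100
  vals <- sapply(c(20, 100, 1000, 1e7), function(ess) aicc(ll, k, ess))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[4], -2 * ll + 2 * k, tolerance = 1e-4)
  expect_error(aicc(0, 10, 11), "ess")
})

test_that("constant-model fit recovers known parameters and flags degenerate input", {
  set.seed(5)
  ch <- simulate_const_ch(400, 12, phi = 0.8, p = 0.6)
  fit <- fit_cjs(ch, cjs_design(~1, ~1), n_starts = 2)
  expect_true(fit$converged)
  expect_equal(invlogit(fit$coefficients$estimate[1]), 0.8, tolerance = 0.08)
  expect_equal(invlogit(fit$coefficients$estimate[2]), 0.6, tolerance = 0.08)
  expect_equal(fit$ess, sum(ch$y[, -ch$T]))
  expect_error(fit_cjs(make_ch(matrix(1, 3, 1)), cjs_design(~1, ~1)),
               "occasions")
})

test_that("a positive effort effect on detection is recovered with the right sign", {
  # heterogeneous effort drives p; fitted effort coefficient positive with
  # 95% interval excluding zero
  set.seed(17)
  n <- 1000; T <- 12
  effort <- round(stats::runif(T, 20, 250))
  p_t <- invlogit(-2 + 0.015 * effort)
  y <- matrix(0L, n, T); y[, 1] <- 1L
  alive <- rep(TRUE, n)
  for (t in 2:T) {
    alive <- alive & (stats::runif(n) < 0.85)
    y[alive & (stats::runif(n) < p_t[t]), t] <- 1L
  }
  ch <- make_ch(y, occasions = dummy_occasions(T, effort = effort))
  fit <- fit_cjs(ch, cjs_design(~1, ~effort), n_starts = 3)
  co <- fit$coefficients[fit$coefficients$term == "p:effort", ]
  expect_gt(co$estimate, 0)
  expect_gt(co$lcl, 0)
})

test_that("nested models never fit worse and weights behave", {
  set.seed(23)
  ch <- simulate_const_ch(200, 8, 0.75, 0.5)
  f0 <- fit_cjs(ch, cjs_design(~1, ~1), n_starts = 2)
  f1 <- fit_cjs(ch, cjs_design(~1, ~effort + flow_1m, label = "p(eff+flow)"),
                n_starts = 2)
  expect_true(f1$converged)
  # covariates are constant here, so the extra terms are pure flexibility:
  # minimized negative log-likelihood cannot increase
  expect_lte(-f1$loglik, -f0$loglik + 1e-4)
  mt <- rank_and_average(list(f0, f1))
  expect_equal(sum(mt$table$weight), 1)
  # weights invariant to a constant AICc shift
  w <- akaike_weights(c(0, 1.3, 4.2))
  expect_equal(akaike_weights(c(0, 1.3, 4.2) + 17), w)
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
})

test_that("model-averaged and single-fit real-parameter predictions agree on structure", {
  set.seed(41)
  ch <- simulate_const_ch(300, 10, 0.8, 0.6)
  f0 <- fit_cjs(ch, cjs_design(~1, ~1), n_starts = 2)
  nd <- data.frame(effort = 10, flow_1m = 1)
  pr <- predict_real(f0, nd, "p")
  expect_true(pr$lcl < pr$estimate & pr$estimate < pr$ucl)
  mt <- rank_and_average(list(f0))
  expect_equal(predict_real(mt, nd, "p")$estimate, pr$estimate)
  expect_error(predict_real(f0, data.frame(x = 1), "p"), NA)
})

test_that("all-zero coefficients predict one half", {
  coefs <- c(intercept = 0, flow_1m = 0, effort = 0, subadult = 0, adult = 0)
  expect_equal(unname(predict_detection(coefs, 3.8, 10, "adult")), 0.5)
  expect_equal(unname(predict_detection(coefs, 120, 400, "juvenile")), 0.5)
})

test_that("capture histories collapse within-occasion recaptures and propagate age", {
  occ <- dummy_occasions(4)
  raw <- data.frame(
    animal_id = c("a1", "a1", "a1", "a2"),
    date = c("2000-08-01", "2000-12-15", "2002-09-01", "2001-08-02"),
    pool_id = "p1",
    sex = c("female", "female", "female", "male"),
    age_class = c("juvenile", "juvenile", "adult", "subadult"),
    weight_g = c("600", "640", "880", "1100"),
    length_cm = "40", lactating = "untested", effort_hours = "10")
  records <- platypopdyn:::validate_capture_records(raw)
  ch <- build_capture_histories(records, occ)
  expect_equal(unname(ch$y["a1", ]), c(1L, 0L, 1L, 0L))  # two captures, one 1
  # juvenile female first caught year t is adult from t+1 onward
  expect_equal(unname(ch$age_class[1, ]), c("juvenile", "adult", "adult", "adult"))
  # per-stage mean weight: juvenile captures averaged, adult stage separate
  expect_equal(ch$weight[1, 1], 620)
  expect_equal(ch$weight[1, 3], 880)
  bad <- records; bad$date[1] <- as.Date("1990-01-01")
  expect_error(build_capture_histories(bad, occ), "outside")
})

test_that("encounter row sums match the generator's capture counts", {
  sim <- small_sim(years = 10, initial_n = 60, seed = 202)
  occ <- build_occasions(sim$records, sim$flows)
  ch <- build_capture_histories(sim$records, occ)
  truth_counts <- rowSums(sim$captured)
  caught <- which(truth_counts > 0)
  expect_equal(unname(rowSums(ch$y)[sim$truth$id[caught]]),
               unname(truth_counts[caught]))
})

test_that("abundance adjustment divides by detectability and fits a trend", {
  out <- estimate_abundance_trend(c(10, 10, 10), c(0.5, 0.5, 0.5))
  expect_equal(out$adjusted, c(20, 20, 20))
  expect_equal(out$slope, 0)
  raw <- c(12, 18, 25, 31)
  id1 <- estimate_abundance_trend(raw, rep(1, 4))
  expect_equal(id1$adjusted, raw)
  expect_equal(id1$slope, unname(coef(lm(raw ~ seq_along(raw)))[2]))
  expect_true(all(estimate_abundance_trend(raw, rep(0.7, 4))$adjusted >= raw))
  expect_error(estimate_abundance_trend(c(1, 2), c(0, 0.5)), "p_hat")
})
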