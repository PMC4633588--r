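# Bayesian building blocks: Binomial-Beta proportion tests, a
# semi-conjugate Gibbs linear model for morphometrics, random-walk
# Metropolis Poisson regression of lactation counts on flow, and the
# descriptive breeding statistics.

#' Bayesian test of a proportion
#'
#' Exact conjugate update `x ~ Binomial(theta, n)`, `theta ~ Beta(1, 1)`,
#' giving posterior `Beta(1 + x, 1 + n - x)` with equal-tailed credible
#' interval.
#'
#' @param x successes (0 <= x <= n).
#' @param n trials.
#' @param level credible level (default 0.95).
#' @return list of class `proportion_posterior`: `x`, `n`, `shape1`,
#'   `shape2`, `mean` (= `(x+1)/(n+2)`), `lower`, `upper`, `level`.
#' @export
beta_binomial_test <- function(x, n, level = 0.95) {
  if (x < 0 || n < 0 || x > n) stopf("need 0 <= x <= n (got x=%g, n=%g)", x, n)
  a <- 1 + x; b <- 1 + n - x
  alpha <- (1 - level) / 2
  out <- list(x = x, n = n, shape1 = a, shape2 = b, mean = a / (a + b),
              lower = stats::qbeta(alpha, a, b),
              upper = stats::qbeta(1 - alpha, a, b), level = level)
  class(out) <- "proportion_posterior"
  out
}

#' Bayesian difference of two proportions
#'
#' Monte-Carlo posterior of `theta1 - theta2` from paired draws of the two
#' independent Beta posteriors.
#'
#' @param x1,n1,x2,n2 successes/trials of the two groups.
#' @param level credible level.
#' @param n_draws paired posterior draws (default 100000).
#' @param seed optional seed.
#' @return list: `mean`, `sd`, `lower`, `upper`, `prob_positive`.
#' @export
beta_binomial_diff <- function(x1, n1, x2, n2, level = 0.95,
                               n_draws = 100000L, seed = NULL) {
  p1 <- beta_binomial_test(x1, n1, level)
  p2 <- beta_binomial_test(x2, n2, level)
  with_seed(seed, {
    d <- stats::rbeta(n_draws, p1$shape1, p1$shape2) -
      stats::rbeta(n_draws, p2$shape1, p2$shape2)
    a <- (1 - level) / 2
    list(mean = mean(d), sd = stats::sd(d),
         lower = unname(stats::quantile(d, a)),
         upper = unname(stats::quantile(d, 1 - a)),
         prob_positive = mean(d > 0))
  })
}

#' Semi-conjugate Gibbs sampler for the Gaussian linear model
#'
#' `y = X beta + e`, `e ~ N(0, sigma^2)`, with a flat Gaussian prior on
#' `beta` (mean and precision zero) and an inverse-Gamma(c0, d0) prior on
#' `sigma^2`.  The sampler alternates the Gaussian full conditional of
#' `beta` and the inverse-Gamma full conditional of `sigma^2`.
#'
#' @param y numeric response.
#' @param X design matrix (full column rank, `nrow(X) > ncol(X)`).
#' @param draws post-burn-in draws (default 10000).
#' @param burn_in burn-in draws (default 1000).
#' @param thin thinning interval (default 5; `draws/thin` draws retained).
#' @param c0,d0 inverse-Gamma prior shape/rate (default 0.001).
#' @param seed optional seed.
#' @return list of class `gibbs_fit`: `summary` data.frame (mean, sd,
#'   2.5%, 97.5% per coefficient and for `sigma2`), retained draw matrices
#'   `beta` and `sigma2`, and `trace` (running means of the first
#'   coefficient in 10 segments, a convergence diagnostic).
#' @export
gibbs_linear_model <- function(y, X, draws = 10000L, burn_in = 1000L,
                               thin = 5L, c0 = 0.001, d0 = 0.001,
                               seed = NULL) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stopf("rows(X) != length(y)")
  if (n <= p) stopf("need more observations than coefficients")
  if (qr(X)$rank < p) stopf("design matrix is rank deficient")
  if (draws <= 0 || thin < 1) stopf("draws must be > 0 and thin >= 1")
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  bhat <- drop(XtXinv %*% crossprod(X, y))
  L <- chol(XtXinv)
  with_seed(seed, {
    n_keep <- floor(draws / thin)
    B <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
    S2 <- numeric(n_keep)
    sigma2 <- stats::var(y)
    kept <- 0L
    total <- burn_in + draws
    for (it in seq_len(total)) {
      beta <- bhat + sqrt(sigma2) * drop(crossprod(L, stats::rnorm(p)))
      rss <- sum((y - drop(X %*% beta))^2)
      sigma2 <- 1 / stats::rgamma(1, c0 + n / 2, d0 + rss / 2)
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        B[kept, ] <- beta
        S2[kept] <- sigma2
      }
    }
    qs <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        q2.5 = unname(stats::quantile(v, 0.025)),
                        q97.5 = unname(stats::quantile(v, 0.975)))
    sm <- rbind(t(apply(B, 2, qs)), sigma2 = qs(S2))
    seg <- split(B[, 1], cut(seq_len(nrow(B)), 10, labels = FALSE))
    out <- list(summary = as.data.frame(sm), beta = B, sigma2 = S2,
                trace = vapply(seg, mean, 0), ols = bhat)
    class(out) <- "gibbs_fit"
    out
  })
}

#' Bayesian Poisson regression of annual lactation counts on flow
#'
#' `y_t ~ Poisson(n_t exp(a + b x_t))` with flat priors on `(a, b)`;
#' posterior sampled by random-walk Metropolis (proposal covariance scaled
#' from the maximum-likelihood fit).
#'
#' @param y annual counts of lactating females.
#' @param offsetn annual counts of tested females (`y <= offsetn`).
#' @param x annual flow covariate (GL).
#' @param draws post-burn-in draws (default 10000).
#' @param burn_in burn-in draws (default 1000).
#' @param seed optional seed.
#' @return list of class `bayes_poisson`: `summary` (mean, sd, 2.5%, 97.5%
#'   for intercept and slope), draw matrix `draws`, `acceptance`.
#' @export
bayes_poisson_regression <- function(y, offsetn, x, draws = 10000L,
                                     burn_in = 1000L, seed = NULL) {
  if (length(y) < 3L) stopf("need at least 3 years")
  if (all(offsetn == 0)) stopf("all-zero exposure")
  if (any(y > offsetn)) stopf("y must be <= offsetn elementwise")
  keep <- offsetn > 0
  y <- y[keep]; offsetn <- offsetn[keep]; x <- x[keep]
  logpost <- function(th)
    sum(stats::dpois(y, offsetn * exp(th[1] + th[2] * x), log = TRUE))
  if (stats::var(x) == 0)
    stopf("x is constant: the slope is not identifiable under a flat prior")
  ml <- suppressWarnings(stats::glm(y ~ x, family = stats::poisson(),
                                    offset = log(offsetn)))
  start <- unname(stats::coef(ml))
  prop_chol <- chol(stats::vcov(ml)) * 2.4 / sqrt(2)
  with_seed(seed, {
    th <- start; lp <- logpost(th)
    out <- matrix(NA_real_, draws, 2, dimnames = list(NULL, c("intercept", "slope")))
    acc <- 0L
    for (it in seq_len(burn_in + draws)) {
      cand <- th + drop(crossprod(prop_chol, stats::rnorm(2)))
      lp_c <- logpost(cand)
      if (is.finite(lp_c) && log(stats::runif(1)) < lp_c - lp) {
        th <- cand; lp <- lp_c; acc <- acc + 1L
      }
      if (it > burn_in) out[it - burn_in, ] <- th
    }
    qs <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        q2.5 = unname(stats::quantile(v, 0.025)),
                        q97.5 = unname(stats::quantile(v, 0.975)))
    res <- list(summary = as.data.frame(t(apply(out, 2, qs))), draws = out,
                acceptance = acc / (burn_in + draws))
    class(res) <- "bayes_poisson"
    res
  })
}

# Decade bins used throughout the descriptive summaries.
DECADES <- list("1973-1983" = 1973:1983, "1984-1993" = 1984:1993,
                "1994-2003" = 1994:2003, "2004-2014" = 2004:2014)

decade_of <- function(year) {
  out <- rep(NA_character_, length(year))
  for (d in names(DECADES)) out[year %in% DECADES[[d]]] <- d
  out
}

#' Breeding, lactation and composition statistics
#'
#' Computes: the annual lactation index (lactating / tested females among
#' December-January captures, one status per female per season), per-decade
#' lactation proportions (females once per year, multiple times per
#' decade), the consecutive-year breeding table (females tested in both
#' seasons of a year pair: both / first only / second only / neither), and
#' per-decade sex-ratio and juvenile:adult proportions (unique animals per
#' year) with Beta-Binomial posteriors.
#'
#' @param records a `capture_records` data.frame.
#' @return list of class `breeding_stats` with components `annual_index`
#'   (data.frame season, n_tested, n_lactating, index), `mean_index`,
#'   `decade_lactation`, `consecutive` (fractions summing to 1 and `n`),
#'   `decade_sex_ratio`, `decade_age_ratio`.
#' @export
breeding_stats <- function(records) {
  yr <- as.integer(format(records$date, "%Y"))
  mo <- as.integer(format(records$date, "%m"))
  # breeding season of a Dec/Jan capture: Dec of year y pairs with Jan y+1
  season <- ifelse(mo == 12L, yr, ifelse(mo == 1L, yr - 1L, NA))
  tested <- records$sex == "female" & records$lactating != "untested" &
    !is.na(season)
  td <- data.frame(id = records$animal_id[tested], season = season[tested],
                   lact = records$lactating[tested] == "yes")
  # one status per female per season (lactating if any yes)
  if (nrow(td)) {
    agg <- stats::aggregate(lact ~ id + season, td, any)
  } else {
    agg <- data.frame(id = character(), season = integer(), lact = logical())
  }
  ann <- if (nrow(agg)) {
    a <- stats::aggregate(cbind(n_tested = lact, n_lactating = lact) ~ season,
                          agg, function(v) c(length(v), sum(v)))
    data.frame(season = a$season, n_tested = a$n_tested[, 1],
               n_lactating = a$n_lactating[, 2])
  } else data.frame(season = integer(), n_tested = integer(),
                    n_lactating = integer())
  ann$index <- ifelse(ann$n_tested > 0, ann$n_lactating / ann$n_tested, NA)

  # per-decade lactation proportion (female-years)
  dec_lact <- lapply(names(DECADES), function(d) {
    sub <- agg[decade_of(agg$season) == d & !is.na(decade_of(agg$season)), ]
    if (!nrow(sub))
      return(data.frame(decade = d, n = 0L, x = 0L, mean = NA_real_,
                        lower = NA_real_, upper = NA_real_, absent = TRUE))
    post <- beta_binomial_test(sum(sub$lact), nrow(sub))
    data.frame(decade = d, n = nrow(sub), x = sum(sub$lact), mean = post$mean,
               lower = post$lower, upper = post$upper, absent = FALSE)
  })
  dec_lact <- do.call(rbind, dec_lact)

  # consecutive-season breeding table
  cons <- c(both = 0L, first_only = 0L, second_only = 0L, neither = 0L)
  if (nrow(agg)) {
    key <- split(agg, agg$id)
    for (a in key) {
      s <- sort(a$season)
      for (yy in s[(s + 1L) %in% s]) {
        l1 <- a$lact[a$season == yy]; l2 <- a$lact[a$season == yy + 1L]
        slot <- if (l1 && l2) "both" else if (l1) "first_only" else if (l2)
          "second_only" else "neither"
        cons[slot] <- cons[slot] + 1L
      }
    }
  }
  n_pairs <- sum(cons)
  cons_frac <- if (n_pairs > 0) cons / n_pairs else cons * NA_real_

  # unique animal-years for composition ratios
  ay <- records[!duplicated(paste(records$animal_id, yr)), ]
  ay_yr <- as.integer(format(ay$date, "%Y"))
  comp <- function(flag) {
    rows <- lapply(names(DECADES), function(d) {
      sub <- flag[decade_of(ay_yr) == d & !is.na(decade_of(ay_yr))]
      if (!length(sub))
        return(data.frame(decade = d, n = 0L, x = 0L, mean = NA_real_,
                          lower = NA_real_, upper = NA_real_, absent = TRUE))
      post <- beta_binomial_test(sum(sub), length(sub))
      data.frame(decade = d, n = length(sub), x = sum(sub), mean = post$mean,
                 lower = post$lower, upper = post$upper, absent = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- list(annual_index = ann,
              mean_index = mean(ann$index, na.rm = TRUE),
              decade_lactation = dec_lact,
              consecutive = list(fractions = cons_frac, n = n_pairs),
              decade_sex_ratio = comp(ay$sex == "female"),
              decade_age_ratio = comp(ay$age_class == "juvenile"))
  class(out) <- "breeding_stats"
  out
}
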