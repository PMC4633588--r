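# Shared fixture builders and independent oracles.  Oracles here are kept
# deliberately naive (enumeration, bisection, quadrature) so they stay
# independent of the implementation paths they check.

# Minimal occasions table with constant covariates.
dummy_occasions <- function(T, effort = 10, flow = 1) {
  start <- as.Date("2000-07-01") + 365 * (seq_len(T) - 1)
  occ <- data.frame(index = seq_len(T), year = 2000 + seq_len(T) - 1,
                    start = start, end = start + 365,
                    midpoint = start + 182,
                    effort_hours = effort, zero_effort = effort == 0,
                    flow_1m = flow, flow_6m = 6 * flow,
                    flow_12m = 12 * flow, flow_24m = 24 * flow)
  class(occ) <- c("occasions", "data.frame")
  occ
}

# Minimal capture_histories object around an encounter matrix.
make_ch <- function(y, sex = NULL, occasions = NULL) {
  y <- as.matrix(y)
  n <- nrow(y); T <- ncol(y)
  if (is.null(sex)) sex <- rep("female", n)
  if (is.null(occasions)) occasions <- dummy_occasions(T)
  ch <- list(y = y, first = apply(y == 1, 1, which.max), n = n, T = T,
             sex = sex, age_first = rep(1L, n),
             age_class = matrix("adult", n, T),
             class5 = matrix(ifelse(sex == "female", "female_adult",
                                    "male_adult"), n, T),
             weight = matrix(900, n, T), occasions = occasions)
  class(ch) <- "capture_histories"
  ch
}

# Design matrices giving one free logit-scale parameter per survival
# interval and per detection occasion (arbitrary time-varying phi/p).
per_occasion_mats <- function(n, T) {
  list(Xphi = kronecker(diag(T - 1), matrix(1, n, 1)),
       Xp = kronecker(diag(T - 1), matrix(1, n, 1)),
       kphi = T - 1L, kp = T - 1L)
}

# ORACLE: probability of one capture history by exhaustive enumeration of
# the occasion of death (fates), for occasion-varying phi (intervals
# 1..T-1) and p (occasions 2..T; p[1] unused).
enum_history_prob <- function(h, phi, p) {
  T <- length(h)
  f <- which(h == 1)[1]
  caps <- which(h == 1)
  total <- 0
  for (L in f:T) {               # L = last occasion alive
    if (any(caps > L)) next
    pr <- 1
    if (L > f) pr <- prod(phi[f:(L - 1)])
    if (L < T) pr <- pr * (1 - phi[L])
    if (L > f)
      pr <- pr * prod(ifelse(h[(f + 1):L] == 1, p[(f + 1):L],
                             1 - p[(f + 1):L]))
    total <- total + pr
  }
  total
}

# Simulate constant-(phi, p) capture histories, all released at occasion 1.
simulate_const_ch <- function(n, T, phi, p) {
  y <- matrix(0L, n, T)
  y[, 1] <- 1L
  alive <- rep(TRUE, n)
  for (t in 2:T) {
    alive <- alive & (stats::runif(n) < phi)
    y[alive & (stats::runif(n) < p), t] <- 1L
  }
  make_ch(y)
}

# ORACLE: Euler-Lotka growth rate by bisection for a female life cycle
# with first breeding at age `afb`, last at `amax`, survivorship to census
# age a of S_adult^(a-1), and per-capita recruitment f (daughters reaching
# census age 1 per breeding-age female per year).
euler_lotka_lambda <- function(f, s_adult, afb = 2, amax = 21) {
  g <- function(lam)
    sum(f * s_adult^(seq(afb, amax) - 1) * lam^(-seq(afb, amax))) - 1
  stats::uniroot(g, c(0.2, 3), tol = 1e-12)$root
}

validate_flows_fixture <- function(y0, y1, flow = 1) {
  platypopdyn:::validate_flow_series(
    data.frame(year = rep(y0:y1, each = 12), month = rep(1:12, y1 - y0 + 1),
               flow_gl = flow))
}

two_record_fixture <- function(d1, d2) {
  platypopdyn:::validate_capture_records(data.frame(
    animal_id = c("a1", "a2"), date = c(d1, d2), pool_id = "p1",
    sex = "female", age_class = "adult", weight_g = "900",
    length_cm = "42", lactating = "no", effort_hours = "10"))
}

# Small synthetic dataset shared across io/movement/bayes tests.
small_sim <- function(years = 12, initial_n = 80, seed = 101, ...) {
  cfg <- truth_config(years = years, initial_n = initial_n, seed = seed, ...)
  truth <- simulate_population(cfg)
  surveys <- simulate_surveys(truth, cfg)
  list(cfg = cfg, truth = truth, records = surveys$records,
       captured = surveys$captured, flows = truth$flows,
       pools = truth$pools)
}
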