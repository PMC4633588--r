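# Global sensitivity analysis of viability over class mortalities and
# dispersal success, with GCV-selected cubic smoothing-spline response
# curves of (log-transformed, centred) time to extinction.
#
# The smoothing spline is the natural-cubic-spline minimizer of
# sum (y - g(x))^2 + lambda * integral g''(x)^2 dx (Reinsch form); the
# penalty matrix K = Q R^-1 Q' is built from the knot spacings, the hat
# matrix is H = N (N'N + lambda K)^-1 N', and lambda minimizes
# GCV(lambda) = n RSS / (n - tr H)^2 over a log-spaced grid refined by
# golden-section search.

SCENARIO_DIMS <- c("female_juvenile_mortality", "female_adult_mortality",
                   "male_juvenile_mortality", "male_subadult_mortality",
                   "male_adult_mortality", "s_disp")

#' Latin-hypercube sample of viability scenarios
#'
#' Samples the five class mortalities and the disperser transit survival
#' (dispersal success) jointly by Latin hypercube: each margin is
#' stratified with exactly one value per 1/n quantile band.
#'
#' @param ranges named list of `c(lo, hi)` ranges for the six dimensions
#'   (`female_juvenile_mortality`, ..., `male_adult_mortality`, `s_disp`);
#'   defaults to `[0, 1]` everywhere.  A degenerate range (`lo == hi`)
#'   holds that dimension constant, with a warning.
#' @param n number of scenarios.
#' @param seed optional seed (same seed, same table).
#' @return data.frame of class `scenario_table` with the six input columns
#'   and a per-row child `seed`.
#' @export
sample_scenarios <- function(ranges = NULL, n = 500L, seed = NULL) {
  if (n < 1) stopf("n must be >= 1")
  full <- stats::setNames(rep(list(c(0, 1)), length(SCENARIO_DIMS)),
                          SCENARIO_DIMS)
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), SCENARIO_DIMS)
    if (length(bad)) stopf("unknown scenario dimension(s): %s",
                           paste(bad, collapse = ", "))
    full[names(ranges)] <- ranges
  }
  with_seed(seed, {
    U <- lhs::randomLHS(n, length(SCENARIO_DIMS))
    out <- as.data.frame(mapply(function(u, r) {
      if (r[1] == r[2]) {
        warnf("degenerate range [%g, %g]: dimension held constant", r[1], r[2])
        rep(r[1], length(u))
      } else r[1] + u * (r[2] - r[1])
    }, as.data.frame(U), full))
    names(out) <- SCENARIO_DIMS
    out$seed <- sample.int(2147483646L, n)
    class(out) <- c("scenario_table", "data.frame")
    out
  })
}

#' Run the viability model over a scenario table
#'
#' For each row, runs [run_pva()] with the row's mortalities and dispersal
#' success overriding the base configuration, and records the median time
#' to extinction (censored at the horizon when fewer than half the
#' iterations went extinct) and the mean stochastic growth rate.
#'
#' @param scenarios a [sample_scenarios()] table.
#' @param base a [pva_config()] supplying everything the rows do not
#'   (reproduction, dispersal fractions, N0, K, horizon).
#' @param iterations iterations per scenario (default 200).
#' @return the completed `scenario_table` with `time_to_extinction`,
#'   `censored` and `mean_r` columns.
#' @export
run_sensitivity <- function(scenarios, base, iterations = 200L) {
  stopifnot(inherits(base, "pva_config"))
  n <- nrow(scenarios)
  tte <- numeric(n); cens <- logical(n); mr <- numeric(n)
  for (i in seq_len(n)) {
    row <- scenarios[i, ]
    surv <- 1 - c(female_juvenile = row$female_juvenile_mortality,
                  female_adult = row$female_adult_mortality,
                  male_juvenile = row$male_juvenile_mortality,
                  male_subadult = row$male_subadult_mortality,
                  male_adult = row$male_adult_mortality)
    cfg <- base
    cfg$survival <- surv[CLASS_LEVELS]
    cfg$s_disp <- row$s_disp
    cfg$iterations <- as.integer(iterations)
    cfg$seed <- row$seed
    res <- tryCatch(run_pva(cfg),
                    error = function(e) stopf("scenario row %d: %s", i,
                                              conditionMessage(e)))
    ext <- res$extinction_year
    if (mean(!is.na(ext)) >= 0.5) {
      tte[i] <- stats::median(ext[!is.na(ext)]); cens[i] <- FALSE
    } else {
      tte[i] <- cfg$years; cens[i] <- TRUE
    }
    mr[i] <- res$r_mean
  }
  scenarios$time_to_extinction <- tte
  scenarios$censored <- cens
  scenarios$mean_r <- mr
  scenarios
}

# Natural-cubic-spline penalty matrix K (k x k) for sorted knots t.
spline_penalty <- function(t) {
  k <- length(t)
  h <- diff(t)
  Q <- matrix(0, k, k - 2L)
  R <- matrix(0, k - 2L, k - 2L)
  for (j in 2:(k - 1L)) {
    Q[j - 1L, j - 1L] <- 1 / h[j - 1L]
    Q[j, j - 1L] <- -1 / h[j - 1L] - 1 / h[j]
    Q[j + 1L, j - 1L] <- 1 / h[j]
    R[j - 1L, j - 1L] <- (h[j - 1L] + h[j]) / 3
    if (j < k - 1L) {
      R[j - 1L, j] <- h[j] / 6
      R[j, j - 1L] <- h[j] / 6
    }
  }
  Q %*% solve(R, t(Q))
}

# Solve the penalized problem at one lambda (ratio scale: the effective
# penalty is lambda * tr(N'N)/tr(K), which keeps the system well
# conditioned across the search range).  Returns knot values g, fitted
# values, RSS, edf (= tr H), gcv.
spline_solve <- function(xs, ys, t, Kpen, counts, idx, lambda) {
  n <- length(ys)
  A <- Kpen * (lambda * sum(counts) / sum(diag(Kpen)))
  diag(A) <- diag(A) + counts
  Nty <- drop(rowsum(ys, idx))      # N'y over knot groups
  Ainv <- chol2inv(chol(A))
  g <- drop(Ainv %*% Nty)
  fitted <- g[idx]
  rss <- sum((ys - fitted)^2)
  edf <- sum(counts * diag(Ainv))
  list(g = g, fitted = fitted, rss = rss, edf = edf,
       gcv = n * rss / (n - edf)^2, Ainv = Ainv)
}

#' GCV score of the smoothing spline at a given penalty
#'
#' Exposed so the GCV minimization can be checked against an exhaustive
#' grid; `lambda` is on the internal ratio scale (`x` mapped to `[0, 1]`,
#' penalty scaled by `tr(N'N)/tr(K)`).
#'
#' @param x predictor (>= 10 distinct values).
#' @param y response.
#' @param lambda penalty (vectorized).
#' @return data.frame with `lambda`, `gcv`, `edf`.
#' @export
spline_gcv <- function(x, y, lambda) {
  pre <- spline_prep(x, y)
  rows <- lapply(lambda, function(l) {
    s <- spline_solve(pre$xs, pre$ys, pre$t, pre$K, pre$counts, pre$idx, l)
    data.frame(lambda = l, gcv = s$gcv, edf = s$edf)
  })
  do.call(rbind, rows)
}

spline_prep <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xr <- range(x)
  if (length(unique(x)) < 10L) stopf("need at least 10 distinct x values")
  xs <- (x - xr[1]) / (xr[2] - xr[1])   # internal [0,1] scale
  ord <- order(xs)
  xs <- xs[ord]; ys <- y[ord]
  t <- unique(xs)
  idx <- match(xs, t)
  counts <- tabulate(idx, nbins = length(t))
  list(xs = xs, ys = ys, t = t, idx = idx, counts = counts,
       K = spline_penalty(t), ord = ord, xrange = xr, x = x[ord])
}

#' Fit a GCV-selected cubic smoothing spline
#'
#' Cubic smoothing spline with the penalty chosen by minimizing
#' `GCV(lambda) = n RSS / (n - tr H)^2` over a log-spaced grid refined by
#' golden-section search; reports the effective degrees of freedom
#' `edf = tr(H)` and a pointwise +/-2 SE band.
#'
#' @param x predictor (>= 10 distinct values required).
#' @param y response (e.g. log-transformed centred time to extinction).
#' @param lambda_grid internal-scale candidate penalties (default 73
#'   log-spaced values over 1e-9..1e9).
#' @param lambda optional fixed penalty (internal ratio scale); skips the
#'   GCV search when supplied.
#' @return object of class `gcv_spline`: `lambda`, `edf`, `fitted`,
#'   `se_fit`, `sigma2`, knot values, and the data (sorted by `x`).
#' @export
fit_gcv_spline <- function(x, y, lambda_grid = 10^seq(-9, 9, length.out = 73),
                           lambda = NULL) {
  pre <- spline_prep(x, y)
  n <- length(pre$ys)
  gcv_at <- function(l) spline_solve(pre$xs, pre$ys, pre$t, pre$K,
                                     pre$counts, pre$idx, l)$gcv
  if (is.null(lambda)) {
    sols <- lapply(lambda_grid, function(l)
      spline_solve(pre$xs, pre$ys, pre$t, pre$K, pre$counts, pre$idx, l))
    scores <- vapply(sols, `[[`, 0, "gcv")
    rsss <- vapply(sols, `[[`, 0, "rss")
    # candidates whose RSS is numerically zero relative to the response
    # scale (e.g. an exactly representable signal) are ties; ties resolve
    # to the smoothest candidate
    near <- scores <= min(scores) * (1 + 1e-9) |
      rsss <= 1e-20 * max(sum(pre$ys^2), .Machine$double.xmin)
    i <- max(which(near))
    lo <- log(lambda_grid[max(1L, i - 1L)])
    hi <- log(lambda_grid[min(length(lambda_grid), i + 1L)])
    opt <- stats::optimize(function(ll) gcv_at(exp(ll)), c(lo, hi),
                           tol = 1e-6)
    lambda <- exp(opt$minimum)
    if (gcv_at(lambda) > scores[i]) lambda <- lambda_grid[i]
  }
  sol <- spline_solve(pre$xs, pre$ys, pre$t, pre$K, pre$counts, pre$idx,
                      lambda)
  sigma2 <- sol$rss / max(n - sol$edf, 1e-8)
  # pointwise variance of the fit: sigma^2 * diag(H H') with
  # H[j, l] = Ainv[idx_j, idx_l] (N is the 0/1 knot incidence)
  B <- sol$Ainv[pre$idx, , drop = FALSE]                  # n x k
  HHt_diag <- rowSums(B[, pre$idx, drop = FALSE]^2)
  out <- list(lambda = lambda, edf = sol$edf, gcv = sol$gcv,
              sigma2 = sigma2, knots = pre$t, g = sol$g,
              x = pre$x, y = pre$ys, fitted = sol$fitted,
              se_fit = sqrt(sigma2 * HHt_diag), xrange = pre$xrange)
  class(out) <- "gcv_spline"
  out
}

#' @export
predict.gcv_spline <- function(object, newdata = object$x, ...) {
  xs <- (newdata - object$xrange[1]) / diff(object$xrange)
  f <- stats::splinefun(object$knots, object$g, method = "natural")
  f(xs)
}

#' @export
print.gcv_spline <- function(x, ...) {
  cat(sprintf("GCV smoothing spline: n = %d, edf = %.2f, lambda = %.3g\n",
              length(x$y), x$edf, x$lambda))
  invisible(x)
}

#' Viability threshold from a fitted response curve
#'
#' Scans the smooth over its predictor range and reports the smallest
#' value at which the fitted viability criterion is met, together with the
#' crossing interval of the pointwise +/-2 SE band.
#'
#' @param fit a `gcv_spline` of a viability metric against a parameter.
#' @param cutoff criterion value (e.g. 0 for mean r, or the horizon for
#'   persistence time).
#' @param direction `">="` (default) if larger fitted values mean viable.
#' @param grid_n scan resolution.
#' @return list of class `threshold_report`: `threshold` (NA if the
#'   criterion is never met), `status` (`"ok"`, `"none within range"` or
#'   `"met everywhere"`), and `band` (crossing interval of the +/-2 SE
#'   envelope).
#' @export
threshold_report <- function(fit, cutoff, direction = c(">=", "<="),
                             grid_n = 500L) {
  direction <- match.arg(direction)
  xs <- seq(fit$xrange[1], fit$xrange[2], length.out = grid_n)
  fhat <- predict(fit, xs)
  se <- stats::approx(fit$x, fit$se_fit, xout = xs, rule = 2)$y
  met <- if (direction == ">=") fhat >= cutoff else fhat <= cutoff
  hi_met <- if (direction == ">=") fhat + 2 * se >= cutoff else fhat - 2 * se <= cutoff
  lo_met <- if (direction == ">=") fhat - 2 * se >= cutoff else fhat + 2 * se <= cutoff
  pick <- function(flags) if (any(flags)) xs[which(flags)[1]] else NA_real_
  thr <- pick(met)
  status <- if (is.na(thr)) "none within range"
  else if (all(met)) "met everywhere" else "ok"
  out <- list(threshold = thr, status = status,
              band = c(optimistic = pick(hi_met), conservative = pick(lo_met)),
              cutoff = cutoff, direction = direction)
  class(out) <- "threshold_report"
  out
}
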