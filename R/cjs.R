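# Cormack-Jolly-Seber inference: capture-history construction, the
# conditional-on-first-capture likelihood with logit-linked covariate
# models for apparent survival (phi) and detection (p), maximum-likelihood
# fitting, AICc ranking, model averaging, real-parameter prediction, and
# detectability-adjusted abundance trends.

#' Build a capture-history matrix from records and occasions
#'
#' Collapses multiple captures of an animal within one occasion to a single
#' encounter, computes per-stage mean weights (multiple recaptures within a
#' life stage contribute one stage average), and propagates age class
#' forward from the age assigned at first capture (females: adult from one
#' year after a juvenile first capture; males: sub-adult at ages 1-2, adult
#' from age 3; adults at first capture receive their minimum age).
#'
#' @param records a `capture_records` data.frame.
#' @param occasions an `occasions` data.frame from [build_occasions()].
#' @return a list of class `capture_histories`: binary matrix `y`
#'   (individuals x occasions), `first` occasion of first capture, `sex`,
#'   `age_first` (age at first capture), per-individual-occasion matrices
#'   `age_class` (character) and `weight` (stage-mean grams), and the
#'   `occasions` table.
#' @export
build_capture_histories <- function(records, occasions) {
  occ_idx <- occasion_of(records$date, occasions)
  if (anyNA(occ_idx)) {
    bad <- which(is.na(occ_idx))[1]
    stopf("record %d (%s) dated outside all occasions", bad,
          records$date[bad])
  }
  ids <- unique(records$animal_id)
  n <- length(ids); T <- nrow(occasions)
  if (T < 2L) stopf("need at least 2 occasions")
  ri <- match(records$animal_id, ids)
  y <- matrix(0L, n, T, dimnames = list(ids, NULL))
  y[cbind(ri, occ_idx)] <- 1L
  ord <- order(ri, records$date)
  first_row <- ord[!duplicated(ri[ord])]
  sex <- as.character(records$sex[first_row])[order(ri[first_row])]
  first <- apply(y == 1L, 1, which.max)

  # age at first capture from the class recorded then (minimum ages for
  # adults: 1 for females, 3 for males so the forward-propagated class
  # sequence is internally consistent)
  cls_first <- as.character(records$age_class[first_row])[order(ri[first_row])]
  age_first <- ifelse(cls_first == "juvenile", 0L,
                      ifelse(cls_first == "subadult", 1L,
                             ifelse(sex == "female", 1L, 3L)))
  age_mat <- outer(age_first - first, seq_len(T), "+")  # age (may be <0 pre-first)
  class_mat <- matrix(class_of(rep(sex, T), pmax(age_mat, 0L)), n, T)
  stage_mat <- sub("^(female|male)_", "", class_mat)

  # per-stage mean weight per individual, mapped onto occasions by the
  # propagated stage; stages with no measurement fall back to the
  # individual's overall mean, then to the class mean across individuals
  rec_age <- age_first[ri] + (occ_idx - first[ri])
  rec_stage <- sub("^(female|male)_", "",
                   class_of(as.character(records$sex), pmax(rec_age, 0L)))
  wkey <- paste(ri, rec_stage)
  wmean <- tapply(records$weight_g, wkey, mean, na.rm = TRUE)
  weight <- matrix(wmean[paste(rep(seq_len(n), T), stage_mat)], n, T)
  weight[is.nan(weight)] <- NA
  ind_mean <- tapply(records$weight_g, ri, mean, na.rm = TRUE)[as.character(seq_len(n))]
  miss <- is.na(weight)
  weight[miss] <- ind_mean[row(weight)[miss]]
  cls_mean <- tapply(records$weight_g, class_of(as.character(records$sex), pmax(rec_age, 0L)),
                     mean, na.rm = TRUE)
  miss <- is.na(weight)
  weight[miss] <- cls_mean[class_mat[miss]]

  out <- list(y = y, first = first, n = n, T = T, sex = sex,
              age_first = age_first, age_class = stage_mat,
              class5 = class_mat, weight = weight, occasions = occasions)
  class(out) <- "capture_histories"
  out
}

#' Specify a CJS covariate model
#'
#' Terms are model formulas over the covariate registry: occasion-level
#' `flow_1m`, `flow_6m`, `flow_12m`, `flow_24m`, `effort`; individual-level
#' `sex`, `weight` (grams, per-stage mean); time-varying `age`
#' (juvenile/subadult/adult factor, juvenile-female reference).  Quadratic
#' terms are written `I(flow_6m^2)` etc. (raw squares).  Both phi and p use
#' the logit link.  Survival-interval covariates are evaluated at the
#' interval's end occasion for flows, and at the interval's start for age
#' and weight.
#'
#' @param phi,p right-hand-side formulas, e.g.
#'   `phi = ~ flow_6m + I(flow_6m^2) + sex + weight + age`.
#' @param label optional model label.
#' @return object of class `cjs_design`.
#' @export
cjs_design <- function(phi = ~1, p = ~1, label = NULL) {
  if (is.null(label))
    label <- sprintf("phi(%s) p(%s)", deparse(phi[[2]]), deparse(p[[2]]))
  structure(list(phi = phi, p = p, label = label), class = "cjs_design")
}

# Long covariate frame for survival intervals t -> t+1 (t = 1..T-1) or
# detection occasions t (= 2..T); rows ordered individual-fastest.
cjs_frame <- function(ch, what = c("phi", "p")) {
  what <- match.arg(what)
  T <- ch$T; n <- ch$n
  ts <- if (what == "phi") seq_len(T - 1L) else 2:T
  cov_t <- if (what == "phi") ts + 1L else ts   # occasion carrying flow/effort
  age_t <- if (what == "phi") ts else ts        # age at interval start / occasion
  occ <- ch$occasions
  df <- data.frame(
    sex = factor(rep(ch$sex, length(ts)), SEX_LEVELS),
    weight = as.vector(ch$weight[, age_t, drop = FALSE]),
    age = factor(as.vector(ch$age_class[, age_t, drop = FALSE]), AGE_LEVELS),
    flow_1m = rep(occ$flow_1m[cov_t], each = n),
    flow_6m = rep(occ$flow_6m[cov_t], each = n),
    flow_12m = rep(occ$flow_12m[cov_t], each = n),
    flow_24m = rep(occ$flow_24m[cov_t], each = n),
    effort = rep(occ$effort_hours[cov_t], each = n))
  df$age <- droplevels(df$age)
  df
}

cjs_matrices <- function(ch, design) {
  Xphi <- stats::model.matrix(design$phi, cjs_frame(ch, "phi"))
  Xp <- stats::model.matrix(design$p, cjs_frame(ch, "p"))
  list(Xphi = Xphi, Xp = Xp, kphi = ncol(Xphi), kp = ncol(Xp))
}

#' CJS negative log-likelihood
#'
#' Conditional on first capture: for each individual, the product of
#' interval survival and detection terms up to the last capture, times the
#' unobserved-tail probability from the recursion
#' `chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1}`, `chi_T = 1`.
#'
#' @param params coefficient vector `c(beta_phi, beta_p)` matching the
#'   design's columns.
#' @param ch a `capture_histories` object.
#' @param design a [cjs_design()] (or precomputed matrices via `mats`).
#' @param mats optional result of the internal design-matrix builder;
#'   supplied by [fit_cjs()] to avoid rebuilding.
#' @return the negative log-likelihood (non-negative scalar).
#' @export
cjs_negloglik <- function(params, ch, design, mats = NULL) {
  if (any(!is.finite(params))) stopf("non-finite parameters")
  if (is.null(mats)) mats <- cjs_matrices(ch, design)
  if (length(params) != mats$kphi + mats$kp)
    stopf("params has length %d but design needs %d", length(params),
          mats$kphi + mats$kp)
  n <- ch$n; T <- ch$T
  bphi <- params[seq_len(mats$kphi)]
  bp <- params[mats$kphi + seq_len(mats$kp)]
  Phi <- matrix(invlogit(drop(mats$Xphi %*% bphi)), n, T - 1L)  # interval t->t+1
  P <- cbind(NA, matrix(invlogit(drop(mats$Xp %*% bp)), n, T - 1L))  # occ 2..T
  # chi recursion
  chi <- matrix(1, n, T)
  for (t in (T - 1L):1L)
    chi[, t] <- (1 - Phi[, t]) + Phi[, t] * (1 - P[, t + 1L]) * chi[, t + 1L]
  y <- ch$y
  last <- T + 1L - apply(y[, T:1, drop = FALSE] == 1L, 1, which.max)
  ll <- 0
  for (i in seq_len(n)) {
    f <- ch$first[i]; l <- last[i]
    if (l > f) {
      ts <- f:(l - 1L)
      ll <- ll + sum(log(Phi[i, ts]) +
                       y[i, ts + 1L] * log(P[i, ts + 1L]) +
                       (1L - y[i, ts + 1L]) * log(1 - P[i, ts + 1L]))
    }
    ll <- ll + log(chi[i, l])
  }
  -ll
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2 loglik + 2k + 2k(k+1) / (ess - k - 1)`, with the effective
#' sample size `ess` taken as the number of release events (captures not on
#' the final occasion), the MARK convention.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param ess effective sample size (must exceed `k + 1`).
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, ess) {
  if (ess <= k + 1) stopf("AICc undefined: ess (%g) must exceed k + 1 (%g)",
                          ess, k + 1)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (ess - k - 1)
}

#' Fit a CJS model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization from a zero start plus jittered
#' restarts; standard errors from the inverse of the numerically
#' differentiated Hessian; Wald 95% intervals on the coefficient scale.
#'
#' @param ch a `capture_histories` object (>= 2 occasions).
#' @param design a [cjs_design()].
#' @param n_starts number of starts (1 zero start + `n_starts - 1` jitters).
#' @param seed seed for the jitters.
#' @return object of class `cjs_fit`: `coefficients` table (estimate, se,
#'   lcl, ucl), `loglik`, `npar`, `ess`, `aicc`, `deviance`, `vcov`,
#'   `converged`, `se_ok`, and the design/label.
#' @export
fit_cjs <- function(ch, design, n_starts = 5L, seed = 1L) {
  if (ch$T < 2L) stopf("need at least 2 occasions")
  mats <- cjs_matrices(ch, design)
  k <- mats$kphi + mats$kp
  nll <- function(par) {
    v <- try(cjs_negloglik(par, ch, design, mats), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  starts <- with_seed(seed, {
    s <- replicate(max(1L, n_starts - 1L), stats::rnorm(k, 0, 0.5),
                   simplify = FALSE)
    c(list(rep(0, k)), s[seq_len(n_starts - 1L)])
  })
  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(s, nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stopf("CJS fit failed from all starts")
  hess <- stats::optimHess(best$par, nll)
  V <- try(solve(hess), silent = TRUE)
  se_ok <- !inherits(V, "try-error") && all(is.finite(V)) && all(diag(V) > 0)
  se <- if (se_ok) sqrt(diag(V)) else rep(NA_real_, k)
  if (!se_ok) V <- matrix(NA_real_, k, k)
  cn <- c(paste0("phi:", colnames(mats$Xphi)), paste0("p:", colnames(mats$Xp)))
  coefs <- data.frame(term = cn, estimate = best$par, se = se,
                      lcl = best$par - 1.96 * se, ucl = best$par + 1.96 * se)
  ess <- sum(ch$y[, -ch$T, drop = FALSE])
  ll <- -best$value
  fit <- list(coefficients = coefs, loglik = ll, npar = k, ess = ess,
              aicc = aicc(ll, k, ess), deviance = -2 * ll, vcov = V,
              converged = best$convergence == 0, se_ok = se_ok,
              design = design, label = design$label, mats_dim = c(mats$kphi, mats$kp))
  class(fit) <- "cjs_fit"
  if (!fit$converged)
    warnf("CJS optimizer did not report convergence for %s", design$label)
  fit
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS fit:", x$label, "\n")
  cat(sprintf("  logLik %.3f  npar %d  ess %d  AICc %.3f\n",
              x$loglik, x$npar, x$ess, x$aicc))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Akaike weights from AICc differences
#'
#' @param delta_aicc vector of AICc differences from the best model.
#' @return normalized weights `exp(-delta/2) / sum(exp(-delta/2))`.
#' @export
akaike_weights <- function(delta_aicc) {
  w <- exp(-delta_aicc / 2)
  w / sum(w)
}

#' Rank fitted CJS models and model-average predictions
#'
#' Ranks converged fits by AICc (ties broken by fewer parameters), retains
#' the smallest set whose cumulative Akaike weight reaches `cumulative`,
#' renormalizes weights over that set, and exposes weight-averaged
#' real-scale predictions.
#'
#' @param fits list of `cjs_fit` objects.
#' @param cumulative cumulative-weight retention threshold (default 0.99).
#' @return object of class `cjs_model_table`: data.frame `table` with
#'   model, npar, AICc, delta, weight (over all fits), retained flag and
#'   renormalized `weight_99`, plus the retained `fits`.
#' @export
rank_and_average <- function(fits, cumulative = 0.99) {
  if (inherits(fits, "cjs_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stopf("no converged fits to rank")
  aiccs <- vapply(fits, `[[`, 0, "aicc")
  npars <- vapply(fits, `[[`, 0, "npar")
  ord <- order(aiccs, npars)
  fits <- fits[ord]; aiccs <- aiccs[ord]; npars <- npars[ord]
  delta <- aiccs - aiccs[1]
  w <- akaike_weights(delta)
  # retain through the first model whose cumulative weight reaches target
  keep <- seq_along(w) <= which(cumsum(w) >= cumulative)[1]
  w99 <- ifelse(keep, w / sum(w[keep]), NA_real_)
  tab <- data.frame(model = vapply(fits, `[[`, "", "label"),
                    npar = npars, loglik = vapply(fits, `[[`, 0, "loglik"),
                    AICc = aiccs, delta = delta, weight = w,
                    retained = keep, weight_99 = w99)
  out <- list(table = tab, fits = fits[keep], cumulative = cumulative)
  class(out) <- "cjs_model_table"
  out
}

#' @export
print.cjs_model_table <- function(x, ...) {
  cat(sprintf("CJS model table (%d models, %.0f%% retention)\n",
              nrow(x$table), 100 * x$cumulative))
  print(transform(x$table, loglik = NULL), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict real-scale survival and detection from a fit
#'
#' Inverse-logit of the linear predictor at given covariates, with
#' delta-method 95% intervals computed on the logit scale.  For a model
#' table, returns the Akaike-weight average of the retained models'
#' real-scale predictions.
#'
#' @param object a `cjs_fit` or `cjs_model_table`.
#' @param newdata data.frame of covariates covering the design's terms
#'   (`sex`, `weight`, `age`, `flow_*`, `effort` as used).
#' @param what `"phi"` or `"p"`.
#' @return data.frame with `estimate`, `se`, `lcl`, `ucl` per row of
#'   `newdata` (model tables: estimate only).
#' @export
predict_real <- function(object, newdata, what = c("phi", "p")) {
  what <- match.arg(what)
  if (inherits(object, "cjs_model_table")) {
    tab <- object$table[object$table$retained, ]
    preds <- mapply(function(f, w) w * predict_real(f, newdata, what)$estimate,
                    object$fits, tab$weight_99)
    est <- if (is.matrix(preds)) rowSums(preds) else sum(preds)
    return(data.frame(estimate = est))
  }
  stopifnot(inherits(object, "cjs_fit"))
  form <- object$design[[what]]
  newdata <- as.data.frame(newdata)
  if ("sex" %in% names(newdata)) newdata$sex <- factor(newdata$sex, SEX_LEVELS)
  if ("age" %in% names(newdata)) newdata$age <- factor(newdata$age, AGE_LEVELS)
  vars <- all.vars(form)
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stopf("missing covariate(s): %s", paste(miss, collapse = ", "))
  mm <- try(stats::model.matrix(form, newdata), silent = TRUE)
  if (inherits(mm, "try-error"))
    stopf("could not build prediction matrix: %s", attr(mm, "condition")$message)
  kphi <- object$mats_dim[1]
  sel <- if (what == "phi") seq_len(kphi) else kphi + seq_len(object$mats_dim[2])
  beta <- object$coefficients$estimate[sel]
  # factor levels absent from the fit are dropped from mm by refitting names
  fit_terms <- sub(sprintf("^%s:", what), "", object$coefficients$term[sel])
  mm <- mm[, fit_terms, drop = FALSE]
  eta <- drop(mm %*% beta)
  V <- object$vcov[sel, sel, drop = FALSE]
  se_eta <- if (all(is.finite(V))) sqrt(rowSums((mm %*% V) * mm)) else NA_real_
  data.frame(estimate = invlogit(eta), se = se_eta * invlogit(eta) * (1 - invlogit(eta)),
             lcl = invlogit(eta - 1.96 * se_eta),
             ucl = invlogit(eta + 1.96 * se_eta))
}

#' Detection probability from published coefficients
#'
#' Convenience inverse-logit predictor for a detection model of the form
#' `intercept + b_flow * flow_1m + b_effort * effort + age-class offset`
#' (juvenile reference class).
#'
#' @param coefs named coefficients: `intercept`, `flow_1m`, `effort`, and
#'   offsets `subadult`, `adult`.
#' @param flow_1m cumulative flow (GL) in the capture month.
#' @param effort annual net-hours.
#' @param age_class `"juvenile"`, `"subadult"` or `"adult"`.
#' @return detection probability (vectorized over the covariates).
#' @export
predict_detection <- function(coefs, flow_1m, effort,
                              age_class = "juvenile") {
  off <- ifelse(age_class == "juvenile", 0, coefs[age_class])
  invlogit(coefs[["intercept"]] + coefs[["flow_1m"]] * flow_1m +
             coefs[["effort"]] * effort + off)
}

#' Detectability-adjusted abundance and trend
#'
#' Horvitz-Thompson style correction: adjusted count = raw count / p-hat,
#' with an ordinary-least-squares annual slope of the adjusted counts.
#'
#' @param counts per-occasion raw counts of distinct animals (>= 0).
#' @param p_hat per-occasion detection probabilities in (0, 1].
#' @param years year index (default `seq_along(counts)`).
#' @return list with `adjusted` counts, `slope` and `intercept` of the OLS
#'   fit of adjusted counts on `years`.
#' @export
estimate_abundance_trend <- function(counts, p_hat, years = seq_along(counts)) {
  if (length(counts) != length(p_hat)) stopf("counts and p_hat lengths differ")
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (any(p_hat <= 0 | p_hat > 1))
    stopf("p_hat must be in (0, 1]: no correction possible at p_hat = 0")
  adjusted <- counts / p_hat
  fit <- stats::lm(adjusted ~ years)
  list(adjusted = adjusted, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
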