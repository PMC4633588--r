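# Residency adjustment of apparent survival, Leslie-matrix oracles, and a
# two-sex age-structured stochastic population simulator (Vortex-style
# event loop: breed -> die -> disperse -> age -> truncate to K).
#
# Individuals within a sex-age class are exchangeable (no inbreeding or
# catastrophes in scope), so per-individual Bernoulli events are drawn as
# class-level binomials -- distributionally identical to an explicit
# per-individual loop.
#
# Class conventions (matching the viability parameterization): females are
# juvenile over their first year and adult thereafter, first breeding at
# age 2; males are juvenile over the first year, sub-adult over the 1->2
# transition, adult from age 2.

#' Adjust apparent survival for dispersal using residency
#'
#' Apparent survival confounds mortality with permanent emigration; with
#' residency `r` as a site-fidelity proxy, adjusted (true) survival is
#' `S = phi / r`, capped at 1 (with a warning).  Dispersal probability is
#' `d = 1 - r`.
#'
#' @param phi named per-class apparent annual survival (in (0, 1]).
#' @param residency named per-class residency (in (0, 1]).
#' @param s_disp disperser transit survival (shared scalar, default 1).
#' @return data.frame of class `vital_rates`: `class`, `phi`, `residency`,
#'   `survival` (adjusted S), `dispersal` (1 - r), `mortality` (1 - S),
#'   with `s_disp` as an attribute.
#' @export
derive_vital_rates <- function(phi, residency, s_disp = 1) {
  if (any(residency <= 0)) stopf("residency must be > 0")
  if (any(phi <= 0 | phi > 1) || any(residency > 1))
    stopf("phi and residency must be in (0, 1]")
  phi <- phi[CLASS_LEVELS]; residency <- residency[CLASS_LEVELS]
  S <- phi / residency
  if (any(S > 1)) {
    warnf("adjusted survival capped at 1 for: %s",
          paste(CLASS_LEVELS[S > 1], collapse = ", "))
    S <- pmin(S, 1)
  }
  out <- data.frame(class = CLASS_LEVELS, phi = unname(phi),
                    residency = unname(residency), survival = unname(S),
                    dispersal = unname(1 - residency),
                    mortality = unname(1 - S))
  attr(out, "s_disp") <- s_disp
  class(out) <- c("vital_rates", "data.frame")
  out
}

#' Configure a population viability simulation
#'
#' Reproduction follows the published viability parameterization: 62% of
#' adult females and 38% of adult males in the breeding pool each year
#' (breeding requires at least one pooled male; mating is polygynous),
#' litters of 1 or 2 with mean 1.5, 50% male births, first breeding at age
#' 2 for both sexes, maximum (reproductive) age 21.
#'
#' @param survival named per-class annual survival probabilities
#'   (`female_juvenile`, `female_adult`, `male_juvenile`, `male_subadult`,
#'   `male_adult`); alternatively supply `mortality` (= 1 - survival).
#' @param mortality optional named per-class mortalities (used if
#'   `survival` missing).
#' @param dispersal named per-class probability a survivor disperses
#'   (default 0 = dispersal disabled).
#' @param s_disp disperser transit survival (default 1; survivors rejoin
#'   the population, so dispersal is then demographically neutral).
#' @param breeding_female,breeding_male breeding-pool entry probabilities.
#' @param litter_mean mean litter size on \{1, ..., litter_max\}.
#' @param litter_max maximum litter size (2).
#' @param male_birth probability a newborn is male.
#' @param age_first_breeding,max_age,max_disperse_age ages in years.
#' @param n0 initial population size (placed at the stable stage).
#' @param K carrying capacity (uniform random truncation; `Inf` disables).
#' @param years simulated horizon.
#' @param iterations Monte-Carlo iterations.
#' @param seed optional integer seed.
#' @return list of class `pva_config`.
#' @export
pva_config <- function(survival = NULL, mortality = NULL,
                       dispersal = c(female_juvenile = 0, female_adult = 0,
                                     male_juvenile = 0, male_subadult = 0,
                                     male_adult = 0),
                       s_disp = 1, breeding_female = 0.62,
                       breeding_male = 0.38, litter_mean = 1.5,
                       litter_max = 2L, male_birth = 0.5,
                       age_first_breeding = 2L, max_age = 21L,
                       max_disperse_age = 15L, n0 = 50L, K = 200,
                       years = 100L, iterations = 1000L, seed = NULL) {
  if (is.null(survival)) {
    if (is.null(mortality)) stopf("supply survival or mortality")
    survival <- 1 - mortality
  }
  survival <- survival[CLASS_LEVELS]
  dispersal <- dispersal[CLASS_LEVELS]
  if (anyNA(survival) || any(survival < 0 | survival > 1))
    stopf("survival must be named probabilities for all five classes")
  if (anyNA(dispersal) || any(dispersal < 0 | dispersal > 1))
    stopf("dispersal must be named probabilities for all five classes")
  probs <- c(s_disp, breeding_female, breeding_male, male_birth)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  if (litter_mean < 1 || litter_mean > litter_max)
    stopf("litter_mean must be in [1, litter_max]")
  if (years < 1 || iterations < 1) stopf("years and iterations must be >= 1")
  cfg <- list(survival = survival, dispersal = dispersal, s_disp = s_disp,
              breeding_female = breeding_female, breeding_male = breeding_male,
              litter_mean = litter_mean, litter_max = as.integer(litter_max),
              male_birth = male_birth,
              age_first_breeding = as.integer(age_first_breeding),
              max_age = as.integer(max_age),
              max_disperse_age = as.integer(max_disperse_age),
              n0 = as.integer(n0), K = K, years = as.integer(years),
              iterations = as.integer(iterations), seed = seed)
  class(cfg) <- "pva_config"
  cfg
}

#' Preset viability scenarios
#'
#' `"apparent"`: the unadjusted apparent mortalities (73/24/87/62/43% for
#' juvF/adF/juvM/subM/adM) with dispersal disabled.  `"adjusted"`: the
#' residency-adjusted mortalities (71/11/77/43/23%) with the published
#' class dispersal fractions and 100% disperser transit survival.
#'
#' @param scenario `"apparent"` or `"adjusted"`.
#' @param ... overrides passed on to [pva_config()].
#' @return a [pva_config()].
#' @export
pva_scenario <- function(scenario = c("apparent", "adjusted"), ...) {
  scenario <- match.arg(scenario)
  m_apparent <- c(female_juvenile = 0.73, female_adult = 0.24,
                  male_juvenile = 0.87, male_subadult = 0.62,
                  male_adult = 0.43)
  m_adjusted <- c(female_juvenile = 0.71, female_adult = 0.11,
                  male_juvenile = 0.77, male_subadult = 0.43,
                  male_adult = 0.23)
  disp <- c(female_juvenile = 0.154, female_adult = 0.145,
            male_juvenile = 0.55, male_subadult = 0.38, male_adult = 0.26)
  if (scenario == "apparent")
    pva_config(mortality = m_apparent, ...)
  else
    pva_config(mortality = m_adjusted, dispersal = disp, s_disp = 1, ...)
}

# Effective survival including transit mortality of dispersers:
# S' = S * (1 - d * (1 - s_disp)), with d applied only through
# max_disperse_age (handled by callers for age-specific maps).
effective_survival <- function(S, d, s_disp) S * (1 - d * (1 - s_disp))

# Per-age survival/dispersal maps used by both the deterministic matrices
# and the simulator.  Ages are the census ages 1..max_age; the transition
# from census age a runs a -> a+1.  The newborn (age 0 -> 1) transition is
# handled separately with the juvenile rates.
female_age_rates <- function(cfg) {
  a <- seq_len(cfg$max_age)
  S <- rep(cfg$survival[["female_adult"]], cfg$max_age)
  d <- ifelse(a <= cfg$max_disperse_age, cfg$dispersal[["female_adult"]], 0)
  list(S = S, d = d)
}

male_age_rates <- function(cfg) {
  a <- seq_len(cfg$max_age)
  S <- ifelse(a == 1L, cfg$survival[["male_subadult"]],
              cfg$survival[["male_adult"]])
  d <- ifelse(a == 1L, cfg$dispersal[["male_subadult"]],
              ifelse(a <= cfg$max_disperse_age,
                     cfg$dispersal[["male_adult"]], 0))
  list(S = S, d = d)
}

#' Dominant eigenvalue of the female projection matrix
#'
#' Deterministic oracle for the stochastic simulator: a female-only Leslie
#' matrix over census ages 1..max_age, with fecundity `breeding_female *
#' litter_mean * (1 - male_birth) * S_juvenile` from first-breeding age to
#' the maximum age and survivals (including disperser transit mortality)
#' from the configuration.  The dominant eigenvalue is found by power
#' iteration to 1e-10.
#'
#' @param config a [pva_config()].
#' @return list: `lambda`, `log_lambda`, the Leslie `matrix`, and the
#'   normalized dominant right eigenvector `stable_age`.
#' @export
leslie_lambda <- function(config) {
  A <- leslie_matrix_female(config)
  ev <- power_iteration(A)
  list(lambda = ev$value, log_lambda = log(ev$value), matrix = A,
       stable_age = ev$vector)
}

leslie_matrix_female <- function(cfg) {
  m <- cfg$max_age
  fr <- female_age_rates(cfg)
  Sj <- effective_survival(cfg$survival[["female_juvenile"]],
                           cfg$dispersal[["female_juvenile"]], cfg$s_disp)
  f <- cfg$breeding_female * cfg$litter_mean * (1 - cfg$male_birth) * Sj
  A <- matrix(0, m, m)
  breed <- seq(cfg$age_first_breeding, m)
  A[1, breed] <- f
  Seff <- effective_survival(fr$S, fr$d, cfg$s_disp)
  for (a in seq_len(m - 1L)) A[a + 1L, a] <- Seff[a]
  A
}

power_iteration <- function(A, tol = 1e-10, max_iter = 100000L) {
  v <- rep(1, nrow(A)) / nrow(A)
  lam <- 1
  for (i in seq_len(max_iter)) {
    w <- drop(A %*% v)
    lam_new <- sum(w)
    if (lam_new == 0) return(list(value = 0, vector = v))
    w <- w / lam_new
    if (max(abs(w - v)) < tol && abs(lam_new - lam) < tol)
      return(list(value = lam_new, vector = w))
    v <- w; lam <- lam_new
  }
  list(value = lam, vector = v)
}

#' Stable stage distribution of the two-sex projection
#'
#' Right dominant eigenvector of the two-sex projection matrix (female
#' Leslie block driving male recruitment), integerized to the configured
#' initial population size by largest remainder.
#'
#' @param config a [pva_config()].
#' @param n total size to allocate (default `config$n0`).
#' @return list: integer vectors `Nf`, `Nm` over census ages 1..max_age,
#'   and the continuous `proportions`.
#' @export
stable_stage <- function(config, n = config$n0) {
  m <- config$max_age
  A <- matrix(0, 2 * m, 2 * m)
  A[1:m, 1:m] <- leslie_matrix_female(config)
  SjM <- effective_survival(config$survival[["male_juvenile"]],
                            config$dispersal[["male_juvenile"]], config$s_disp)
  fM <- config$breeding_female * config$litter_mean * config$male_birth * SjM
  A[m + 1L, seq(config$age_first_breeding, m)] <- fM
  mr <- male_age_rates(config)
  Seff <- effective_survival(mr$S, mr$d, config$s_disp)
  for (a in seq_len(m - 1L)) A[m + a + 1L, m + a] <- Seff[a]
  ev <- power_iteration(A)
  prop <- ev$vector
  # non-reproducing configurations have no meaningful stable stage; fall
  # back to uniform ages so cohort experiments remain well-defined
  if (ev$value <= 1e-12 || !all(is.finite(prop)) || sum(prop) <= 0)
    prop <- rep(1, 2L * m)
  counts <- largest_remainder(prop, n)
  list(Nf = counts[1:m], Nm = counts[(m + 1L):(2L * m)], proportions = prop)
}

# Integerize proportional shares to sum exactly to n.
largest_remainder <- function(p, n) {
  p <- p / sum(p)
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Remove `m` individuals uniformly at random (without replacement) from a
# vector of class counts: multivariate hypergeometric draw.
remove_uniform <- function(counts, m) {
  pool <- rep(seq_along(counts), counts)
  drop_idx <- pool[sample.int(length(pool), m)]
  counts - tabulate(drop_idx, nbins = length(counts))
}

#' Run the stochastic viability simulation
#'
#' Yearly event order (post-breeding annual census): (1) breeding -- each
#' adult female (age >= first breeding age) enters the pool independently;
#' litters are produced only if at least one adult male entered the male
#' pool; (2) mortality by class, newborns included; (3) dispersal --
#' survivors disperse with their class probability and die in transit with
#' probability `1 - s_disp`, otherwise rejoin; (4) aging and promotion,
#' individuals exceeding the maximum age die; (5) uniform random truncation
#' to the carrying capacity.  All randomness comes from one seeded stream.
#'
#' @param config a [pva_config()].
#' @return object of class `pva_result`: trajectory matrix `N` (iterations
#'   x years+1, year 0 = initial), pooled annual log-growth mean/sd
#'   (`r_mean`, `r_sd`), per-iteration `extinction_year` (NA if extant),
#'   class trajectory array `N_class` (iterations x years+1 x female/
#'   male_subadult/male_adult at census), and the `config`.
#' @export
run_pva <- function(config) {
  stopifnot(inherits(config, "pva_config"))
  with_seed(config$seed, run_pva_impl(config))
}

run_pva_impl <- function(cfg) {
  m <- cfg$max_age
  init <- stable_stage(cfg)
  fr <- female_age_rates(cfg); mr <- male_age_rates(cfg)
  SjF <- cfg$survival[["female_juvenile"]]
  SjM <- cfg$survival[["male_juvenile"]]
  dJF <- cfg$dispersal[["female_juvenile"]]
  dJM <- cfg$dispersal[["male_juvenile"]]
  p2 <- (cfg$litter_mean - 1) / (cfg$litter_max - 1)  # P(litter of 2)
  ni <- cfg$iterations; ny <- cfg$years
  N <- matrix(NA_integer_, ni, ny + 1L)
  Ncls <- array(NA_integer_, c(ni, ny + 1L, 3L),
                dimnames = list(NULL, NULL, c("female", "male_subadult",
                                              "male_adult")))
  ext_year <- rep(NA_integer_, ni)
  growth <- vector("list", ni)

  for (it in seq_len(ni)) {
    Nf <- init$Nf; Nm <- init$Nm
    tot <- sum(Nf) + sum(Nm)
    N[it, 1L] <- tot
    Ncls[it, 1L, ] <- c(sum(Nf), Nm[1L], sum(Nm[-1L]))
    gr <- numeric(0)
    for (t in seq_len(ny)) {
      if (tot == 0L) { N[it, t + 1L] <- 0L; Ncls[it, t + 1L, ] <- 0L; next }
      # (1) breeding
      n_breed_f <- stats::rbinom(1L, sum(Nf[cfg$age_first_breeding:m]),
                                 cfg$breeding_female)
      n_pool_m <- stats::rbinom(1L, sum(Nm[cfg$age_first_breeding:m]),
                                cfg$breeding_male)
      newF <- newM <- 0L
      if (n_breed_f > 0L && n_pool_m > 0L) {
        offspring <- n_breed_f + stats::rbinom(1L, n_breed_f, p2)
        newM <- stats::rbinom(1L, offspring, cfg$male_birth)
        newF <- offspring - newM
      }
      # (2) mortality (class-level binomial survival draws)
      newF <- stats::rbinom(1L, newF, SjF)
      newM <- stats::rbinom(1L, newM, SjM)
      survF <- stats::rbinom(m, Nf, fr$S)
      survM <- stats::rbinom(m, Nm, mr$S)
      # (3) dispersal: transit deaths among dispersing survivors
      if (cfg$s_disp < 1) {
        newF <- newF - stats::rbinom(1L, stats::rbinom(1L, newF, dJF),
                                     1 - cfg$s_disp)
        newM <- newM - stats::rbinom(1L, stats::rbinom(1L, newM, dJM),
                                     1 - cfg$s_disp)
        survF <- survF - stats::rbinom(m, stats::rbinom(m, survF, fr$d),
                                       1 - cfg$s_disp)
        survM <- survM - stats::rbinom(m, stats::rbinom(m, survM, mr$d),
                                       1 - cfg$s_disp)
      }
      # (4) aging; age-max_age survivors exceed the maximum age and die
      Nf <- c(newF, survF[-m])
      Nm <- c(newM, survM[-m])
      # (5) truncation to K
      tot_new <- sum(Nf) + sum(Nm)
      if (is.finite(cfg$K) && tot_new > cfg$K) {
        counts <- remove_uniform(c(Nf, Nm), tot_new - cfg$K)
        Nf <- counts[1:m]; Nm <- counts[(m + 1L):(2L * m)]
        tot_new <- sum(Nf) + sum(Nm)
      }
      if (tot > 0L && tot_new > 0L) gr <- c(gr, log(tot_new / tot))
      if (tot_new == 0L && is.na(ext_year[it])) ext_year[it] <- t
      tot <- tot_new
      N[it, t + 1L] <- tot
      Ncls[it, t + 1L, ] <- c(sum(Nf), Nm[1L], sum(Nm[-1L]))
    }
    growth[[it]] <- gr
  }
  g <- unlist(growth)
  out <- list(N = N, N_class = Ncls,
              r_mean = if (length(g)) mean(g) else NA_real_,
              r_sd = if (length(g) > 1) stats::sd(g) else NA_real_,
              r_values = g, extinction_year = ext_year, config = cfg)
  class(out) <- "pva_result"
  out
}

#' Summarize a viability simulation
#'
#' @param result a `pva_result`.
#' @param horizons years at which to report extinction probability
#'   (default 50 and 100, clipped to the simulated span).
#' @return list of class `pva_summary`: `r_mean`, `r_sd`,
#'   `extinction_prob` (named by horizon), `median_time_to_extinction`
#'   (among extinct iterations; NA with `censored = TRUE` if none went
#'   extinct), `prop_extinct`.
#' @export
summarize_pva <- function(result, horizons = c(50L, 100L)) {
  horizons <- horizons[horizons <= result$config$years]
  if (!length(horizons)) stopf("no horizon within the simulated span")
  ext <- result$extinction_year
  probs <- vapply(horizons, function(h) mean(!is.na(ext) & ext <= h), 0)
  names(probs) <- paste0("year_", horizons)
  extinct <- ext[!is.na(ext)]
  out <- list(r_mean = result$r_mean, r_sd = result$r_sd,
              extinction_prob = probs,
              median_time_to_extinction =
                if (length(extinct)) stats::median(extinct) else NA_real_,
              censored = length(extinct) == 0L,
              prop_extinct = mean(!is.na(ext)))
  class(out) <- "pva_summary"
  out
}

#' @export
print.pva_summary <- function(x, ...) {
  cat(sprintf("Stochastic r: %.4f (sd %.4f)\n", x$r_mean, x$r_sd))
  for (h in names(x$extinction_prob))
    cat(sprintf("  P(extinct by %s): %.3f\n", sub("year_", "year ", h),
                x$extinction_prob[[h]]))
  if (x$censored) cat("  Median time to extinction: censored (none extinct)\n")
  else cat(sprintf("  Median time to extinction: %.1f years\n",
                   x$median_time_to_extinction))
  invisible(x)
}
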