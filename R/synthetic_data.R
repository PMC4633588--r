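# Ground-truthed synthetic field data: a pool-structured platypus
# population with class-specific survival, Markov pool movement, effort-
# and flow-dependent detection, and class-specific morphometrics.  The
# generator's bookkeeping (who was alive/where/captured) travels with the
# records so downstream estimators can be checked against truth.

#' Configuration for the synthetic population generator
#'
#' Defaults describe a 15-pool upper-river study reach observed for 40
#' years: class survival at the dispersal-adjusted scale, class residency
#' as observed from consecutive recaptures, detection on the logit scale
#' driven by monthly flow and annual netting effort, weights and lengths at
#' the scale reported for the five field classes, a 0.39 annual lactation
#' probability for adult females, roughly 137 net-hours of effort per year
#' and lognormal monthly flows averaging 3.8 GL.
#'
#' @param n_pools number of pools along the reach.
#' @param pool_spacing metres of chainage between neighbouring pools.
#' @param years number of annual survey occasions.
#' @param initial_n initial population size.
#' @param survival named per-class annual survival probabilities.
#' @param residency named per-class probability of staying in the same pool
#'   between years.
#' @param movement_scale metres; scale of the geometric inter-pool movement
#'   kernel (moves decay by `exp(-distance/movement_scale)`).
#' @param detection logit-scale detection coefficients: `intercept`,
#'   `flow_1m` (per GL of flow in the midpoint month), `effort` (per annual
#'   net-hour), and class offsets `subadult`, `adult` (juvenile reference).
#' @param weight_mean,weight_sd per-class weight distributions (grams).
#' @param length_mean,length_sd per-class length distributions (cm).
#' @param breeding_prob probability an adult female (age >= 2) breeds (and
#'   lactates) in a year.
#' @param litter_mean mean litter size on \{1, 2\}.
#' @param effort_hours net-hours per survey year (length 1 or `years`).
#' @param flow_meanlog,flow_sdlog lognormal parameters of monthly flow (GL).
#' @param start_year first survey year (July-June survey years).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list of class `truth_config`.
#' @export
truth_config <- function(n_pools = 15L, pool_spacing = 1100, years = 40L,
                         initial_n = 60L,
                         survival = c(female_juvenile = 0.29, female_adult = 0.89,
                                      male_juvenile = 0.23, male_subadult = 0.57,
                                      male_adult = 0.77),
                         residency = c(female_juvenile = 0.93, female_adult = 0.85,
                                       male_juvenile = 0.43, male_subadult = 0.66,
                                       male_adult = 0.74),
                         movement_scale = 500,
                         detection = c(intercept = -0.0417, flow_1m = -0.0537,
                                       effort = 0.0128, subadult = 1.053,
                                       adult = -0.728),
                         weight_mean = c(female_juvenile = 647, female_adult = 864,
                                         male_juvenile = 816, male_subadult = 1200,
                                         male_adult = 1403),
                         weight_sd = c(female_juvenile = 128, female_adult = 130,
                                       male_juvenile = 128, male_subadult = 130,
                                       male_adult = 131),
                         length_mean = c(female_juvenile = 39.1, female_adult = 42.7,
                                         male_juvenile = 42.9, male_subadult = 48.2,
                                         male_adult = 50.3),
                         length_sd = c(female_juvenile = 2, female_adult = 2,
                                       male_juvenile = 2, male_subadult = 2,
                                       male_adult = 2),
                         breeding_prob = 0.39, litter_mean = 1.5,
                         effort_hours = 137,
                         flow_meanlog = log(3.8) - 0.5, flow_sdlog = 1,
                         start_year = 1973L, seed = NULL) {
  cfg <- list(n_pools = as.integer(n_pools), pool_spacing = pool_spacing,
              years = as.integer(years), initial_n = as.integer(initial_n),
              survival = survival[CLASS_LEVELS], residency = residency[CLASS_LEVELS],
              movement_scale = movement_scale, detection = detection,
              weight_mean = weight_mean[CLASS_LEVELS],
              weight_sd = weight_sd[CLASS_LEVELS],
              length_mean = length_mean[CLASS_LEVELS],
              length_sd = length_sd[CLASS_LEVELS],
              breeding_prob = breeding_prob, litter_mean = litter_mean,
              effort_hours = if (length(effort_hours) == 1L)
                rep(effort_hours, years) else effort_hours,
              flow_meanlog = flow_meanlog, flow_sdlog = flow_sdlog,
              start_year = as.integer(start_year), seed = seed)
  if (length(cfg$effort_hours) != cfg$years)
    stopf("effort_hours must have length 1 or years")
  probs <- c(cfg$survival, cfg$residency, cfg$breeding_prob)
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stopf("survival, residency and breeding_prob must be probabilities in [0,1]")
  if (any(c(cfg$weight_sd, cfg$length_sd) < 0)) stopf("sds must be >= 0")
  if (cfg$years < 2L) stopf("years must be >= 2")
  if (cfg$litter_mean < 1 || cfg$litter_mean > 2)
    stopf("litter_mean must be in [1, 2]")
  class(cfg) <- "truth_config"
  cfg
}

# Movement kernel: from pool i, stay with residency prob of the class;
# otherwise move to pool j != i with probability proportional to
# exp(-|chainage_i - chainage_j| / movement_scale) (geometric decay over
# the regular pool ladder).
move_kernel <- function(n_pools, spacing, scale) {
  d <- abs(outer(seq_len(n_pools), seq_len(n_pools), "-")) * spacing
  w <- exp(-d / scale)
  diag(w) <- 0
  sweep(w, 1, rowSums(w), "/")
}

#' Simulate a ground-truthed population
#'
#' Simulates per-individual annual alive/dead state, pool occupancy
#' (Markov: stay with the class residency probability, else move with a
#' geometrically decaying kernel over chainage distance), breeding by adult
#' females, and per-life-stage weights and lengths.
#'
#' @param config a [truth_config()].
#' @return a list of class `truth_trajectory` with vectors `id`, `sex`,
#'   `birth_year` (index scale; `<= 0` for founders) and `years x`
#'   individual matrices `alive`, `age`, `pool`, `lactating`, per-stage
#'   `weight`/`length` draws, plus the realized `pools`, `flows` and
#'   per-year `effort` the surveys will use.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  ny <- cfg$years
  kern <- move_kernel(cfg$n_pools, cfg$pool_spacing, cfg$movement_scale)
  # founders: even sex ratio, ages from a short geometric mix
  n0 <- cfg$initial_n
  sex <- sample(SEX_LEVELS, n0, replace = TRUE)
  age0 <- ifelse(stats::runif(n0) < 0.3, 0L,
                 pmin(1L + stats::rgeom(n0, 0.4), 12L))
  id <- sprintf("A%04d", seq_len(n0))
  birth_year <- 1L - age0
  pool0 <- sample.int(cfg$n_pools, n0, replace = TRUE)

  cap <- 20L * n0 + 200L  # generous container; grown if exceeded
  alive <- matrix(FALSE, cap, ny); age <- matrix(NA_integer_, cap, ny)
  pool <- matrix(NA_integer_, cap, ny); lact <- matrix(FALSE, cap, ny)
  stage_w <- matrix(NA_real_, cap, 3L, dimnames = list(NULL, AGE_LEVELS))
  stage_l <- matrix(NA_real_, cap, 3L, dimnames = list(NULL, AGE_LEVELS))
  sex_all <- character(cap); id_all <- character(cap); by_all <- integer(cap)
  n <- n0
  sex_all[1:n0] <- sex; id_all[1:n0] <- id; by_all[1:n0] <- birth_year
  alive[1:n0, 1L] <- TRUE; age[1:n0, 1L] <- age0; pool[1:n0, 1L] <- pool0

  grow <- function(need) {
    extra <- max(need, cap)
    alive <<- rbind(alive, matrix(FALSE, extra, ny))
    age <<- rbind(age, matrix(NA_integer_, extra, ny))
    pool <<- rbind(pool, matrix(NA_integer_, extra, ny))
    lact <<- rbind(lact, matrix(FALSE, extra, ny))
    stage_w <<- rbind(stage_w, matrix(NA_real_, extra, 3L))
    stage_l <<- rbind(stage_l, matrix(NA_real_, extra, 3L))
    sex_all <<- c(sex_all, character(extra))
    id_all <<- c(id_all, character(extra))
    by_all <<- c(by_all, integer(extra))
    cap <<- cap + extra
  }

  # stage-specific morphometrics are drawn once, on first entering a stage
  draw_stage <- function(idx, t) {
    cls <- class_of(sex_all[idx], age[idx, t])
    stg <- sub("^(female|male)_", "", cls)
    col <- match(stg, AGE_LEVELS)
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (is.na(stage_w[i, col[k]])) {
        stage_w[i, col[k]] <<- max(50, stats::rnorm(1, cfg$weight_mean[cls[k]],
                                                    cfg$weight_sd[cls[k]]))
        stage_l[i, col[k]] <<- max(10, stats::rnorm(1, cfg$length_mean[cls[k]],
                                                    cfg$length_sd[cls[k]]))
      }
    }
  }
  draw_stage(1:n0, 1L)

  for (t in seq_len(ny)) {
    cur <- which(alive[, t])
    # breeding: adult-class females (age >= 1) breed with breeding_prob;
  # litters
    # of 1 or 2 (mean litter_mean); offspring are age-0 juveniles in the
    # mother's pool, catchable this same season
    mums <- cur[sex_all[cur] == "female" & age[cur, t] >= 1L]
    breeds <- mums[stats::runif(length(mums)) < cfg$breeding_prob]
    lact[breeds, t] <- TRUE
    if (length(breeds)) {
      litter <- 1L + (stats::runif(length(breeds)) < (cfg$litter_mean - 1))
      nb <- sum(litter)
      if (n + nb > cap) grow(nb)
      kid <- (n + 1L):(n + nb)
      id_all[kid] <- sprintf("A%04d", kid)
      sex_all[kid] <- sample(SEX_LEVELS, nb, replace = TRUE)
      by_all[kid] <- t
      alive[kid, t] <- TRUE
      age[kid, t] <- 0L
      pool[kid, t] <- rep(pool[breeds, t], litter)
      n <- n + nb
      draw_stage(kid, t)
    }
    if (t == ny) break
    # survival to t+1, then movement, then aging
    cur <- which(alive[, t])
    cls <- class_of(sex_all[cur], age[cur, t])
    surv <- cur[stats::runif(length(cur)) < cfg$survival[cls]]
    if (length(surv)) {
      cls_s <- class_of(sex_all[surv], age[surv, t])
      stay <- stats::runif(length(surv)) < cfg$residency[cls_s]
      newpool <- pool[surv, t]
      movers <- which(!stay)
      for (m in movers)
        newpool[m] <- sample.int(cfg$n_pools, 1L, prob = kern[pool[surv[m], t], ])
      alive[surv, t + 1L] <- TRUE
      age[surv, t + 1L] <- age[surv, t] + 1L
      pool[surv, t + 1L] <- newpool
      draw_stage(surv, t + 1L)
    }
  }

  keep <- 1:n
  yrs <- cfg$start_year + seq_len(ny) - 1L
  # monthly flows covering a 24-month lookback before the first midpoint
  fy <- rep((cfg$start_year - 2L):(cfg$start_year + ny), each = 12L)
  fm <- rep(1:12, length.out = length(fy))
  flows <- validate_flow_series(data.frame(
    year = fy, month = fm,
    flow_gl = stats::rlnorm(length(fy), cfg$flow_meanlog, cfg$flow_sdlog)))
  pools <- data.frame(pool_id = sprintf("p%d", seq_len(cfg$n_pools)),
                      chainage_m = (seq_len(cfg$n_pools) - 1L) * cfg$pool_spacing)
  class(pools) <- c("pool_map", "data.frame")
  out <- list(config = cfg, id = id_all[keep], sex = sex_all[keep],
              birth_year = by_all[keep],
              alive = alive[keep, , drop = FALSE],
              age = age[keep, , drop = FALSE],
              pool = pool[keep, , drop = FALSE],
              lactating = lact[keep, , drop = FALSE],
              stage_weight = stage_w[keep, , drop = FALSE],
              stage_length = stage_l[keep, , drop = FALSE],
              survey_years = yrs, effort = cfg$effort_hours,
              pools = pools, flows = flows)
  class(out) <- "truth_trajectory"
  out
}

#' Simulate annual netting surveys of a true population
#'
#' Every alive individual is captured in year `t` with probability
#' `invlogit(intercept + b_flow * flow_1m + b_effort * effort_t + class
#' offset)`, where `flow_1m` is the flow of the month containing the
#' occasion midpoint (December of the survey year).  Captures emit valid
#' [read_capture_records()]-format rows dated 15 January (inside the
#' December-March season), with the individual's true class, pool, stage
#' weight and length.  Adult females are tested for lactation; males and
#' juveniles are recorded as untested.
#'
#' @param truth a `truth_trajectory` from [simulate_population()].
#' @param config the same [truth_config()] (detection coefficients used).
#' @param seed optional seed for the capture draws.
#' @return list with `records` (a `capture_records` data.frame), the
#'   logical `captured` bookkeeping matrix (individuals x years), per-year
#'   `p` detection probabilities by class, and `occ_flow_1m`.
#' @export
simulate_surveys <- function(truth, config = truth$config, seed = config$seed) {
  stopifnot(inherits(truth, "truth_trajectory"))
  with_seed(seed, simulate_surveys_impl(truth, config))
}

simulate_surveys_impl <- function(truth, cfg) {
  ny <- cfg$years
  b <- cfg$detection
  idx <- month_index(truth$flows$year, truth$flows$month)
  flow_dec <- truth$flows$flow_gl[match(month_index(truth$survey_years, 12L), idx)]
  captured <- matrix(FALSE, nrow(truth$alive), ny)
  rows <- vector("list", ny)
  for (t in seq_len(ny)) {
    cur <- which(truth$alive[, t])
    if (!length(cur)) next
    cls <- class_of(truth$sex[cur], truth$age[cur, t])
    off <- ifelse(grepl("adult$", cls) & !grepl("subadult$", cls), b[["adult"]],
                  ifelse(grepl("subadult$", cls), b[["subadult"]], 0))
    eta <- b[["intercept"]] + b[["flow_1m"]] * flow_dec[t] +
      b[["effort"]] * truth$effort[t] + off
    caught <- cur[stats::runif(length(cur)) < invlogit(eta)]
    captured[caught, t] <- TRUE
    if (!length(caught)) next
    cls_c <- class_of(truth$sex[caught], truth$age[caught, t])
    stg <- sub("^(female|male)_", "", cls_c)
    col <- match(stg, AGE_LEVELS)
    w <- truth$stage_weight[cbind(caught, col)]
    l <- truth$stage_length[cbind(caught, col)]
    lactating <- ifelse(truth$sex[caught] == "male" | stg == "juvenile",
                        "untested",
                        ifelse(truth$lactating[caught, t], "yes", "no"))
    rows[[t]] <- data.frame(
      animal_id = truth$id[caught],
      date = sprintf("%d-01-15", truth$survey_years[t] + 1L),
      pool_id = sprintf("p%d", truth$pool[caught, t]),
      sex = truth$sex[caught],
      age_class = stg,
      weight_g = round(w, 1), length_cm = round(l, 1),
      lactating = lactating,
      effort_hours = truth$effort[t])
  }
  raw <- do.call(rbind, rows)
  if (is.null(raw))
    raw <- data.frame(animal_id = character(), date = character(),
                      pool_id = character(), sex = character(),
                      age_class = character(), weight_g = character(),
                      length_cm = character(), lactating = character(),
                      effort_hours = character())
  raw[] <- lapply(raw, as.character)
  records <- validate_capture_records(raw)
  list(records = records, captured = captured, occ_flow_1m = flow_dec)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [simulate_population()] and [simulate_surveys()] and writes
#' `capture_records.csv`, `pools.csv`, `flows.csv` and `truth.json`
#' (configuration echo incl. seed, plus summary counts) to `dir`.
#'
#' @param config a [truth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `truth`, `surveys` and written `paths`.
#' @export
simulate_dataset <- function(config, dir) {
  truth <- simulate_population(config)
  surveys <- simulate_surveys(truth, config,
                              seed = child_seed(config$seed, 1L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "capture_records.csv"),
             pools = file.path(dir, "pools.csv"),
             flows = file.path(dir, "flows.csv"),
             truth = file.path(dir, "truth.json"))
  write_capture_records(surveys$records, paths[["records"]])
  write_pool_map(truth$pools, paths[["pools"]])
  write_flow_series(truth$flows, paths[["flows"]])
  meta <- list(seed = config$seed, years = config$years,
               n_individuals = length(truth$id),
               n_records = nrow(surveys$records),
               survival = as.list(config$survival),
               residency = as.list(config$residency),
               detection = as.list(config$detection))
  jsonlite::write_json(meta, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, surveys = surveys, paths = paths))
}
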