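# Pool residency and movement distances from consecutive recaptures.

#' Consecutive-recapture movement pairs
#'
#' One pair per consecutive capture of each animal, with the class taken at
#' the earlier capture (when the movement decision was made) and the
#' distance as the absolute chainage difference between pools.  When
#' `occasions` is supplied, within-occasion recaptures are collapsed to the
#' first capture so pairs span occasions only.
#'
#' @param records a `capture_records` data.frame.
#' @param pools a `pool_map`; every `pool_id` in the records must appear.
#' @param occasions optional `occasions` table for within-occasion collapse.
#' @return data.frame of class `move_pairs`: `animal_id`, `class_at_first`
#'   (five-level sex-age class), `distance` (metres), `same_pool`.
#' @export
consecutive_moves <- function(records, pools, occasions = NULL) {
  unknown <- setdiff(unique(records$pool_id), pools$pool_id)
  if (length(unknown))
    stopf("pool_id absent from pool map: %s", paste(unknown, collapse = ", "))
  df <- records[order(records$animal_id, records$date), ]
  if (!is.null(occasions)) {
    occ <- occasion_of(df$date, occasions)
    df <- df[!duplicated(paste(df$animal_id, occ)), ]
  }
  chain <- pools$chainage_m[match(df$pool_id, pools$pool_id)]
  same_animal <- df$animal_id[-1] == df$animal_id[-nrow(df)]
  i1 <- which(same_animal)          # earlier capture of each pair
  stage <- as.character(df$age_class)
  cls <- ifelse(df$sex == "female",
                ifelse(stage == "juvenile", "female_juvenile", "female_adult"),
                paste0("male_", sub("subadult", "subadult", stage)))
  out <- data.frame(animal_id = df$animal_id[i1],
                    class_at_first = cls[i1],
                    distance = abs(chain[i1 + 1L] - chain[i1]),
                    same_pool = df$pool_id[i1 + 1L] == df$pool_id[i1])
  class(out) <- c("move_pairs", "data.frame")
  out
}

#' Per-class residency and movement-distance summaries
#'
#' Residency (probability consecutive recaptures fall in the same pool) is
#' estimated with a Beta(1 + x, 1 + n - x) posterior over same-pool counts;
#' distance means carry central bootstrap intervals.  Classes with no pairs
#' are flagged absent.
#'
#' @param moves a `move_pairs` data.frame.
#' @param level credible/confidence level (default 0.95).
#' @param n_boot bootstrap resamples for the distance mean (default 10000).
#' @param threshold_m long-distance threshold (default 2000 m).
#' @param seed optional seed for the bootstrap.
#' @return data.frame, one row per class: `n_pairs`, `n_same`, `residency`
#'   (posterior mean), `residency_lcl`, `residency_ucl`, `mean_distance`,
#'   `dist_lcl`, `dist_ucl`, `max_distance`, `frac_over_threshold`,
#'   `absent`.
#' @export
residency_and_distances <- function(moves, level = 0.95, n_boot = 10000L,
                                    threshold_m = 2000, seed = NULL) {
  with_seed(seed, {
    rows <- lapply(CLASS_LEVELS, function(cl) {
      d <- moves[moves$class_at_first == cl, ]
      n <- nrow(d)
      if (n == 0L)
        return(data.frame(class = cl, n_pairs = 0L, n_same = 0L,
                          residency = NA_real_, residency_lcl = NA_real_,
                          residency_ucl = NA_real_, mean_distance = NA_real_,
                          dist_lcl = NA_real_, dist_ucl = NA_real_,
                          max_distance = NA_real_,
                          frac_over_threshold = NA_real_, absent = TRUE))
      x <- sum(d$same_pool)
      post <- beta_binomial_test(x, n, level)
      bm <- replicate(n_boot, mean(sample(d$distance, n, replace = TRUE)))
      a <- (1 - level) / 2
      data.frame(class = cl, n_pairs = n, n_same = x,
                 residency = post$mean, residency_lcl = post$lower,
                 residency_ucl = post$upper,
                 mean_distance = mean(d$distance),
                 dist_lcl = unname(stats::quantile(bm, a)),
                 dist_ucl = unname(stats::quantile(bm, 1 - a)),
                 max_distance = max(d$distance),
                 frac_over_threshold = mean(d$distance > threshold_m),
                 absent = FALSE)
    })
    do.call(rbind, rows)
  })
}
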