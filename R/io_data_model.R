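# Reading, validating and writing the delimited-text field formats, and
# construction of annual survey occasions with flow covariates.
#
# capture_records.csv columns:
#   animal_id,date,pool_id,sex,age_class,weight_g,length_cm,lactating,effort_hours
# pools.csv columns: pool_id,chainage_m
# flows.csv columns: year,month,flow_gl
# All files UTF-8, comma-delimited, "." decimal mark, ISO-8601 dates.

#' Read capture records
#'
#' Parses a capture-record file (one row per capture event) and validates
#' every row.  Invalid rows are reported together with their row numbers and
#' the whole read fails, so a returned table is always fully valid.
#'
#' @param path path to a `capture_records.csv`-format file.
#' @return a `data.frame` of class `capture_records` with columns
#'   `animal_id` (character), `date` (`Date`), `pool_id` (character), `sex`
#'   (factor female/male), `age_class` (factor juvenile/subadult/adult),
#'   `weight_g`, `length_cm` (numeric, `NA` when unmeasured), `lactating`
#'   (factor yes/no/untested) and `effort_hours` (numeric net-hours of the
#'   survey session that produced the record).  Row order is preserved.
#' @export
read_capture_records <- function(path) {
  if (!file.exists(path)) stopf("capture record file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                         fileEncoding = "UTF-8")
  required <- c("animal_id", "date", "pool_id", "sex", "age_class",
                "weight_g", "length_cm", "lactating", "effort_hours")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stopf("capture record file is missing mandatory column(s): %s",
          paste(missing, collapse = ", "))
  validate_capture_records(raw)
}

# Coerce + validate a character data.frame of raw rows; row numbers in
# diagnostics refer to data rows (header excluded).
validate_capture_records <- function(raw) {
  n <- nrow(raw)
  out <- data.frame(
    animal_id = raw$animal_id,
    date = as.Date(raw$date, format = "%Y-%m-%d"),
    pool_id = raw$pool_id,
    sex = factor(ifelse(raw$sex %in% SEX_LEVELS, raw$sex, NA), SEX_LEVELS),
    age_class = factor(ifelse(raw$age_class %in% AGE_LEVELS, raw$age_class, NA),
                       AGE_LEVELS),
    weight_g = suppressWarnings(as.numeric(raw$weight_g)),
    length_cm = suppressWarnings(as.numeric(raw$length_cm)),
    lactating = factor(ifelse(raw$lactating %in% c(LACT_LEVELS, ""),
                              ifelse(raw$lactating == "", "untested", raw$lactating),
                              NA), LACT_LEVELS),
    effort_hours = suppressWarnings(as.numeric(raw$effort_hours)),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    class(out) <- c("capture_records", "data.frame")
    return(out)
  }
  problems <- character(0)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      problems <<- c(problems, sprintf("row %d: %s", rows, what))
  }
  bad(is.na(out$animal_id) | out$animal_id == "", "empty animal_id")
  bad(is.na(out$date), sprintf("unparseable date '%s'", raw$date))
  bad(is.na(out$pool_id) | out$pool_id == "", "empty pool_id")
  bad(is.na(out$sex), sprintf("invalid sex '%s'", raw$sex))
  bad(is.na(out$age_class), sprintf("invalid age_class '%s'", raw$age_class))
  bad(is.na(out$lactating), sprintf("invalid lactating '%s'", raw$lactating))
  bad(!is.na(out$weight_g) & out$weight_g <= 0, "non-positive weight_g")
  bad(!is.na(out$length_cm) & out$length_cm <= 0, "non-positive length_cm")
  bad(is.na(out$effort_hours) | out$effort_hours < 0,
      "missing or negative effort_hours")
  bad(!is.na(out$lactating) & out$lactating == "yes" &
        !is.na(out$sex) & out$sex == "male", "lactating male")
  if (length(problems))
    stopf("invalid capture records:\n%s",
          paste(utils::head(problems, 20L), collapse = "\n"))
  class(out) <- c("capture_records", "data.frame")
  out
}

#' Write capture records
#'
#' Inverse of [read_capture_records()]; `write` then `read` round-trips to
#' identical records.
#'
#' @param records a `capture_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_capture_records <- function(records, path) {
  df <- data.frame(
    animal_id = as.character(records$animal_id),
    date = format(records$date, "%Y-%m-%d"),
    pool_id = as.character(records$pool_id),
    sex = as.character(records$sex),
    age_class = as.character(records$age_class),
    weight_g = records$weight_g,
    length_cm = records$length_cm,
    lactating = as.character(records$lactating),
    effort_hours = records$effort_hours)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pool chainage map
#'
#' @param path path to `pools.csv` with columns `pool_id,chainage_m`
#'   (metres along the channel from an arbitrary downstream origin).
#' @return data.frame of class `pool_map`.
#' @export
read_pool_map <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("pool_id", "chainage_m") %in% names(df)))
    stopf("pool map needs columns pool_id, chainage_m")
  df$pool_id <- as.character(df$pool_id)
  if (anyDuplicated(df$pool_id))
    stopf("duplicate pool_id in pool map: %s",
          paste(unique(df$pool_id[duplicated(df$pool_id)]), collapse = ", "))
  if (any(!is.finite(df$chainage_m) | df$chainage_m < 0))
    stopf("chainages must be finite and non-negative")
  class(df) <- c("pool_map", "data.frame")
  df
}

#' @rdname read_pool_map
#' @param pools a `pool_map` data.frame.
#' @export
write_pool_map <- function(pools, path) {
  utils::write.csv(as.data.frame(pools), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a monthly river-flow series
#'
#' @param path path to `flows.csv` with columns `year,month,flow_gl`
#'   (total monthly flow volume in gigalitres).
#' @return data.frame of class `flow_series`, ordered by month, with
#'   contiguous month coverage enforced.
#' @export
read_flow_series <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("year", "month", "flow_gl") %in% names(df)))
    stopf("flow series needs columns year, month, flow_gl")
  validate_flow_series(df)
}

validate_flow_series <- function(df) {
  df <- df[order(month_index(df$year, df$month)), , drop = FALSE]
  if (any(!is.finite(df$flow_gl) | df$flow_gl < 0))
    stopf("flows must be finite and non-negative")
  if (any(df$month < 1 | df$month > 12)) stopf("month must be in 1..12")
  idx <- month_index(df$year, df$month)
  if (nrow(df) > 1 && !all(diff(idx) == 1L))
    stopf("flow series months are not contiguous")
  rownames(df) <- NULL
  class(df) <- c("flow_series", "data.frame")
  df
}

#' @rdname read_flow_series
#' @param flows a `flow_series` data.frame.
#' @export
write_flow_series <- function(flows, path) {
  utils::write.csv(as.data.frame(flows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Cumulative flow (GL) over the `k` calendar months ending at month `mi`
# (month_index scale); errors if the series does not cover the window.
cumulative_flow <- function(flows, mi, k, label = "") {
  idx <- month_index(flows$year, flows$month)
  need <- (mi - k + 1L):mi
  hit <- match(need, idx)
  if (anyNA(hit))
    stopf("flow series does not cover the %d-month lookback for %s", k, label)
  sum(flows$flow_gl[hit])
}

#' Build annual survey occasions
#'
#' Partitions the study span into 12-month survey-year windows starting at
#' `season_start_month` (default July, so each December-March austral
#' breeding season falls inside a single occasion), sums netting effort per
#' window and attaches cumulative-flow covariates ending at the window
#' midpoint.
#'
#' A survey session is identified by its date; all records of one session
#' carry the session's total effort, which is counted once.  Occasions with
#' zero recorded effort are retained and flagged.
#'
#' @param records a `capture_records` data.frame (non-empty).
#' @param flows a `flow_series` covering every occasion's 24-month lookback.
#' @param season_start_month integer 1..12; first calendar month of the
#'   survey year.
#' @return data.frame of class `occasions` with columns `index`, `year`
#'   (survey year = calendar year of the window start), `start`, `end`
#'   (half-open `[start, end)`), `midpoint`, `effort_hours`, `zero_effort`,
#'   and `flow_1m`, `flow_6m`, `flow_12m`, `flow_24m` (GL, cumulative over
#'   the 1/6/12/24 months ending at the midpoint month).
#' @export
build_occasions <- function(records, flows, season_start_month = 7L) {
  if (nrow(records) == 0L) stopf("no capture records")
  if (!(season_start_month %in% 1:12)) stopf("season_start_month must be in 1..12")
  ssm <- as.integer(season_start_month)
  yr <- as.integer(format(records$date, "%Y"))
  mo <- as.integer(format(records$date, "%m"))
  survey_year <- yr - (mo < ssm)
  years <- seq(min(survey_year), max(survey_year))
  occ <- lapply(seq_along(years), function(i) {
    y <- years[i]
    start <- as.Date(sprintf("%d-%02d-01", y, ssm))
    end <- as.Date(sprintf("%d-%02d-01", y + 1L, ssm))
    mid <- start + floor(as.numeric(end - start) / 2)
    in_window <- survey_year == y
    # one effort value per survey session (keyed by date)
    eff <- 0
    if (any(in_window)) {
      sess <- records[in_window, c("date", "effort_hours")]
      sess <- sess[!duplicated(sess$date), ]
      eff <- sum(sess$effort_hours)
    }
    mi <- month_index(as.integer(format(mid, "%Y")), as.integer(format(mid, "%m")))
    lab <- sprintf("occasion [%s, %s)", start, end)
    data.frame(index = i, year = y, start = start, end = end, midpoint = mid,
               effort_hours = eff, zero_effort = eff == 0,
               flow_1m = cumulative_flow(flows, mi, 1L, lab),
               flow_6m = cumulative_flow(flows, mi, 6L, lab),
               flow_12m = cumulative_flow(flows, mi, 12L, lab),
               flow_24m = cumulative_flow(flows, mi, 24L, lab))
  })
  occ <- do.call(rbind, occ)
  class(occ) <- c("occasions", "data.frame")
  occ
}

# Index of the occasion window containing each date (NA if none).
occasion_of <- function(dates, occasions) {
  out <- rep(NA_integer_, length(dates))
  for (i in seq_len(nrow(occasions))) {
    hit <- dates >= occasions$start[i] & dates < occasions$end[i]
    out[hit] <- occasions$index[i]
  }
  out
}
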