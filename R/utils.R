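# Internal helpers shared across modules.

SEX_LEVELS <- c("female", "male")
AGE_LEVELS <- c("juvenile", "subadult", "adult")
LACT_LEVELS <- c("yes", "no", "untested")

# The five field sex-age classes, in the order used throughout the package.
CLASS_LEVELS <- c("female_juvenile", "female_adult",
                  "male_juvenile", "male_subadult", "male_adult")

#' Inverse logit
#'
#' @param x numeric vector on the logit scale.
#' @return probabilities in (0, 1).
#' @export
invlogit <- function(x) stats::plogis(x)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for pipeline stage / scenario i under a parent
# seed; kept within 32-bit integer range.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * i) %% 2147483647L) + 1L
}

# Map sex + integer age (years) to one of the five field classes.
# Females: juvenile in their first year, adult thereafter.  Males: juvenile
# in their first year, sub-adult ages 1-2, adult from age 3 (full spurs by
# the third year of life).
class_of <- function(sex, age) {
  ifelse(sex == "female",
         ifelse(age < 1, "female_juvenile", "female_adult"),
         ifelse(age < 1, "male_juvenile",
                ifelse(age <= 2, "male_subadult", "male_adult")))
}

# year*12 + month-1: integer month index used for flow lookups.
month_index <- function(year, month) as.integer(year) * 12L + as.integer(month) - 1L

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
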