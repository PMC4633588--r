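# Published parameter estimates from the four-decade (1973-2014) upper
# Shoalhaven River platypus mark-recapture study, used as inputs for
# prediction, survival adjustment and viability scenarios.

#' Published detection coefficients (logit scale)
#'
#' Model-averaged detection-probability coefficients from the top-ranked
#' CJS models of the long-term Shoalhaven study: intercept (juvenile
#' female reference), cumulative flow (GL) in the capture month, annual
#' netting effort (net-hours), and sub-adult/adult class offsets.
#'
#' @return named numeric vector suitable for [predict_detection()].
#' @export
shoalhaven_detection_coefficients <- function() {
  c(intercept = -0.0417, flow_1m = -0.0537, effort = 0.0128,
    subadult = 1.053, adult = -0.728)
}

#' Published apparent-survival coefficients (logit scale)
#'
#' Model-averaged apparent-survival coefficients from the same study:
#' intercept (juvenile female), cumulative 6-month flow (linear and
#' quadratic, GL), male offset, weight (linear and quadratic, grams), and
#' sub-adult/adult class offsets.
#'
#' @return named numeric vector.
#' @export
shoalhaven_survival_coefficients <- function() {
  c(intercept = -7.3804, flow_6m = 0.0008, flow_6m2 = -0.0001,
    male = -1.8673, weight = 0.0132, weight2 = 0,
    subadult = 0.3448, adult = 1.05)
}

#' Published CJS model-ranking table
#'
#' The 13 top-ranked (99% cumulative weight) CJS model structures with
#' their parameter counts, AICc, AICc differences, published Akaike
#' weights and deviances.
#'
#' @return data.frame with columns `model`, `npar`, `AICc`, `delta`,
#'   `weight`, `deviance`.
#' @export
shoalhaven_model_table <- function() {
  data.frame(
    model = c(
      "phi(6m.flow+sex+weight+age) p(1m.flow+effort+age)",
      "phi(1m.flow+sex+weight+age) p(1m.flow+effort+age)",
      "phi(6m.flow+sex+weight+age) p(1m.flow+effort+sex+age)",
      "phi(1m.flow+sex+weight+age) p(1m.flow+effort+sex+age)",
      "phi(6m.flow+sex+weight+age) p(1m.flow+effort)",
      "phi(6m.flow+sex+weight+age) p(1m.flow+effort+sex)",
      "phi(12m.flow+sex+weight+age) p(1m.flow+effort+age)",
      "phi(12m.flow+sex+weight+age) p(1m.flow+effort)",
      "phi(6m.flow+sex+weight) p(1m.flow+effort)",
      "phi(1m.flow+sex+weight+age) p(1m.flow+effort+sex)",
      "phi(6m.flow+sex+weight) p(1m.flow+effort+age)",
      "phi(12m.flow+sex+weight+age) p(1m.flow+effort+sex+age)",
      "phi(6m.flow+sex+weight) p(1m.flow+effort+sex)"),
    npar = c(13L, 13L, 14L, 14L, 11L, 12L, 13L, 11L, 9L, 12L, 11L, 14L, 10L),
    AICc = c(2266.73, 2268.22, 2268.69, 2270.05, 2271.90, 2272.98, 2273.07,
             2273.36, 2273.88, 2274.16, 2274.78, 2275.00, 2275.14),
    delta = c(0, 1.49, 1.95, 3.32, 5.16, 6.24, 6.34, 6.62, 7.15, 7.43,
              8.04, 8.27, 8.41),
    weight = c(0.42, 0.20, 0.16, 0.08, 0.03, 0.02, 0.02, 0.02, 0.01, 0.01,
               0.01, 0.01, 0.01),
    deviance = c(2240.44, 2241.92, 2240.35, 2241.71, 2249.68, 2248.72,
                 2246.78, 2251.14, 2255.74, 2249.91, 2252.56, 2246.66,
                 2254.97))
}

#' Published apparent survival, residency and dispersal by class
#'
#' Apparent annual survival from the CJS fits, pool residency from
#' consecutive recaptures, and the dispersal fractions (1 - residency
#' scale) used in the viability scenarios, for the five sex-age classes.
#'
#' @return data.frame with one row per class: `class`, `phi` (apparent
#'   survival), `dispersal` (fraction dispersing), `residency`
#'   (`1 - dispersal`).
#' @export
shoalhaven_class_rates <- function() {
  data.frame(
    class = CLASS_LEVELS,
    phi = c(0.27, 0.76, 0.13, 0.38, 0.57),
    dispersal = c(0.154, 0.145, 0.55, 0.38, 0.26),
    residency = 1 - c(0.154, 0.145, 0.55, 0.38, 0.26))
}
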