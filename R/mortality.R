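#' Build a table of maximum mortality records
#'
#' One row per numerical-response fit: the temperature, the derived maximum
#' mortality rate, the prey metric it came from, and an explicit exclusion
#' flag. Exclusions are *input*, not computed: outlier status is a judgement
#' about the underlying fit (e.g. a non-satiated treatment), so excluded
#' records must carry a non-empty reason.
#'
#' @param temperature Temperature, degC.
#' @param delta_max Maximum mortality rate, d^-1 (negative by convention).
#' @param prey_kind `"abundance"` or `"biomass"` (recycled).
#' @param excluded Logical exclusion flags (recycled, default FALSE).
#' @param reason Reason text, required non-empty wherever `excluded` is TRUE.
#'
#' @return A tibble with class `mortality_records`.
#' @export
mortality_records <- function(temperature, delta_max,
                              prey_kind = "abundance",
                              excluded = FALSE, reason = "") {
  n <- length(temperature)
  stopifnot(length(delta_max) == n)
  out <- tibble::tibble(temperature = temperature,
                        delta_max = delta_max,
                        prey_kind = rep_len(prey_kind, n),
                        excluded = rep_len(excluded, n),
                        reason = rep_len(reason, n))
  if (any(out$excluded & !nzchar(out$reason))) {
    stop("every excluded record needs a non-empty `reason`", call. = FALSE)
  }
  class(out) <- c("mortality_records", class(out))
  out
}

#' Least-squares trend of maximum mortality with temperature
#'
#' Ordinary least squares of the maximum mortality rate on temperature over
#' the non-excluded records. The slope is tested for deviation from zero
#' with a two-sided t test (t = slope / SE, df = n - 2), and a pointwise
#' confidence band evaluator is attached.
#'
#' @param records A [mortality_records()] table (any data frame with
#'   `temperature`, `delta_max` and optionally `excluded` works).
#' @param ci_level Level for the confidence band (default 0.95).
#'
#' @return An object of class `mortality_trend`: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `t_stat`, `p_value`, `df`, `n_used`,
#'   `n_excluded`, `ci_level`, the underlying `lm` fit, and
#'   `band(temperature)` returning a tibble with `fit`, `lower`, `upper`.
#' @export
mortality_trend <- function(records, ci_level = 0.95) {
  stopifnot(is.data.frame(records),
            all(c("temperature", "delta_max") %in% names(records)))
  excluded <- if ("excluded" %in% names(records)) records$excluded else FALSE
  used <- records[!excluded, , drop = FALSE]
  if (nrow(used) < 3L) {
    stop("need at least 3 non-excluded records", call. = FALSE)
  }
  if (length(unique(used$temperature)) < 2L) {
    stop("records must span at least 2 temperatures", call. = FALSE)
  }
  fit <- stats::lm(delta_max ~ temperature, data = used)
  sm <- summary(fit)$coefficients
  slope <- sm["temperature", "Estimate"]
  slope_se <- sm["temperature", "Std. Error"]
  band <- function(temperature) {
    pr <- stats::predict(fit, newdata = data.frame(temperature = temperature),
                         interval = "confidence", level = ci_level)
    tibble::tibble(temperature = temperature, fit = pr[, "fit"],
                   lower = pr[, "lwr"], upper = pr[, "upr"])
  }
  structure(list(
    slope = slope, intercept = sm["(Intercept)", "Estimate"],
    slope_se = slope_se, intercept_se = sm["(Intercept)", "Std. Error"],
    t_stat = sm["temperature", "t value"],
    p_value = sm["temperature", "Pr(>|t|)"],
    df = fit$df.residual, n_used = nrow(used),
    n_excluded = sum(excluded), ci_level = ci_level,
    lm_fit = fit, band = band
  ), class = "mortality_trend")
}

#' @export
print.mortality_trend <- function(x, ...) {
  cat(sprintf(
    "Mortality trend: slope %.4f +/- %.4f d^-1 degC^-1 (t = %.2f, df = %d, p = %.3g)\n",
    x$slope, x$slope_se, x$t_stat, x$df, x$p_value))
  cat(sprintf("  intercept %.3f d^-1; n = %d used, %d excluded\n",
              x$intercept, x$n_used, x$n_excluded))
  invisible(x)
}

#' Predict mortality at a temperature from the fitted trend
#'
#' @param trend A [mortality_trend()].
#' @param temperature Temperature(s), degC.
#'
#' @return Predicted mortality rate(s), d^-1.
#' @export
predict_mortality <- function(trend, temperature) {
  stopifnot(inherits(trend, "mortality_trend"))
  trend$intercept + trend$slope * temperature
}

#' Summary statistics of maximum mortality
#'
#' Mean, sample standard deviation and median of the non-excluded mortality
#' rates. Because the model yields negative mortality rates, the
#' `"positive"` convention multiplies by -1 for direct comparison with
#' growth rates.
#'
#' @param records A [mortality_records()] table.
#' @param sign_convention `"as_is"` (default) or `"positive"`.
#'
#' @return A list: `mean`, `sd` (`NA` for a single record), `median`, `n`.
#' @export
summarize_mortality <- function(records,
                                sign_convention = c("as_is", "positive")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(is.data.frame(records), "delta_max" %in% names(records))
  excluded <- if ("excluded" %in% names(records)) records$excluded else FALSE
  v <- records$delta_max[!excluded]
  if (length(v) < 1L) stop("no non-excluded records", call. = FALSE)
  if (sign_convention == "positive") v <- -v
  list(mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       median = stats::median(v),
       n = length(v))
}

#' Community grazing rate of a grazer population
#'
#' Grazer abundance (individuals L^-1) times individual clearance rate
#' (mL ind^-1 d^-1), converted to a specific loss rate (d^-1) for the prey
#' population (factor 1e-3 L/mL).
#'
#' @param grazer_abundance Grazers per litre (>= 0).
#' @param clearance_rate Volume swept clear per grazer per day,
#'   mL ind^-1 d^-1 (>= 0).
#'
#' @return Community grazing rate, d^-1.
#' @examples
#' community_grazing_rate(0.3, 18)  # sparse alpine copepods: ~0.005 / d
#' @export
community_grazing_rate <- function(grazer_abundance, clearance_rate) {
  stopifnot(all(grazer_abundance >= 0), all(clearance_rate >= 0))
  grazer_abundance * clearance_rate * 1e-3
}

#' Grazer density required to offset a growth rate
#'
#' Inverse of [community_grazing_rate()]: how many grazers per litre are
#' needed for their community grazing to balance a prey growth rate `r`.
#'
#' @param r Prey population growth rate to offset, d^-1.
#' @param clearance_rate Individual clearance rate, mL ind^-1 d^-1 (> 0).
#'
#' @return Required grazer density, individuals L^-1.
#' @examples
#' required_grazer_density(1.0, 37)  # ~27 ind / L
#' @export
required_grazer_density <- function(r, clearance_rate) {
  if (any(clearance_rate <= 0)) {
    stop("`clearance_rate` must be > 0", call. = FALSE)
  }
  r / (clearance_rate * 1e-3)
}
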