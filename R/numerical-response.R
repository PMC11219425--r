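#' Threshold numerical-response parameters
#'
#' Parameter triple of the threshold numerical response
#' r(P) = r_max (P - P') / \[k + (P - P')\]: a rectangular hyperbola shifted
#' so that growth crosses zero at the threshold food level P'. `k` controls
#' the curvature (it is *not* a Michaelis-Menten half-saturation constant
#' because of the shift) and must be positive; a negative threshold is not
#' interpretable, so `p_prime >= 0`.
#'
#' @param r_max Maximum specific growth rate at food satiation, d^-1.
#' @param p_prime Threshold food concentration (x-axis intercept), prey units.
#' @param k Curvature constant, prey units (> 0).
#'
#' @return A list of class `nr_params`.
#' @examples
#' nr_params(0.61, 1.34, 2.66)
#' @export
nr_params <- function(r_max, p_prime, k) {
  stopifnot(is.numeric(r_max), length(r_max) == 1L, is.finite(r_max),
            is.numeric(p_prime), length(p_prime) == 1L, is.finite(p_prime),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (p_prime < 0) stop("`p_prime` must be >= 0", call. = FALSE)
  structure(list(r_max = r_max, p_prime = p_prime, k = k),
            class = "nr_params")
}

#' @export
print.nr_params <- function(x, ...) {
  cat(sprintf("NR params: r_max = %.4g d^-1, P' = %.4g, k = %.4g\n",
              x$r_max, x$p_prime, x$k))
  invisible(x)
}

as_nr_params <- function(x) {
  if (inherits(x, "nr_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(nr_params(x[1], x[2], x[3]))
  if (is.list(x) && all(c("r_max", "p_prime", "k") %in% names(x))) {
    return(nr_params(x$r_max, x$p_prime, x$k))
  }
  stop("cannot interpret `params` as nr_params", call. = FALSE)
}

#' Rate points for response-curve fitting
#'
#' A tidy table of (prey level, growth rate) observations at one or more
#' temperatures, the input to [fit_nr()] and (via the fitted r_max values)
#' [fit_lactin2()]. The prey metric must not be mixed within one fit:
#' either bacterial abundance or carbon biomass.
#'
#' @param temperature Temperature treatment, degrees C.
#' @param prey_value Food level (cells mL^-1 or mg C L^-1, see `prey_kind`).
#' @param r Specific growth rate, d^-1.
#' @param prey_kind `"abundance"` or `"biomass"`.
#'
#' @return A tibble with columns `temperature`, `prey_value`, `r`,
#'   `prey_kind`.
#' @export
rate_points <- function(temperature, prey_value, r,
                        prey_kind = c("abundance", "biomass")) {
  prey_kind <- match.arg(prey_kind)
  if (any(!is.finite(prey_value)) || any(prey_value < 0)) {
    stop("`prey_value` must be non-negative and finite", call. = FALSE)
  }
  tibble::tibble(temperature = temperature, prey_value = prey_value,
                 r = r, prey_kind = prey_kind)
}

#' Evaluate the threshold numerical response
#'
#' @param params An [nr_params()] (or a length-3 numeric `c(r_max, p_prime, k)`).
#' @param P Prey level(s), same units as `p_prime` and `k`.
#'
#' @return Growth rate(s), d^-1.
#' @examples
#' p <- nr_params(0.6057, 1.3392, 2.6633)
#' nr_predict(p, 0)          # growth at zero food: the maximum mortality rate
#' nr_predict(p, p$p_prime)  # zero by construction
#' @export
nr_predict <- function(params, P) {
  params <- as_nr_params(params)
  denom <- params$k + (P - params$p_prime)
  if (any(abs(denom) < .Machine$double.eps * 16)) {
    bad <- P[abs(denom) < .Machine$double.eps * 16][1]
    stop("numerical response has a pole at P = ", format(bad), call. = FALSE)
  }
  params$r_max * (P - params$p_prime) / denom
}

#' Maximum physiological mortality rate
#'
#' The numerical response evaluated at zero food,
#' delta_max = -r_max P' / (k - P'): the starvation-driven decline rate, the
#' low-food counterpart of r_max. Negative whenever 0 < P' < k and r_max > 0;
#' zero when there is no threshold (P' = 0).
#'
#' @inheritParams nr_predict
#' @return Mortality rate at zero food, d^-1 (usually negative).
#' @examples
#' delta_max(nr_params(0.6057, 1.3392, 2.6633))  # about -0.61
#' @export
delta_max <- function(params) {
  params <- as_nr_params(params)
  if (abs(params$k - params$p_prime) < .Machine$double.eps * 16) {
    stop("delta_max undefined: k = p_prime puts the pole at P = 0",
         call. = FALSE)
  }
  nr_predict(params, 0)
}

nr_jacobian <- function(theta, P) {
  q <- P - theta[2]
  d <- theta[3] + q
  cbind(r_max = q / d,
        p_prime = -theta[1] * theta[3] / d^2,
        k = -theta[1] * q / d^2)
}

nr_start_values <- function(prey, r) {
  p_prime0 <- if (any(r <= 0)) max(prey[r <= 0]) else min(prey) / 2
  k0 <- diff(range(prey)) / 2
  c(r_max = max(r), p_prime = max(p_prime0, 1e-8), k = max(k0, 1e-8))
}

#' Fit the threshold numerical response to rate points
#'
#' Bounded Levenberg-Marquardt least squares of growth rate on prey level at
#' a single temperature, with k > 0 and P' >= 0. Standard errors come from
#' the Jacobian-based covariance s^2 (J'J)^-1 and per-coefficient two-sided
#' t tests use n - 3 degrees of freedom. The derived maximum mortality rate
#' and its Monte-Carlo interval (see [delta_max_interval()]) are attached.
#' Points with negative growth are retained — they are what pins down the
#' threshold.
#'
#' @param points A data frame with columns `prey_value` and `r` (and
#'   optionally `temperature`, `prey_kind`), e.g. from [rate_points()];
#'   at least 5 points at one temperature and one prey metric, at least one
#'   with positive growth.
#' @param init Optional starting [nr_params()]. By default r_max starts at
#'   the largest observed rate, P' at the largest prey level with r <= 0
#'   (or half the smallest prey level if all rates are positive), and k at
#'   half the prey range.
#' @param level Confidence level for the mortality interval (default 0.95).
#' @param n_draws,seed Passed to [delta_max_interval()].
#'
#' @return An object of class `nr_fit`: fitted `params`, `se`, `p_values`,
#'   `covariance`, `delta_max`, `delta_max_interval`, `n_points`,
#'   `prey_kind`, `temperature`, `converged`, `rss`, `sigma2`, `df`.
#' @examples
#' pts <- rate_points(15, c(0.2, 0.5, 1, 2, 4, 8),
#'                    nr_predict(nr_params(1, 0.3, 1), c(0.2, 0.5, 1, 2, 4, 8)))
#' fit <- fit_nr(pts)
#' coef(fit)
#' @export
fit_nr <- function(points, init = NULL, level = 0.95,
                   n_draws = 1e5, seed = 1L) {
  stopifnot(is.data.frame(points),
            all(c("prey_value", "r") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("prey_value", "r")]), ]
  n <- nrow(points)
  if (n < 5L) {
    stop("at least 5 rate points are required for a reported fit",
         call. = FALSE)
  }
  if ("temperature" %in% names(points) &&
      length(unique(points$temperature)) > 1L) {
    stop("all points must share one temperature; fit per treatment",
         call. = FALSE)
  }
  if ("prey_kind" %in% names(points) &&
      length(unique(points$prey_kind)) > 1L) {
    stop("prey metric (abundance vs biomass) must not be mixed in one fit",
         call. = FALSE)
  }
  prey <- points$prey_value
  r <- points$r
  if (!any(r > 0)) {
    stop("no positive growth rates observed; the response cannot be fitted",
         call. = FALSE)
  }
  theta0 <- if (is.null(init)) {
    nr_start_values(prey, r)
  } else {
    init <- as_nr_params(init)
    c(r_max = init$r_max, p_prime = max(init$p_prime, 1e-8), k = init$k)
  }
  resid_fn <- function(theta) r - theta[1] * (prey - theta[2]) /
    (theta[3] + (prey - theta[2]))
  jac_fn <- function(theta) -nr_jacobian(theta, prey)
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn, jac = jac_fn,
    lower = c(-Inf, 0, 1e-10), upper = rep(Inf, 3),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-8, ptol = 1e-8, maxiter = 1000, maxfev = 10000))
  theta <- fit$par
  converged <- fit$info %in% 1:3
  df <- n - 3L
  rss <- fit$deviance
  sigma2 <- rss / df
  J <- nr_jacobian(theta, prey)
  covariance <- tryCatch(solve(crossprod(J)) * sigma2,
                         error = function(e) matrix(NA_real_, 3, 3))
  dimnames(covariance) <- list(names(theta), names(theta))
  se <- sqrt(diag(covariance))
  t_stat <- theta / se
  p_values <- 2 * stats::pt(-abs(t_stat), df = df)
  params <- nr_params(theta[["r_max"]], theta[["p_prime"]], theta[["k"]])
  out <- structure(list(
    params = params,
    se = se,
    p_values = p_values,
    covariance = covariance,
    delta_max = tryCatch(delta_max(params), error = function(e) NA_real_),
    delta_max_interval = NULL,
    n_points = n,
    prey_kind = if ("prey_kind" %in% names(points)) points$prey_kind[1] else NA_character_,
    temperature = if ("temperature" %in% names(points)) points$temperature[1] else NA_real_,
    converged = converged,
    info = fit$info,
    message = fit$message,
    rss = rss,
    sigma2 = sigma2,
    df = df,
    data = tibble::as_tibble(points),
    level = level
  ), class = "nr_fit")
  if (converged && all(is.finite(se))) {
    out$delta_max_interval <- delta_max_interval(out, level = level,
                                                 n_draws = n_draws,
                                                 seed = seed)
  }
  out
}

#' @export
coef.nr_fit <- function(object, ...) {
  c(r_max = object$params$r_max, p_prime = object$params$p_prime,
    k = object$params$k)
}

#' @export
vcov.nr_fit <- function(object, ...) object$covariance

#' @export
print.nr_fit <- function(x, ...) {
  cat("Threshold numerical-response fit")
  if (is.finite(x$temperature)) cat(sprintf(" at %g degC", x$temperature))
  if (!is.na(x$prey_kind)) cat(sprintf(" (%s)", x$prey_kind))
  cat(sprintf("\n  n = %d, converged: %s, RSS = %.4g\n",
              x$n_points, x$converged, x$rss))
  est <- coef(x)
  tab <- cbind(estimate = est, se = x$se, p = x$p_values)
  print(round(tab, 4))
  ci <- x$delta_max_interval
  cat(sprintf("  delta_max = %.3f d^-1", x$delta_max))
  if (!is.null(ci)) {
    cat(sprintf(" [%.3f, %.3f] (%d%% MC)",
                ci$lower, ci$upper, round(100 * x$level)))
  }
  cat("\n")
  invisible(x)
}

#' Monte-Carlo interval for the maximum mortality rate
#'
#' Propagates the fitted parameter covariance through the zero-food
#' evaluation of the numerical response. Parameter draws come from a
#' multivariate t with n - 3 degrees of freedom around the estimates
#' (normal draws scaled by sqrt(df / chi^2_df), which accounts for the
#' uncertainty in the residual variance at the small n typical of these
#' campaigns). Draws that violate the interpretability constraints
#' (k > P', P' >= 0) are discarded; if more than half are invalid the
#' interval is flagged unreliable.
#'
#' @param fit An `nr_fit` from [fit_nr()].
#' @param level Interval level (default 0.95, equal-tailed).
#' @param n_draws Number of parameter draws (default 1e5).
#' @param seed Integer seed; fixed seed gives an identical interval.
#'
#' @return A list: `lower`, `upper`, `level`, `n_valid`, `prop_valid`,
#'   `reliable`, `n_draws`, `seed`.
#' @export
delta_max_interval <- function(fit, level = 0.95, n_draws = 1e5, seed = 1L) {
  stopifnot(inherits(fit, "nr_fit"))
  if (!fit$converged) {
    stop("fit did not converge; no interval is reported", call. = FALSE)
  }
  V <- fit$covariance
  if (any(!is.finite(V))) {
    stop("parameter covariance is not available", call. = FALSE)
  }
  theta <- coef(fit)
  draws <- withr::with_seed(seed, {
    z <- MASS::mvrnorm(n_draws, mu = c(0, 0, 0), Sigma = V, tol = 1e-8)
    scale <- sqrt(fit$df / stats::rchisq(n_draws, df = fit$df))
    sweep(z * scale, 2, theta, "+")
  })
  valid <- draws[, 3] > draws[, 2] & draws[, 2] >= 0 & draws[, 3] > 0
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    warning("all parameter draws violated k > p_prime >= 0; ",
            "no interval is reported", call. = FALSE)
    return(list(lower = NA_real_, upper = NA_real_, level = level,
                n_valid = 0L, prop_valid = 0, reliable = FALSE,
                n_draws = n_draws, seed = seed))
  }
  d <- -draws[valid, 1] * draws[valid, 2] / (draws[valid, 3] - draws[valid, 2])
  alpha <- (1 - level) / 2
  q <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
  list(lower = q[1], upper = q[2], level = level,
       n_valid = n_valid, prop_valid = n_valid / n_draws,
       reliable = n_valid / n_draws >= 0.5,
       n_draws = n_draws, seed = seed)
}

#' Rate points at near-to-satiating food levels
#'
#' The `n` points with the largest prey values (3 to 5 by convention —
#' the food levels at which growth is close to its plateau). Ties at the
#' cutoff are all kept, so more than `n` points may be returned; a message
#' notes this.
#'
#' @param points A data frame with a `prey_value` column.
#' @param n How many top food levels to keep (3-5; values outside warn but
#'   are honoured).
#'
#' @return The selected rows of `points`, highest prey first.
#' @export
satiating_subset <- function(points, n) {
  stopifnot(is.data.frame(points), "prey_value" %in% names(points))
  n <- as.integer(n)
  if (n > nrow(points)) {
    stop("`n` exceeds the number of points", call. = FALSE)
  }
  if (n < 3L || n > 5L) {
    warning("`n` outside the conventional 3-5 satiating levels",
            call. = FALSE)
  }
  ord <- order(points$prey_value, decreasing = TRUE)
  cutoff <- points$prey_value[ord][n]
  keep <- points$prey_value >= cutoff
  if (sum(keep) > n) {
    message("ties at the satiating cutoff: keeping ", sum(keep),
            " points instead of ", n)
  }
  out <- points[keep, , drop = FALSE]
  out[order(out$prey_value, decreasing = TRUE), , drop = FALSE]
}

rmax_of <- function(x) {
  if (inherits(x, "nr_fit")) return(x$params$r_max)
  stop("expected an nr_fit", call. = FALSE)
}

#' Paired comparison of r_max between two fit series
#'
#' Two-sided paired t test of the maximum growth rates from two matched
#' series of numerical-response fits (typically abundance-based vs
#' biomass-based fits of the same experiments), matched by temperature.
#'
#' @param fits_a,fits_b Either lists of `nr_fit` objects or data frames with
#'   columns `temperature` and `r_max`. Must be matched by temperature.
#'
#' @return A list: `t_stat`, `p_value`, `df`, `mean_difference`, `n`, and
#'   the paired table `pairs`.
#' @export
compare_rmax_paired <- function(fits_a, fits_b) {
  extract <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("temperature", "r_max") %in% names(x)))
      return(tibble::tibble(temperature = x$temperature, r_max = x$r_max))
    }
    tibble::tibble(temperature = vapply(x, function(f) f$temperature, 0),
                   r_max = vapply(x, rmax_of, 0))
  }
  a <- extract(fits_a)
  b <- extract(fits_b)
  if (nrow(a) != nrow(b) || nrow(a) < 2L) {
    stop("need two matched series of length >= 2", call. = FALSE)
  }
  a <- a[order(a$temperature), ]
  b <- b[order(b$temperature), ]
  if (!isTRUE(all.equal(a$temperature, b$temperature))) {
    stop("temperatures do not match between the two series", call. = FALSE)
  }
  d <- a$r_max - b$r_max
  if (stats::sd(d) < .Machine$double.eps * 16) {
    if (all(abs(d) < .Machine$double.eps * 16)) {
      return(list(t_stat = 0, p_value = 1, df = length(d) - 1L,
                  mean_difference = 0, n = length(d),
                  degenerate = TRUE,
                  pairs = tibble::tibble(temperature = a$temperature,
                                         r_max_a = a$r_max,
                                         r_max_b = b$r_max)))
    }
    stop("differences have zero variance (constant offset); ",
         "the paired t statistic is unbounded", call. = FALSE)
  }
  tt <- stats::t.test(a$r_max, b$r_max, paired = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate),
       n = length(d), degenerate = FALSE,
       pairs = tibble::tibble(temperature = a$temperature,
                              r_max_a = a$r_max, r_max_b = b$r_max))
}
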