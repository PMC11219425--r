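#' Lactin-2 thermal performance parameters
#'
#' Parameters of the Lactin-2 thermal performance curve
#' rate(T) = exp(a T) - exp(a t_max - (t_max - T) / delta_t) + b.
#' The curve rises roughly exponentially with coefficient `a`, collapses
#' sharply within `delta_t` degrees below `t_max`, and is shifted
#' vertically by `b` (negative `b` lets the curve cross zero, giving
#' critical thermal limits). One fixed convention is used throughout to
#' avoid the rho/lambda symbol drift across the literature.
#'
#' @param a Rate-increase coefficient, 1/degC.
#' @param b Vertical offset, d^-1 (typically negative).
#' @param t_max Upper reference temperature of the model, degC. Note this is
#'   a curve parameter, not the critical limit CTmax.
#' @param delta_t Width of the supraoptimal decline, degC (> 0).
#'
#' @return A list of class `lactin2_params`.
#' @examples
#' lactin2_params(a = 0.05, b = -0.75, t_max = 23.5, delta_t = 3.3)
#' @export
lactin2_params <- function(a, b, t_max, delta_t) {
  vals <- c(a = a, b = b, t_max = t_max, delta_t = delta_t)
  if (!all(is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (delta_t <= 0) stop("`delta_t` must be > 0", call. = FALSE)
  structure(as.list(vals), class = "lactin2_params")
}

#' @export
print.lactin2_params <- function(x, ...) {
  cat(sprintf("Lactin-2: a = %.4g /degC, b = %.4g d^-1, t_max = %.4g degC, delta_t = %.4g degC\n",
              x$a, x$b, x$t_max, x$delta_t))
  invisible(x)
}

as_lactin2_params <- function(x) {
  if (inherits(x, "lactin2_params")) return(x)
  if (inherits(x, "lactin2_fit")) return(x$params)
  if (is.numeric(x) && length(x) == 4L) {
    return(lactin2_params(x[1], x[2], x[3], x[4]))
  }
  if (is.list(x) && all(c("a", "b", "t_max", "delta_t") %in% names(x))) {
    return(lactin2_params(x$a, x$b, x$t_max, x$delta_t))
  }
  stop("cannot interpret `params` as lactin2_params", call. = FALSE)
}

#' Evaluate the Lactin-2 thermal performance curve
#'
#' @param params A [lactin2_params()] (or length-4 numeric
#'   `c(a, b, t_max, delta_t)`, or a `lactin2_fit`).
#' @param temp Temperature(s), degC.
#'
#' @return Performance (growth rate), d^-1. At `temp = t_max` the two
#'   exponentials cancel and the value is exactly `b`.
#' @examples
#' p <- lactin2_params(0.1, -0.2, 25, 4)
#' lactin2_rate(p, 15)
#' lactin2_rate(p, 25)  # == b
#' @export
lactin2_rate <- function(params, temp) {
  params <- as_lactin2_params(params)
  exp(params$a * temp) -
    exp(params$a * params$t_max - (params$t_max - temp) / params$delta_t) +
    params$b
}

#' Fit the Lactin-2 curve by multistart least squares
#'
#' Levenberg-Marquardt least squares from many random starting points,
#' keeping the best converged fit (lowest residual sum of squares). Starts
#' are drawn uniformly from a in \[0.01, 0.3\], b in \[-2, 0\],
#' t_max in \[max(T), max(T) + 10\], delta_t in \[1, 10\]; delta_t is kept
#' positive during optimisation. Reproducible for a fixed `seed`.
#'
#' @param points A data frame with columns `temperature` and `rate`
#'   (a `r` column is accepted as an alias for `rate`); at least 4 distinct
#'   temperatures. Duplicate temperatures are legitimate observations and
#'   are not collapsed.
#' @param n_starts Number of random starts (default 25).
#' @param seed Integer seed for the start draws.
#'
#' @return An object of class `lactin2_fit`: `params`, `covariance`, `se`,
#'   `rss`, `sigma2`, `df`, `converged`, `n_starts`, `n_converged`,
#'   `start_diagnostics`, `data`.
#' @examples
#' pts <- data.frame(temperature = c(5, 10, 15, 18, 20, 21),
#'                   rate = lactin2_rate(lactin2_params(0.05, -0.7, 23, 3),
#'                                       c(5, 10, 15, 18, 20, 21)))
#' fit_lactin2(pts, n_starts = 10, seed = 1)
#' @export
fit_lactin2 <- function(points, n_starts = 25, seed = 1L) {
  stopifnot(is.data.frame(points), "temperature" %in% names(points))
  if (!"rate" %in% names(points) && "r" %in% names(points)) {
    points$rate <- points$r
  }
  stopifnot("rate" %in% names(points))
  points <- points[stats::complete.cases(points[, c("temperature", "rate")]), ]
  temp <- points$temperature
  rate <- points$rate
  if (length(unique(temp)) < 4L) {
    stop("at least 4 distinct temperatures are required", call. = FALSE)
  }
  resid_fn <- function(theta) {
    rate - (exp(theta[1] * temp) -
              exp(theta[1] * theta[3] - (theta[3] - temp) / theta[4]) +
              theta[2])
  }
  t_hi <- max(temp)
  starts <- withr::with_seed(seed, {
    data.frame(a = stats::runif(n_starts, 0.01, 0.3),
               b = stats::runif(n_starts, -2, 0),
               t_max = stats::runif(n_starts, t_hi, t_hi + 10),
               delta_t = stats::runif(n_starts, 1, 10))
  })
  best <- NULL
  diags <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    theta0 <- unlist(starts[i, ])
    # a start that exhausts its iterations is just a failed start; nls.lm
    # reports that as a warning, which would drown out real signals
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = theta0, fn = resid_fn,
        lower = c(-Inf, -Inf, -Inf, 1e-3), upper = rep(Inf, 4),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxiter = 1000, maxfev = 10000))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diags[[i]] <- list(start = theta0, converged = FALSE,
                         message = conditionMessage(fit), rss = NA_real_)
      next
    }
    ok <- fit$info %in% 1:3
    diags[[i]] <- list(start = theta0, converged = ok,
                       message = fit$message, rss = fit$deviance)
    if (ok && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  n_converged <- sum(vapply(diags, function(d) isTRUE(d$converged), TRUE))
  if (is.null(best)) {
    stop("no multistart converged; per-start diagnostics:\n",
         paste(vapply(seq_along(diags), function(i) {
           sprintf("  start %d: %s", i, diags[[i]]$message)
         }, ""), collapse = "\n"), call. = FALSE)
  }
  theta <- best$par
  n <- length(rate)
  df <- n - 4L
  rss <- best$deviance
  sigma2 <- if (df > 0) rss / df else NA_real_
  J <- numeric_jacobian(function(th) -resid_fn(th), theta)
  covariance <- tryCatch(solve(crossprod(J)) * sigma2,
                         error = function(e) matrix(NA_real_, 4, 4))
  dimnames(covariance) <- list(names(theta), names(theta))
  structure(list(
    params = lactin2_params(theta[["a"]], theta[["b"]], theta[["t_max"]],
                            theta[["delta_t"]]),
    covariance = covariance,
    se = sqrt(diag(covariance)),
    rss = rss, sigma2 = sigma2, df = df,
    converged = TRUE,
    n_starts = n_starts, n_converged = n_converged,
    seed = seed,
    start_diagnostics = diags,
    data = tibble::tibble(temperature = temp, rate = rate)
  ), class = "lactin2_fit")
}

numeric_jacobian <- function(f, theta, eps = 1e-6) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

#' @export
coef.lactin2_fit <- function(object, ...) {
  unlist(object$params[c("a", "b", "t_max", "delta_t")])
}

#' @export
vcov.lactin2_fit <- function(object, ...) object$covariance

#' @export
print.lactin2_fit <- function(x, ...) {
  cat(sprintf("Lactin-2 TPC fit: n = %d, RSS = %.4g (%d/%d starts converged)\n",
              nrow(x$data), x$rss, x$n_converged, x$n_starts))
  print(x$params)
  invisible(x)
}

#' Thermal traits of a fitted performance curve
#'
#' Numerically extracts the temperature optimum (Topt; coarse grid of
#' `grid_n` points then local refinement), the rate at the optimum, the
#' critical thermal limits CTmax and CTmin (bracketed root finding above,
#' respectively below, the optimum; each is `NA` when the curve does not
#' cross zero on that side — shallow cold limbs often approach the axis
#' only asymptotically), and the thermal safety margin TSM = CTmax - Topt.
#'
#' @param params A [lactin2_params()], `lactin2_fit`, or length-4 numeric.
#' @param search_lo,search_hi Search window, degC; defaults
#'   \[-20, t_max + 30\].
#' @param grid_n Coarse grid size (default 2000).
#'
#' @return A list of class `tpc_traits`: `t_opt`, `r_at_opt`, `ct_max`,
#'   `ct_min`, `tsm`, `degenerate` (TRUE when the rate at the optimum is
#'   not positive), and the search window used.
#' @examples
#' p <- lactin2_params(0.0523, -0.753, 23.5, 3.34)
#' tpc_traits(p)
#' @export
tpc_traits <- function(params, search_lo = -20, search_hi = NULL,
                       grid_n = 2000) {
  params <- as_lactin2_params(params)
  if (is.null(search_hi)) search_hi <- params$t_max + 30
  f <- function(T) lactin2_rate(params, T)
  extract_traits(f, search_lo, search_hi, grid_n)
}

# Grid-then-refine trait extraction for an arbitrary performance function:
# coarse argmax + local optimize for the optimum, sign-change bracketing +
# uniroot for the critical limits on either side of it.
extract_traits <- function(f, search_lo, search_hi, grid_n = 2000) {
  if (search_lo >= search_hi) stop("`search_lo` must be below `search_hi`",
                                   call. = FALSE)
  grid <- seq(search_lo, search_hi, length.out = grid_n)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  t_opt <- opt$maximum
  r_at_opt <- opt$objective
  degenerate <- r_at_opt <= 0
  bracket_root <- function(a, b) {
    g <- seq(a, b, length.out = max(64L, ceiling(grid_n / 4)))
    v <- f(g)
    s <- which(v[-1] * v[-length(v)] <= 0 & is.finite(v[-1]))
    if (length(s) == 0L) return(NA_real_)
    s <- s[1]
    stats::uniroot(f, c(g[s], g[s + 1]), tol = 1e-9)$root
  }
  ct_max <- if (degenerate) NA_real_ else bracket_root(t_opt, search_hi)
  ct_min <- if (degenerate) NA_real_ else {
    # search downward from the optimum so the first crossing below it wins
    g <- seq(t_opt, search_lo, length.out = max(64L, ceiling(grid_n / 4)))
    v <- f(g)
    s <- which(v[-1] * v[-length(v)] <= 0 & is.finite(v[-1]))
    if (length(s) == 0L) NA_real_ else {
      s <- s[1]
      stats::uniroot(f, sort(c(g[s], g[s + 1])), tol = 1e-9)$root
    }
  }
  structure(list(
    t_opt = t_opt, r_at_opt = r_at_opt,
    ct_max = ct_max, ct_min = ct_min,
    tsm = if (is.na(ct_max)) NA_real_ else tsm(t_opt, ct_max),
    degenerate = degenerate,
    search_lo = search_lo, search_hi = search_hi
  ), class = "tpc_traits")
}

#' @export
print.tpc_traits <- function(x, ...) {
  cat(sprintf("Thermal traits: Topt = %.2f degC (rate %.3f d^-1), CTmax = %s, CTmin = %s, TSM = %s\n",
              x$t_opt, x$r_at_opt,
              if (is.na(x$ct_max)) "undefined" else sprintf("%.2f degC", x$ct_max),
              if (is.na(x$ct_min)) "undefined" else sprintf("%.2f degC", x$ct_min),
              if (is.na(x$tsm)) "undefined" else sprintf("%.2f degC", x$tsm)))
  if (x$degenerate) cat("  (degenerate: rate at optimum is not positive)\n")
  invisible(x)
}

#' Thermal safety margin
#'
#' TSM = CTmax - Topt: how far above its optimum an organism can warm
#' before performance collapses to zero. Small margins flag vulnerability
#' to warming.
#'
#' @param t_opt Temperature optimum, degC.
#' @param ct_max Upper critical temperature, degC.
#'
#' @return The margin, degC.
#' @examples
#' tsm(17.3, 21.9)  # 4.6
#' @export
tsm <- function(t_opt, ct_max) {
  stopifnot(is.finite(t_opt), is.finite(ct_max))
  ct_max - t_opt
}
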