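#' Carbon conversion settings for bacterial prey
#'
#' Bundles the per-cell biovolumes of the two bacterial morphotypes and the
#' volume-to-carbon conversion factor used when expressing prey as carbon
#' biomass. Defaults are the measured cell volumes of the heat-killed
#' *Listonella pelagia* prey (cocci 0.14 um^3, rods 1.25 um^3) and the
#' conventional 200 fg C um^-3 factor.
#'
#' @param volume_cocci Cell volume of cocci, um^3.
#' @param volume_rods Cell volume of rods, um^3.
#' @param carbon_factor Carbon content per unit biovolume, fg C um^-3.
#'
#' @return A list of class `carbon_spec` with the three components.
#' @examples
#' carbon_spec()
#' carbon_spec(volume_rods = 1.1)
#' @export
carbon_spec <- function(volume_cocci = 0.14, volume_rods = 1.25,
                        carbon_factor = 200) {
  for (nm in c("volume_cocci", "volume_rods", "carbon_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  structure(list(volume_cocci = volume_cocci, volume_rods = volume_rods,
                 carbon_factor = carbon_factor),
            class = "carbon_spec")
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", field, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

#' Specific growth rate from paired counts
#'
#' Exponential growth rate r = ln(Nt / N0) / t from initial and final
#' abundances over an incubation of length `t` days.
#'
#' @param N0 Initial abundance (cells mL^-1); must be positive.
#' @param Nt Final abundance (cells mL^-1); must be positive.
#' @param t Incubation duration in days; must be positive.
#'
#' @return Specific growth rate, d^-1. Vectorised over all arguments.
#' @examples
#' growth_rate(20, 40, 1)   # ln 2
#' growth_rate(50, 30, 1)   # negative: population declined
#' @export
growth_rate <- function(N0, Nt, t) {
  check_positive(N0, "N0")
  check_positive(Nt, "Nt")
  check_positive(t, "t")
  log(Nt / N0) / t
}

#' Project a population forward under exponential growth
#'
#' Nt = N0 * exp(r * t), the inverse of [growth_rate()]. Abundance units are
#' whatever `N0` carries (per mL or per L).
#'
#' @param N0 Initial abundance (>= 0).
#' @param r Specific growth rate, d^-1 (may be negative).
#' @param t Time in days (>= 0).
#'
#' @return Projected abundance in the units of `N0`.
#' @examples
#' project_population(1000, -0.43, 14)  # starvation decline over two weeks
#' @export
project_population <- function(N0, r, t) {
  if (!is.numeric(N0) || any(!is.finite(N0)) || any(N0 < 0)) {
    stop("`N0` must be non-negative and finite", call. = FALSE)
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative and finite", call. = FALSE)
  }
  N0 * exp(r * t)
}

#' Depletion-averaged (geometric mean) prey concentration
#'
#' Mean food level over an incubation during which prey declined or grew
#' exponentially from `P0` to `Pt`. The default `"corrected"` mode is the
#' standard depletion average (Pt - P0) / ln(Pt / P0), which is dimensionally
#' consistent, symmetric in growth and decline, and tends to `P0` as
#' `Pt -> P0`. The `"literal"` mode evaluates (Pt - P0) / ln(Pt - P0), an
#' alternative printed form kept for transparency; it is only defined for
#' Pt - P0 > 0 and Pt - P0 != 1 and is not recommended.
#'
#' @param P0 Initial prey concentration (cells mL^-1), positive.
#' @param Pt Final prey concentration (cells mL^-1), positive.
#' @param mode `"corrected"` (default) or `"literal"`.
#'
#' @return Mean prey concentration in the units of `P0`.
#' @examples
#' mean_prey(1e6, 2e6)            # 1e6 / ln 2
#' mean_prey(1e6, 1e6)            # equal endpoints: returns P0
#' @export
mean_prey <- function(P0, Pt, mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  check_positive(P0, "P0")
  check_positive(Pt, "Pt")
  if (mode == "corrected") {
    lr <- log(Pt / P0)
    out <- ifelse(abs(lr) < 1e-12, P0, (Pt - P0) / lr)
    return(out)
  }
  d <- Pt - P0
  if (any(d <= 0)) {
    stop("literal mode requires Pt > P0", call. = FALSE)
  }
  if (any(d == 1)) {
    stop("literal mode undefined for Pt - P0 = 1 (log of 1)", call. = FALSE)
  }
  d / log(d)
}

#' Convert bacterial abundance to carbon biomass
#'
#' Converts a cell concentration to carbon biomass given the morphotype
#' split between cocci and rods. Internally fg C mL^-1, reported as
#' mg C L^-1 (factor 1e-12 mg/fg times 1e3 mL/L).
#'
#' @param abundance Bacterial abundance, cells mL^-1 (>= 0).
#' @param frac_cocci Fraction of cells that are cocci, in \[0, 1\]; the
#'   remainder are rods.
#' @param spec A [carbon_spec()].
#'
#' @return Carbon biomass, mg C L^-1. Vectorised over `abundance` and
#'   `frac_cocci`.
#' @examples
#' abundance_to_carbon(1e6, 1.0)  # all cocci: 0.028 mg C / L
#' abundance_to_carbon(1e6, 0.0)  # all rods:  0.25  mg C / L
#' @export
abundance_to_carbon <- function(abundance, frac_cocci, spec = carbon_spec()) {
  if (!is.numeric(abundance) || any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("`abundance` must be non-negative and finite", call. = FALSE)
  }
  if (!is.numeric(frac_cocci) || any(!is.finite(frac_cocci)) ||
      any(frac_cocci < 0) || any(frac_cocci > 1)) {
    stop("`frac_cocci` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(spec, "carbon_spec"))
  mean_volume <- frac_cocci * spec$volume_cocci +
    (1 - frac_cocci) * spec$volume_rods
  fg_per_ml <- abundance * mean_volume * spec$carbon_factor
  fg_per_ml * 1e-12 * 1e3
}

#' @export
print.carbon_spec <- function(x, ...) {
  cat("Carbon conversion:",
      sprintf("cocci %.3g um^3, rods %.3g um^3, %.4g fg C/um^3\n",
              x$volume_cocci, x$volume_rods, x$carbon_factor))
  invisible(x)
}
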