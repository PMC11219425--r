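#' Configuration of a synthetic microcosm campaign
#'
#' Describes a full numerical-response campaign the way the reference
#' design ran it: a set of temperature treatments, each with `wells_per_temperature`
#' 10-mL wells at food levels spread across `prey_range` with denser
#' coverage at low food (no replicates — each food level is a single
#' experiment), initial ciliate inocula drawn from `initial_ciliates`,
#' and 24-h incubations. Each treatment carries its own true
#' numerical-response parameter triple; defaults are the abundance-based
#' reference fits (in cells mL^-1), so the synthetic world is shaped like
#' the study.
#'
#' @param temperatures Treatment temperatures, degC.
#' @param wells_per_temperature Wells per treatment (default 24).
#' @param prey_range Range of initial prey levels, cells mL^-1
#'   (default 0.1e6 to 10e6).
#' @param low_food_bias Exponent (> 0) of the biased log-spacing: prey is
#'   placed at `lo * (hi/lo)^(u^low_food_bias)` for uniform `u`; values
#'   above 1 concentrate wells at low food. Default 1.5.
#' @param initial_ciliates Range of initial ciliate abundance, cells mL^-1
#'   (default 20 to 40).
#' @param duration Incubation length, days (default 1).
#' @param true_nr_params Named list, one [nr_params()] per temperature
#'   (names = temperature values). Defaults to the published abundance
#'   triples rescaled to cells mL^-1.
#' @param prey_decay_rate First-order prey decay, d^-1 (passive settling of
#'   the heat-killed food; default 0 = constant food).
#' @param count_noise `"poisson_subsample"` (default — counting error from
#'   fixed-volume subsamples), `"gaussian_rate"` (additive rate noise), or
#'   `"none"`.
#' @param noise_scale SD of the rate noise for `"gaussian_rate"`, d^-1
#'   (default 0.1).
#' @param subsample_volume Counted subsample volume for the Poisson model,
#'   mL (default 3).
#' @param frac_cocci Morphotype split of the prey (default 0.5).
#' @param seed Integer seed; the whole campaign is reproducible from it.
#'
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(temperatures = c(5, 10, 15, 19, 21),
                            wells_per_temperature = 24,
                            prey_range = c(0.1e6, 10e6),
                            low_food_bias = 1.5,
                            initial_ciliates = c(20, 40),
                            duration = 1,
                            true_nr_params = NULL,
                            prey_decay_rate = 0,
                            count_noise = c("poisson_subsample",
                                            "gaussian_rate", "none"),
                            noise_scale = 0.1,
                            subsample_volume = 3,
                            frac_cocci = 0.5,
                            seed = 1L) {
  count_noise <- match.arg(count_noise)
  stopifnot(length(prey_range) == 2L, all(prey_range > 0),
            prey_range[1] < prey_range[2],
            length(initial_ciliates) == 2L, all(initial_ciliates > 0),
            initial_ciliates[1] <= initial_ciliates[2],
            duration > 0, low_food_bias > 0,
            wells_per_temperature >= 1, prey_decay_rate >= 0,
            noise_scale >= 0, subsample_volume > 0,
            frac_cocci >= 0, frac_cocci <= 1)
  if (is.null(true_nr_params)) {
    tab <- colpidium_nr_params()
    tab <- tab[tab$prey_kind == "abundance" &
                 tab$temperature %in% temperatures, ]
    true_nr_params <- stats::setNames(
      lapply(seq_len(nrow(tab)), function(i) {
        nr_params(tab$r_max[i], tab$p_prime[i] * 1e6, tab$k[i] * 1e6)
      }),
      as.character(tab$temperature))
  }
  if (!all(as.character(temperatures) %in% names(true_nr_params))) {
    stop("`true_nr_params` must name every temperature", call. = FALSE)
  }
  structure(list(
    temperatures = temperatures,
    wells_per_temperature = as.integer(wells_per_temperature),
    prey_range = prey_range, low_food_bias = low_food_bias,
    initial_ciliates = initial_ciliates, duration = duration,
    true_nr_params = lapply(true_nr_params, as_nr_params),
    prey_decay_rate = prey_decay_rate,
    count_noise = count_noise, noise_scale = noise_scale,
    subsample_volume = subsample_volume,
    frac_cocci = frac_cocci,
    seed = as.integer(seed)
  ), class = "campaign_config")
}

#' Simulate one well-level campaign
#'
#' For every well: the initial prey level comes from the biased
#' log-spacing; prey decays passively at `prey_decay_rate`; the true growth
#' rate is the numerical response evaluated at the depletion-averaged prey
#' level; the final ciliate count is the exponential projection. Observation
#' noise is then applied — `"poisson_subsample"` draws the counted cells in
#' a `subsample_volume` aliquot as Poisson and divides back (ciliate counts
#' only: prey counts come from cytometry of millions of cells, where
#' counting error is negligible); `"gaussian_rate"` perturbs the true rate
#' before projection. Identical seed, identical campaign.
#'
#' @param config A [campaign_config()].
#'
#' @return A tibble of well records: `well_id`, `temperature_C`,
#'   `duration_d`, `ciliate_N0_per_mL`, `ciliate_Nt_per_mL`,
#'   `prey_P0_per_mL`, `prey_Pt_per_mL`, `frac_cocci`, plus the latent
#'   `true_r` (kept for recovery studies; readers ignore it).
#' @examples
#' wells <- generate_campaign(campaign_config(temperatures = 15, seed = 7))
#' head(wells)
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  withr::with_seed(config$seed, {
    out <- lapply(config$temperatures, function(temp) {
      n <- config$wells_per_temperature
      theta <- config$true_nr_params[[as.character(temp)]]
      lo <- config$prey_range[1]; hi <- config$prey_range[2]
      u <- stats::runif(n)
      P0 <- lo * (hi / lo)^(u^config$low_food_bias)
      Pt <- P0 * exp(-config$prey_decay_rate * config$duration)
      P_bar <- mean_prey(P0, Pt)
      N0 <- stats::runif(n, config$initial_ciliates[1],
                         config$initial_ciliates[2])
      true_r <- nr_predict(theta, P_bar)
      r_eff <- true_r
      if (config$count_noise == "gaussian_rate") {
        r_eff <- true_r + stats::rnorm(n, 0, config$noise_scale)
      }
      Nt <- N0 * exp(r_eff * config$duration)
      N0_obs <- N0
      Nt_obs <- Nt
      if (config$count_noise == "poisson_subsample") {
        v <- config$subsample_volume
        N0_obs <- stats::rpois(n, N0 * v) / v
        Nt_obs <- stats::rpois(n, Nt * v) / v
      }
      tibble::tibble(
        well_id = sprintf("T%g_w%02d", temp, seq_len(n)),
        temperature_C = temp,
        duration_d = config$duration,
        ciliate_N0_per_mL = N0_obs,
        ciliate_Nt_per_mL = Nt_obs,
        prey_P0_per_mL = P0,
        prey_Pt_per_mL = Pt,
        frac_cocci = config$frac_cocci,
        true_r = true_r
      )
    })
    do.call(rbind, out)
  })
}

#' Truth-versus-fit recovery experiment
#'
#' Repeats generate-then-fit over `n_campaigns` independent campaigns and
#' reports, per temperature and parameter, the truth, mean estimate, bias,
#' empirical SE of the estimates, and the empirical coverage of the
#' Monte-Carlo mortality interval at its nominal level. Campaigns whose fit
#' fails or does not converge are counted, not fatal.
#'
#' @param config A [campaign_config()]; campaign `i` uses seed
#'   `config$seed + i`.
#' @param n_campaigns Number of replicate campaigns (>= 1).
#' @param level Nominal level of the mortality interval (default 0.95).
#' @param n_draws Draws per interval (default 1e4; see
#'   [delta_max_interval()]).
#'
#' @return A list of class `recovery_report`: `summary` (tibble with one
#'   row per temperature x parameter), `delta_max_coverage` (tibble per
#'   temperature), `n_campaigns`, `n_failed`.
#' @export
recovery_experiment <- function(config, n_campaigns, level = 0.95,
                                n_draws = 1e4) {
  stopifnot(inherits(config, "campaign_config"), n_campaigns >= 1)
  temps <- config$temperatures
  est <- array(NA_real_, dim = c(n_campaigns, length(temps), 3),
               dimnames = list(NULL, as.character(temps),
                               c("r_max", "p_prime", "k")))
  covered <- matrix(NA, n_campaigns, length(temps),
                    dimnames = list(NULL, as.character(temps)))
  n_failed <- 0L
  for (i in seq_len(n_campaigns)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    wells <- generate_campaign(cfg_i)
    for (j in seq_along(temps)) {
      w <- wells[wells$temperature_C == temps[j] &
                   wells$ciliate_N0_per_mL > 0 &
                   wells$ciliate_Nt_per_mL > 0, ]
      pts <- rate_points(
        temps[j], w$prey_P0_per_mL,
        growth_rate(w$ciliate_N0_per_mL, w$ciliate_Nt_per_mL, w$duration_d))
      fit <- tryCatch(
        fit_nr(pts, n_draws = n_draws, seed = cfg_i$seed + 1000L),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      est[i, j, ] <- coef(fit)
      ci <- fit$delta_max_interval
      if (!is.null(ci)) {
        d_true <- delta_max(config$true_nr_params[[as.character(temps[j])]])
        covered[i, j] <- d_true >= ci$lower & d_true <= ci$upper
      }
    }
  }
  rows <- list()
  for (j in seq_along(temps)) {
    theta <- config$true_nr_params[[as.character(temps[j])]]
    truth <- c(r_max = theta$r_max, p_prime = theta$p_prime, k = theta$k)
    for (p in c("r_max", "p_prime", "k")) {
      e <- est[, j, p]
      truth_p <- truth[[p]]
      mean_p <- mean(e, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        temperature = temps[j], parameter = p, truth = truth_p,
        mean_estimate = mean_p,
        bias = mean_p - truth_p,
        empirical_se = stats::sd(e, na.rm = TRUE),
        n_fits = sum(!is.na(e)))
    }
  }
  cov_tab <- tibble::tibble(
    temperature = temps,
    nominal = level,
    coverage = vapply(seq_along(temps),
                      function(j) mean(covered[, j], na.rm = TRUE), 0),
    n_intervals = vapply(seq_along(temps),
                         function(j) sum(!is.na(covered[, j])), 0L))
  structure(list(summary = do.call(rbind, rows),
                 delta_max_coverage = cov_tab,
                 n_campaigns = n_campaigns, n_failed = n_failed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d campaigns (%d failed fits)\n",
              x$n_campaigns, x$n_failed))
  print(x$summary)
  cat("delta_max interval coverage:\n")
  print(x$delta_max_coverage)
  invisible(x)
}
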