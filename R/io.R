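#' Analysis configuration for the well-table pipeline
#'
#' Collects every knob of [run_pipeline()] in one validated object so a run
#' is fully determined by (wells, config): which prey metric(s) to fit,
#' how the mean prey level is computed, the carbon conversion, how the
#' thermal performance curve gets its input points, which mortality records
#' are excluded as outliers, and the Monte-Carlo interval settings.
#'
#' @param prey_metric `"abundance"`, `"biomass"`, or `"both"` (default).
#' @param mean_prey_mode Passed to [mean_prey()] (default `"corrected"`).
#' @param carbon A [carbon_spec()].
#' @param tpc_input `"fitted_rmax"` (default: fit the TPC to the per-
#'   temperature fitted r_max values) or `"satiating"` (fit it to the
#'   measured rates at the `tpc_satiating_n` highest food levels).
#' @param tpc_satiating_n Number of top food levels for the `"satiating"`
#'   rule (3-5, default 5).
#' @param tpc_exclude_temperatures Temperatures dropped from the TPC input
#'   (e.g. treatments that never reached satiating food). Default none.
#' @param delta_max_exclusions Data frame with columns `temperature`,
#'   `prey_kind`, `reason`: mortality records flagged as outliers before
#'   the temperature regression. Default none.
#' @param interval_level,interval_draws Settings of the mortality interval.
#' @param scenarios Optional list of grazing scenarios, each a list with
#'   `grazer_abundance` (ind L^-1) and `clearance_rate` (mL ind^-1 d^-1).
#' @param seed Integer seed used for every stochastic stage.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(prey_metric = c("both", "abundance", "biomass"),
                            mean_prey_mode = c("corrected", "literal"),
                            carbon = carbon_spec(),
                            tpc_input = c("fitted_rmax", "satiating"),
                            tpc_satiating_n = 5,
                            tpc_exclude_temperatures = numeric(),
                            delta_max_exclusions = NULL,
                            interval_level = 0.95,
                            interval_draws = 1e5,
                            scenarios = list(),
                            seed = 1L) {
  prey_metric <- match.arg(prey_metric)
  mean_prey_mode <- match.arg(mean_prey_mode)
  tpc_input <- match.arg(tpc_input)
  stopifnot(inherits(carbon, "carbon_spec"),
            interval_level > 0, interval_level < 1, interval_draws >= 100)
  if (!is.null(delta_max_exclusions)) {
    stopifnot(is.data.frame(delta_max_exclusions),
              all(c("temperature", "prey_kind", "reason") %in%
                    names(delta_max_exclusions)))
  }
  structure(list(
    prey_metric = prey_metric, mean_prey_mode = mean_prey_mode,
    carbon = carbon, tpc_input = tpc_input,
    tpc_satiating_n = tpc_satiating_n,
    tpc_exclude_temperatures = tpc_exclude_temperatures,
    delta_max_exclusions = delta_max_exclusions,
    interval_level = interval_level, interval_draws = interval_draws,
    scenarios = scenarios, seed = as.integer(seed)
  ), class = "analysis_config")
}

well_required_cols <- c("temperature_C", "duration_d", "ciliate_N0_per_mL",
                        "ciliate_Nt_per_mL", "prey_P0_per_mL",
                        "prey_Pt_per_mL")

#' Read a well-record table
#'
#' Delimited text with one row per experimental well. Comma and tab
#' delimiters are auto-detected (or forced via `delim`); CRLF and LF line
#' endings parse identically. Required columns: `temperature_C`,
#' `duration_d`, `ciliate_N0_per_mL`, `ciliate_Nt_per_mL`,
#' `prey_P0_per_mL`, `prey_Pt_per_mL`; `frac_cocci` and `well_id` are
#' optional (`frac_cocci` defaults to 0.5 with a message, since the
#' morphotype split is needed for carbon conversion).
#'
#' @param path File path.
#' @param delim `NULL` (auto), `","` or `"\t"`.
#'
#' @return A tibble of validated well records.
#' @export
read_wells <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(well_required_cols, names(df))
  if (length(missing) > 0L) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"frac_cocci" %in% names(df)) {
    message("no `frac_cocci` column; assuming an even cocci/rod split (0.5)")
    df$frac_cocci <- 0.5
  }
  if (!"well_id" %in% names(df)) {
    df$well_id <- sprintf("row%03d", seq_len(nrow(df)))
  }
  validate_wells(df)
  tibble::as_tibble(df)
}

validate_wells <- function(df) {
  problems <- character()
  note <- function(rows, what) {
    if (any(rows)) {
      problems <<- c(problems, paste0("row ", which(rows), ": ", what))
    }
  }
  note(!is.finite(df$duration_d) | df$duration_d <= 0,
       "duration_d must be > 0")
  for (col in c("ciliate_N0_per_mL", "ciliate_Nt_per_mL",
                "prey_P0_per_mL", "prey_Pt_per_mL")) {
    note(!is.finite(df[[col]]) | df[[col]] < 0,
         paste0(col, " must be >= 0"))
  }
  note(!is.finite(df$frac_cocci) | df$frac_cocci < 0 | df$frac_cocci > 1,
       "frac_cocci must lie in [0, 1]")
  if (length(problems) > 0L) {
    stop("invalid well records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(df)
}

#' Write a well-record table
#'
#' @param wells A well-record data frame (see [read_wells()] for columns).
#' @param path Output path.
#' @param delim `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path, delim = ",") {
  keep <- intersect(c("well_id", well_required_cols, "frac_cocci"),
                    names(wells))
  utils::write.table(wells[, keep], path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

wells_to_rate_points <- function(wells, metric, config) {
  ok <- wells$ciliate_N0_per_mL > 0 & wells$ciliate_Nt_per_mL > 0
  if (any(!ok)) {
    warning(sum(!ok), " well(s) with zero ciliate counts dropped ",
            "(growth rate undefined)", call. = FALSE)
    wells <- wells[ok, , drop = FALSE]
  }
  r <- growth_rate(wells$ciliate_N0_per_mL, wells$ciliate_Nt_per_mL,
                   wells$duration_d)
  prey <- if (metric == "abundance") {
    wells$prey_P0_per_mL / 1e6  # fit in units of 1e6 cells / mL
  } else {
    p_bar <- mean_prey(wells$prey_P0_per_mL, wells$prey_Pt_per_mL,
                       mode = config$mean_prey_mode)
    abundance_to_carbon(p_bar, wells$frac_cocci, config$carbon)
  }
  rate_points(wells$temperature_C, prey, r, prey_kind = metric)
}

#' Run the full numerical-and-thermal-response pipeline
#'
#' Growth rates per well, a threshold numerical-response fit per
#' temperature and prey metric, the derived maximum-mortality table with
#' configured exclusions, a Lactin-2 thermal performance fit with trait
#' extraction (skipped with a warning when fewer than four distinct
#' temperatures are available), the mortality-temperature regression
#' (skipped below three records), the paired r_max comparison when both
#' prey metrics are fitted, and any configured grazing scenarios.
#' Deterministic given `config$seed`.
#'
#' @param wells A validated well-record table ([read_wells()] or
#'   [generate_campaign()]).
#' @param config An [analysis_config()].
#'
#' @return A list of class `result_bundle` with elements `nr_fits`
#'   (list per metric, then per temperature), `nr_summary` (flat tibble),
#'   `delta_max_records`, `mortality_trend`, `mortality_summary`,
#'   `tpc_fit`, `tpc_traits`, `rmax_comparison`, `scenarios`, `partial`,
#'   `warnings`, `provenance`.
#' @export
run_pipeline <- function(wells, config = analysis_config()) {
  stopifnot(is.data.frame(wells), inherits(config, "analysis_config"))
  validate_wells(as.data.frame(wells))
  metrics <- switch(config$prey_metric,
                    both = c("abundance", "biomass"),
                    config$prey_metric)
  notes <- character()
  partial <- FALSE

  nr_fits <- list()
  summaries <- list()
  for (metric in metrics) {
    pts_all <- wells_to_rate_points(wells, metric, config)
    fits <- list()
    for (temp in sort(unique(pts_all$temperature))) {
      pts <- pts_all[pts_all$temperature == temp, ]
      fit <- tryCatch(
        fit_nr(pts, level = config$interval_level,
               n_draws = config$interval_draws, seed = config$seed),
        error = function(e) e)
      if (inherits(fit, "error")) {
        notes <- c(notes, sprintf("NR fit failed (%s, %g degC): %s",
                                  metric, temp, conditionMessage(fit)))
        partial <- TRUE
        next
      }
      fits[[as.character(temp)]] <- fit
      ci <- fit$delta_max_interval
      summaries[[length(summaries) + 1L]] <- tibble::tibble(
        temperature = temp, prey_kind = metric,
        r_max = fit$params$r_max, r_max_se = fit$se[["r_max"]],
        r_max_p = fit$p_values[["r_max"]],
        p_prime = fit$params$p_prime, p_prime_se = fit$se[["p_prime"]],
        p_prime_p = fit$p_values[["p_prime"]],
        k = fit$params$k, k_se = fit$se[["k"]], k_p = fit$p_values[["k"]],
        delta_max = fit$delta_max,
        delta_max_lower = if (is.null(ci)) NA_real_ else ci$lower,
        delta_max_upper = if (is.null(ci)) NA_real_ else ci$upper,
        converged = fit$converged, n_points = fit$n_points)
    }
    nr_fits[[metric]] <- fits
  }
  nr_summary <- if (length(summaries)) do.call(rbind, summaries) else NULL

  delta_records <- NULL
  trend <- NULL
  mortality_summary <- NULL
  if (!is.null(nr_summary)) {
    excl <- rep(FALSE, nrow(nr_summary))
    reason <- rep("", nrow(nr_summary))
    ex_tab <- config$delta_max_exclusions
    if (!is.null(ex_tab)) {
      for (i in seq_len(nrow(ex_tab))) {
        hit <- nr_summary$temperature == ex_tab$temperature[i] &
          nr_summary$prey_kind == ex_tab$prey_kind[i]
        excl[hit] <- TRUE
        reason[hit] <- ex_tab$reason[i]
      }
    }
    delta_records <- mortality_records(
      nr_summary$temperature, nr_summary$delta_max,
      prey_kind = nr_summary$prey_kind, excluded = excl, reason = reason)
    trend <- tryCatch(
      mortality_trend(delta_records, ci_level = config$interval_level),
      error = function(e) {
        notes <<- c(notes, paste("mortality trend skipped:",
                                 conditionMessage(e)))
        partial <<- TRUE
        NULL
      })
    mortality_summary <- summarize_mortality(delta_records,
                                             sign_convention = "positive")
  }

  tpc_points <- NULL
  if (config$tpc_input == "fitted_rmax" && !is.null(nr_summary)) {
    keep <- !nr_summary$temperature %in% config$tpc_exclude_temperatures
    tpc_points <- tibble::tibble(temperature = nr_summary$temperature[keep],
                                 rate = nr_summary$r_max[keep])
  } else if (config$tpc_input == "satiating") {
    parts <- list()
    for (metric in metrics) {
      pts_all <- wells_to_rate_points(wells, metric, config)
      for (temp in sort(unique(pts_all$temperature))) {
        if (temp %in% config$tpc_exclude_temperatures) next
        pts <- pts_all[pts_all$temperature == temp, ]
        top <- satiating_subset(pts, min(config$tpc_satiating_n, nrow(pts)))
        parts[[length(parts) + 1L]] <-
          tibble::tibble(temperature = temp, rate = top$r)
      }
      break  # measured rates are metric-independent; one pass suffices
    }
    tpc_points <- do.call(rbind, parts)
  }
  tpc_fit <- NULL
  tpc_tr <- NULL
  if (is.null(tpc_points) || length(unique(tpc_points$temperature)) < 4L) {
    notes <- c(notes, "TPC skipped: fewer than 4 distinct temperatures")
    partial <- TRUE
  } else {
    tpc_fit <- tryCatch(fit_lactin2(tpc_points, seed = config$seed),
                        error = function(e) {
                          notes <<- c(notes, paste("TPC fit failed:",
                                                   conditionMessage(e)))
                          partial <<- TRUE
                          NULL
                        })
    if (!is.null(tpc_fit)) tpc_tr <- tpc_traits(tpc_fit)
  }

  rmax_comparison <- NULL
  if (length(metrics) == 2L &&
      length(nr_fits$abundance) >= 2L &&
      length(nr_fits$abundance) == length(nr_fits$biomass)) {
    rmax_comparison <- tryCatch(
      compare_rmax_paired(unname(nr_fits$abundance),
                          unname(nr_fits$biomass)),
      error = function(e) NULL)
  }

  scenario_results <- lapply(config$scenarios, function(s) {
    g <- community_grazing_rate(s$grazer_abundance, s$clearance_rate)
    list(grazer_abundance = s$grazer_abundance,
         clearance_rate = s$clearance_rate,
         community_grazing_rate = g)
  })

  structure(list(
    nr_fits = nr_fits,
    nr_summary = nr_summary,
    delta_max_records = delta_records,
    mortality_trend = trend,
    mortality_summary = mortality_summary,
    tpc_points = tpc_points,
    tpc_fit = tpc_fit,
    tpc_traits = tpc_tr,
    rmax_comparison = rmax_comparison,
    scenarios = scenario_results,
    partial = partial,
    warnings = notes,
    provenance = list(
      input_hash = rlang::hash(as.data.frame(wells)),
      config_hash = rlang::hash(config),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("protistNR")))
  ), class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Numerical/thermal response result bundle",
      if (x$partial) "(partial)" else "", "\n")
  if (!is.null(x$nr_summary)) {
    cat(sprintf("  %d NR fits over %d temperatures\n",
                nrow(x$nr_summary), length(unique(x$nr_summary$temperature))))
  }
  if (!is.null(x$mortality_trend)) print(x$mortality_trend)
  if (!is.null(x$tpc_traits)) print(x$tpc_traits)
  if (length(x$warnings)) cat("  notes:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Serialise a result bundle to JSON
#'
#' Fixed key order and explicit digits so identical inputs and seed give a
#' byte-identical file. Fit objects are reduced to their numeric summaries.
#'
#' @param bundle A `result_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  simplify <- list(
    nr_summary = bundle$nr_summary,
    delta_max_records = bundle$delta_max_records,
    mortality_trend = if (!is.null(bundle$mortality_trend)) {
      tr <- bundle$mortality_trend
      list(slope = tr$slope, intercept = tr$intercept,
           slope_se = tr$slope_se, t_stat = tr$t_stat,
           p_value = tr$p_value, df = tr$df, n_used = tr$n_used)
    },
    mortality_summary = bundle$mortality_summary,
    tpc = if (!is.null(bundle$tpc_fit)) {
      list(params = unclass(bundle$tpc_fit$params),
           rss = bundle$tpc_fit$rss,
           traits = unclass(bundle$tpc_traits)[
             c("t_opt", "r_at_opt", "ct_max", "ct_min", "tsm")])
    },
    rmax_comparison = if (!is.null(bundle$rmax_comparison)) {
      bundle$rmax_comparison[c("t_stat", "p_value", "df",
                               "mean_difference", "n")]
    },
    scenarios = bundle$scenarios,
    partial = bundle$partial,
    warnings = bundle$warnings,
    provenance = bundle$provenance)
  jsonlite::write_json(simplify, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reproduce the reference Colpidium kleini analysis
#'
#' Re-runs every desk-scale computation of the reference study from its
#' packaged published constants ([colpidium_nr_params()],
#' [colpidium_constants()]): the ten maximum mortality rates from the
#' printed parameter triples, the paired r_max comparison between the two
#' prey metrics, the mortality-temperature regression with the study's two
#' outlier exclusions plus its 8 degC prediction, the sign-flipped
#' mortality summaries, the Lactin-2 fit to the eight published r_max
#' values (10 degC excluded) with trait extraction, the thermal-safety-
#' margin identities, and the grazing arithmetic for the source lake.
#' Scenario projections use rates at the study's reported 2-dp precision,
#' matching its printed arithmetic chain.
#'
#' @param seed Seed for the multistart TPC fit.
#' @param n_starts Multistart count for the TPC fit.
#'
#' @return A list of class `reference_analysis`; see the elements in the
#'   examples.
#' @examples
#' \donttest{
#' ref <- reproduce_reference(seed = 1)
#' ref$mortality_trend$slope
#' ref$tpc2_traits$t_opt
#' }
#' @export
reproduce_reference <- function(seed = 1L, n_starts = 25) {
  tab <- colpidium_nr_params()
  consts <- colpidium_constants()

  tab$delta_max <- vapply(seq_len(nrow(tab)), function(i) {
    delta_max(nr_params(tab$r_max[i], tab$p_prime[i], tab$k[i]))
  }, 0)

  rmax_cmp <- compare_rmax_paired(
    tab[tab$prey_kind == "abundance", c("temperature", "r_max")],
    tab[tab$prey_kind == "biomass", c("temperature", "r_max")])

  records <- mortality_records(
    tab$temperature, tab$delta_max, prey_kind = tab$prey_kind,
    excluded = tab$delta_max_outlier,
    reason = ifelse(tab$delta_max_outlier,
                    "flagged as outlier in the reference analysis", ""))
  trend <- mortality_trend(records)
  t_habitat <- consts$habitat_temperature
  mortality_at_habitat <- predict_mortality(trend, t_habitat)
  summary_pos <- summarize_mortality(records, sign_convention = "positive")

  scen <- consts$starvation_scenario
  starvation <- list(
    temperature = t_habitat,
    rate = round(mortality_at_habitat, 2),
    n0_per_L = scen$n0_per_L, days = scen$days,
    projected_per_L = project_population(scen$n0_per_L,
                                         round(mortality_at_habitat, 2),
                                         scen$days))

  grazing <- list(
    community_rate = community_grazing_rate(
      consts$grazer_abundance_per_L,
      consts$clearance_ml_per_ind_day[["at_8C"]]),
    required_density = required_grazer_density(
      consts$satiating_rmax,
      consts$clearance_ml_per_ind_day[["at_15C"]]))

  tpc2_in <- tab[tab$temperature %in% consts$tpc2_temperatures,
                 c("temperature", "r_max")]
  names(tpc2_in)[2] <- "rate"
  tpc2_fit <- fit_lactin2(tpc2_in, n_starts = n_starts, seed = seed)
  tpc2_tr <- tpc_traits(tpc2_fit)

  tsm_identities <- list(
    tpc1 = tsm(consts$tpc1$t_opt, consts$tpc1$ct_max),
    tpc2 = tsm(consts$tpc2$t_opt, consts$tpc2$ct_max))

  structure(list(
    delta_max_table = tab[, c("temperature", "prey_kind", "delta_max",
                              "delta_max_printed", "delta_max_outlier")],
    rmax_comparison = rmax_cmp,
    mortality_records = records,
    mortality_trend = trend,
    mortality_at_habitat = mortality_at_habitat,
    mortality_summary = summary_pos,
    starvation = starvation,
    grazing = grazing,
    tpc2_fit = tpc2_fit,
    tpc2_traits = tpc2_tr,
    tsm_identities = tsm_identities,
    seed = seed
  ), class = "reference_analysis")
}

#' @export
print.reference_analysis <- function(x, ...) {
  cat("Reference C. kleini analysis, recomputed from published constants\n")
  cat(sprintf("  delta_max table: %d values, max |recomputed - printed| = %.3f\n",
              nrow(x$delta_max_table),
              max(abs(round(x$delta_max_table$delta_max, 2) -
                        x$delta_max_table$delta_max_printed))))
  print(x$mortality_trend)
  cat(sprintf("  mortality summary (positive): mean %.2f +/- %.2f, median %.2f\n",
              x$mortality_summary$mean, x$mortality_summary$sd,
              x$mortality_summary$median))
  cat(sprintf("  at %g degC: %.2f d^-1; %g cells/L -> %.1f cells/L after %g d\n",
              x$starvation$temperature, x$mortality_at_habitat,
              x$starvation$n0_per_L, x$starvation$projected_per_L,
              x$starvation$days))
  cat(sprintf("  grazing: community %.4f d^-1; required density %.1f ind/L\n",
              x$grazing$community_rate, x$grazing$required_density))
  print(x$tpc2_traits)
  cat(sprintf("  TSM identities: %.1f degC (TPC1), %.1f degC (TPC2)\n",
              x$tsm_identities$tpc1, x$tsm_identities$tpc2))
  invisible(x)
}
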