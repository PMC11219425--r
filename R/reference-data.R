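#' Published numerical-response parameters for Colpidium kleini
#'
#' The fitted threshold numerical-response parameters of the reference
#' *Colpidium kleini* growth study: one row per temperature treatment
#' (5, 10, 15, 19, 21 degC) and prey metric. Abundance-based fits are in
#' units of 1e6 bacterial cells mL^-1; biomass-based fits in mg C L^-1.
#' `delta_max_printed` is the study's reported maximum mortality rate
#' (2 dp) and `delta_max_outlier` marks the two values the study set aside
#' when regressing mortality on temperature (the 10 degC abundance fit,
#' whose treatment never reached satiating food, and the 15 degC biomass
#' fit).
#'
#' @return A tibble with columns `temperature`, `prey_kind`, `r_max`,
#'   `r_max_se`, `r_max_p`, `p_prime`, `p_prime_se`, `p_prime_p`, `k`,
#'   `k_se`, `k_p`, `delta_max_printed`, `delta_max_ci_printed`,
#'   `delta_max_outlier`.
#' @examples
#' tab <- colpidium_nr_params()
#' delta_max(nr_params(tab$r_max[5], tab$p_prime[5], tab$k[5]))
#' @export
colpidium_nr_params <- function() {
  tibble::tibble(
    temperature = rep(c(5, 10, 15, 19, 21), 2),
    prey_kind = rep(c("abundance", "biomass"), each = 5),
    r_max   = c(0.5487, 0.5091, 1.2145, 1.0970, 0.6057,
                0.5164, 0.8174, 1.1254, 1.0223, 0.6536),
    r_max_se = c(0.1355, 0.2741, 0.4366, 0.1765, 0.1829,
                 0.1243, 0.8573, 0.2657, 0.1375, 0.1931),
    r_max_p = c(0.0006, 0.0788, 0.0119, 1e-04, 0.0037,
                0.0005, 0.3523, 0.0004, 1e-04, 0.0031),
    p_prime = c(0.3307, 2.2253, 1.0517, 0.4782, 1.3392,
                0.0674, 0.4273, 0.0498, 0.0487, 0.1927),
    p_prime_se = c(0.1392, 0.4045, 0.5382, 0.1309, 0.2335,
                   0.0293, 0.0959, 0.0502, 0.0089, 0.0275),
    p_prime_p = c(0.0276, 1e-04, 0.0656, 0.0018, 1e-04,
                  0.0320, 0.0003, 0.3340, 1e-04, 1e-04),
    k       = c(0.8712, 2.9493, 3.3707, 1.6911, 2.6633,
                0.1583, 1.1180, 0.6900, 0.1094, 0.3568),
    k_se    = c(0.7080, 1.8471, 3.5695, 0.7900, 1.4792,
                0.1450, 1.1314, 0.4558, 0.0503, 0.1792),
    k_p     = c(0.2328, 0.1268, 0.3569, 0.0462, 0.0877,
                0.2877, 0.3355, 0.1465, 0.0432, 0.0611),
    delta_max_printed = c(-0.34, -1.56, -0.55, -0.43, -0.61,
                          -0.38, -0.51, -0.09, -0.82, -0.77),
    delta_max_ci_printed = c(-1.08, -6.49, -2.73, -1.13, -1.50,
                             -1.62, -1.02, -0.35, -2.43, -1.92),
    delta_max_outlier = c(FALSE, TRUE, FALSE, FALSE, FALSE,
                          FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

#' Ancillary constants of the reference Colpidium kleini study
#'
#' Published quantities used by [reproduce_reference()] and the worked
#' ecological scenarios: the thermal traits of the two reported thermal
#' performance curves (TPC1 fitted to measured near-satiating growth rates
#' — not re-fittable here because those raw points were never tabulated —
#' and TPC2 fitted to the r_max estimates of [colpidium_nr_params()]),
#' copepod clearance rates, the grazer density and habitat temperature of
#' the source lake, and the starvation-projection scenario.
#'
#' @return A nested list; see examples.
#' @examples
#' colpidium_constants()$tpc2
#' @export
colpidium_constants <- function() {
  list(
    tpc1 = list(t_opt = 17.3, ct_max = 21.9, r_max = 0.97),
    tpc2 = list(t_opt = 16.4, ct_max = 22.4, r_max = 1.20),
    tpc2_temperatures = c(5, 15, 19, 21),  # 10 degC discarded: food never satiating
    clearance_ml_per_ind_day = c(at_15C = 37, at_8C = 18),
    grazer_abundance_per_L = 0.3,
    habitat_temperature = 8,
    starvation_scenario = list(n0_per_L = 1000, days = 14),
    satiating_rmax = 1.0  # r_max near 1 d^-1 at 15 degC, food levels tested
  )
}
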