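# Shared fixtures built in code.

# Published NR parameter table split by prey metric.
table_abund <- function() {
  tab <- colpidium_nr_params()
  tab[tab$prey_kind == "abundance", ]
}
table_biom <- function() {
  tab <- colpidium_nr_params()
  tab[tab$prey_kind == "biomass", ]
}

# Exact rate points on a known threshold NR curve.
exact_nr_points <- function(theta = nr_params(1.0, 1.5, 0.5),
                            prey = c(0.2, 0.6, 1.2, 2, 3.5, 5, 7, 10),
                            temperature = 15) {
  rate_points(temperature, prey, nr_predict(theta, prey))
}

# Exact rate points on a known Lactin-2 curve.
exact_tpc_points <- function(params = lactin2_params(0.05, -0.7, 23, 3),
                             temps = c(5, 10, 15, 18, 20, 21)) {
  data.frame(temperature = temps, rate = lactin2_rate(params, temps))
}

# Minimal nr_fit shell for interval tests with a hand-set covariance.
fake_nr_fit <- function(theta, se, n = 24) {
  params <- nr_params(theta[1], theta[2], theta[3])
  structure(list(
    params = params,
    se = stats::setNames(se, c("r_max", "p_prime", "k")),
    covariance = diag(se^2),
    delta_max = delta_max(params),
    n_points = n, converged = TRUE, df = n - 3L,
    rss = NA_real_, sigma2 = NA_real_
  ), class = "nr_fit")
}
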