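test_that("campaigns are reproducible from their seed", {
  cfg <- campaign_config(seed = 123)
  w1 <- generate_campaign(cfg)
  w2 <- generate_campaign(cfg)
  expect_identical(w1, w2)
  w3 <- generate_campaign(campaign_config(seed = 124))
  expect_false(identical(w1, w3))
  expect_equal(nrow(w1), 5 * 24)
})

test_that("low-food bias places the median prey level below the midpoint", {
  cfg <- campaign_config(temperatures = 15, wells_per_temperature = 200,
                         seed = 5)
  wells <- generate_campaign(cfg)
  expect_lt(median(wells$prey_P0_per_mL), mean(cfg$prey_range))
  expect_true(all(wells$prey_P0_per_mL >= cfg$prey_range[1]))
  expect_true(all(wells$prey_P0_per_mL <= cfg$prey_range[2]))
})

test_that("a noiseless campaign round-trips the truth at every temperature", {
  cfg <- campaign_config(count_noise = "none", seed = 42)
  wells <- generate_campaign(cfg)
  for (temp in cfg$temperatures) {
    w <- wells[wells$temperature_C == temp, ]
    pts <- rate_points(temp, w$prey_P0_per_mL,
                       growth_rate(w$ciliate_N0_per_mL, w$ciliate_Nt_per_mL,
                                   w$duration_d))
    fit <- fit_nr(pts, n_draws = 100)
    truth <- cfg$true_nr_params[[as.character(temp)]]
    expect_equal(coef(fit),
                 c(r_max = truth$r_max, p_prime = truth$p_prime,
                   k = truth$k),
                 tolerance = 1e-4)
  }
})

test_that("cold low-food wells grow at the rates seen in the source habitat", {
  # 5 degC treatment restricted to in-situ bacterial levels; the fitted
  # response spans 0.19-0.26 d^-1 there, overlapping the measured 0.18-0.24
  cfg <- campaign_config(temperatures = 5, count_noise = "none",
                         prey_range = c(0.8e6, 1.1e6), seed = 9)
  wells <- generate_campaign(cfg)
  expect_true(all(wells$true_r > 0.18))
  expect_true(all(wells$true_r < 0.26))
  expect_true(any(wells$true_r >= 0.18 & wells$true_r <= 0.24))
})

test_that("noiseless recovery has zero bias; Poisson counting error is larger at low food", {
  cfg <- campaign_config(temperatures = 15, count_noise = "none", seed = 31)
  rep0 <- recovery_experiment(cfg, n_campaigns = 3, n_draws = 200)
  expect_equal(rep0$n_failed, 0)
  expect_true(all(abs(rep0$summary$bias / rep0$summary$truth) < 1e-5))
  # Poisson subsampling: relative rate error shrinks as survivors increase
  cfg_p <- campaign_config(temperatures = 15, count_noise = "poisson_subsample",
                           seed = 7, wells_per_temperature = 60)
  errs_lo <- errs_hi <- numeric()
  for (i in 1:30) {
    cfg_i <- cfg_p
    cfg_i$seed <- cfg_p$seed + i
    w <- generate_campaign(cfg_i)
    ok <- w$ciliate_N0_per_mL > 0 & w$ciliate_Nt_per_mL > 0
    w <- w[ok, ]
    r_obs <- growth_rate(w$ciliate_N0_per_mL, w$ciliate_Nt_per_mL,
                         w$duration_d)
    err <- r_obs - w$true_r
    lo <- w$prey_P0_per_mL < 1e6
    errs_lo <- c(errs_lo, err[lo])
    errs_hi <- c(errs_hi, err[!lo])
  }
  expect_gt(sd(errs_lo), sd(errs_hi))
})
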