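test_that("nr_predict has the threshold, asymptote and pole the model implies", {
  p <- nr_params(0.6057, 1.3392, 2.6633)
  expect_equal(nr_predict(p, p$p_prime), 0)
  expect_equal(nr_predict(p, 1e12), p$r_max, tolerance = 1e-9)
  p5 <- nr_params(0.5487, 0.3307, 0.8712)
  expect_equal(nr_predict(p5, 1.2019),
               0.5487 * (1.2019 - 0.3307) / (0.8712 + (1.2019 - 0.3307)))
  expect_error(nr_predict(nr_params(1, 2, 1), 1), "pole")
  # strictly increasing beyond the pole when r_max > 0
  P <- seq(p$p_prime - p$k + 0.01, 20, length.out = 200)
  expect_true(all(diff(nr_predict(p, P)) > 0))
})

test_that("delta_max equals the zero-food prediction and has the right sign", {
  set.seed(11)
  for (i in 1:100) {
    rmax <- runif(1, 0.1, 3)
    pp <- runif(1, 0, 2)
    k <- pp + runif(1, 0.05, 3)  # k > p_prime keeps zero food off the pole
    th <- nr_params(rmax, pp, k)
    expect_equal(delta_max(th), nr_predict(th, 0))
    if (pp > 0) expect_lt(delta_max(th), 0)
  }
  expect_equal(delta_max(nr_params(1.7, 0, 1)), 0)
  expect_error(delta_max(nr_params(1, 1, 1)), "pole")
})

test_that("all published delta_max cells are reproduced at printed rounding", {
  tab <- colpidium_nr_params()
  recomputed <- vapply(seq_len(nrow(tab)), function(i) {
    delta_max(nr_params(tab$r_max[i], tab$p_prime[i], tab$k[i]))
  }, 0)
  expect_equal(round(recomputed, 2), tab$delta_max_printed)
})

test_that("noiseless points are recovered exactly, with vanishing SEs", {
  # curvature below the threshold: all prey on the ecological branch P > P'-k
  theta <- nr_params(1.0, 1.5, 0.5)
  pts <- exact_nr_points(theta, prey = c(1.2, 1.8, 2.5, 3.5, 5, 7, 9, 12))
  suppressWarnings(fit <- fit_nr(pts))
  expect_true(fit$converged)
  expect_equal(coef(fit), c(r_max = 1.0, p_prime = 1.5, k = 0.5),
               tolerance = 1e-6)
  expect_true(all(fit$se < 1e-6))
  # a well-posed threshold (P' < k): interval collapses onto the estimate
  theta2 <- nr_params(1.0, 0.5, 1.5)
  fit2 <- fit_nr(exact_nr_points(theta2))
  expect_equal(fit2$delta_max, delta_max(theta2), tolerance = 1e-6)
  ci <- fit2$delta_max_interval
  expect_lt(ci$upper - ci$lower, 1e-6)
  expect_equal((ci$upper + ci$lower) / 2, delta_max(theta2),
               tolerance = 1e-6)
})

test_that("fit_nr enforces its preconditions", {
  pts <- exact_nr_points()
  expect_error(fit_nr(pts[1:4, ]), "at least 5")
  neg <- pts
  neg$r <- -abs(neg$r) - 0.1
  expect_error(fit_nr(neg), "no positive growth")
  mixed <- pts
  mixed$temperature[1] <- 99
  expect_error(fit_nr(mixed), "one temperature")
  mixed2 <- pts
  mixed2$prey_kind[1] <- "biomass"
  expect_error(fit_nr(mixed2), "prey metric")
})

test_that("the fitted minimum beats a dense grid search on small inputs", {
  set.seed(3)
  prey <- c(0.2, 0.5, 1, 1.8, 3, 4.5, 7, 10)
  r <- nr_predict(nr_params(1.1, 0.8, 2.0), prey) + rnorm(8, 0, 0.08)
  pts <- rate_points(15, prey, r)
  fit <- fit_nr(pts)
  rss <- function(th) sum((r - th[1] * (prey - th[2]) /
                             (th[3] + (prey - th[2])))^2)
  grid <- expand.grid(r_max = seq(0.5, 2, length.out = 40),
                      p_prime = seq(0, 2, length.out = 40),
                      k = seq(0.1, 5, length.out = 40))
  grid_rss <- min(apply(grid, 1, rss))
  expect_lte(fit$rss, grid_rss + 1e-4)
})

test_that("estimator bias is small relative to its sampling spread", {
  # single-temperature campaigns in units of 1e6 cells/mL; nonlinear LS
  # carries a finite-sample bias, so the check is bias against spread
  theta <- nr_params(1.2145, 1.0517, 3.3707)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 3)
  set.seed(905)
  prey <- 0.1 * (10 / 0.1)^(((seq_len(24) - 0.5) / 24)^1.5)
  for (i in seq_len(n_rep)) {
    r <- nr_predict(theta, prey) + rnorm(24, 0, 0.1)
    f <- tryCatch(fit_nr(rate_points(15, prey, r), n_draws = 100),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) est[i, ] <- coef(f)
  }
  expect_gt(sum(!is.na(est[, 1])), 150)
  truth <- c(theta$r_max, theta$p_prime, theta$k)
  for (j in 1:3) {
    e <- est[, j][!is.na(est[, j])]
    expect_lt(abs(mean(e) - truth[j]), 0.4 * sd(e))
  }
})

test_that("the mortality interval is seed-reproducible and covers the estimate", {
  # published 5 degC abundance triple with its SEs, zero covariances
  fit <- fake_nr_fit(c(0.5487, 0.3307, 0.8712), c(0.1355, 0.1392, 0.7080))
  ci1 <- delta_max_interval(fit, n_draws = 1e5, seed = 99)
  ci2 <- delta_max_interval(fit, n_draws = 1e5, seed = 99)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, -0.34)
  expect_gt(ci1$upper, -0.34)
  expect_true(ci1$reliable)
  ci3 <- delta_max_interval(fit, n_draws = 1e5, seed = 100)
  expect_false(identical(ci1$lower, ci3$lower))
})

test_that("satiating subset takes the top food levels and keeps ties", {
  pts <- rate_points(5, c(1, 5, 3, 9, 7, 2), c(0.1, 0.4, 0.3, 0.5, 0.45, 0.2))
  top3 <- satiating_subset(pts, 3)
  expect_equal(sort(top3$prey_value), c(5, 7, 9))
  tied <- rate_points(5, c(1, 9, 9, 9, 9, 2), 1:6 / 10)
  expect_message(out <- satiating_subset(tied, 3), "ties")
  expect_equal(nrow(out), 4)
  expect_warning(satiating_subset(pts, 2), "3-5")
  expect_error(satiating_subset(pts, 10), "exceeds")
  # oracle: plain sort-and-slice on a generated campaign (distinct levels)
  wells <- generate_campaign(campaign_config(temperatures = 15, seed = 4,
                                             count_noise = "none"))
  pts2 <- rate_points(15, wells$prey_P0_per_mL, wells$true_r)
  expect_equal(
    sort(satiating_subset(pts2, 5)$prey_value),
    sort(sort(pts2$prey_value, decreasing = TRUE)[1:5]))
})

test_that("paired r_max comparison matches the published contrast", {
  a <- table_abund()[, c("temperature", "r_max")]
  b <- table_biom()[, c("temperature", "r_max")]
  cmp <- compare_rmax_paired(a, b)
  expect_equal(cmp$p_value, 0.6839, tolerance = 1e-3)
  expect_gt(cmp$p_value, 0.05)
  same <- compare_rmax_paired(a, a)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  shifted <- b
  shifted$r_max <- a$r_max + 0.2
  expect_error(compare_rmax_paired(a, shifted), "zero variance")
  wrong <- b
  wrong$temperature <- wrong$temperature + 1
  expect_error(compare_rmax_paired(a, wrong), "match")
})
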