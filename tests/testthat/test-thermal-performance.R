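test_that("Lactin-2 evaluation matches hand algebra and its identities", {
  p <- lactin2_params(0.1, -0.2, 25, 4)
  expect_equal(lactin2_rate(p, 15), exp(1.5) - exp(2.5 - 2.5) - 0.2)
  # at t_max the two exponentials cancel: rate = b (randomised identity)
  set.seed(8)
  for (i in 1:50) {
    q <- lactin2_params(runif(1, 0.01, 0.3), runif(1, -2, 0),
                        runif(1, 15, 35), runif(1, 1, 10))
    expect_equal(lactin2_rate(q, q$t_max), q$b)
  }
  # cold limit: both exponentials vanish for a > 0, rate -> b
  expect_equal(lactin2_rate(p, -1e4), p$b, tolerance = 1e-12)
})

test_that("noiseless Lactin-2 points are recovered by the multistart fit", {
  truth <- lactin2_params(0.05, -0.7, 23, 3)
  fit <- fit_lactin2(exact_tpc_points(truth), seed = 1)
  expect_equal(coef(fit),
               c(a = 0.05, b = -0.7, t_max = 23, delta_t = 3),
               tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
})

test_that("fit_lactin2 contracts: duplicates kept, seeds reproduce, few temps error", {
  pts <- exact_tpc_points()
  dup <- rbind(pts, data.frame(temperature = 15, rate = pts$rate[3] + 0.1))
  fit <- fit_lactin2(dup, seed = 2)
  expect_equal(nrow(fit$data), 7)
  f1 <- fit_lactin2(pts, seed = 5)
  f2 <- fit_lactin2(pts, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_lactin2(pts[1:3, ]), "4 distinct")
})

test_that("grid/root trait machinery matches a closed-form parabola oracle", {
  # rate(T) = 1 - (T - 10)^2 / 25: argmax 10, zeros at 5 and 15
  tr <- protistNR:::extract_traits(function(T) 1 - (T - 10)^2 / 25, -20, 40)
  expect_equal(tr$t_opt, 10, tolerance = 1e-6)
  expect_equal(tr$r_at_opt, 1, tolerance = 1e-9)
  expect_equal(tr$ct_max, 15, tolerance = 1e-6)
  expect_equal(tr$ct_min, 5, tolerance = 1e-6)
  expect_equal(tr$tsm, 5, tolerance = 1e-6)
})

test_that("trait extraction satisfies its own defining conditions", {
  p <- lactin2_params(0.0523, -0.753, 23.5, 3.34)
  tr <- tpc_traits(p)
  # optimum beats a 10x finer brute-force grid within refinement tolerance
  fine <- seq(tr$search_lo, tr$search_hi, length.out = 20000)
  expect_lt(abs(tr$t_opt - fine[which.max(lactin2_rate(p, fine))]), 0.01)
  expect_gte(tr$r_at_opt, max(lactin2_rate(p, fine)) - 1e-9)
  # CTmax is a genuine zero crossing with negative rate just above
  expect_lt(abs(lactin2_rate(p, tr$ct_max)), 1e-8)
  expect_lt(lactin2_rate(p, tr$ct_max + 0.05), 0)
  expect_gt(tr$ct_max, tr$t_opt)
  expect_equal(tr$tsm, tr$ct_max - tr$t_opt)
})

test_that("curves that never cross zero leave the limits undefined", {
  # positive offset keeps the whole window above zero at the cold end
  p <- lactin2_params(0.02, 0.5, 25, 3)
  tr <- tpc_traits(p, search_lo = -10, search_hi = 26)
  expect_true(is.na(tr$ct_min) || lactin2_rate(p, tr$ct_min) < 1e-6)
  expect_false(tr$degenerate)
})

test_that("tsm is the plain difference of the two limits", {
  expect_equal(tsm(17.3, 21.9), 4.6)
  expect_equal(tsm(16.4, 22.4), 6.0)
  expect_equal(tsm(12, 12), 0)
})

test_that("the optimum is recovered within half a degree under realistic noise", {
  truth <- lactin2_params(0.05, -0.7, 23, 3)
  t_opt_true <- tpc_traits(truth)$t_opt
  temps <- c(5, 10, 15, 18, 20, 21)
  mu <- lactin2_rate(truth, temps)
  set.seed(314)
  errs <- replicate(100, {
    pts <- data.frame(temperature = temps, rate = mu + rnorm(6, 0, 0.05))
    fit <- tryCatch(fit_lactin2(pts, n_starts = 10,
                                seed = sample.int(1e6, 1)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(tpc_traits(fit)$t_opt - t_opt_true)
  })
  expect_lt(median(errs, na.rm = TRUE), 0.5)
})
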