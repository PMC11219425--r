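test_that("OLS trend matches the normal-equation oracle on random data", {
  set.seed(17)
  for (i in 1:20) {
    x <- runif(8, 4, 22)
    y <- -0.2 - 0.02 * x + rnorm(8, 0, 0.1)
    tr <- mortality_trend(mortality_records(x, y))
    slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept_oracle <- mean(y) - slope_oracle * mean(x)
    res <- y - intercept_oracle - slope_oracle * x
    se_oracle <- sqrt(sum(res^2) / 6 / sum((x - mean(x))^2))
    expect_equal(tr$slope, slope_oracle)
    expect_equal(tr$intercept, intercept_oracle)
    expect_equal(tr$slope_se, se_oracle)
    expect_equal(tr$t_stat, slope_oracle / se_oracle)
    expect_equal(tr$df, 6)
  }
})

test_that("collinear input gives the exact slope with vanishing SE", {
  x <- c(5, 10, 15, 20)
  # lm warns about the essentially perfect fit; the point is the exactness
  suppressWarnings(tr <- mortality_trend(mortality_records(x, 2 - 0.1 * x)))
  expect_equal(tr$slope, -0.1)
  expect_lt(tr$slope_se, 1e-10)
  expect_lt(tr$p_value, 1e-10)
})

test_that("exclusions are honoured and require reasons", {
  expect_error(mortality_records(5, -0.3, excluded = TRUE, reason = ""),
               "reason")
  rec <- mortality_records(c(5, 10, 15, 19), c(-0.3, -9, -0.5, -0.6),
                           excluded = c(FALSE, TRUE, FALSE, FALSE),
                           reason = c("", "non-satiated treatment", "", ""))
  tr <- mortality_trend(rec)
  expect_equal(tr$n_used, 3)
  expect_equal(tr$n_excluded, 1)
  all_excl <- mortality_records(c(5, 10, 15), rep(-1, 3),
                                excluded = TRUE, reason = "x")
  expect_error(mortality_trend(all_excl), "at least 3")
})

test_that("prediction passes through the centroid and is affine", {
  rec <- mortality_records(c(5, 10, 15, 19, 21), c(-0.3, -0.4, -0.5, -0.55, -0.7))
  tr <- mortality_trend(rec)
  expect_equal(predict_mortality(tr, mean(rec$temperature)),
               mean(rec$delta_max))
  expect_equal(predict_mortality(tr, 8), tr$intercept + 8 * tr$slope)
  band <- tr$band(c(8, 15))
  expect_true(all(band$lower < band$fit & band$fit < band$upper))
})

test_that("mortality summaries respect the sign convention", {
  rec <- mortality_records(c(5, 10, 15), c(-0.3, -0.5, -0.7))
  s_as_is <- summarize_mortality(rec)
  s_pos <- summarize_mortality(rec, sign_convention = "positive")
  expect_equal(s_pos$mean, -s_as_is$mean)
  expect_equal(s_pos$median, -s_as_is$median)
  expect_equal(s_pos$sd, s_as_is$sd)
  one <- summarize_mortality(mortality_records(5, -0.4))
  expect_equal(one$mean, -0.4)
  expect_equal(one$median, -0.4)
  expect_true(is.na(one$sd))
})

test_that("grazing arithmetic converts units correctly and round-trips", {
  expect_equal(community_grazing_rate(0.3, 18), 0.0054)
  expect_equal(community_grazing_rate(0, 100), 0)
  expect_equal(community_grazing_rate(1, 1000), 1.0)
  expect_equal(required_grazer_density(1.0, 37), 1000 / 37)
  expect_equal(required_grazer_density(0, 37), 0)
  for (r in c(0.05, 0.43, 1)) {
    expect_equal(community_grazing_rate(required_grazer_density(r, 37), 37), r)
  }
  expect_error(required_grazer_density(1, 0), "clearance")
})
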