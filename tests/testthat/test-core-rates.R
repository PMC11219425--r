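test_that("growth_rate evaluates ln(Nt/N0)/t and rejects bad inputs", {
  expect_equal(growth_rate(20, 40, 1), log(2))
  expect_equal(growth_rate(1000, 1000, 3), 0)
  expect_equal(growth_rate(50, 30, 1), log(30 / 50))
  # vectorised, sign follows the direction of change
  r <- growth_rate(c(10, 10, 10), c(20, 10, 5), 2)
  expect_identical(sign(r), sign(c(20, 10, 5) - 10))
  expect_error(growth_rate(0, 10, 1), "N0")
  expect_error(growth_rate(10, -1, 1), "Nt")
  expect_error(growth_rate(10, 10, 0), "t")
})

test_that("projection inverts the growth rate over a parameter grid", {
  expect_equal(project_population(100, 0, 5), 100)
  expect_equal(project_population(100, log(2), 1), 200)
  expect_equal(project_population(1000, -0.43, 14), 1000 * exp(-0.43 * 14))
  for (r in seq(-3, 3, by = 0.5)) {
    for (t in c(0.25, 1, 4, 10)) {
      expect_equal(growth_rate(50, project_population(50, r, t), t), r)
    }
  }
  expect_error(project_population(100, 0.1, -1), "t")
  expect_error(project_population(-5, 0.1, 1), "N0")
})

test_that("corrected mean prey is the depletion average with a stable limit", {
  expect_equal(mean_prey(1e6, 1e6), 1e6)
  expect_equal(mean_prey(1e6, 2e6), 1e6 / log(2))
  # strictly between the endpoints whenever they differ
  set.seed(42)
  for (i in 1:50) {
    P0 <- runif(1, 1e4, 1e7)
    Pt <- runif(1, 1e4, 1e7)
    if (P0 == Pt) next
    m <- mean_prey(P0, Pt)
    expect_gt(m, min(P0, Pt))
    expect_lt(m, max(P0, Pt))
  }
  # near-equal endpoints fall back to P0 rather than 0/0
  expect_equal(mean_prey(1e6, 1e6 * (1 + 1e-15)), 1e6)
})

test_that("literal mean prey mode matches its formula and guards its domain", {
  expect_equal(mean_prey(2, 10, mode = "literal"), 8 / log(8))
  expect_error(mean_prey(10, 2, mode = "literal"), "Pt > P0")
  expect_error(mean_prey(2, 3, mode = "literal"), "Pt - P0 = 1")
})

test_that("carbon conversion is linear in abundance, decreasing in frac_cocci", {
  expect_equal(abundance_to_carbon(0, 0.5), 0)
  expect_equal(abundance_to_carbon(1e6, 1.0), 0.028)
  expect_equal(abundance_to_carbon(1e6, 0.0), 0.25)
  a <- abundance_to_carbon(2e6, 0.3)
  expect_equal(a, 2 * abundance_to_carbon(1e6, 0.3))
  fr <- seq(0, 1, by = 0.1)
  b <- abundance_to_carbon(1e6, fr)
  expect_true(all(diff(b) < 0))
  expect_error(abundance_to_carbon(1e6, 1.2), "frac_cocci")
  expect_error(carbon_spec(volume_cocci = -1), "volume_cocci")
})
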