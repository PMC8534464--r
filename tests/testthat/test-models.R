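test_that("Peleg prediction matches direct arithmetic", {
  # t/(k1 + k2 t) with the atmospheric water-loss constants
  expect_equal(peleg_predict(1800, 36.2, 0.017), 1800 / (36.2 + 0.017 * 1800))
  expect_equal(peleg_predict(1800, 36.2, 0.017), 26.9461, tolerance = 1e-4)
  expect_equal(peleg_predict(0, 36.2, 0.017), 0)
  # asymptote is the equilibrium 1/k2
  expect_equal(peleg_predict(1e12, 36.2, 0.017), 1 / 0.017, tolerance = 1e-6)
})

test_that("Azuara prediction matches direct arithmetic", {
  expect_equal(azuara_predict(1800, 5.4e-4, 56.53),
               5.4e-4 * 1800 * 56.53 / (1 + 5.4e-4 * 1800))
  expect_equal(azuara_predict(1800, 5.4e-4, 56.53), 27.8637, tolerance = 1e-4)
  expect_equal(azuara_predict(0, 5.4e-4, 56.53), 0)
  # half-saturation at t = 1/S
  expect_equal(azuara_predict(1 / 5.4e-4, 5.4e-4, 56.53), 56.53 / 2)
})

test_that("Peleg and Azuara are the same hyperbola under reparameterization", {
  # k1 = 1/(S*y_inf), k2 = 1/y_inf
  set.seed(1)
  for (i in 1:20) {
    S <- 10^runif(1, -5, -3); y_inf <- runif(1, 20, 80)
    t <- sort(runif(9, 0, 4e4))
    expect_equal(peleg_predict(t, 1 / (S * y_inf), 1 / y_inf),
                 azuara_predict(t, S, y_inf), tolerance = 1e-12)
  }
})

test_that("Crank sphere series matches the brute-force oracle", {
  r <- berry_radius_m()
  De <- 2.19e-10
  # frozen value computed with the 10,000-term oracle
  expect_equal(crank_ratio(1800, De, r, n_terms = 30), 0.463247,
               tolerance = 1e-5)
  expect_equal(crank_ratio(1800, De, r, n_terms = 30),
               crank_series_oracle(1800, De, r, 10000), tolerance = 1e-12)
  expect_equal(crank_ratio(1e9, De, r), 0, tolerance = 1e-12)
})

test_that("30-term truncation is exact to 1e-10 for Fourier numbers >= 0.02", {
  r <- berry_radius_m()
  for (De in c(0.62e-10, 2.19e-10)) {
    fo <- c(0.02, 0.05, 0.1, 0.5, 1)
    t <- fo * r^2 / De
    expect_lt(max(abs(crank_ratio(t, De, r, n_terms = 30) -
                      crank_series_oracle(t, De, r, 10000))), 1e-10)
  }
})

test_that("first mode dominates the series for Fourier numbers >= 0.2", {
  r <- berry_radius_m()
  De <- 2.19e-10
  t <- c(0.2, 0.3, 0.5, 1) * r^2 / De
  expect_lt(max(abs(crank_ratio(t, De, r, n_terms = 1) -
                    crank_ratio(t, De, r, n_terms = 30))), 1e-3)
})

test_that("the truncated series at t = 0 documents its truncation error", {
  # 30-term partial sum of (6/pi^2) sum 1/n^2 vs the analytic limit 1
  expect_equal(crank_ratio(0, 2.19e-10, 3.29e-3, exact_t0 = FALSE),
               (6 / pi^2) * sum(1 / (1:30)^2))
  expect_equal(crank_ratio(0, 2.19e-10, 3.29e-3, exact_t0 = FALSE), 0.9801,
               tolerance = 1e-4)
  # default returns the analytic value
  expect_equal(crank_ratio(0, 2.19e-10, 3.29e-3), 1)
})

test_that("Page ratio matches direct arithmetic and degenerate cases", {
  expect_equal(page_ratio(1800, 7.62e-3, 0.592), exp(-7.62e-3 * 1800^0.592))
  expect_equal(page_ratio(1800, 7.62e-3, 0.592), 0.52504, tolerance = 1e-5)
  expect_equal(page_ratio(0, 7.62e-3, 0.592), 1)
  expect_equal(page_ratio(c(10, 1e5), 0, 0.592), c(1, 1))
})

test_that("increasing models increase and ratio models decrease (monotonicity)", {
  set.seed(7)
  t <- sort(runif(50, 1, 4e4))
  for (i in 1:20) {
    k1 <- runif(1, 5, 500); k2 <- runif(1, 0.005, 0.08)
    expect_true(all(diff(peleg_predict(t, k1, k2)) > 0))
    S <- 10^runif(1, -5, -3); y_inf <- runif(1, 10, 90)
    expect_true(all(diff(azuara_predict(t, S, y_inf)) > 0))
    A <- 10^runif(1, -4, -2); B <- runif(1, 0.3, 1.2)
    expect_true(all(diff(page_ratio(t, A, B)) < 0))
    De <- 10^runif(1, -10.5, -9.5)
    expect_true(all(diff(crank_ratio(t, De, 3.29e-3)) < 0))
  }
})

test_that("model parameter positivity is enforced", {
  expect_error(peleg_predict(10, -1, 0.017), class = "osmokin_invalid_input")
  expect_error(peleg_predict(-5, 36.2, 0.017), class = "osmokin_invalid_input")
  expect_error(azuara_predict(10, 0, 56), class = "osmokin_invalid_input")
  expect_error(crank_ratio(10, 0, 3.29e-3), class = "osmokin_invalid_input")
  expect_error(crank_ratio(10, 2e-10, -1), class = "osmokin_invalid_input")
  expect_error(page_ratio(10, -0.1, 0.5), class = "osmokin_invalid_input")
})

test_that("sphere radius is the quarter-sum of length and width, in meters", {
  expect_equal(sphere_radius(6.65, 6.51), 3.29e-3)
  expect_equal(sphere_radius(2, 2), 1e-3)
  expect_error(sphere_radius(0, 6.51), class = "osmokin_invalid_input")
})

test_that("dimensionless transform is 1 - Y/Yinf with guarded equilibrium", {
  d <- to_dimensionless(c(0, 1800), c(0, 26.95), y_inf = 57.67)
  expect_equal(d$ratio[1], 1)
  expect_equal(d$ratio[2], 1 - 26.95 / 57.67)
  expect_equal(d$ratio[2], 0.5327, tolerance = 1e-4)
  expect_equal(to_dimensionless(10, 28.835, 57.67)$ratio, 0.5)
  err <- expect_error(to_dimensionless(c(0, 1800), c(0, 60), y_inf = 57.67),
                      class = "osmokin_equilibrium_inconsistency")
  expect_match(conditionMessage(err), "1800")
})
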