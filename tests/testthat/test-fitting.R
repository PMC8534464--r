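test_that("goodness of fit follows the standard R^2 and RMSE definitions", {
  g <- od_goodness(c(0, 10, 20), c(1, 10, 19))
  expect_equal(g$rmse, sqrt(2 / 3))
  expect_equal(g$r_squared, 1 - 2 / 200)
  perfect <- od_goodness(c(1, 5, 9), c(1, 5, 9))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  # predicting the mean gives R^2 = 0 by definition
  expect_equal(od_goodness(c(0, 10, 20), rep(10, 3))$r_squared, 0)
  # constant observed data: R^2 undefined
  expect_true(is.na(od_goodness(rep(3, 4), rep(3, 4))$r_squared))
})

test_that("Peleg fit recovers generating parameters exactly on noise-free data", {
  for (id in c("WL1", "WL2", "SG1", "SG2")) {
    p <- ref_row(id)
    d <- peleg_true_series(p$k1, p$k2)
    f <- fit_peleg(d, WL_pct)
    expect_lt(abs(f$params[["k1"]] - p$k1) / p$k1, 1e-6)
    expect_lt(abs(f$params[["k2"]] - p$k2) / p$k2, 1e-6)
    expect_equal(f$equilibrium, 1 / f$params[["k2"]])
    expect_equal(f$quality$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("Peleg equilibrium is reported from the unrounded estimate", {
  d <- peleg_true_series(50, 0.016)
  f <- fit_peleg(d, WL_pct)
  expect_equal(f$equilibrium, 62.5, tolerance = 1e-6)
})

test_that("degenerate series are rejected with a fit-failure error", {
  flat <- tibble::tibble(time_s = paper_times_s(), WL_pct = 0)
  expect_error(fit_peleg(flat, WL_pct), class = "osmokin_fit_failure")
  two_pts <- tibble::tibble(time_s = c(0, 1800), WL_pct = c(0, 10))
  expect_error(fit_peleg(two_pts, WL_pct), class = "osmokin_fit_failure")
})

test_that("Azuara linearization recovers (S, y_inf) exactly on model-true data", {
  cases <- list(c(S = 5.4e-4, y_inf = 56.53), c(S = 1.2e-4, y_inf = 31.07))
  for (cs in cases) {
    t <- paper_times_s()
    d <- tibble::tibble(time_s = t, SG_pct = azuara_predict(t, cs["S"], cs["y_inf"]))
    f <- fit_azuara(d, SG_pct)
    expect_lt(abs(f$params[["S"]] - cs[["S"]]) / cs[["S"]], 1e-9)
    expect_lt(abs(f$params[["y_inf"]] - cs[["y_inf"]]) / cs[["y_inf"]], 1e-9)
    expect_equal(f$equilibrium, f$params[["y_inf"]])
  }
})

test_that("linearized Azuara equals direct NLS on model-true data", {
  t <- paper_times_s()
  d <- tibble::tibble(time_s = t, WL_pct = azuara_predict(t, 3.6e-4, 60.92))
  lin <- fit_azuara(d, WL_pct, method = "linearized")
  nls <- fit_azuara(d, WL_pct, method = "nls")
  expect_equal(lin$params, nls$params, tolerance = 1e-9)
})

test_that("a decreasing t/Y trend invalidates the Azuara linearization", {
  # Y growing super-linearly makes t/Y decrease => implied S <= 0
  t <- c(0, 1800, 3600, 7200, 14400)
  d <- tibble::tibble(time_s = t, WL_pct = c(0, 1, 4, 16, 70))
  expect_error(fit_azuara(d, WL_pct), class = "osmokin_linearization_invalid")
})

test_that("Page fit recovers (A, B) on noise-free dimensionless data", {
  t <- paper_times_s()
  for (id in c("WL1", "SG2")) {
    p <- ref_row(id)
    d <- tibble::tibble(time_s = t, ratio = page_ratio(t, p$A, p$B))
    f <- fit_page(d, ratio, space = "ratio")
    expect_lt(abs(f$params[["A"]] - p$A) / p$A, 1e-6)
    expect_lt(abs(f$params[["B"]] - p$B) / p$B, 1e-6)
  }
})

test_that("Page NLS agrees with the closed-form log-log regression oracle", {
  t <- paper_times_s()
  d <- tibble::tibble(time_s = t, ratio = page_ratio(t, 2.48e-3, 0.694))
  f <- fit_page(d, ratio, space = "ratio")
  pos <- t > 0
  oracle <- lm(log(-log(d$ratio[pos])) ~ log(t[pos]))
  expect_equal(f$params[["B"]], unname(coef(oracle)[2]), tolerance = 1e-9)
  expect_equal(f$params[["A"]], exp(unname(coef(oracle)[1])), tolerance = 1e-9)
})

test_that("a ratio identically 1 (no transfer) is rejected", {
  d <- tibble::tibble(time_s = paper_times_s(),
                      ratio = rep(1, length(paper_times_s())))
  expect_error(fit_page(d, ratio, space = "ratio"),
               class = "osmokin_fit_failure")
})

test_that("Crank fit recovers the effective diffusivity on noise-free data", {
  r <- berry_radius_m()
  t <- paper_times_s()
  for (De in c(2.19e-10, 0.62e-10)) {
    d <- tibble::tibble(time_s = t, ratio = crank_ratio(t, De, r))
    f <- fit_crank(d, ratio, radius = r, space = "ratio")
    expect_lt(abs(f$params[["De"]] - De) / De, 1e-6)
    expect_length(f$flags, 0)
  }
})

test_that("first-mode log-linear slope gives the Crank fit's magnitude", {
  # at large Fourier number the series is single-mode:
  # ln(ratio) = ln(6/pi^2) - pi^2 De t / r^2
  r <- berry_radius_m(); De <- 2.19e-10
  t <- seq(0.25, 1, by = 0.25) * r^2 / De
  ratio <- crank_ratio(t, De, r)
  slope <- coef(lm(log(ratio) ~ t))[[2]]
  De_loglin <- -slope * r^2 / pi^2
  d <- tibble::tibble(time_s = t, ratio = ratio)
  f <- fit_crank(d, ratio, radius = r, space = "ratio")
  expect_lt(abs(De_loglin - f$params[["De"]]) / f$params[["De"]], 0.01)
})

test_that("percent-space entry to ratio fits uses the supplied equilibrium", {
  t <- paper_times_s()
  y_inf <- 1 / 0.017
  wl <- y_inf * (1 - crank_ratio(t, 2.19e-10, berry_radius_m()))
  d <- tibble::tibble(time_s = t, WL_pct = wl)
  f <- fit_crank(d, WL_pct, y_inf = y_inf, radius = berry_radius_m(),
                 space = "percent")
  expect_lt(abs(f$params[["De"]] - 2.19e-10) / 2.19e-10, 1e-6)
})

test_that("fits are invariant to the time unit when parameters are rescaled", {
  p <- ref_row("WL1")
  d_s <- peleg_true_series(p$k1, p$k2)
  d_h <- dplyr::mutate(d_s, time_s = time_s / 3600)
  f_s <- fit_peleg(d_s, WL_pct)
  f_h <- fit_peleg(d_h, WL_pct)
  # k1 carries the time unit, k2 does not; quality is unit-free
  expect_equal(f_h$params[["k1"]], f_s$params[["k1"]] / 3600, tolerance = 1e-6)
  expect_equal(f_h$params[["k2"]], f_s$params[["k2"]], tolerance = 1e-6)
  expect_equal(f_h$quality$r_squared, f_s$quality$r_squared, tolerance = 1e-9)
  expect_equal(f_h$data$fitted, f_s$data$fitted, tolerance = 1e-6)
})

test_that("compare_models fits all four models and ranks the true one first", {
  k <- simulate_kinetics(
    truth_wl = list(model = "peleg", k1 = 36.2, k2 = 0.017),
    truth_sg = list(model = "peleg", k1 = 202.4, k2 = 0.030),
    noise_sd = 0, n_replicates = 1, seed = 3, treatment = "atm"
  )
  cmp <- compare_models(k, radius = berry_radius_m())
  expect_s3_class(cmp, "od_model_comparison")
  expect_equal(nrow(cmp$summary), 8)  # 4 models x 2 quantities
  best <- cmp$summary[cmp$summary$rank == 1, ]
  expect_equal(best$model, c("peleg", "peleg"))
  expect_true(all(is.na(cmp$summary$error)))
  # equilibrium present for Peleg/Azuara only
  eq <- cmp$summary
  expect_true(all(!is.na(eq$equilibrium[eq$model %in% c("peleg", "azuara")])))
  expect_true(all(is.na(eq$equilibrium[eq$model %in% c("page", "crank")])))
})

test_that("an individual fit failure is ranked out, not fatal", {
  # constant series breaks every model but must not abort the comparison
  k <- tibble::tibble(
    treatment = "flat", time_s = paper_times_s(),
    WL_pct = peleg_predict(paper_times_s(), 36.2, 0.017),
    SG_pct = 0
  )
  cmp <- compare_models(k, radius = berry_radius_m())
  sg <- cmp$summary[cmp$summary$quantity == "SG_pct", ]
  expect_true(all(!is.na(sg$error)))
  wl <- cmp$summary[cmp$summary$quantity == "WL_pct", ]
  expect_true(all(is.na(wl$error)))
  expect_equal(wl$model[wl$rank == 1], "peleg")
})

test_that("tidy and glance expose fitted parameters and quality", {
  d <- peleg_true_series(36.2, 0.017)
  f <- fit_peleg(d, WL_pct)
  td <- tidy(f)
  expect_equal(td$term, c("k1", "k2"))
  gl <- glance(f)
  expect_equal(gl$model, "peleg")
  expect_equal(gl$n_points, nrow(d))
  expect_s3_class(autoplot(f), "ggplot")
})
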