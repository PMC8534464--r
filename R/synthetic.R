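#' Published kinetic parameters for autumn olive osmotic dehydration
#'
#' Fitted model parameters reported for osmotic dehydration of autumn
#' olive berries in 70% sucrose at 70 degC, at atmospheric pressure
#' (treatment 1) and under continuous vacuum (treatment 2), for water loss
#' (WL) and sugar gain (SG). These serve as ground truth for the synthetic
#' generator and for parameter-recovery studies. Units: `k1` s x percent^-1,
#' `k2` percent^-1, `S` s^-1, `y_inf` percent, `A` s^-B, `B` dimensionless,
#' `De` m^2 s^-1. The equivalent sphere radius of the berries is 3.29 mm
#' (length 6.65 mm, width 6.51 mm).
#'
#' @return A tibble with one row per treatment x quantity and one column
#'   per model parameter.
#' @examples
#' reference_kinetic_params()
#' @export
reference_kinetic_params <- function() {
  tibble(
    series = c("WL1", "WL2", "SG1", "SG2"),
    treatment = c("atmospheric", "vacuum", "atmospheric", "vacuum"),
    quantity = c("WL", "WL", "SG", "SG"),
    k1 = c(36.2, 50.7, 202.4, 254.3),
    k2 = c(0.017, 0.016, 0.030, 0.033),
    S = c(5.4e-4, 3.6e-4, 1.5e-4, 1.2e-4),
    y_inf = c(56.53, 60.92, 33.86, 31.07),
    A = c(7.62e-3, 2.48e-3, 5.80e-3, 2.20e-3),
    B = c(0.592, 0.694, 0.798, 0.893),
    De = c(2.19e-10, 1.55e-10, 0.72e-10, 0.62e-10)
  )
}

#' Reference colour readings of fresh and osmo-dehydrated berries
#'
#' Mean CIELAB coordinates (and their standard deviations) per sampling
#' time for the atmospheric-pressure treatment, used as the default means
#' of the colour-reading simulator.
#'
#' @return A tibble with columns `time_h`, `L`, `a`, `b`, `L_sd`, `a_sd`,
#'   `b_sd`.
#' @export
reference_color_means <- function() {
  tibble(
    time_h = c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 10),
    L = c(31.53, 27.78, 28.25, 28.16, 28.01, 28.66, 28.44, 27.12, 26.52),
    a = c(6.10, 9.65, 8.01, 7.49, 6.70, 7.54, 7.01, 5.89, 6.70),
    b = c(4.43, 7.71, 6.95, 6.65, 5.91, 6.45, 5.95, 5.45, 5.81),
    L_sd = c(1.23, 1.09, 0.74, 0.84, 0.62, 1.07, 1.18, 1.01, 0.68),
    a_sd = c(1.27, 0.90, 1.09, 1.28, 0.71, 0.85, 1.09, 1.05, 0.45),
    b_sd = c(0.46, 0.67, 0.76, 0.74, 0.40, 0.84, 0.54, 0.64, 0.31)
  )
}

#' Default sampling design of the dehydration experiment
#'
#' Sampling times 0, 0.5, 1, 1.5, 2, 3, 4, 5 and 10 h, in hours.
#'
#' @return A numeric vector of times in hours.
#' @export
default_sampling_times_h <- function() {
  c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 10)
}

eval_truth <- function(truth, t) {
  model <- truth$model %||% abort("`truth` must name a model.",
                                  class = "osmokin_invalid_input")
  switch(model,
    peleg = peleg_predict(t, truth$k1, truth$k2),
    azuara = azuara_predict(t, truth$S, truth$y_inf),
    page = truth$y_inf * (1 - page_ratio(t, truth$A, truth$B)),
    crank = truth$y_inf * (1 - crank_ratio(t, truth$De, truth$radius,
                                           n_terms = truth$n_terms %||% 30)),
    abort(sprintf("unknown truth model '%s'.", model),
          class = "osmokin_invalid_input")
  )
}

truth_equilibrium <- function(truth) {
  switch(truth$model,
         peleg = 1 / truth$k2,
         truth$y_inf)
}

#' Simulate replicate mass-transfer kinetics
#'
#' Generates WL and SG trajectories from a known ("truth") model plus
#' additive Gaussian measurement noise, at the experiment's sampling
#' times. WL and SG are 0 at time 0 by construction (they are defined
#' relative to the initial state), so noise is applied at t > 0 only;
#' WR = WL - SG identically. Reproducible under a fixed seed.
#'
#' @param truth_wl,truth_sg Lists describing the generating model for WL
#'   and SG, e.g. `list(model = "peleg", k1 = 36.2, k2 = 0.017)`;
#'   `"azuara"` (`S`, `y_inf`), `"page"` (`A`, `B`, `y_inf`) and `"crank"`
#'   (`De`, `radius`, `y_inf`) are also accepted.
#' @param times_h Sampling times in hours; the first must be 0.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   percentage points. Default 1.
#' @param n_replicates Replicates per time point. Default 3.
#' @param seed Integer seed; required for reproducibility.
#' @param treatment Label attached to the series.
#' @param realism_check If `TRUE`, require SG equilibrium < WL equilibrium
#'   (as the experiment's treatments satisfy).
#' @return A tibble with columns `treatment`, `replicate`, `time_s`,
#'   `WL_pct`, `SG_pct`, `WR_pct`; the generating truth is attached as the
#'   `"truth"` attribute.
#' @examples
#' simulate_kinetics(
#'   truth_wl = list(model = "peleg", k1 = 36.2, k2 = 0.017),
#'   truth_sg = list(model = "peleg", k1 = 202.4, k2 = 0.030),
#'   noise_sd = 0, n_replicates = 1, seed = 1
#' )
#' @export
simulate_kinetics <- function(truth_wl, truth_sg,
                              times_h = default_sampling_times_h(),
                              noise_sd = 1, n_replicates = 3, seed,
                              treatment = "synthetic",
                              realism_check = FALSE) {
  if (missing(seed)) {
    abort("`seed` is required so simulated datasets are reproducible.",
          class = "osmokin_invalid_input")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "osmokin_invalid_input")
  }
  if (times_h[1] != 0) {
    abort("`times_h` must start at 0.", class = "osmokin_invalid_input")
  }
  if (realism_check &&
      truth_equilibrium(truth_sg) >= truth_equilibrium(truth_wl)) {
    abort("realism check failed: SG equilibrium must be below WL equilibrium.",
          class = "osmokin_invalid_input")
  }
  t_s <- time_to_seconds(times_h, "h")
  wl_true <- eval_truth(truth_wl, t_s)
  sg_true <- eval_truth(truth_sg, t_s)
  withr::with_seed(seed, {
    out <- map(seq_len(n_replicates), function(r) {
      noise_wl <- c(0, rnorm(length(t_s) - 1, 0, noise_sd))
      noise_sg <- c(0, rnorm(length(t_s) - 1, 0, noise_sd))
      tibble(
        treatment = treatment, replicate = r, time_s = t_s,
        WL_pct = wl_true + noise_wl,
        SG_pct = sg_true + noise_sg
      )
    }) %>% list_rbind()
  })
  out$WR_pct <- out$WL_pct - out$SG_pct
  attr(out, "truth") <- list(WL = truth_wl, SG = truth_sg,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Invert the mass balance: kinetics back to raw measurements
#'
#' Given WL/WR trajectories (percent of initial mass), the initial mass
#' `Wi` and initial moisture fraction `Xi`, reconstructs the raw mass and
#' moisture observations that would have produced them:
#' `Wf = Wi (1 - WR/100)` and `Xf = (Wi Xi - Wi WL/100) / Wf`. Feeding the
#' result back through [build_kinetics()] reproduces WL/SG/WR exactly.
#'
#' @param kinetics A tibble with `treatment`, `time_s`, `WL_pct`, `WR_pct`
#'   (a `replicate` column, if present, is carried through as distinct
#'   treatments suffixed by replicate).
#' @param Wi Initial mass in grams. Default 100.
#' @param Xi Initial moisture fraction. Default 0.7724 (fresh autumn olive
#'   berries).
#' @return A tibble with columns `treatment`, `time_h`, `mass_g`,
#'   `moisture` (fraction), the `measurements.csv` schema.
#' @examples
#' k <- tibble::tibble(treatment = "atm", time_s = c(0, 1800),
#'                     WL_pct = c(0, 25.24), WR_pct = c(0, 20))
#' inverse_mass_balance(k)  # mass 80 g, moisture 0.65 at t = 1800 s
#' @export
inverse_mass_balance <- function(kinetics, Wi = 100, Xi = 0.7724) {
  check_mass(Wi, "Wi")
  if (Xi <= 0 || Xi >= 1) {
    abort("`Xi` must be strictly inside (0, 1).",
          class = "osmokin_invalid_input")
  }
  df <- as_tibble(kinetics)
  if ("replicate" %in% names(df)) {
    df$treatment <- paste(df$treatment, df$replicate, sep = "_r")
    df$replicate <- NULL
  }
  if (any(df$WR_pct >= 100)) {
    abort("WR must stay below 100% for the inversion to give positive mass.",
          class = "osmokin_infeasible_trajectory")
  }
  Wf <- Wi * (1 - df$WR_pct / 100)
  Xf <- (Wi * Xi - Wi * df$WL_pct / 100) / Wf
  bad <- which(Xf < 0 | Xf > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "infeasible trajectory: implied moisture fraction %.4f at t = %.6g s lies outside [0, 1]; the truth parameters are physically inconsistent with Xi = %.4f.",
      Xf[bad[1]], df$time_s[bad[1]], Xi),
      class = "osmokin_infeasible_trajectory")
  }
  tibble(
    treatment = df$treatment,
    time_h = df$time_s / 3600,
    mass_g = Wf,
    moisture = Xf
  )
}

#' Simulate a full raw-measurement dataset
#'
#' Convenience wrapper: [simulate_kinetics()] followed by
#' [inverse_mass_balance()], producing a table in the raw
#' `measurements.csv` schema whose derived kinetics equal the simulated
#' ones exactly.
#'
#' @inheritParams simulate_kinetics
#' @inheritParams inverse_mass_balance
#' @return A tibble with `treatment`, `time_h`, `mass_g`, `moisture`.
#' @export
simulate_measurements <- function(truth_wl, truth_sg,
                                  times_h = default_sampling_times_h(),
                                  noise_sd = 1, n_replicates = 3, seed,
                                  treatment = "synthetic",
                                  Wi = 100, Xi = 0.7724) {
  k <- simulate_kinetics(truth_wl, truth_sg, times_h = times_h,
                         noise_sd = noise_sd, n_replicates = n_replicates,
                         seed = seed, treatment = treatment)
  inverse_mass_balance(k, Wi = Wi, Xi = Xi)
}

#' Simulate colorimeter readings
#'
#' Gaussian readings around per-time mean CIELAB triples, emulating the
#' "n readings per repetition" structure of a colorimeter protocol.
#' Defaults use the published per-time means and SDs of the
#' atmospheric-pressure treatment.
#'
#' @param means A tibble with columns `time_h`, `L`, `a`, `b` and
#'   optionally `L_sd`, `a_sd`, `b_sd`; default [reference_color_means()].
#' @param n_readings Readings per repetition. Default 5.
#' @param n_reps Repetitions. Default 3.
#' @param seed Integer seed; required.
#' @param treatment Label for the generated rows.
#' @return A tibble with `treatment`, `time_h`, `rep`, `reading`, `L`,
#'   `a`, `b`.
#' @export
simulate_color <- function(means = reference_color_means(), n_readings = 5,
                           n_reps = 3, seed, treatment = "synthetic") {
  if (missing(seed)) {
    abort("`seed` is required so simulated datasets are reproducible.",
          class = "osmokin_invalid_input")
  }
  for (col in c("L_sd", "a_sd", "b_sd")) {
    if (!col %in% names(means)) means[[col]] <- 1
  }
  withr::with_seed(seed, {
    pmap(means, function(time_h, L, a, b, L_sd, a_sd, b_sd, ...) {
      n <- n_readings * n_reps
      tibble(
        treatment = treatment, time_h = time_h,
        rep = base::rep(seq_len(n_reps), each = n_readings),
        reading = base::rep(seq_len(n_readings), times = n_reps),
        L = rnorm(n, L, L_sd), a = rnorm(n, a, a_sd), b = rnorm(n, b, b_sd)
      )
    }) %>% list_rbind()
  })
}
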