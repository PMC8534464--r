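#' Kinetic models of osmotic mass transfer
#'
#' Four standard descriptions of how water loss (WL) or solid gain (SG)
#' evolves during osmotic dehydration, all with time in seconds:
#'
#' * **Peleg**: `Y(t) = t / (k1 + k2 t)`; `Y(0) = 0`, equilibrium `1/k2`.
#' * **Azuara**: `Y(t) = S t Yinf / (1 + S t)`; `Y(0) = 0`, equilibrium
#'   `Yinf`. Algebraically the same hyperbola as Peleg with
#'   `k1 = 1/(S Yinf)` and `k2 = 1/Yinf`.
#' * **Crank (sphere)**: the series solution of Fick's second law for a
#'   sphere of radius `r`, predicting the *unaccomplished* dimensionless
#'   ratio `1 - Y(t)/Yinf`:
#'   `(6/pi^2) * sum_{n=1..N} exp(-n^2 pi^2 De t / r^2) / n^2`.
#' * **Page**: the empirical stretched exponential `exp(-A t^B)`, also on
#'   the dimensionless ratio.
#'
#' @param t Time in seconds, non-negative.
#' @param k1 Peleg rate constant, s·percent^-1, positive.
#' @param k2 Peleg capacity constant, percent^-1, positive; `1/k2` is the
#'   equilibrium WL or SG.
#' @param S Azuara rate constant, s^-1, positive.
#' @param y_inf Equilibrium WL or SG in percent, positive.
#' @param De Effective diffusivity in m^2 s^-1, positive.
#' @param radius Equivalent sphere radius in meters, positive.
#' @param n_terms Number of series terms (default 30).
#' @param exact_t0 If `TRUE` (default) return the analytic value 1 at
#'   `t = 0` instead of the truncated sum (0.98007 at 30 terms); set to
#'   `FALSE` to expose the raw truncated series.
#' @param A Page scale constant, s^-B, non-negative.
#' @param B Page exponent, dimensionless, positive.
#' @return A numeric vector: percent for [peleg_predict()] and
#'   [azuara_predict()], a dimensionless ratio in `(0, 1]` for
#'   [crank_ratio()] and [page_ratio()].
#' @examples
#' peleg_predict(1800, k1 = 36.2, k2 = 0.017)        # 26.95
#' azuara_predict(1800, S = 5.4e-4, y_inf = 56.53)   # 27.86
#' crank_ratio(1800, De = 2.19e-10, radius = 3.29e-3) # 0.4632
#' page_ratio(1800, A = 7.62e-3, B = 0.592)          # 0.5250
#' @name kinetic_models
NULL

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative time in seconds.",
          class = "osmokin_invalid_input")
  }
  invisible(t)
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", what),
          class = "osmokin_invalid_input")
  }
  invisible(x)
}

#' @rdname kinetic_models
#' @export
peleg_predict <- function(t, k1, k2) {
  check_time(t); check_positive(k1, "k1"); check_positive(k2, "k2")
  t / (k1 + k2 * t)
}

#' @rdname kinetic_models
#' @export
azuara_predict <- function(t, S, y_inf) {
  check_time(t); check_positive(S, "S"); check_positive(y_inf, "y_inf")
  S * t * y_inf / (1 + S * t)
}

#' @rdname kinetic_models
#' @export
crank_ratio <- function(t, De, radius, n_terms = 30, exact_t0 = TRUE) {
  check_time(t); check_positive(De, "De"); check_positive(radius, "radius")
  if (!is.numeric(n_terms) || n_terms < 1 || n_terms != round(n_terms)) {
    abort("`n_terms` must be a positive integer.",
          class = "osmokin_invalid_input")
  }
  k <- seq_len(n_terms)
  out <- vapply(
    t,
    function(ti) (6 / pi^2) * sum(exp(-k^2 * pi^2 * De * ti / radius^2) / k^2),
    numeric(1)
  )
  if (exact_t0) out[t == 0] <- 1
  out
}

#' @rdname kinetic_models
#' @export
page_ratio <- function(t, A, B) {
  check_time(t); check_positive(B, "B")
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A < 0) {
    abort("`A` must be a single non-negative finite number.",
          class = "osmokin_invalid_input")
  }
  exp(-A * t^B)
}

#' Equivalent sphere radius of a fruit
#'
#' The fruit diameter is taken as the mean of its length and width; the
#' radius is half that, converted from millimetres to meters:
#' `r = (length + width) / 4 / 1000`.
#'
#' @param length_mm,width_mm Fruit length and width in millimetres, positive.
#' @return Radius in meters.
#' @examples
#' sphere_radius(6.65, 6.51)  # 3.29e-3 m
#' @export
sphere_radius <- function(length_mm, width_mm) {
  check_positive(length_mm, "length_mm")
  check_positive(width_mm, "width_mm")
  (length_mm + width_mm) / 4 / 1000
}

#' Unaccomplished mass-transfer ratio
#'
#' Converts a WL or SG series (percent) into the dimensionless ratio
#' `1 - Y(t)/Yinf` used by the Crank and Page models: 1 before any
#' transfer, approaching 0 at equilibrium. Requires the equilibrium value
#' to exceed every observation, otherwise the ratio would leave `(0, 1]`.
#'
#' @param times Times in seconds.
#' @param y Observed WL or SG in percent (`y[times == 0]` must be 0 if a
#'   time-0 point is present).
#' @param y_inf Equilibrium value in percent; must exceed `max(y)`.
#' @return A tibble with columns `time_s` and `ratio`.
#' @examples
#' to_dimensionless(c(0, 1800), c(0, 26.95), y_inf = 57.67)
#' @export
to_dimensionless <- function(times, y, y_inf) {
  check_time(times)
  check_positive(y_inf, "y_inf")
  if (length(times) != length(y)) {
    abort("`times` and `y` must have the same length.",
          class = "osmokin_invalid_input")
  }
  bad <- which(y >= y_inf)
  if (length(bad) > 0) {
    abort(sprintf(
      "equilibrium value y_inf = %.6g does not exceed the observation %.6g at t = %.6g s; the dimensionless ratio is undefined.",
      y_inf, y[bad[1]], times[bad[1]]),
      class = "osmokin_equilibrium_inconsistency")
  }
  tibble(time_s = times, ratio = 1 - y / y_inf)
}
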