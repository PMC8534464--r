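#' Mass-transfer quantities from raw weight and moisture measurements
#'
#' During osmotic dehydration a fruit batch of initial mass `Wi` (g) and
#' moisture fraction `Xi` evolves to mass `Wf` and moisture fraction `Xf`.
#' Three quantities summarise the exchange, all expressed as percent of the
#' initial mass:
#'
#' * water loss `WL = 100 (Wi Xi - Wf Xf) / Wi`,
#' * solid gain `SG = 100 (Wf (1 - Xf) - Wi (1 - Xi)) / Wi`,
#' * weight reduction `WR = 100 (Wi - Wf) / Wi`.
#'
#' The three are algebraically linked: `WR = WL - SG` for any valid input.
#' Negative values are physically meaningful (water or solute moving the
#' "wrong" way early in the process) and are returned unclamped.
#'
#' @param Wi,Wf Initial and current fruit mass in grams; must be positive.
#' @param Xi,Xf Initial and current moisture as a mass fraction in `[0, 1]`.
#' @return A numeric vector in percent of the initial mass.
#' @examples
#' compute_water_loss(100, 0.7724, 80, 0.65)   # 25.24
#' compute_solid_gain(100, 0.7724, 80, 0.65)   #  5.24
#' compute_weight_reduction(100, 80)           # 20
#' @name mass_transfer
NULL

check_mass <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be a positive finite mass in grams.", what),
          class = "osmokin_invalid_input")
  }
  invisible(x)
}

check_moisture <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a moisture fraction in [0, 1].", what),
          class = "osmokin_invalid_input")
  }
  invisible(x)
}

#' @rdname mass_transfer
#' @export
compute_water_loss <- function(Wi, Xi, Wf, Xf) {
  check_mass(Wi, "Wi"); check_mass(Wf, "Wf")
  check_moisture(Xi, "Xi"); check_moisture(Xf, "Xf")
  100 * (Wi * Xi - Wf * Xf) / Wi
}

#' @rdname mass_transfer
#' @export
compute_solid_gain <- function(Wi, Xi, Wf, Xf) {
  check_mass(Wi, "Wi"); check_mass(Wf, "Wf")
  check_moisture(Xi, "Xi"); check_moisture(Xf, "Xf")
  100 * (Wf * (1 - Xf) - Wi * (1 - Xi)) / Wi
}

#' @rdname mass_transfer
#' @export
compute_weight_reduction <- function(Wi, Wf) {
  check_mass(Wi, "Wi"); check_mass(Wf, "Wf")
  100 * (Wi - Wf) / Wi
}

#' Normalise a moisture column to a fraction
#'
#' Experimental records mix percent and fractional moisture. Values above
#' 1.5 cannot be fractions, so a column whose maximum exceeds 1.5 is taken
#' to be in percent and divided by 100, with a warning.
#'
#' @param x Numeric moisture values, either fractions or percentages.
#' @return Moisture as a fraction in `[0, 1]`.
#' @export
as_moisture_fraction <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort("moisture must be numeric, finite and non-negative.",
          class = "osmokin_invalid_input")
  }
  if (any(x > 1.5)) {
    warn("moisture values > 1.5 detected; interpreting the column as percent and dividing by 100.")
    x <- x / 100
  }
  check_moisture(x, "moisture")
  x
}

#' Convert a time column to seconds
#'
#' @param x Numeric times.
#' @param unit One of `"s"`, `"min"`, `"h"`.
#' @return Times in seconds.
#' @export
time_to_seconds <- function(x, unit = c("s", "min", "h")) {
  unit <- arg_match(unit)
  x * switch(unit, s = 1, min = 60, h = 3600)
}

#' Build a kinetics series from raw measurements
#'
#' Turns a table of per-time-point mass/moisture observations into the
#' mass-transfer series (WL, SG, WR as percent of initial mass) for each
#' treatment. Every treatment must contain exactly one time-0 row, which
#' supplies the initial mass `Wi` and moisture `Xi`; times must be unique
#' within a treatment. Rows are returned sorted by time.
#'
#' @param measurements A data frame with columns `treatment`, a time column,
#'   `mass_g` and `moisture` (fraction or percent; percent is detected and
#'   converted with a warning).
#' @param time_col Name of the time column. Defaults to `"time_h"`.
#' @param time_unit Unit of the time column (`"h"`, `"min"` or `"s"`).
#' @return A tibble with columns `treatment`, `time_s`, `WL_pct`, `SG_pct`,
#'   `WR_pct`, one row per time point, satisfying `WR = WL - SG`.
#' @examples
#' m <- tibble::tibble(
#'   treatment = "atm", time_h = c(0, 0.5),
#'   mass_g = c(100, 80), moisture = c(0.7724, 0.65)
#' )
#' build_kinetics(m)
#' @export
build_kinetics <- function(measurements, time_col = "time_h",
                           time_unit = c("h", "min", "s")) {
  time_unit <- arg_match(time_unit)
  required <- c("treatment", time_col, "mass_g", "moisture")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    abort(paste0("`measurements` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "osmokin_schema_error")
  }
  df <- as_tibble(measurements) %>%
    mutate(
      time_s = time_to_seconds(.data[[time_col]], time_unit),
      moisture = as_moisture_fraction(moisture)
    )

  df %>%
    group_by(treatment) %>%
    group_modify(~ {
      dat <- arrange(.x, time_s)
      if (anyDuplicated(dat$time_s)) {
        abort(sprintf("treatment '%s' has duplicate time points.", .y$treatment),
              class = "osmokin_schema_error")
      }
      n0 <- sum(dat$time_s == 0)
      if (n0 != 1) {
        abort(sprintf(
          "treatment '%s' must have exactly one time-0 row (found %d).",
          .y$treatment, n0), class = "osmokin_schema_error")
      }
      Wi <- dat$mass_g[dat$time_s == 0]
      Xi <- dat$moisture[dat$time_s == 0]
      tibble(
        time_s = dat$time_s,
        WL_pct = compute_water_loss(Wi, Xi, dat$mass_g, dat$moisture),
        SG_pct = compute_solid_gain(Wi, Xi, dat$mass_g, dat$moisture),
        WR_pct = compute_weight_reduction(Wi, dat$mass_g)
      )
    }) %>%
    ungroup()
}

#' Average replicate kinetics
#'
#' Replicate beakers can be aggregated either before or after computing
#' WL/SG; the package computes per row and exposes the mean as an explicit
#' step so the choice is visible.
#'
#' @param kinetics A replicate-level kinetics tibble with `treatment`,
#'   `time_s` and the `WL_pct`/`SG_pct`/`WR_pct` columns (e.g. from
#'   [simulate_kinetics()]).
#' @return One row per treatment and time, values averaged over replicates.
#' @export
aggregate_kinetics <- function(kinetics) {
  kinetics %>%
    group_by(treatment, time_s) %>%
    summarise(across(all_of(c("WL_pct", "SG_pct", "WR_pct")), mean),
              .groups = "drop") %>%
    arrange(treatment, time_s)
}

#' Read and write the package CSV schemas
#'
#' `read_measurements()` reads `treatment,time_h,mass_g,moisture` tables;
#' `read_kinetics()`/`write_kinetics()` handle the derived
#' `treatment,time_s,WL_pct,SG_pct,WR_pct` schema; `read_color()` reads
#' `treatment,time_h,rep,L,a,b` colorimeter tables.
#'
#' @param path File path of a CSV file.
#' @param kinetics A kinetics tibble as produced by [build_kinetics()].
#' @return A tibble (readers) or the input, invisibly (writer).
#' @name osmokin_io
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("treatment", "time_h", "mass_g", "moisture")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "osmokin_schema_error")
  }
  df
}

#' @rdname osmokin_io
#' @export
read_kinetics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("treatment", "time_s", "WL_pct", "SG_pct", "WR_pct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "osmokin_schema_error")
  }
  df
}

#' @rdname osmokin_io
#' @export
write_kinetics <- function(kinetics, path) {
  readr::write_csv(kinetics, path)
  invisible(kinetics)
}

#' @rdname osmokin_io
#' @export
read_color <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("treatment", "time_h", "rep", "L", "a", "b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "osmokin_schema_error")
  }
  df
}
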