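#' CIELAB colour change
#'
#' Euclidean colour difference between a sample and a reference reading:
#' `dE = sqrt(dL^2 + da^2 + db^2)`. This is a metric on CIELAB triples
#' (symmetric, zero iff equal, triangle inequality).
#'
#' @param L_ref,a_ref,b_ref Reference (fresh fruit) CIELAB coordinates.
#' @param L,a,b Sample CIELAB coordinates; vectors are recycled against the
#'   reference.
#' @return A numeric vector of non-negative colour differences.
#' @examples
#' delta_e(31.53, 6.10, 4.43, 27.78, 9.65, 7.71)  # 6.12
#' @export
delta_e <- function(L_ref, a_ref, b_ref, L, a, b) {
  stopifnot(is.numeric(L_ref), is.numeric(a_ref), is.numeric(b_ref),
            is.numeric(L), is.numeric(a), is.numeric(b))
  sqrt((L - L_ref)^2 + (a - a_ref)^2 + (b - b_ref)^2)
}

#' Per-reading colour change table
#'
#' Adds `dL`, `da`, `db` and `dE` columns to a colorimeter table
#' (`treatment, time_h, rep, L, a, b`), relative to a fresh (time-0)
#' reference. Two referencing conventions are supported, since aggregation
#' order matters (mean-of-dE >= dE-of-means by convexity):
#'
#' * `"grand_mean"`: one reference per treatment, the mean of all its
#'   time-0 readings (default);
#' * `"per_rep"`: each repetition is compared with its own time-0 mean.
#'
#' @param color A tibble with columns `treatment`, `time_h`, `rep`, `L`,
#'   `a`, `b` (one row per reading).
#' @param reference `"grand_mean"` or `"per_rep"`.
#' @return The input with `dL`, `da`, `db`, `dE` columns added.
#' @export
color_change <- function(color, reference = c("grand_mean", "per_rep")) {
  reference <- arg_match(reference)
  required <- c("treatment", "time_h", "rep", "L", "a", "b")
  missing_cols <- setdiff(required, names(color))
  if (length(missing_cols) > 0) {
    abort(paste0("`color` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "osmokin_schema_error")
  }
  if (!any(color$time_h == 0)) {
    abort("no time-0 (fresh reference) readings present.",
          class = "osmokin_schema_error")
  }
  ref_keys <- if (reference == "grand_mean") "treatment" else c("treatment", "rep")
  refs <- color %>%
    filter(time_h == 0) %>%
    group_by(across(all_of(ref_keys))) %>%
    summarise(L_ref = mean(L), a_ref = mean(a), b_ref = mean(b),
              .groups = "drop")
  out <- color %>%
    left_join(refs, by = ref_keys) %>%
    mutate(
      dL = L - L_ref, da = a - a_ref, db = b - b_ref,
      dE = delta_e(L_ref, a_ref, b_ref, L, a, b)
    ) %>%
    select(-L_ref, -a_ref, -b_ref)
  as_tibble(out)
}

#' Summarise colour change per treatment and time
#'
#' Reports both aggregation orders: `dE_mean`, the mean of per-reading dE
#' values (the reported statistic), and `dE_of_means`, the dE between the
#' mean CIELAB triple and the reference. By Jensen's inequality
#' `dE_mean >= dE_of_means`.
#'
#' @inheritParams color_change
#' @return A tibble with one row per treatment and time.
#' @export
summarize_color_change <- function(color,
                                   reference = c("grand_mean", "per_rep")) {
  reference <- arg_match(reference)
  cc <- color_change(color, reference)
  per_reading <- cc %>%
    group_by(treatment, time_h) %>%
    summarise(
      L = mean(L), a = mean(a), b = mean(b),
      dE_mean = mean(dE), dE_sd = sd(dE), n_readings = n(),
      dE_of_means = sqrt(mean(dL)^2 + mean(da)^2 + mean(db)^2),
      .groups = "drop"
    )
  per_reading
}

#' Re-express a concentration on the initial fresh-weight basis
#'
#' Osmotic dehydration concentrates constituents: a pigment measured per
#' 100 g of *dehydrated* fruit overstates retention. Multiplying by the
#' remaining mass fraction `(1 - WR/100)` converts to mg per 100 g of
#' *initial* fresh weight, which is the fair comparison with fresh fruit.
#'
#' @param concentration Concentration per 100 g current fresh weight.
#' @param WR_pct Weight reduction in percent, in `[0, 100)`.
#' @return Concentration per 100 g initial fresh weight.
#' @examples
#' to_initial_mass_basis(24.31, 20.61)  # 19.30
#' @export
to_initial_mass_basis <- function(concentration, WR_pct) {
  if (any(!is.finite(WR_pct)) || any(WR_pct < 0) || any(WR_pct >= 100)) {
    abort("`WR_pct` must be in [0, 100).", class = "osmokin_invalid_input")
  }
  concentration * (1 - WR_pct / 100)
}

#' Percent loss of a constituent
#'
#' Relative decrease from an initial to a final value, e.g. titratable
#' acidity dropping from 1.14% to 0.51% malic acid is a 55.3% acid loss.
#'
#' @param initial_value,final_value Values in the same units;
#'   `initial_value` must be non-zero.
#' @return Loss as a percentage of the initial value (negative for a gain).
#' @examples
#' percent_loss(1.14, 0.51)  # 55.26
#' @export
percent_loss <- function(initial_value, final_value) {
  if (any(initial_value == 0)) {
    abort("`initial_value` must be non-zero.", class = "osmokin_invalid_input")
  }
  100 * (initial_value - final_value) / initial_value
}
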