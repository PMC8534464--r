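#' Goodness of fit for kinetic models
#'
#' Standard regression diagnostics used to judge model adequacy:
#' `R^2 = 1 - SS_res/SS_tot` (total sum of squares about the observed mean)
#' and `RMSE = sqrt(mean((obs - pred)^2))`, in the units of the data
#' (percent for WL/SG, dimensionless for ratio-space fits). On constant
#' observed data `SS_tot = 0` and `R^2` is undefined (`NA`).
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A one-row tibble with `r_squared`, `rmse` and `n_points`.
#' @examples
#' od_goodness(c(0, 10, 20), c(1, 10, 19))  # R^2 = 0.99, RMSE = 0.8165
#' @export
od_goodness <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.",
          class = "osmokin_invalid_input")
  }
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  tibble(
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean(res^2)),
    n_points = length(observed)
  )
}

new_od_fit <- function(model, params, data, space, equilibrium = NA_real_,
                       y_inf = NA_real_, radius = NA_real_, n_terms = NA_integer_,
                       flags = character()) {
  quality <- od_goodness(data$observed, data$fitted)
  structure(
    list(model = model, params = params, equilibrium = equilibrium,
         y_inf = y_inf, radius = radius, n_terms = n_terms,
         space = space, quality = quality, data = data, flags = flags),
    class = "od_fit"
  )
}

nls_control_default <- function() {
  minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                             ftol = 1e-15, ptol = 1e-15)
}

extract_xy <- function(data, y, time) {
  t <- dplyr::pull(data, {{ time }})
  yv <- dplyr::pull(data, {{ y }})
  check_time(t)
  if (anyNA(yv) || any(!is.finite(yv))) {
    abort("the response column contains non-finite values.",
          class = "osmokin_invalid_input")
  }
  ord <- order(t)
  list(t = t[ord], y = yv[ord])
}

#' Fit the Peleg model
#'
#' Bounded nonlinear least squares of `Y(t) = t/(k1 + k2 t)` on a WL or SG
#' series in percent, time in seconds. Starting values are deterministic:
#' `k2 = 1/(1.05 max Y)` (equilibrium slightly above the largest
#' observation) and `k1 = t1/Y1` from the first point with positive
#' transfer. The equilibrium estimate is `1/k2`.
#'
#' @param data A data frame holding the series (e.g. one treatment of a
#'   [build_kinetics()] result).
#' @param y Column with the response in percent (unquoted), e.g. `WL_pct`.
#' @param time Column with time in seconds (unquoted); default `time_s`.
#' @return An object of class `od_fit`; see [tidy.od_fit()] and
#'   [glance.od_fit()].
#' @examples
#' d <- tibble::tibble(time_s = c(0, 1800, 3600, 7200, 18000, 36000))
#' d$WL_pct <- peleg_predict(d$time_s, 36.2, 0.017)
#' fit <- fit_peleg(d, WL_pct)
#' tidy(fit)
#' @export
fit_peleg <- function(data, y, time = time_s) {
  xy <- extract_xy(data, {{ y }}, {{ time }})
  t <- xy$t; yv <- xy$y
  if (sum(t > 0) < 3) {
    abort("Peleg fit needs at least 3 points with t > 0.",
          class = "osmokin_fit_failure")
  }
  if (all(yv == 0) || sd(yv) == 0) {
    abort("degenerate data: the response is constant, no kinetics to fit.",
          class = "osmokin_fit_failure")
  }
  i1 <- which(t > 0 & yv > 0)[1]
  if (is.na(i1)) {
    abort("no positive observations; cannot form Peleg starting values.",
          class = "osmokin_fit_failure")
  }
  start <- list(k1 = t[i1] / yv[i1], k2 = 1 / (1.05 * max(yv)))
  fit <- tryCatch(
    minpack.lm::nlsLM(yv ~ t / (k1 + k2 * t), start = start,
                      lower = c(1e-12, 1e-12),
                      control = nls_control_default()),
    error = function(e) {
      abort(paste0("Peleg fit failed to converge: ", conditionMessage(e),
                   sprintf(" (start k1=%.4g, k2=%.4g, n=%d)",
                           start$k1, start$k2, length(t))),
            class = "osmokin_fit_failure")
    }
  )
  p <- coef(fit)
  dat <- tibble(time_s = t, observed = yv,
                fitted = peleg_predict(t, p[["k1"]], p[["k2"]]))
  new_od_fit("peleg", c(k1 = p[["k1"]], k2 = p[["k2"]]), dat,
             space = "percent", equilibrium = 1 / p[["k2"]])
}

#' Fit the Azuara model
#'
#' The default estimator is the model's own linearization: for `t > 0`,
#' `t/Y(t) = 1/(S Yinf) + t/Yinf`, so an ordinary least-squares line of
#' `t/Y` on `t` gives `Yinf = 1/slope` and `S = slope/intercept`. The
#' `"nls"` method fits the hyperbola directly by bounded least squares
#' (started from the linearization) and exists mainly as a cross-check:
#' on model-true data the two agree exactly.
#'
#' @inheritParams fit_peleg
#' @param method `"linearized"` (the classical estimator, default) or
#'   `"nls"`.
#' @return An `od_fit` with parameters `S`, `y_inf` and equilibrium `y_inf`.
#' @export
fit_azuara <- function(data, y, time = time_s,
                       method = c("linearized", "nls")) {
  method <- arg_match(method)
  xy <- extract_xy(data, {{ y }}, {{ time }})
  t <- xy$t; yv <- xy$y
  keep <- t > 0 & yv > 0
  if (sum(keep) < 3) {
    abort("Azuara fit needs at least 3 points with t > 0 and Y > 0.",
          class = "osmokin_fit_failure")
  }
  tl <- t[keep]; zl <- tl / yv[keep]
  line <- lm(zl ~ tl)
  slope <- coef(line)[["tl"]]
  intercept <- coef(line)[["(Intercept)"]]
  if (slope <= 0 || intercept <= 0) {
    abort(sprintf(
      "linearization invalid: t/Y regression gives slope %.4g, intercept %.4g (both must be positive; a non-increasing t/Y trend implies S <= 0).",
      slope, intercept), class = "osmokin_linearization_invalid")
  }
  S <- slope / intercept
  y_inf <- 1 / slope
  if (method == "nls") {
    fit <- tryCatch(
      minpack.lm::nlsLM(yv ~ S * t * y_inf / (1 + S * t),
                        start = list(S = S, y_inf = y_inf),
                        lower = c(1e-12, 1e-12),
                        control = nls_control_default()),
      error = function(e) {
        abort(paste0("Azuara NLS failed to converge: ", conditionMessage(e)),
              class = "osmokin_fit_failure")
      }
    )
    S <- coef(fit)[["S"]]; y_inf <- coef(fit)[["y_inf"]]
  }
  dat <- tibble(time_s = t, observed = yv,
                fitted = azuara_predict(t, S, y_inf))
  new_od_fit("azuara", c(S = S, y_inf = y_inf), dat,
             space = "percent", equilibrium = y_inf)
}

prepare_ratio <- function(t, yv, y_inf, space) {
  if (space == "ratio") {
    if (any(yv <= 0) || any(yv > 1)) {
      abort("ratio-space data must lie in (0, 1].",
            class = "osmokin_invalid_input")
    }
    tibble(time_s = t, ratio = yv)
  } else {
    check_positive(y_inf, "y_inf")
    to_dimensionless(t, yv, y_inf)
  }
}

#' Fit the Page model
#'
#' Least squares of the stretched exponential `exp(-A t^B)` on the
#' dimensionless unaccomplished ratio. When `space = "percent"` the series
#' is first converted with [to_dimensionless()] using `y_inf` (by
#' convention the equilibrium of a prior Peleg fit). Starting values come
#' from the exact log-log linearization `ln(-ln ratio) = ln A + B ln t`.
#'
#' @inheritParams fit_peleg
#' @param y_inf Equilibrium value in percent; required when
#'   `space = "percent"`.
#' @param space `"percent"` if `y` is WL/SG in percent, `"ratio"` if `y`
#'   is already the dimensionless ratio.
#' @return An `od_fit` with parameters `A` and `B`, scored in ratio space.
#' @export
fit_page <- function(data, y, time = time_s, y_inf = NULL,
                     space = c("percent", "ratio")) {
  space <- arg_match(space)
  xy <- extract_xy(data, {{ y }}, {{ time }})
  rat <- prepare_ratio(xy$t, xy$y, y_inf, space)
  t <- rat$time_s; r <- rat$ratio
  interior <- t > 0 & r > 0 & r < 1
  if (sum(interior) < 3) {
    abort("Page fit needs at least 3 points with t > 0 and ratio in (0, 1); a ratio identically 1 means no mass transfer.",
          class = "osmokin_fit_failure")
  }
  ll <- lm(log(-log(r[interior])) ~ log(t[interior]))
  B0 <- max(coef(ll)[[2]], 1e-3)
  A0 <- exp(coef(ll)[[1]])
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ exp(-A * t^B), start = list(A = A0, B = B0),
                      lower = c(1e-12, 1e-12),
                      control = nls_control_default()),
    error = function(e) {
      abort(paste0("Page fit failed to converge: ", conditionMessage(e)),
            class = "osmokin_fit_failure")
    }
  )
  p <- coef(fit)
  flags <- if (p[["A"]] <= 1e-10) "A_at_zero_boundary" else character()
  dat <- tibble(time_s = t, observed = r,
                fitted = page_ratio(t, p[["A"]], p[["B"]]))
  new_od_fit("page", c(A = p[["A"]], B = p[["B"]]), dat,
             space = "ratio", y_inf = y_inf %||% NA_real_, flags = flags)
}

#' Fit the Crank sphere-diffusion model
#'
#' One-dimensional least squares over the effective diffusivity `De` of the
#' truncated Fickian series for a sphere, on the dimensionless ratio. The
#' search is on `log10(De)`, bracketed three decades either side of the
#' first-mode log-linear estimate (`slope of ln(ratio) vs t = -pi^2 De/r^2`),
#' which makes the fit deterministic and scale-free. A solution at the
#' bracket edge is flagged.
#'
#' @inheritParams fit_page
#' @param radius Equivalent sphere radius in meters (see [sphere_radius()]).
#' @param n_terms Number of series terms, default 30.
#' @return An `od_fit` with parameter `De` (m^2 s^-1), scored in ratio space.
#' @export
fit_crank <- function(data, y, time = time_s, y_inf = NULL, radius,
                      n_terms = 30, space = c("percent", "ratio")) {
  space <- arg_match(space)
  check_positive(radius, "radius")
  xy <- extract_xy(data, {{ y }}, {{ time }})
  rat <- prepare_ratio(xy$t, xy$y, y_inf, space)
  t <- rat$time_s; r <- rat$ratio
  interior <- t > 0 & r > 0 & r < 1
  if (sum(interior) < 2) {
    abort("Crank fit needs at least 2 points with t > 0 and ratio in (0, 1).",
          class = "osmokin_fit_failure")
  }
  sl <- coef(lm(log(r[interior]) ~ t[interior]))[[2]]
  if (sl >= 0) {
    abort("ratio does not decay with time; cannot form a diffusivity starting value.",
          class = "osmokin_fit_failure")
  }
  De0 <- -sl * radius^2 / pi^2
  sse <- function(l10) {
    sum((r - crank_ratio(t, 10^l10, radius, n_terms = n_terms))^2)
  }
  bracket <- log10(De0) + c(-3, 3)
  opt <- optimize(sse, interval = bracket, tol = 1e-10)
  De <- 10^opt$minimum
  flags <- if (min(abs(opt$minimum - bracket)) < 1e-3) "De_at_search_bound"
           else character()
  dat <- tibble(time_s = t, observed = r,
                fitted = crank_ratio(t, De, radius, n_terms = n_terms))
  new_od_fit("crank", c(De = De), dat, space = "ratio",
             y_inf = y_inf %||% NA_real_, radius = radius,
             n_terms = as.integer(n_terms), flags = flags)
}

od_fit_one <- function(model, data, ycol, y_inf = NULL, radius = NULL,
                       n_terms = 30) {
  switch(model,
    peleg  = fit_peleg(data, ycol),
    azuara = fit_azuara(data, ycol),
    page   = fit_page(data, ycol, y_inf = y_inf),
    crank  = fit_crank(data, ycol, y_inf = y_inf, radius = radius,
                       n_terms = n_terms),
    abort(sprintf("unknown model '%s'.", model),
          class = "osmokin_invalid_input")
  )
}

#' Fit and rank all four kinetic models
#'
#' Fits Peleg, Azuara (linearized), Page and Crank to each requested
#' quantity of each treatment and ranks the models by `R^2` (ties broken
#' by percent-scale RMSE). The equilibrium needed by the ratio-space
#' models (Page, Crank) is taken from the Peleg fit by default. Individual
#' fit failures do not abort the comparison; the failing model is ranked
#' out with its error message.
#'
#' @param kinetics A kinetics tibble (`treatment`, `time_s`, `WL_pct`,
#'   `SG_pct`, ...), e.g. from [build_kinetics()] or [aggregate_kinetics()].
#' @param radius Equivalent sphere radius in meters, for the Crank model.
#' @param n_terms Crank series terms, default 30.
#' @param quantities Response columns to fit, default `WL_pct` and `SG_pct`.
#' @param y_inf_source Which fitted equilibrium feeds the dimensionless
#'   transform: `"peleg"` (default) or `"azuara"`.
#' @return An object of class `od_model_comparison`: a list with `summary`
#'   (one row per treatment x quantity x model, ranked) and `fits` (the
#'   underlying `od_fit` objects).
#' @export
compare_models <- function(kinetics, radius, n_terms = 30,
                           quantities = c("WL_pct", "SG_pct"),
                           y_inf_source = c("peleg", "azuara")) {
  y_inf_source <- arg_match(y_inf_source)
  check_positive(radius, "radius")
  stopifnot(all(c("treatment", "time_s") %in% names(kinetics)))
  quantities <- intersect(quantities, names(kinetics))
  if (length(quantities) == 0) {
    abort("none of the requested quantity columns are present.",
          class = "osmokin_schema_error")
  }
  grid <- tidyr::expand_grid(
    treatment = unique(kinetics$treatment),
    quantity = quantities
  )
  models <- c("peleg", "azuara", "page", "crank")
  fits <- list()
  rows <- pmap(grid, function(treatment, quantity) {
    dat <- kinetics[kinetics$treatment == treatment, ]
    peleg <- tryCatch(od_fit_one("peleg", dat, quantity), error = identity)
    azuara <- tryCatch(od_fit_one("azuara", dat, quantity), error = identity)
    y_inf <- if (y_inf_source == "peleg") {
      if (inherits(peleg, "od_fit")) peleg$equilibrium else NA_real_
    } else {
      if (inherits(azuara, "od_fit")) azuara$equilibrium else NA_real_
    }
    res <- list(peleg = peleg, azuara = azuara)
    for (m in c("page", "crank")) {
      res[[m]] <- if (is.na(y_inf)) {
        simpleError("no equilibrium available for the dimensionless transform")
      } else {
        tryCatch(od_fit_one(m, dat, quantity, y_inf = y_inf,
                            radius = radius, n_terms = n_terms),
                 error = identity)
      }
    }
    for (m in models) {
      fits[[paste(treatment, quantity, m, sep = ".")]] <<- res[[m]]
    }
    map(models, function(m) {
      f <- res[[m]]
      if (inherits(f, "od_fit")) {
        pct <- percent_scale_quality(f, dat, quantity)
        tibble(
          treatment = treatment, quantity = quantity, model = m,
          r_squared = f$quality$r_squared, rmse = f$quality$rmse,
          rmse_pct = pct, equilibrium = f$equilibrium,
          y_inf_used = f$y_inf, error = NA_character_
        )
      } else {
        tibble(
          treatment = treatment, quantity = quantity, model = m,
          r_squared = NA_real_, rmse = NA_real_, rmse_pct = NA_real_,
          equilibrium = NA_real_, y_inf_used = NA_real_,
          error = conditionMessage(f)
        )
      }
    }) %>% list_rbind()
  })
  summary <- list_rbind(rows) %>%
    group_by(treatment, quantity) %>%
    mutate(rank = rank_fits(r_squared, rmse_pct)) %>%
    ungroup() %>%
    arrange(treatment, quantity, rank)
  params <- map(fits, function(f) {
    if (inherits(f, "od_fit")) as.list(f$params) else list()
  })
  structure(list(summary = summary, fits = fits, params = params),
            class = "od_model_comparison")
}

# rank by R^2 (desc), ties by percent-scale RMSE (asc); failures last
rank_fits <- function(r2, rmse_pct) {
  ord <- order(-ifelse(is.na(r2), -Inf, r2), ifelse(is.na(rmse_pct), Inf, rmse_pct))
  out <- integer(length(r2))
  out[ord] <- seq_along(r2)
  out
}

# RMSE of a fit re-expressed on the percent scale of the raw series, so
# percent- and ratio-space fits are comparable
percent_scale_quality <- function(fit, dat, ycol) {
  obs <- dat[[ycol]][order(dat$time_s)]
  if (fit$space == "percent") {
    return(fit$quality$rmse)
  }
  pred_pct <- fit$y_inf * (1 - fit$data$fitted)
  sqrt(mean((obs - pred_pct)^2))
}

#' @export
print.od_model_comparison <- function(x, ...) {
  cat("Kinetic model comparison (rank 1 = best R^2 per treatment/quantity)\n")
  print(x$summary, ...)
  invisible(x)
}
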