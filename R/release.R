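#' Fit a UV calibration line
#'
#' Ordinary least squares of absorbance on concentration (Beer-Lambert
#' linearity). The slope must come out positive for the calibration to be
#' usable for inversion.
#'
#' @param concentrations_mg_ml standard concentrations, mg/mL.
#' @param absorbances measured absorbances (same length).
#' @param wavelength_nm analytical wavelength, stored as metadata.
#' @return a `calibration_fit` with `slope`, `intercept`, `r_squared`,
#'   `wavelength_nm`.
#' @examples
#' conc <- c(0.1, 0.2, 0.4, 0.5, 0.6, 0.8, 1.0)
#' fit_calibration(conc, 0.5831 * conc - 0.0169)
#' @export
fit_calibration <- function(concentrations_mg_ml, absorbances,
                            wavelength_nm = 276.5) {
  if (length(unique(concentrations_mg_ml)) < 3) {
    stop_input("calibration needs >= 3 distinct concentration levels")
  }
  stopifnot(length(concentrations_mg_ml) == length(absorbances))
  fit <- lm(absorbances ~ concentrations_mg_ml)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 1e-6) {
    warn("calibration slope is ~0 or negative; curve flagged unusable")
  }
  new_calibration_fit(slope = slope, intercept = unname(coef(fit)[1]),
                      r_squared = r_squared(absorbances, stats::fitted(fit)),
                      wavelength_nm = wavelength_nm)
}

new_calibration_fit <- function(slope, intercept, r_squared, wavelength_nm) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, wavelength_nm = wavelength_nm),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration at %.1f nm: A = %.4f*C %+.4f (R2 = %.4f)\n",
              x$wavelength_nm, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a calibration line: absorbance to concentration
#'
#' `(A - intercept)/slope`; negative results (absorbance below the blank
#' line) are floored at zero with a warning.
#'
#' @param absorbance absorbance reading(s).
#' @param calib a `calibration_fit`.
#' @return concentration(s) in mg/mL.
#' @export
absorbance_to_conc <- function(absorbance, calib) {
  stopifnot(inherits(calib, "calibration_fit"))
  if (!is.finite(calib$slope) || calib$slope <= 0) {
    stop_input("calibration slope must be > 0")
  }
  conc <- (absorbance - calib$intercept) / calib$slope
  if (any(conc < 0)) {
    warn("negative concentration(s) floored at 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Describe an enhancer-cell release experiment
#'
#' Geometry and schedule of the in-vitro release test: a semisolid holder
#' (enhancer cell) with a fixed exposed orifice sits in a stirred acceptor
#' vessel; at scheduled times an aliquot is withdrawn for assay and replaced
#' with fresh medium.
#'
#' @param times_min sampling schedule, strictly increasing (default the
#'   standard 15, 30, 60, 90, 120, 150 min).
#' @param vessel_volume_ml acceptor volume (default 50 mL).
#' @param sample_volume_ml withdrawn/replaced aliquot (default 3 mL).
#' @param orifice_area_cm2 exposed release area (default 3.8 cm2).
#' @param loaded_dose_mg drug mass loaded in the cell (concentration in mg/g
#'   times the ~1 g fill).
#' @param temperature_c bath temperature (default 32 C, skin surface).
#' @return a `release_experiment` list.
#' @export
release_experiment <- function(times_min = c(15, 30, 60, 90, 120, 150),
                               vessel_volume_ml = 50, sample_volume_ml = 3,
                               orifice_area_cm2 = 3.8, loaded_dose_mg = NULL,
                               temperature_c = 32) {
  if (is.unsorted(times_min, strictly = TRUE) || any(times_min <= 0)) {
    stop_input("times_min must be positive and strictly increasing")
  }
  check_number(vessel_volume_ml, "vessel_volume_ml", positive = TRUE)
  check_number(sample_volume_ml, "sample_volume_ml", positive = TRUE)
  if (sample_volume_ml >= vessel_volume_ml) {
    stop_input("sample volume must be smaller than the vessel volume")
  }
  check_number(orifice_area_cm2, "orifice_area_cm2", positive = TRUE)
  if (!is.null(loaded_dose_mg)) check_number(loaded_dose_mg, "loaded_dose_mg",
                                             positive = TRUE)
  structure(list(times_min = times_min, vessel_volume_ml = vessel_volume_ml,
                 sample_volume_ml = sample_volume_ml,
                 orifice_area_cm2 = orifice_area_cm2,
                 loaded_dose_mg = loaded_dose_mg,
                 temperature_c = temperature_c),
            class = "release_experiment")
}

#' Cumulative release per unit area with withdrawal correction
#'
#' Each sampling removes analyte with the aliquot and dilutes the vessel by
#' the water replaced, so measured concentrations underestimate cumulative
#' release. The standard sampling-and-replacement mass balance
#' `Q_n = (C_n*V + sum_{i<n} C_i*V_s) / A` restores the true cumulative
#' amount released per unit orifice area; it exactly inverts the withdrawal
#' process.
#'
#' @param concs_mg_ml vessel concentrations at the schedule times, mg/mL.
#' @param exp a [release_experiment()].
#' @param tol relative tolerance beyond which a decrease in Q is flagged
#'   (default 1e-6; measured profiles with noise warrant a looser value).
#' @return a tibble (`release_profile`) with `time_min` and `q_mg_cm2`.
#' @export
cumulative_release <- function(concs_mg_ml, exp, tol = 1e-6) {
  stopifnot(inherits(exp, "release_experiment"))
  if (length(concs_mg_ml) != length(exp$times_min)) {
    stop_input("got %d concentrations for %d scheduled times",
               length(concs_mg_ml), length(exp$times_min))
  }
  if (any(concs_mg_ml < 0)) stop_input("concentrations must be >= 0")
  v <- exp$vessel_volume_ml; vs <- exp$sample_volume_ml
  removed <- c(0, cumsum(concs_mg_ml * vs)[-length(concs_mg_ml)])
  q <- (concs_mg_ml * v + removed) / exp$orifice_area_cm2
  if (any(diff(q) < -tol * pmax(head(q, -1), .Machine$double.eps))) {
    warn("corrected cumulative release is not monotonically non-decreasing")
  }
  if (!is.null(exp$loaded_dose_mg) &&
      any(q * exp$orifice_area_cm2 > exp$loaded_dose_mg * (1 + 1e-6))) {
    warn("corrected cumulative release exceeds the loaded dose")
  }
  structure(tibble(time_min = exp$times_min, q_mg_cm2 = q),
            class = c("release_profile", "tbl_df", "tbl", "data.frame"))
}

# model forms (q_inf in mg/cm2):
#   zero      Q = k0 * t
#   first     Q = q_inf * (1 - exp(-k1 t))
#   higuchi   Q = kH * sqrt(t)           (window 15-150 min, through origin)
#   kp        Q/q_inf = kKP * t^n        (restricted to Q/q_inf <= 0.6)
#   weibull   Q/q_inf = 1 - exp(-(t/tau_d)^beta)
release_models <- c("zero", "first", "higuchi", "korsmeyer_peppas", "weibull")

#' Fit a kinetic release model to a cumulative profile
#'
#' Model forms and fitting strategy: zero-order `Q = k0*t` and Higuchi
#' `Q = kH*sqrt(t)` are through-origin least squares (the Higuchi fit is
#' restricted to its conventional 15–150 min window by default); first-order
#' `Q = Qinf*(1 - exp(-k1*t))` minimizes SSE over k1 by golden-section
#' search; Korsmeyer-Peppas fits `log(Q/Qinf) = log(kKP) + n*log(t)` on the
#' points with fractional release at or below 0.6; Weibull fits
#' `log(-log(1 - Q/Qinf)) = beta*log(t) - beta*log(tau_d)`. R2 is always
#' reported about the mean on the original Q scale, so a constrained or
#' misspecified model can score below zero.
#'
#' @param profile a [cumulative_release()] result or tibble with `time_min`,
#'   `q_mg_cm2`.
#' @param model one of `"zero"`, `"first"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`, `"weibull"`.
#' @param q_inf asymptotic release per area (mg/cm2); required for the
#'   first-order, Korsmeyer-Peppas and Weibull models. The usual choice is
#'   loaded dose / orifice area.
#' @param higuchi_window fitting window in minutes for the Higuchi model.
#' @param higuchi_origin fit Higuchi through the origin (default TRUE); the
#'   intercept-allowed variant is available for diagnostics.
#' @return a `kinetic_fit` with `model`, `params` (named list), `r_squared`,
#'   `n` and `q_inf` (when used).
#' @export
fit_release_model <- function(profile, model = release_models, q_inf = NULL,
                              higuchi_window = c(15, 150),
                              higuchi_origin = TRUE) {
  model <- match.arg(model)
  t <- profile$time_min; q <- profile$q_mg_cm2
  needs_qinf <- model %in% c("first", "korsmeyer_peppas", "weibull")
  if (needs_qinf && is.null(q_inf)) {
    stop_input("model '%s' requires q_inf", model)
  }
  fitted_of <- NULL
  params <- list()
  n_used <- length(t)
  switch(model,
    zero = {
      k0 <- sum(q * t) / sum(t^2)
      params <- list(k0 = k0)
      fitted_of <- function(t) k0 * t
    },
    higuchi = {
      keep <- t >= higuchi_window[1] & t <= higuchi_window[2]
      if (sum(keep) < 3) stop_input("Higuchi window holds < 3 points")
      tw <- t[keep]; qw <- q[keep]
      n_used <- sum(keep)
      if (higuchi_origin) {
        kh <- sum(qw * sqrt(tw)) / sum(tw)
        params <- list(kH = kh, intercept = 0)
        fitted_of <- function(t) kh * sqrt(t)
      } else {
        fit <- lm(qw ~ sqrt(tw))
        params <- list(kH = unname(coef(fit)[2]),
                       intercept = unname(coef(fit)[1]))
        fitted_of <- function(t) params$intercept + params$kH * sqrt(t)
      }
      t <- tw; q <- qw
    },
    first = {
      sse <- function(k1) sum((q - q_inf * (1 - exp(-k1 * t)))^2)
      # bracket: from near-zero to fast-depletion rates
      opt <- optimize(sse, interval = c(1e-8, 10 / min(t)), tol = 1e-12)
      k1 <- opt$minimum
      params <- list(k1 = k1)
      fitted_of <- function(t) q_inf * (1 - exp(-k1 * t))
    },
    korsmeyer_peppas = {
      frac <- q / q_inf
      keep <- frac > 0 & frac <= 0.6
      if (sum(keep) < 3) {
        stop_input("Korsmeyer-Peppas needs >= 3 points with Q/Qinf in (0, 0.6]")
      }
      n_used <- sum(keep)
      fit <- lm(log(frac[keep]) ~ log(t[keep]))
      params <- list(kKP = exp(unname(coef(fit)[1])),
                     n = unname(coef(fit)[2]))
      fitted_of <- function(t) q_inf * params$kKP * t^params$n
      t <- t[keep]; q <- q[keep]
    },
    weibull = {
      frac <- q / q_inf
      keep <- frac > 0 & frac < 1
      if (sum(keep) < 3) {
        stop_input("Weibull needs >= 3 points with Q/Qinf in (0, 1)")
      }
      n_used <- sum(keep)
      y <- log(-log(1 - frac[keep]))
      fit <- lm(y ~ log(t[keep]))
      beta <- unname(coef(fit)[2])
      tau_d <- exp(-unname(coef(fit)[1]) / beta)
      params <- list(beta = beta, tau_d = tau_d)
      fitted_of <- function(t) q_inf * (1 - exp(-(t / tau_d)^beta))
      t <- t[keep]; q <- q[keep]
    }
  )
  structure(list(model = model, params = params,
                 r_squared = r_squared(q, fitted_of(t)),
                 q_inf = if (needs_qinf) q_inf else NULL,
                 n = n_used, fitted = fitted_of),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  p <- paste(sprintf("%s = %.5g", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("Kinetic fit [%s]: %s; R2 = %.4f (n = %d)\n",
              x$model, p, x$r_squared, x$n))
  invisible(x)
}

#' Fit and rank all five kinetic models on one profile
#'
#' @inheritParams fit_release_model
#' @return list with `table` (tibble: model, parameter summary, R2, rank)
#'   and `fits` (named list of `kinetic_fit`s). The best model (highest R2)
#'   ranks 1. Profiles with only 3 points trigger a degrees-of-freedom
#'   warning but are still ranked.
#' @export
compare_models <- function(profile, q_inf, higuchi_window = c(15, 150)) {
  if (nrow(profile) <= 3) {
    warn("3 or fewer profile points: model ranking has ~no spare degrees of freedom")
  }
  fits <- lapply(release_models, function(m) {
    tryCatch(fit_release_model(profile, m, q_inf = q_inf,
                               higuchi_window = higuchi_window),
             error = function(e) NULL)
  })
  names(fits) <- release_models
  ok <- !vapply(fits, is.null, logical(1))
  tab <- tibble(
    model = release_models[ok],
    params = vapply(fits[ok], function(f) {
      paste(sprintf("%s=%.4g", names(f$params), unlist(f$params)),
            collapse = ", ")
    }, character(1)),
    r_squared = vapply(fits[ok], function(f) f$r_squared, numeric(1))
  )
  tab$rank <- rank(-tab$r_squared, ties.method = "min")
  tab <- tab[order(tab$rank), ]
  list(table = tab, fits = fits, best = tab$model[1])
}

#' Compare release rates across formulations
#'
#' Summarizes replicate rate estimates per formulation (mean, SD, n) and runs
#' Welch's two-sample t-test on every formulation pair. With a single
#' replicate in a group the summary is still produced but no test involving
#' that group is attempted.
#'
#' @param rates tibble with columns `formulation_id` and `rate` (one row per
#'   replicate fit), or a named list of numeric vectors.
#' @return list with `summary` (per-formulation tibble) and `tests`
#'   (pairwise tibble with t statistic and two-sided p).
#' @export
release_rate_comparison <- function(rates) {
  if (is.list(rates) && !is.data.frame(rates)) {
    rates <- dplyr::bind_rows(lapply(names(rates), function(id) {
      tibble(formulation_id = id, rate = rates[[id]])
    }))
  }
  rates <- as_tibble(rates)
  if (!all(c("formulation_id", "rate") %in% names(rates)) || nrow(rates) == 0) {
    stop_input("rates must have columns formulation_id, rate and >= 1 row")
  }
  smry <- dplyr::summarise(dplyr::group_by(rates, .data$formulation_id),
                           mean = mean(.data$rate),
                           sd = sd(.data$rate),
                           n = dplyr::n(), .groups = "drop")
  ids <- smry$formulation_id
  tests <- NULL
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    tests <- dplyr::bind_rows(apply(pairs, 2, function(pr) {
      a <- rates$rate[rates$formulation_id == pr[1]]
      b <- rates$rate[rates$formulation_id == pr[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble(group_a = pr[1], group_b = pr[2],
                      t = NA_real_, p_value = NA_real_))
      }
      wt <- welch_t(a, b)
      tibble(group_a = pr[1], group_b = pr[2], t = wt$t, p_value = wt$p_value)
    }))
  }
  list(summary = smry, tests = tests)
}
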