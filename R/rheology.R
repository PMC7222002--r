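#' Build a flow curve from a shear-ramp experiment
#'
#' A flow test ramps the shear rate up (100 to 1100 1/s in the standard
#' protocol) and back down while recording shear stress. For a thixotropic
#' material the structure broken down on the way up has not recovered on the
#' way down, so the descending branch lies below the ascending one and the
#' two enclose a hysteresis loop.
#'
#' @param data data frame with columns `shear_rate_s1`, `shear_stress_pa`,
#'   `phase` (`"ascending"`/`"descending"`).
#' @param temperature_c measurement temperature, deg C.
#' @param formulation_id optional label.
#' @return a `flow_curve` tibble with attributes.
#' @export
flow_curve <- function(data, temperature_c = 25, formulation_id = "sample") {
  data <- as_tibble(data)
  req <- c("shear_rate_s1", "shear_stress_pa", "phase")
  if (!all(req %in% names(data))) {
    stop_input("flow data needs columns: %s", paste(req, collapse = ", "))
  }
  if (!all(data$phase %in% c("ascending", "descending"))) {
    stop_input("phase must be 'ascending' or 'descending'")
  }
  if (any(data$shear_rate_s1 <= 0)) stop_input("shear rates must be > 0")
  up <- data[data$phase == "ascending", ]
  dn <- data[data$phase == "descending", ]
  if (nrow(up) && is.unsorted(up$shear_rate_s1)) {
    stop_input("ascending-phase rates must be non-decreasing")
  }
  if (nrow(dn) && is.unsorted(rev(dn$shear_rate_s1))) {
    stop_input("descending-phase rates must be non-increasing")
  }
  structure(data, temperature_c = temperature_c,
            formulation_id = formulation_id,
            class = c("flow_curve", class(data)))
}

#' Summarize step-rate viscosity replicates
#'
#' The step test holds the sample at fixed shear rates (300, 700, 1100 1/s in
#' the standard protocol) and records viscosity; replicates are summarized as
#' mean +/- sample SD per formulation x temperature x rate cell. A cell whose
#' mean viscosity falls with increasing rate marks shear-thinning behaviour.
#'
#' @param readings data frame with columns `formulation_id`, `temperature_c`,
#'   `shear_rate_s1`, `viscosity_mpas` (one row per replicate reading).
#' @return tibble with per-cell `viscosity_mean`, `viscosity_sd`, `n` and a
#'   per formulation x temperature logical `shear_thinning`.
#' @export
summarize_step_viscosity <- function(readings) {
  readings <- as_tibble(readings)
  req <- c("formulation_id", "temperature_c", "shear_rate_s1", "viscosity_mpas")
  if (!all(req %in% names(readings))) {
    stop_input("viscosity readings need columns: %s", paste(req, collapse = ", "))
  }
  if (any(readings$viscosity_mpas <= 0)) stop_input("viscosity must be > 0")
  out <- dplyr::summarise(
    dplyr::group_by(readings, .data$formulation_id, .data$temperature_c,
                    .data$shear_rate_s1),
    viscosity_mean = mean(.data$viscosity_mpas),
    viscosity_sd = sd(.data$viscosity_mpas),
    n = dplyr::n(), .groups = "drop"
  )
  if (any(out$n < 2)) {
    bad <- out[out$n < 2, ]
    stop_input("need >= 2 replicates per cell; single reading for %s at %g C, %g 1/s",
               bad$formulation_id[1], bad$temperature_c[1], bad$shear_rate_s1[1])
  }
  flags <- dplyr::summarise(
    dplyr::group_by(out, .data$formulation_id, .data$temperature_c),
    shear_thinning = all(diff(.data$viscosity_mean[order(.data$shear_rate_s1)]) < 0),
    .groups = "drop"
  )
  dplyr::left_join(out, flags, by = c("formulation_id", "temperature_c"))
}

#' Ratio of viscosities between two temperatures
#'
#' Quantifies how strongly warming (e.g. from 25 C storage to 32 C skin
#' temperature) thins a formulation at a given shear rate.
#'
#' @param table a summary with columns `formulation_id`, `temperature_c`,
#'   `shear_rate_s1`, `viscosity_mean` ([summarize_step_viscosity()] output
#'   or [reference_viscosity()]).
#' @param formulation formulation_id to look up.
#' @param rate shear rate in 1/s.
#' @param temperatures numeric length-2 `(numerator, denominator)`, default
#'   `c(25, 32)`.
#' @return ratio of mean viscosities.
#' @export
temperature_ratio <- function(table, formulation, rate, temperatures = c(25, 32)) {
  pick <- function(tc) {
    v <- table$viscosity_mean[table$formulation_id == formulation &
                                table$temperature_c == tc &
                                table$shear_rate_s1 == rate]
    if (length(v) != 1 || !is.finite(v)) {
      stop_input("no viscosity cell for %s at %g C, %g 1/s", formulation, tc, rate)
    }
    v
  }
  pick(temperatures[1]) / pick(temperatures[2])
}

#' Fit a yield-stress flow model to the ascending branch
#'
#' Two variants of the Casson-type yield-stress description are available.
#' `"linear"` fits `tau = tau_y + eta*gammadot` by ordinary least squares —
#' algebraically the Bingham plastic form, and the form in which the model is
#' often quoted for semi-solids. `"square_root"` fits the conventional Casson
#' law `sqrt(tau) = sqrt(tau_y) + sqrt(eta*gammadot)`, linear in
#' `sqrt(gammadot)` after the square-root transform. In both variants the
#' yield stress is clipped at zero.
#'
#' @param curve a [flow_curve()].
#' @param variant `"linear"` (default) or `"square_root"`.
#' @return a `casson_fit` with `tau_y` (Pa), `eta` (Pa·s), `r_squared`
#'   (computed on the stress scale) and `variant`.
#' @export
fit_casson <- function(curve, variant = c("linear", "square_root")) {
  variant <- match.arg(variant)
  up <- curve[curve$phase == "ascending", ]
  if (nrow(up) < 3) stop_input("need >= 3 ascending-phase points")
  if (length(unique(up$shear_rate_s1)) < 2) {
    stop_input("singular design: all ascending points at one shear rate")
  }
  g <- up$shear_rate_s1; tau <- up$shear_stress_pa
  if (variant == "linear") {
    fit <- lm(tau ~ g)
    tau_y <- max(0, unname(coef(fit)[1]))
    eta <- unname(coef(fit)[2])
    fitted_tau <- tau_y + eta * g
  } else {
    if (any(tau < 0)) stop_input("square-root variant needs non-negative stresses")
    fit <- lm(sqrt(tau) ~ sqrt(g))
    tau_y <- max(0, unname(coef(fit)[1]))^2
    eta <- unname(coef(fit)[2])^2
    fitted_tau <- (sqrt(tau_y) + sqrt(eta * g))^2
  }
  if (is.na(eta) || eta <= 0) {
    warn("fitted consistency eta is not positive; flow curve may be degenerate")
  }
  structure(
    list(tau_y = tau_y, eta = eta,
         r_squared = r_squared(tau, fitted_tau),
         variant = variant, n = nrow(up),
         temperature_c = attr(curve, "temperature_c"),
         formulation_id = attr(curve, "formulation_id")),
    class = "casson_fit"
  )
}

#' @export
print.casson_fit <- function(x, ...) {
  cat(sprintf(
    "Yield-stress fit (%s): tau_y = %.4g Pa, eta = %.4g Pa.s, R2 = %.4f (n = %d)\n",
    x$variant, x$tau_y, x$eta, x$r_squared, x$n))
  invisible(x)
}

#' Hysteresis-loop area between ascending and descending flow branches
#'
#' The loop area on the rate–stress plane is the standard thixotropy measure:
#' the descending branch is interpolated onto the ascending branch's rate
#' grid over the shared rate interval and `integral (tau_up - tau_down)
#' d(gammadot)` is taken by the trapezoidal rule. Positive area (ascending
#' branch above descending) indicates thixotropy; negative area is flagged
#' anti-thixotropic.
#'
#' @param curve a [flow_curve()] with both phases.
#' @return number with class `hysteresis_area`: loop area in Pa/s, with an
#'   attribute `behaviour` of `"thixotropic"`, `"anti-thixotropic"` or
#'   `"reversible"` (|area| below `tol`).
#' @param tol absolute area below which the loop is called reversible.
#' @export
hysteresis_area <- function(curve, tol = 1e-8) {
  up <- curve[curve$phase == "ascending", ]
  dn <- curve[curve$phase == "descending", ]
  if (nrow(up) < 2 || nrow(dn) < 2) stop_input("both phases need >= 2 points")
  lo <- max(min(up$shear_rate_s1), min(dn$shear_rate_s1))
  hi <- min(max(up$shear_rate_s1), max(dn$shear_rate_s1))
  if (lo >= hi) stop_input("ascending and descending rate ranges do not overlap")
  grid <- sort(unique(up$shear_rate_s1[up$shear_rate_s1 >= lo &
                                         up$shear_rate_s1 <= hi]))
  if (!lo %in% grid) grid <- c(lo, grid)
  if (!hi %in% grid) grid <- c(grid, hi)
  tau_up <- approx(up$shear_rate_s1, up$shear_stress_pa, xout = grid,
                   ties = mean)$y
  dn_ord <- dn[order(dn$shear_rate_s1), ]
  tau_dn <- approx(dn_ord$shear_rate_s1, dn_ord$shear_stress_pa, xout = grid,
                   ties = mean)$y
  area <- trapz(grid, tau_up - tau_dn)
  behaviour <- if (abs(area) <= tol) "reversible"
  else if (area > 0) "thixotropic" else "anti-thixotropic"
  structure(area, behaviour = behaviour, class = "hysteresis_area")
}

#' @export
print.hysteresis_area <- function(x, ...) {
  cat(sprintf("Hysteresis loop area: %.6g Pa/s (%s)\n",
              unclass(x), attr(x, "behaviour")))
  invisible(x)
}

#' Compare thixotropy between two temperatures
#'
#' @param areas_25,areas_32 named numeric vectors of loop areas per
#'   formulation at the two temperatures (names = formulation ids, matched).
#' @return tibble with per-formulation areas, `ratio` (32 C over 25 C, NA
#'   when the 25 C loop is zero) and the rank ordering by 25 C area
#'   (1 = largest loop).
#' @export
compare_thixotropy <- function(areas_25, areas_32) {
  ids <- names(areas_25)
  if (is.null(ids) || is.null(names(areas_32))) {
    stop_input("areas must be named by formulation")
  }
  if (!setequal(ids, names(areas_32))) {
    stop_input("the two temperature sets name different formulations")
  }
  a25 <- as.numeric(areas_25[ids])
  a32 <- as.numeric(areas_32[ids])
  ratio <- ifelse(a25 == 0, NA_real_, a32 / a25)
  tibble(formulation_id = ids, area_25 = a25, area_32 = a32,
         ratio = ratio,
         rank_25 = rank(-a25, ties.method = "min"))
}
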