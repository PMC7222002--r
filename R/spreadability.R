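#' Build a spreadability curve from parallel-plate measurements
#'
#' In the parallel-plate spreading test a fixed volume of ointment is placed
#' between two glass plates; the upper plate (298.0 g here) rests on the
#' sample and calibrated weights are added stepwise (20–500 g). After each
#' step the sample diameter is read. The total load acting on the sample is
#' the plate mass plus the added weights.
#'
#' @param data data frame with columns `replicate`, `added_mass_g`,
#'   `diameter_cm` (optionally `formulation_id`).
#' @param formulation_id label for the formulation; taken from `data` if
#'   present there.
#' @param plate_mass_g mass of the upper plate in grams (default 298).
#' @return A `spreadability_curve`: the validated tibble with attributes
#'   `formulation_id` and `plate_mass_g`.
#' @export
spreadability_curve <- function(data, formulation_id = NULL, plate_mass_g = 298) {
  data <- as_tibble(data)
  req <- c("replicate", "added_mass_g", "diameter_cm")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop_input("spreadability data is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  check_number(plate_mass_g, "plate_mass_g", positive = TRUE)
  if (is.null(formulation_id)) {
    formulation_id <- if ("formulation_id" %in% names(data)) {
      unique(data$formulation_id)[1]
    } else "sample"
  }
  bad <- which(!is.finite(data$diameter_cm) | data$diameter_cm <= 0)
  if (length(bad)) {
    stop_input("non-positive diameter at row(s) %s", paste(bad, collapse = ", "))
  }
  if (any(data$added_mass_g < 0)) stop_input("added_mass_g must be >= 0")
  for (r in split(data, data$replicate)) {
    if (is.unsorted(r$added_mass_g, strictly = TRUE)) {
      stop_input("added_mass_g must be strictly increasing within replicate %s",
                 r$replicate[1])
    }
  }
  if (length(unique(data$added_mass_g)) < 3) {
    stop_input("at least 3 load steps are required")
  }
  structure(data,
            formulation_id = formulation_id,
            plate_mass_g = plate_mass_g,
            class = c("spreadability_curve", class(data)))
}

#' Convert spread diameters to mean sample areas per load
#'
#' Each diameter reading becomes a circle area pi*(d/2)^2; areas are averaged
#' over replicates at each load step. Loads are reported as total applied
#' mass, i.e. plate mass plus added weights.
#'
#' @param curve a [spreadability_curve()].
#' @return tibble with `load_g` (total mass), `area_cm2` (replicate mean) and
#'   `n` (replicates contributing).
#' @examples
#' d <- data.frame(replicate = 1, added_mass_g = c(0, 20, 50),
#'                 diameter_cm = c(2, 2.2, 2.5))
#' diameters_to_areas(spreadability_curve(d))
#' @export
diameters_to_areas <- function(curve) {
  stopifnot(inherits(curve, "spreadability_curve"))
  plate <- attr(curve, "plate_mass_g")
  dat <- tibble(load_g = plate + curve$added_mass_g,
                area_cm2 = pi * (curve$diameter_cm / 2)^2)
  dplyr::summarise(dplyr::group_by(dat, .data$load_g),
                   area_cm2 = mean(.data$area_cm2),
                   n = dplyr::n(), .groups = "drop")
}

#' Fit the logarithmic spreading law area = a*ln(load) + b
#'
#' The spreading of a semi-solid under increasing load follows a log law in
#' the total applied mass: sample area grows as `a*ln(x) + b`. The fit is
#' ordinary least squares of mean area on ln(load).
#'
#' @param areas tibble from [diameters_to_areas()] (columns `load_g`,
#'   `area_cm2`), or any data frame with those columns.
#' @param load_range optional numeric length-2 restricting which loads enter
#'   the fit; also stored on the result as the default integration range.
#' @return A `log_spread_fit` with elements `a` (cm2 per ln g), `b` (cm2),
#'   `r_squared`, `load_range` and `data` (the fitted points).
#' @export
fit_log_spread <- function(areas, load_range = NULL) {
  areas <- as_tibble(areas)
  stopifnot(all(c("load_g", "area_cm2") %in% names(areas)))
  if (!is.null(load_range)) {
    stopifnot(length(load_range) == 2)
    areas <- areas[areas$load_g >= load_range[1] & areas$load_g <= load_range[2], ]
  } else {
    load_range <- range(areas$load_g)
  }
  if (length(unique(areas$load_g)) < 3) {
    stop_input("log-law fit needs >= 3 distinct loads (got %d)",
               length(unique(areas$load_g)))
  }
  fit <- lm(area_cm2 ~ log(load_g), data = areas)
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         r_squared = r_squared(areas$area_cm2, stats::fitted(fit)),
         load_range = as.numeric(load_range),
         data = areas),
    class = "log_spread_fit"
  )
}

#' @export
print.log_spread_fit <- function(x, ...) {
  cat(sprintf("Log spreading law: area = %.3f*ln(load) %+.3f  (R2 = %.3f)\n",
              x$a, x$b, x$r_squared))
  cat(sprintf("Load range: %.0f-%.0f g\n", x$load_range[1], x$load_range[2]))
  invisible(x)
}

#' Area under the spreading curve
#'
#' Integrates the spreading curve over a load range. The default integrates
#' the fitted log law in closed form,
#' `integral(a*ln x + b) = a*(x*ln x - x) + b*x`, between the range limits;
#' `method = "trapezoid"` instead applies the trapezoidal rule to the raw
#' per-load mean areas stored in the fit.
#'
#' @param fit a [fit_log_spread()] result.
#' @param load_range numeric length-2; defaults to the fit's stored range
#'   (total mass, plate included: 298–798 g in the standard protocol).
#' @param method `"closed_form"` (default) or `"trapezoid"`.
#' @return AUC in cm2·g.
#' @export
area_under_spread <- function(fit, load_range = NULL,
                              method = c("closed_form", "trapezoid")) {
  stopifnot(inherits(fit, "log_spread_fit"))
  method <- match.arg(method)
  if (is.null(load_range)) load_range <- fit$load_range
  lo <- load_range[1]; hi <- load_range[2]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop_input("degenerate load_range [%g, %g]", lo, hi)
  }
  if (method == "closed_form") {
    antider <- function(x) {
      # lim x->0 of x*ln(x) - x is 0; guard so a range touching 0 integrates b*x
      xlnx <- ifelse(x == 0, 0, x * log(x))
      fit$a * (xlnx - x) + fit$b * x
    }
    antider(hi) - antider(lo)
  } else {
    dat <- fit$data[fit$data$load_g >= lo & fit$data$load_g <= hi, ]
    dat <- dat[order(dat$load_g), ]
    if (nrow(dat) < 2) stop_input("trapezoid AUC needs >= 2 points in range")
    trapz(dat$load_g, dat$area_cm2)
  }
}

#' Spreadability index relative to a reference formulation
#'
#' `i(S) = AUC_test / AUC_reference`. An index above 1 means the tested
#' formulation spreads better than the reference; below 1, worse.
#'
#' @param auc_test,auc_reference areas under the spread curve (same units).
#' @param digits rounding used for reporting (default 3, the conventional
#'   presentation); pass `NULL` to skip rounding.
#' @return the index as a plain number.
#' @export
spreadability_index <- function(auc_test, auc_reference, digits = 3) {
  check_number(auc_test, "auc_test", positive = TRUE)
  check_number(auc_reference, "auc_reference", positive = TRUE)
  i_s <- auc_test / auc_reference
  if (!is.null(digits)) i_s <- round(i_s, digits)
  i_s
}

#' Spreadability report for a set of formulations
#'
#' Runs the whole spreadability chain — areas, log-law fit, AUC, index
#' against the named reference — for each formulation and returns the usual
#' report table (fit coefficients, R2, AUC, i(S)).
#'
#' @param curves list of [spreadability_curve()] objects.
#' @param reference formulation_id used as the i(S) denominator (default the
#'   first curve).
#' @param load_range integration range in total grams; default `c(298, 798)`.
#' @param auc_method passed to [area_under_spread()].
#' @return tibble with one row per formulation.
#' @export
spreadability_report <- function(curves, reference = NULL,
                                 load_range = c(298, 798),
                                 auc_method = "closed_form") {
  stopifnot(length(curves) >= 1)
  rows <- lapply(curves, function(cv) {
    fit <- fit_log_spread(diameters_to_areas(cv))
    tibble(formulation_id = attr(cv, "formulation_id"),
           a = fit$a, b = fit$b, r_squared = fit$r_squared,
           auc = area_under_spread(fit, load_range, method = auc_method))
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(reference)) reference <- out$formulation_id[1]
  if (!reference %in% out$formulation_id) {
    stop_input("reference formulation '%s' not among the curves", reference)
  }
  auc_ref <- out$auc[out$formulation_id == reference][1]
  out$i_s <- vapply(out$auc, spreadability_index, numeric(1),
                    auc_reference = auc_ref)
  out$i_s[out$formulation_id == reference] <- NA_real_
  out
}
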