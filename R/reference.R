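#' Reference characterization tables for the ACTH/Lekobaza formulation series
#'
#' Published bench-characterization values for a seven-formulation series of
#' emulsion ointments built on the hydrophilic cream base Lekobaza: the plain
#' base (F-1), the base with 1 mL of 1 mol/L acetic acid emulsified in (F-2),
#' and five corticotropin (ACTH) ointments at 5, 10, 15, 20 and 25 mg/g
#' (F-3 to F-7). These tables are shipped because several package-level
#' consistency checks take the printed values as their input: the
#' spreadability index must be reproducible from the printed AUC column, the
#' closed-form integral of each printed log-law must agree with the printed
#' AUC, and texture fold-changes are plain arithmetic on the printed TPA rows.
#'
#' @return Each function returns a tibble:
#' \describe{
#'   \item{`reference_formulations()`}{composition per 10 g batch:
#'     `formulation_id`, `acth_mg` (mg per 10 g), `acth_mg_g` (mg per g),
#'     `acetic_acid_ml` (1 mol/L solution), `base` (q.s. note).}
#'   \item{`reference_ph()`}{`formulation_id`, `ph_mean`, `ph_sd` (n = 5).}
#'   \item{`reference_spreadability()`}{log-law fit `area = a*ln(load) + b`
#'     per formulation (`a` in cm2 per ln(g), `b` in cm2), `r_squared`, the
#'     printed area under the spread curve `auc` (cm2·g scale) over total
#'     load 298–798 g, and the printed spreadability index `i_s` relative to
#'     F-1 (NA for the reference itself).}
#'   \item{`reference_viscosity()`}{step-rate viscosity means and SDs
#'     (mPa·s, n = 5): `formulation_id`, `temperature_c` (25/32),
#'     `shear_rate_s1` (300/700/1100), `viscosity_mean`, `viscosity_sd`.}
#'   \item{`reference_texture()`}{TPA parameters (n = 5): `formulation_id`,
#'     `hardness_n`, `cohesiveness`, `adhesiveness_mj`, `elasticity`,
#'     `adhesion_force_n` with their `*_sd` columns (F-1, F-2, F-3, F-6).}
#'   \item{`reference_release_rates()`}{Higuchi release rates fitted over
#'     15–150 min (n = 6): `formulation_id`, `acth_mg_g`, `rate_mean`
#'     (mg/cm2/min^0.5), `rate_sd`, `r_squared`.}
#'   \item{`reference_calibration()`}{a [calibration_fit] for the UV assay at
#'     276.5 nm: absorbance = 0.5831 * conc(mg/mL) − 0.0169, R2 = 0.9996.}
#' }
#' @examples
#' ref <- reference_spreadability()
#' # the printed index column is the ratio of printed AUCs
#' round(ref$auc / ref$auc[ref$formulation_id == "F-1"], 3)
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_formulations <- function() {
  tibble(
    formulation_id = paste0("F-", 1:7),
    acth_mg = c(0, 0, 50, 100, 150, 200, 250),
    acth_mg_g = c(0, 0, 50, 100, 150, 200, 250) / 10,
    acetic_acid_ml = c(0, 1, 1, 1, 1, 1, 1),
    base = "Lekobaza to 10.0 g"
  )
}

#' @rdname reference_tables
#' @export
reference_ph <- function() {
  tibble(
    formulation_id = paste0("F-", 1:7),
    ph_mean = c(6.30, 3.43, 3.61, 3.79, 3.86, 3.92, 4.00),
    ph_sd = c(0.02, 0.02, 0.07, 0.04, 0.02, 0.02, 0.02)
  )
}

#' @rdname reference_tables
#' @export
reference_spreadability <- function() {
  tibble(
    formulation_id = paste0("F-", 1:7),
    a = c(20.899, 21.851, 19.898, 16.791, 20.814, 20.474, 17.752),
    b = c(-92.743, -93.754, -82.552, -67.144, -89.592, -86.238, -80.112),
    r_squared = c(0.943, 0.933, 0.931, 0.942, 0.957, 0.937, 0.966),
    auc = c(19281.4, 21786.7, 21246.4, 19111.5, 20523.5, 21215.6, 15660.8),
    i_s = c(NA, 1.130, 1.102, 0.991, 1.064, 1.100, 0.812)
  )
}

#' @rdname reference_tables
#' @export
reference_viscosity <- function() {
  grid <- expand.grid(
    shear_rate_s1 = c(300, 700, 1100),
    temperature_c = c(25, 32),
    formulation_id = paste0("F-", 1:7),
    stringsAsFactors = FALSE
  )
  # means/SDs ordered F-1..F-7, within each: (300, 700, 1100) x (25 C, 32 C)
  means <- c(
    1907, 1257, 741, 754, 528, 471,
    1019, 747, 611, 597, 435, 407,
    1102, 738, 596, 584, 423, 397,
    1408, 809, 651, 606, 439, 401,
    1622, 1096, 877, 1423, 984, 644,
    2749, 1295, 914, 2272, 1148, 858,
    2071, 1364, 798, 1853, 1236, 782
  )
  sds <- c(
    43, 26, 21, 13, 42, 8,
    74, 25, 16, 7, 2, 12,
    28, 22, 12, 10, 45, 12,
    57, 16, 10, 31, 7, 2,
    13, 56, 19, 14, 25, 29,
    63, 137, 44, 51, 10, 13,
    89, 88, 26, 32, 25, 5
  )
  out <- as_tibble(grid[, c("formulation_id", "temperature_c", "shear_rate_s1")])
  # grid varies rate fastest, then temperature, then formulation - same layout
  out$viscosity_mean <- means
  out$viscosity_sd <- sds
  out
}

#' @rdname reference_tables
#' @export
reference_texture <- function() {
  tibble(
    formulation_id = c("F-1", "F-2", "F-3", "F-6"),
    hardness_n = c(0.419, 0.205, 0.227, 0.801),
    hardness_sd = c(0.070, 0.018, 0.004, 0.015),
    cohesiveness = c(1.107, 0.885, 0.869, 0.360),
    cohesiveness_sd = c(0.050, 0.043, 0.036, 0.048),
    adhesiveness_mj = c(0.567, 0.325, 0.400, 1.683),
    adhesiveness_sd = c(0.058, 0.050, 0.000, 0.075),
    elasticity = c(1.130, 0.950, 0.947, 0.787),
    elasticity_sd = c(0.026, 0.021, 0.042, 0.166),
    adhesion_force_n = c(-0.130, -0.053, -0.059, -0.260),
    adhesion_force_sd = c(0.003, 0.002, 0.005, 0.012)
  )
}

#' @rdname reference_tables
#' @export
reference_release_rates <- function() {
  tibble(
    formulation_id = c("F-5", "F-6", "F-7"),
    acth_mg_g = c(15, 20, 25),
    rate_mean = c(0.41, 0.48, 0.52),
    rate_sd = c(0.02, 0.05, 0.03),
    r_squared = c(0.98, 0.98, 0.92)
  )
}

#' @rdname reference_tables
#' @export
reference_calibration <- function() {
  new_calibration_fit(
    slope = 0.5831, intercept = -0.0169, r_squared = 0.9996,
    wavelength_nm = 276.5
  )
}
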