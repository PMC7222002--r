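# Synthetic-instrument generators. Each one simulates the measurement chain
# of one bench instrument from known ground truth and returns an object the
# corresponding analysis stage can consume, with the truth attached as a
# sidecar attribute ("ground_truth"), so every stage can be validated by
# parameter recovery.

#' Simulate a parallel-plate spreadability experiment
#'
#' Generates replicate diameter readings from the log spreading law
#' `area = a*ln(total load) + b` with additive Gaussian area noise, then
#' converts areas back to the diameters an operator would record.
#'
#' @param a,b true log-law coefficients (cm2 per ln g, cm2).
#' @param added_mass_g added weights per step; defaults to the standard
#'   0–500 g in 20 g steps on top of the 298 g plate.
#' @param plate_mass_g upper-plate mass (default 298 g).
#' @param n_reps replicates (default 5).
#' @param noise_sd_cm2 SD of area noise (cm2), default 0 (noiseless).
#' @param seed RNG seed for reproducibility.
#' @param formulation_id label.
#' @return a [spreadability_curve()] with attribute `ground_truth`.
#' @export
gen_spreadability <- function(a, b, added_mass_g = seq(0, 500, by = 20),
                              plate_mass_g = 298, n_reps = 5,
                              noise_sd_cm2 = 0, seed = NULL,
                              formulation_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  check_number(noise_sd_cm2, "noise_sd_cm2", nonneg = TRUE)
  load <- plate_mass_g + added_mass_g
  mu <- a * log(load) + b
  if (any(mu <= 0)) {
    stop_input("log law implies non-positive area at load %g g",
               load[which(mu <= 0)[1]])
  }
  rows <- lapply(seq_len(n_reps), function(r) {
    area <- mu + rnorm(length(mu), 0, noise_sd_cm2)
    area <- pmax(area, 1e-6) # an operator cannot read a negative diameter
    tibble(replicate = r, added_mass_g = added_mass_g,
           diameter_cm = 2 * sqrt(area / pi))
  })
  out <- spreadability_curve(dplyr::bind_rows(rows),
                             formulation_id = formulation_id,
                             plate_mass_g = plate_mass_g)
  attr(out, "ground_truth") <- list(a = a, b = b, noise_sd_cm2 = noise_sd_cm2)
  out
}

#' Simulate a thixotropic up/down flow curve
#'
#' A structural-kinetics model drives the time dependence: a structure
#' parameter lambda in [0, 1] breaks down under shear and recovers at rest,
#' `dlambda/dt = -k_b*gammadot*lambda + k_r*(1 - lambda)`, and the stress is
#' the yield-stress law scaled by the remaining structure,
#' `tau = (tau_y + eta*gammadot) * (floor + (1 - floor)*lambda)`. With
#' `k_b > 0` the ascending ramp sees more structure than the descending one,
#' producing a positive hysteresis loop; with `k_b = 0` the curve is
#' reversible. A pre-shear dwell (100 1/s for 15 s, as in the standard
#' protocol) is applied before the ramp.
#'
#' @param tau_y,eta yield stress (Pa) and consistency (Pa·s).
#' @param breakdown_rate,recovery_rate structural rate constants `k_b`
#'   (dimensionless per unit strain) and `k_r` (1/s).
#' @param rates ascending ramp of shear rates (1/s); the descending ramp is
#'   its reverse. Default 100–1100 1/s in 50 1/s steps.
#' @param dwell_s time spent at each ramp step (default 1 s).
#' @param lambda_floor fraction of stress retained at full breakdown
#'   (default 0.2), so stress never collapses to zero.
#' @param temperature_c metadata label (default 25).
#' @param noise_sd_pa Gaussian stress noise SD (default 0).
#' @param seed RNG seed.
#' @param formulation_id label.
#' @return a [flow_curve()] with attribute `ground_truth`.
#' @export
gen_flow_curve <- function(tau_y, eta, breakdown_rate = 0,
                           recovery_rate = 0.05,
                           rates = seq(100, 1100, by = 50), dwell_s = 1,
                           lambda_floor = 0.2, temperature_c = 25,
                           noise_sd_pa = 0, seed = NULL,
                           formulation_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  if (any(rates <= 0) || dwell_s <= 0) stop_input("ramp rates and dwell must be > 0")
  check_number(breakdown_rate, "breakdown_rate", nonneg = TRUE)
  check_number(recovery_rate, "recovery_rate", nonneg = TRUE)

  # exact update of the linear structure ODE over a constant-rate dwell
  evolve <- function(lambda, g, dt) {
    decay <- breakdown_rate * g + recovery_rate
    if (decay == 0) return(lambda)
    lam_eq <- recovery_rate / decay
    lam_eq + (lambda - lam_eq) * exp(-decay * dt)
  }
  lambda <- 1
  lambda <- evolve(lambda, 100, 15) # pre-shear dwell
  ramp <- c(rates, rev(rates))
  phase <- rep(c("ascending", "descending"), each = length(rates))
  tau <- numeric(length(ramp))
  for (i in seq_along(ramp)) {
    lambda <- evolve(lambda, ramp[i], dwell_s)
    tau[i] <- (tau_y + eta * ramp[i]) *
      (lambda_floor + (1 - lambda_floor) * lambda)
  }
  if (noise_sd_pa > 0) tau <- tau + rnorm(length(tau), 0, noise_sd_pa)
  out <- flow_curve(tibble(shear_rate_s1 = ramp, shear_stress_pa = tau,
                           phase = phase),
                    temperature_c = temperature_c,
                    formulation_id = formulation_id)
  attr(out, "ground_truth") <- list(tau_y = tau_y, eta = eta,
                                    breakdown_rate = breakdown_rate,
                                    recovery_rate = recovery_rate,
                                    lambda_floor = lambda_floor)
  out
}

#' Simulate a two-cycle TPA force-time trace from target parameters
#'
#' Builds a piecewise-linear trace whose extracted parameters equal the
#' requested [tpa_profile()]: episode 1 rises to the hardness over
#' `depth/descent speed` seconds and falls symmetrically; the detachment
#' lobe is a triangle whose minimum is the adhesion force and whose work
#' (at the ascent speed) is the adhesiveness; after the pause, episode 2 is
#' a triangle with compression duration scaled by the elasticity and peak
#' chosen so its time-area is cohesiveness times episode 1's. Segment
#' breakpoints are included in the sampling grid so that trapezoidal
#' integrals of the sampled trace are exact in the noiseless case.
#'
#' @param profile a [tpa_profile()] of target parameters.
#' @param descent_speed_mm_s,ascent_speed_mm_s,target_depth_mm probe
#'   kinematics (defaults 5, 0.1, 10).
#' @param pause_s pause between the cycles (default 60 s).
#' @param sample_rate_hz sampling rate (default 20 Hz).
#' @param noise_sd_n Gaussian force noise SD (default 0).
#' @param seed RNG seed.
#' @return a [tpa_trace()] with attribute `ground_truth`.
#' @export
gen_tpa <- function(profile, descent_speed_mm_s = 5, ascent_speed_mm_s = 0.1,
                    target_depth_mm = 10, pause_s = 60, sample_rate_hz = 20,
                    noise_sd_n = 0, seed = NULL) {
  stopifnot(inherits(profile, "tpa_profile"))
  if (!is.null(seed)) set.seed(seed)
  h <- profile$hardness_n
  fmin <- profile$adhesion_force_n
  adh <- profile$adhesiveness_mj
  if (adh > 0 && fmin >= 0) {
    stop_input("inconsistent profile: adhesiveness > 0 needs a negative adhesion force")
  }
  if (adh == 0 && fmin < 0) {
    stop_input("inconsistent profile: a negative adhesion force needs adhesiveness > 0")
  }
  t1c <- target_depth_mm / descent_speed_mm_s # compression duration, ep 1
  t2c <- profile$elasticity * t1c
  p2 <- profile$cohesiveness * h / profile$elasticity # ep-2 peak force
  lead <- 1 # flat baseline bracketing the trace, s
  gap <- 1 # baseline between episode 1 and the detachment lobe, s

  # breakpoints as (time, force) pairs; segments are linear in between
  tp <- c(0, lead)
  fp <- c(0, 0)
  add <- function(dt, fend) {
    tp <<- c(tp, tail(tp, 1) + dt)
    fp <<- c(fp, fend)
  }
  add(t1c, h); add(t1c, 0) # episode 1: symmetric triangle
  if (adh > 0) {
    # triangle of |area|*ascent = adhesiveness, minimum fmin
    t_lobe <- 2 * adh / (abs(fmin) * ascent_speed_mm_s)
    add(gap, 0); add(t_lobe / 2, fmin); add(t_lobe / 2, 0)
  }
  add(pause_s, 0)
  add(t2c, p2); add(t2c, 0) # episode 2
  add(lead, 0)

  grid <- sort(unique(c(seq(0, tail(tp, 1), by = 1 / sample_rate_hz), tp)))
  force <- approx(tp, fp, xout = grid)$y
  if (noise_sd_n > 0) force <- force + rnorm(length(force), 0, noise_sd_n)
  out <- tpa_trace(tibble(time_s = grid, force_n = force),
                   descent_speed_mm_s = descent_speed_mm_s,
                   ascent_speed_mm_s = ascent_speed_mm_s,
                   target_depth_mm = target_depth_mm)
  attr(out, "ground_truth") <- profile
  out
}

# evaluate a kinetic model's cumulative release (mg/cm2) at times t
eval_release_model <- function(model, params, t, q_inf = NULL) {
  switch(model,
    zero = params$k0 * t,
    higuchi = params$kH * sqrt(t),
    first = q_inf * (1 - exp(-params$k1 * t)),
    korsmeyer_peppas = q_inf * params$kKP * t^params$n,
    weibull = q_inf * (1 - exp(-(t / params$tau_d)^params$beta)),
    stop_input("unknown release model '%s'", model)
  )
}

#' Simulate an enhancer-cell release experiment end to end
#'
#' Generates the true cumulative release from a chosen kinetic model, pushes
#' it through the vessel: at each scheduled time the newly released mass
#' enters the acceptor volume, an aliquot is withdrawn for assay (removing
#' analyte) and replaced with fresh medium (diluting the vessel). The assay
#' converts concentration to absorbance through the calibration line and
#' adds photometric noise, uniform on +/- `photometric_accuracy` — the
#' semantics of an instrument accuracy specification.
#'
#' @param model,params kinetic model and its true parameters (see
#'   [fit_release_model()] for the forms).
#' @param exp a [release_experiment()]; its `loaded_dose_mg` caps the
#'   release and sets `q_inf` for the saturating models.
#' @param calib a `calibration_fit` (default the shipped
#'   [reference_calibration()]).
#' @param n_reps assay replicates per time point (default 1).
#' @param photometric_accuracy half-width of the uniform absorbance noise
#'   (default 0.005 A; set 0 for a noiseless run).
#' @param cap_at_dose cap the true cumulative release at the loaded dose
#'   (default TRUE, with a warning when the cap engages). Disable to
#'   validate exact inversion of the measurement chain when the nominal
#'   kinetic law overruns the dose within the schedule.
#' @param seed RNG seed.
#' @return a `release_simulation`: list with `absorbance` (tibble
#'   `time_min`, `replicate`, `absorbance`), `experiment`, `calibration`,
#'   and `ground_truth` (model, params, the true `q_mg_cm2` profile).
#' @export
gen_release_experiment <- function(model, params, exp = release_experiment(),
                                   calib = reference_calibration(),
                                   n_reps = 1, photometric_accuracy = 0.005,
                                   cap_at_dose = TRUE, seed = NULL) {
  stopifnot(inherits(exp, "release_experiment"),
            inherits(calib, "calibration_fit"))
  if (!is.null(seed)) set.seed(seed)
  check_number(photometric_accuracy, "photometric_accuracy", nonneg = TRUE)
  t <- exp$times_min
  q_inf <- if (!is.null(exp$loaded_dose_mg)) {
    exp$loaded_dose_mg / exp$orifice_area_cm2
  } else NULL
  q_true <- eval_release_model(model, params, t, q_inf = q_inf)
  if (!is.null(q_inf) && cap_at_dose && any(q_true > q_inf)) {
    warn("model release exceeds the loaded dose; capped at dose")
    q_true <- pmin(q_true, q_inf)
  }
  mass <- q_true * exp$orifice_area_cm2 # cumulative released mass, mg
  v <- exp$vessel_volume_ml; vs <- exp$sample_volume_ml
  conc <- numeric(length(t))
  removed <- 0
  for (i in seq_along(t)) {
    conc[i] <- (mass[i] - removed) / v
    removed <- removed + conc[i] * vs
  }
  abs_rows <- lapply(seq_len(n_reps), function(r) {
    noise <- if (photometric_accuracy > 0) {
      runif(length(t), -photometric_accuracy, photometric_accuracy)
    } else 0
    tibble(time_min = t, replicate = r,
           absorbance = calib$slope * conc + calib$intercept + noise)
  })
  structure(list(absorbance = dplyr::bind_rows(abs_rows),
                 experiment = exp, calibration = calib,
                 ground_truth = list(model = model, params = params,
                                     q_mg_cm2 = q_true,
                                     conc_mg_ml = conc)),
            class = "release_simulation")
}

#' Analyze a simulated (or real) release data set back to a kinetic fit
#'
#' The full analysis chain: average assay replicates per time point, invert
#' the calibration, apply the withdrawal/replacement correction, fit the
#' requested kinetic model.
#'
#' @param sim a `release_simulation`, or a list with elements `absorbance`
#'   (tibble `time_min`, `replicate`, `absorbance`), `experiment`,
#'   `calibration`.
#' @param model kinetic model to fit (default `"higuchi"`).
#' @param q_inf asymptote for the saturating models; defaults to loaded
#'   dose / orifice area when the experiment carries a dose.
#' @param ... passed to [fit_release_model()].
#' @return list with `profile` (the corrected [cumulative_release()]) and
#'   `fit` (the `kinetic_fit`).
#' @export
analyze_release <- function(sim, model = "higuchi", q_inf = NULL, ...) {
  ab <- dplyr::summarise(dplyr::group_by(sim$absorbance, .data$time_min),
                         absorbance = mean(.data$absorbance),
                         .groups = "drop")
  ab <- ab[order(ab$time_min), ]
  conc <- absorbance_to_conc(ab$absorbance, sim$calibration)
  profile <- cumulative_release(conc, sim$experiment, tol = 1)
  if (is.null(q_inf) && !is.null(sim$experiment$loaded_dose_mg)) {
    q_inf <- sim$experiment$loaded_dose_mg / sim$experiment$orifice_area_cm2
  }
  fit <- fit_release_model(profile, model, q_inf = q_inf, ...)
  list(profile = profile, fit = fit)
}
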