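test_that("all generators are deterministic under a fixed seed", {
  s1 <- gen_spreadability(20, -80, noise_sd_cm2 = 0.5, seed = 1)
  s2 <- gen_spreadability(20, -80, noise_sd_cm2 = 0.5, seed = 1)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  f1 <- gen_flow_curve(5, 0.002, breakdown_rate = 1e-4, noise_sd_pa = 0.1, seed = 2)
  f2 <- gen_flow_curve(5, 0.002, breakdown_rate = 1e-4, noise_sd_pa = 0.1, seed = 2)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  p <- tpa_profile(0.5, 1.0, 0.5, 1.0, -0.1)
  t1 <- gen_tpa(p, noise_sd_n = 0.002, seed = 3)
  t2 <- gen_tpa(p, noise_sd_n = 0.002, seed = 3)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  r1 <- gen_release_experiment("higuchi", list(kH = 0.41),
                               exp = release_experiment(loaded_dose_mg = 40),
                               seed = 4)
  r2 <- gen_release_experiment("higuchi", list(kH = 0.41),
                               exp = release_experiment(loaded_dose_mg = 40),
                               seed = 4)
  expect_identical(r1$absorbance, r2$absorbance)
})

test_that("spreadability generator round-trips and obeys sampling theory", {
  cv <- gen_spreadability(20.899, -92.743, noise_sd_cm2 = 0)
  fit <- suppressWarnings(fit_log_spread(diameters_to_areas(cv)))
  expect_equal(fit$a, 20.899, tolerance = 1e-9)
  expect_equal(fit$b, -92.743, tolerance = 1e-9)

  # with many replicates the fitted slope sits within 3 SE of the truth
  cv_n <- gen_spreadability(20.899, -92.743, n_reps = 1000,
                            noise_sd_cm2 = 0.5, seed = 13)
  areas <- diameters_to_areas(cv_n)
  fit_n <- fit_log_spread(areas)
  se_a <- summary(lm(area_cm2 ~ log(load_g), data = areas))$coefficients[2, 2]
  expect_lt(abs(fit_n$a - 20.899), 3 * se_a)

  expect_error(gen_spreadability(1, -10), "non-positive area")
})

test_that("flow-curve generator produces the expected loop phenomenology", {
  rev_cv <- gen_flow_curve(5, 0.002, breakdown_rate = 0)
  expect_equal(as.numeric(hysteresis_area(rev_cv)), 0, tolerance = 1e-9)

  thix <- gen_flow_curve(5, 0.002, breakdown_rate = 2e-4, recovery_rate = 0.02)
  expect_gt(as.numeric(hysteresis_area(thix)), 0)

  # the lower-viscosity (skin-temperature analogue) run has the smaller loop
  warm <- gen_flow_curve(5, 0.001, breakdown_rate = 2e-4, recovery_rate = 0.02,
                         temperature_c = 32)
  expect_lt(as.numeric(hysteresis_area(warm)),
            as.numeric(hysteresis_area(thix)))

  expect_error(gen_flow_curve(5, 0.002, rates = c(-1, 100)), "must be > 0")
})

test_that("TPA generator round-trips randomized and published profiles to 1e-3", {
  ref <- reference_texture()
  for (i in seq_len(nrow(ref))) {
    p <- profile_from_ref(ref[i, ])
    got <- extract_tpa(gen_tpa(p))
    expect_equal(profile_as_vector(got), profile_as_vector(p), tolerance = 1e-3)
  }

  set.seed(17)
  for (i in 1:15) {
    p <- tpa_profile(hardness_n = runif(1, 0.1, 2),
                     cohesiveness = runif(1, 0.3, 1.5),
                     adhesiveness_mj = runif(1, 0.1, 2),
                     elasticity = runif(1, 0.5, 1.5),
                     adhesion_force_n = -runif(1, 0.03, 0.4))
    got <- extract_tpa(gen_tpa(p))
    expect_equal(profile_as_vector(got), profile_as_vector(p), tolerance = 1e-3)
  }

  # doubling the sampling rate moves extracted parameters < 0.5%
  p <- profile_from_ref(ref[1, ])
  a <- profile_as_vector(extract_tpa(gen_tpa(p, sample_rate_hz = 20)))
  b <- profile_as_vector(extract_tpa(gen_tpa(p, sample_rate_hz = 40)))
  expect_lt(max(abs(a - b) / abs(a)), 0.005)

  expect_error(gen_tpa(tpa_profile(1, 1, 0.5, 1, 0)), "inconsistent profile")
  expect_error(gen_tpa(tpa_profile(1, 1, 0, 1, -0.1)), "inconsistent profile")
})

test_that("release generator feeds the pipeline back its own ground truth", {
  # end-to-end noiseless round trip at a published rate
  sim <- suppressWarnings(gen_release_experiment(
    "higuchi", list(kH = 0.41),
    exp = release_experiment(loaded_dose_mg = 15),
    photometric_accuracy = 0, cap_at_dose = FALSE))
  fit <- suppressWarnings(analyze_release(sim))$fit
  expect_equal(fit$params$kH, 0.41, tolerance = 1e-6)

  # zero-rate model: absorbances sit at the calibration intercept
  sim0 <- gen_release_experiment("zero", list(k0 = 0),
                                 exp = release_experiment(loaded_dose_mg = 15),
                                 photometric_accuracy = 0)
  expect_equal(sim0$absorbance$absorbance,
               rep(reference_calibration()$intercept, 6))

  # the dose cap engages (with a warning) when the law overruns the load
  expect_warning(
    gen_release_experiment("higuchi", list(kH = 0.41),
                           exp = release_experiment(loaded_dose_mg = 15),
                           photometric_accuracy = 0),
    "capped")

  # capped runs respect mass balance
  sim_cap <- suppressWarnings(gen_release_experiment(
    "higuchi", list(kH = 0.41), exp = release_experiment(loaded_dose_mg = 15),
    photometric_accuracy = 0))
  prof <- suppressWarnings(analyze_release(sim_cap))$profile
  expect_true(all(prof$q_mg_cm2 * 3.8 <= 15 + 1e-9))
})
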