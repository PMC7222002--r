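std_conc <- c(0.1, 0.2, 0.4, 0.5, 0.6, 0.8, 1.0)

test_that("calibration fit recovers the assay line and tolerates stated noise", {
  ab <- 0.5831 * std_conc - 0.0169
  fit <- suppressWarnings(fit_calibration(std_conc, ab))
  expect_equal(fit$slope, 0.5831, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.0169, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(42)
  for (i in 1:10) {
    fit_n <- fit_calibration(std_conc, ab + runif(7, -0.005, 0.005))
    expect_gte(fit_n$r_squared, 0.999)
  }

  expect_warning(fit_calibration(std_conc, rep(0.3, 7)), "unusable")
  expect_error(fit_calibration(c(0.1, 0.1, 0.1), c(1, 2, 3)), "3 distinct")
})

test_that("calibration inversion is exact and floors negative readings", {
  calib <- reference_calibration()
  expect_equal(absorbance_to_conc(0.5662, calib), 1.0, tolerance = 1e-9)
  expect_equal(absorbance_to_conc(-0.0169, calib), 0)
  expect_equal(absorbance_to_conc(-0.0169 + 0.5831 * 0.5, calib), 0.5,
               tolerance = 1e-12)
  expect_warning(absorbance_to_conc(-0.1, calib), "floored")
  expect_error(
    absorbance_to_conc(0.3, structure(list(slope = -1, intercept = 0),
                                      class = "calibration_fit")),
    "slope")
})

test_that("withdrawal correction: hand value, zeros, and exact forward inversion", {
  exp1 <- release_experiment(times_min = 15)
  q <- cumulative_release(1.0, exp1)
  expect_equal(q$q_mg_cm2, 50 / 3.8, tolerance = 1e-9)

  exp6 <- release_experiment()
  expect_equal(cumulative_release(rep(0, 6), exp6)$q_mg_cm2, rep(0, 6))
  expect_error(cumulative_release(c(1, 2), exp6), "6 scheduled")

  # forward-simulate a known monotone release, measure, correct: exact inversion
  set.seed(5)
  for (vs in c(1, 3, 5)) {
    ex <- release_experiment(sample_volume_ml = vs)
    q_true <- cumsum(runif(6, 0.1, 0.8)) # mg/cm2
    mass <- q_true * ex$orifice_area_cm2
    conc <- numeric(6); removed <- 0
    for (i in 1:6) {
      conc[i] <- (mass[i] - removed) / ex$vessel_volume_ml
      removed <- removed + conc[i] * vs
    }
    q_rec <- cumulative_release(conc, ex)$q_mg_cm2
    expect_equal(q_rec, q_true, tolerance = 1e-9)
  }
})

test_that("kinetic fits recover their generating models and rank correctly", {
  t <- c(15, 30, 60, 90, 120, 150)

  # exact Higuchi data
  prof_h <- tibble::tibble(time_min = t, q_mg_cm2 = 0.41 * sqrt(t))
  fit_h <- fit_release_model(prof_h, "higuchi")
  expect_equal(fit_h$params$kH, 0.41, tolerance = 1e-12)
  expect_equal(fit_h$r_squared, 1, tolerance = 1e-12)

  # zero-order data: Higuchi cannot reach R2 = 1 and the ranking prefers zero
  prof_z <- tibble::tibble(time_min = t, q_mg_cm2 = 0.02 * t)
  expect_lt(fit_release_model(prof_z, "higuchi")$r_squared, 1)
  cmp <- compare_models(prof_z, q_inf = 10)
  expect_identical(cmp$best, "zero")

  # first-order recovery via 1-D SSE minimization
  k1 <- 0.02; qinf <- 5
  prof_f <- tibble::tibble(time_min = t, q_mg_cm2 = qinf * (1 - exp(-k1 * t)))
  fit_f <- fit_release_model(prof_f, "first", q_inf = qinf)
  expect_equal(fit_f$params$k1, k1, tolerance = 1e-6)
  expect_error(fit_release_model(prof_f, "first"), "q_inf")

  # Korsmeyer-Peppas on exact power-law data below 60% release
  kkp <- 0.02; n_exp <- 0.62
  prof_kp <- tibble::tibble(time_min = t, q_mg_cm2 = qinf * kkp * t^n_exp)
  fit_kp <- fit_release_model(prof_kp, "korsmeyer_peppas", q_inf = qinf)
  expect_equal(fit_kp$params$n, n_exp, tolerance = 1e-9)
  expect_equal(fit_kp$params$kKP, kkp, tolerance = 1e-9)

  # Weibull recovery, and its beta = 1 limit equals the first-order rate
  beta <- 1.4; tau_d <- 80
  prof_w <- tibble::tibble(time_min = t,
                           q_mg_cm2 = qinf * (1 - exp(-(t / tau_d)^beta)))
  fit_w <- fit_release_model(prof_w, "weibull", q_inf = qinf)
  expect_equal(fit_w$params$beta, beta, tolerance = 1e-9)
  expect_equal(fit_w$params$tau_d, tau_d, tolerance = 1e-6)

  fit_w1 <- fit_release_model(prof_f, "weibull", q_inf = qinf)
  expect_equal(fit_w1$params$beta, 1, tolerance = 1e-9)
  expect_equal(1 / fit_w1$params$tau_d,
               fit_release_model(prof_f, "first", q_inf = qinf)$params$k1,
               tolerance = 1e-6)

  # true generating model never ranks below another on its own noiseless data
  for (spec in list(list(m = "higuchi", p = prof_h),
                    list(m = "zero", p = prof_z),
                    list(m = "first", p = prof_f),
                    list(m = "weibull", p = prof_w))) {
    cmp_i <- compare_models(spec$p, q_inf = qinf)
    own <- cmp_i$table$r_squared[cmp_i$table$model == spec$m]
    expect_true(all(own >= cmp_i$table$r_squared - 1e-9))
  }
})

test_that("noisy Higuchi data still fits the Higuchi model well", {
  t <- c(15, 30, 60, 90, 120, 150)
  set.seed(9)
  for (i in 1:10) {
    prof <- tibble::tibble(time_min = t,
                           q_mg_cm2 = 0.41 * sqrt(t) + rnorm(6, 0, 0.05))
    expect_gt(fit_release_model(prof, "higuchi")$r_squared, 0.9)
  }
})

test_that("3-point profiles are ranked but warn about degrees of freedom", {
  prof3 <- tibble::tibble(time_min = c(15, 60, 150),
                          q_mg_cm2 = 0.41 * sqrt(c(15, 60, 150)))
  expect_warning(cmp <- compare_models(prof3, q_inf = 5), "degrees of freedom")
  expect_identical(cmp$best, "higuchi")
})

test_that("rate comparison summarizes replicates and separates published groups", {
  rr <- release_rate_comparison(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(rr$tests$t, 0)
  expect_equal(rr$tests$p_value, 1)

  expect_error(release_rate_comparison(tibble::tibble(formulation_id = character(),
                                                      rate = numeric())),
               ">= 1 row")

  # power at the published effect: {0.41 +/- 0.02} vs {0.52 +/- 0.03}, n = 6
  set.seed(21)
  rej <- replicate(200, {
    a <- rnorm(6, 0.41, 0.02); b <- rnorm(6, 0.52, 0.03)
    release_rate_comparison(list(A = a, B = b))$tests$p_value < 0.05
  })
  expect_gte(mean(rej), 0.95)

  # single replicate: descriptive only
  rr1 <- release_rate_comparison(list(A = 0.4, B = c(0.5, 0.6)))
  expect_true(is.na(rr1$tests$p_value))
  expect_equal(nrow(rr1$summary), 2)
})
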