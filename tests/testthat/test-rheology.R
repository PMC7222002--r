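test_that("step-viscosity summary gives replicate mean/SD and guards cells", {
  readings <- tibble::tibble(
    formulation_id = "F-1", temperature_c = 25,
    shear_rate_s1 = rep(c(300, 700), each = 2),
    viscosity_mpas = c(1900, 1914, 1250, 1250)
  )
  out <- summarize_step_viscosity(readings)
  cell <- out[out$shear_rate_s1 == 300, ]
  expect_equal(cell$viscosity_mean, 1907)
  expect_equal(cell$viscosity_sd, 14 / sqrt(2), tolerance = 1e-12)
  expect_equal(out$viscosity_sd[out$shear_rate_s1 == 700], 0)
  expect_true(all(out$shear_thinning)) # 1907 -> 1250 falls with rate

  expect_error(
    summarize_step_viscosity(readings[c(1, 3, 4), ]),
    "single reading"
  )
})

test_that("temperature ratios reproduce the published thinning regimes", {
  ref <- reference_viscosity()
  # strong thinning of the plain base at low rate
  expect_equal(temperature_ratio(ref, "F-1", 300), 1907 / 754, tolerance = 1e-12)
  expect_equal(round(temperature_ratio(ref, "F-1", 300), 2), 2.53)
  # the 'practically does not change' regime at high rate, high concentration
  expect_equal(round(temperature_ratio(ref, "F-7", 1100), 2), 1.02)
  expect_error(temperature_ratio(ref, "F-1", 12345), "no viscosity cell")
})

test_that("yield-stress fits recover exact data and match a grid-search oracle", {
  g <- seq(100, 1100, by = 100)
  up <- tibble::tibble(shear_rate_s1 = g, shear_stress_pa = 5 + 0.002 * g,
                       phase = "ascending")
  cv <- flow_curve(up)
  fit <- fit_casson(cv)
  expect_equal(fit$tau_y, 5, tolerance = 1e-9)
  expect_equal(fit$eta, 0.002, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # Newtonian data has ~zero yield stress
  newt <- flow_curve(tibble::tibble(shear_rate_s1 = g,
                                    shear_stress_pa = 0.001 * g,
                                    phase = "ascending"))
  expect_lt(fit_casson(newt)$tau_y, 1e-9)

  # linear variant equals plain OLS of stress on rate
  set.seed(11)
  noisy <- flow_curve(tibble::tibble(
    shear_rate_s1 = g, shear_stress_pa = 5 + 0.002 * g + rnorm(length(g), 0, 0.1),
    phase = "ascending"))
  fit_n <- fit_casson(noisy)
  ora <- ols_oracle(noisy$shear_rate_s1, noisy$shear_stress_pa)
  expect_equal(fit_n$tau_y, ora[1], tolerance = 1e-9)
  expect_equal(fit_n$eta, ora[2], tolerance = 1e-9)

  # and matches a brute-force 2-D grid search within grid resolution
  sse <- function(ty, eta) sum((noisy$shear_stress_pa - ty - eta * noisy$shear_rate_s1)^2)
  grid <- expand.grid(ty = seq(4, 6, by = 0.01),
                      eta = seq(0.0015, 0.0025, by = 5e-6))
  best <- grid[which.min(mapply(sse, grid$ty, grid$eta)), ]
  expect_lt(abs(fit_n$tau_y - best$ty), 0.01)   # one ty grid step
  expect_lt(abs(fit_n$eta - best$eta), 1e-5)    # two eta grid steps


  # square-root variant recovers its own generating model without noise
  ty <- 3; eta <- 0.004
  tau_sq <- (sqrt(ty) + sqrt(eta * g))^2
  fit_sq <- fit_casson(flow_curve(tibble::tibble(
    shear_rate_s1 = g, shear_stress_pa = tau_sq, phase = "ascending")),
    variant = "square_root")
  expect_equal(fit_sq$tau_y, ty, tolerance = 1e-6)
  expect_equal(fit_sq$eta, eta, tolerance = 1e-6)

  one_rate <- tibble::tibble(shear_rate_s1 = rep(100, 3),
                             shear_stress_pa = c(5, 5, 5), phase = "ascending")
  expect_error(fit_casson(flow_curve(one_rate)), "singular design")
})

test_that("hysteresis area: hand rectangle, sign conventions, resampling stability", {
  g <- seq(100, 1100, by = 100)
  mk <- function(tau_up, tau_dn) {
    flow_curve(tibble::tibble(
      shear_rate_s1 = c(g, rev(g)),
      shear_stress_pa = c(tau_up, rev(tau_dn)),
      phase = rep(c("ascending", "descending"), each = length(g))))
  }
  # parallel offset lines: area = offset * rate span = 5 * 1000
  a <- hysteresis_area(mk(10 + 0.01 * g, 5 + 0.01 * g))
  expect_equal(as.numeric(a), 5000, tolerance = 1e-9)
  expect_identical(attr(a, "behaviour"), "thixotropic")

  same <- hysteresis_area(mk(10 + 0.01 * g, 10 + 0.01 * g))
  expect_equal(as.numeric(same), 0)
  expect_identical(attr(same, "behaviour"), "reversible")

  anti <- hysteresis_area(mk(5 + 0.01 * g, 10 + 0.01 * g))
  expect_lt(as.numeric(anti), 0)
  expect_identical(attr(anti, "behaviour"), "anti-thixotropic")

  # denser sampling of the same smooth curves moves the result < 0.5%
  up_f <- function(x) 8 + 0.012 * x - 1e-6 * x^2
  dn_f <- function(x) 4 + 0.010 * x
  g2 <- seq(100, 1100, by = 25)
  a_coarse <- as.numeric(hysteresis_area(mk(up_f(g), dn_f(g))))
  a_fine <- as.numeric(hysteresis_area(flow_curve(tibble::tibble(
    shear_rate_s1 = c(g2, rev(g2)),
    shear_stress_pa = c(up_f(g2), rev(dn_f(g2))),
    phase = rep(c("ascending", "descending"), each = length(g2))))))
  expect_lt(abs(a_fine - a_coarse) / a_coarse, 0.005)

  no_overlap <- flow_curve(tibble::tibble(
    shear_rate_s1 = c(100, 200, 600, 500),
    shear_stress_pa = c(1, 2, 2, 1),
    phase = c("ascending", "ascending", "descending", "descending")))
  expect_error(hysteresis_area(no_overlap), "overlap")
})

test_that("thixotropy comparison pairs areas, ratios and ordering", {
  out <- compare_thixotropy(c(`F-1` = 5000, `F-2` = 2000),
                            c(`F-1` = 2500, `F-2` = 2000))
  expect_equal(out$ratio, c(0.5, 1.0))
  expect_equal(out$rank_25, c(1L, 2L))
  out0 <- compare_thixotropy(c(A = 0), c(A = 10))
  expect_true(is.na(out0$ratio))
  expect_error(compare_thixotropy(c(A = 1), c(B = 1)), "different formulations")
})
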