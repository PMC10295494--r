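test_that("BSA formulas reproduce direct evaluation and scale correctly", {
  # direct evaluation of the published formulas at the cohort mean
  # anthropometrics (frozen oracle values)
  expect_equal(compute_bsa(1.67, 74.16, "du_bois"),
               0.007184 * 74.16^0.425 * 167^0.725, tolerance = 1e-12)
  expect_equal(compute_bsa(1.67, 74.16, "du_bois"), 1.830872,
               tolerance = 1e-6)
  expect_equal(compute_bsa(1.67, 74.16, "mosteller"), 1.854778,
               tolerance = 1e-6)
  # Mosteller homogeneity: mass scaled by k scales BSA by sqrt(k)
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(compute_bsa(1.7, 80 * k, "mosteller"),
                 sqrt(k) * compute_bsa(1.7, 80, "mosteller"))
  }
  expect_error(compute_bsa(-1.6, 70), "positive")
  expect_error(compute_bsa(1.6, 0), "positive")
})

test_that("BMI matches its definition and edge identities", {
  expect_equal(compute_bmi(1.67, 74.16), 74.16 / 1.67^2)
  expect_equal(round(compute_bmi(1.67, 74.16), 2), 26.59)
  expect_equal(compute_bmi(2.0, 80.0), 20.0)
  expect_equal(compute_bmi(1.0, 33.3), 33.3)  # identity at unit height
  expect_error(compute_bmi(0, 70), "positive")
})

test_that("aortic strain follows the relative diameter change", {
  expect_equal(ao_strain(34.50, 33.42), 100 * (34.50 - 33.42) / 33.42)
  expect_equal(ao_strain(34.50, 33.42), 3.23160, tolerance = 1e-5)
  expect_equal(ao_strain(31, 31), 0)
  expect_equal(ao_strain(62, 31), 100)
  expect_error(ao_strain(30, 31), "systolic")
  expect_warning(out <- ao_strain(30, 31, clamp_negative = TRUE), "clamped")
  expect_equal(out, 0)
})

test_that("distensibility reproduces the 2*strain/pulse-pressure form", {
  expect_equal(ao_distensibility(3.29, 143.20, 88.40), 2 * 3.29 / 54.8)
  expect_equal(round(ao_distensibility(3.29, 143.20, 88.40), 2), 0.12)
  expect_equal(round(ao_distensibility(2.67, 143.20, 88.40), 2), 0.10)
  expect_equal(ao_distensibility(0, 120, 80), 0)
  expect_error(ao_distensibility(2, 80, 80), "sbp > dbp")
})

test_that("stiffness index interpretations evaluate as specified", {
  expect_equal(ao_stiffness_index(143.20, 88.40, 2.67),
               log((143.20 / 88.40) / 0.0267), tolerance = 1e-12)
  expect_equal(round(ao_stiffness_index(143.20, 88.40, 2.67), 3), 4.105)
  expect_equal(round(ao_stiffness_index(143.20, 88.40, 2.67,
                                        "classic_beta"), 2), 18.07)
  # closed form at sbp/dbp = e: log_of_ratio index = 1 - ln(strain/100)
  for (s in c(0.5, 2.67, 8)) {
    expect_equal(ao_stiffness_index(90 * exp(1), 90, s),
                 1 - log(s / 100), tolerance = 1e-12)
  }
  expect_error(ao_stiffness_index(140, 90, 0), "undefined")
  expect_warning(
    clamped <- ao_stiffness_index(140, 90, 0.01, clamp_strain = TRUE),
    "clamped")
  expect_equal(clamped, ao_stiffness_index(140, 90, 0.1))
})

test_that("EAT indices divide by BSA and round-trip exactly", {
  idx <- eat_indices(9.51, 60.03, 1.82)
  expect_equal(round(idx$thickness_index, 2), 5.23)
  expect_equal(round(idx$volume_index, 2), 32.98)
  expect_equal(eat_indices(0, 0, 1.9), list(thickness_index = 0,
                                            volume_index = 0))
  # round trip: index * BSA recovers the raw measurement
  set.seed(11)
  th <- runif(50, 2, 20); vol <- runif(50, 10, 120); bsa <- runif(50, 1.4, 2.4)
  idx <- eat_indices(th, vol, bsa)
  expect_equal(idx$thickness_index * bsa, th, tolerance = 1e-14)
  expect_equal(idx$volume_index * bsa, vol, tolerance = 1e-14)
  expect_error(eat_indices(9, 60, 0), "bsa")
})

test_that("derive_indices composes the per-operation results", {
  d <- derive_indices(mean_record())
  expect_equal(d$bsa, compute_bsa(1.67, 74.16))
  expect_equal(d$bmi, compute_bmi(1.67, 74.16))
  expect_equal(d$pulse_pressure, 54.8)
  expect_equal(d$ao_strain, ao_strain(34.50, 33.42))
  expect_equal(d$ao_distensibility,
               ao_distensibility(d$ao_strain, 143.20, 88.40))
  expect_equal(d$ao_stiffness_index,
               ao_stiffness_index(143.20, 88.40, d$ao_strain))
  expect_equal(d$eat_volume_index, 60.03 / d$bsa)
  # zero strain: strain and distensibility are 0, stiffness index errors
  rec <- mean_record()
  rec$ao_systolic_diameter <- rec$ao_diastolic_diameter
  expect_error(derive_indices(rec), "undefined.*MEAN")
  clamped <- suppressWarnings(derive_indices(rec, clamp_strain = TRUE))
  expect_equal(clamped$ao_strain, 0)
  expect_equal(clamped$ao_distensibility, 0)
  expect_equal(clamped$ao_stiffness_index,
               ao_stiffness_index(143.20, 88.40, 0.1))
  # anthropometric outputs do not couple to aortic fields
  rec2 <- mean_record()
  rec2$ao_systolic_diameter <- 40
  rec2$sbp <- 160
  d2 <- derive_indices(rec2)
  expect_equal(d2$bsa, d$bsa)
  expect_equal(d2$bmi, d$bmi)
})

test_that("derived quantities satisfy the exact identities and monotonicity", {
  co <- generate_cohort(default_spec(seed = 99))
  d <- derive_indices(co)
  # distensibility * pulse pressure = 2 * strain, machine precision
  expect_equal(d$ao_distensibility * d$pulse_pressure, 2 * d$ao_strain,
               tolerance = 1e-14)
  # log_of_ratio = ln(pressure ratio) - ln(strain fraction)
  expect_equal(d$ao_stiffness_index,
               log(d$sbp / d$dbp) - log(d$ao_strain / 100),
               tolerance = 1e-12)
  # stiffness strictly decreasing in strain at fixed pressures
  strains <- seq(0.5, 12, by = 0.25)
  for (interp in c("log_of_ratio", "classic_beta")) {
    idx <- ao_stiffness_index(143, 88, strains, interp)
    expect_true(all(diff(idx) < 0))
  }
  # distensibility increasing in strain, decreasing in pulse pressure
  expect_true(all(diff(ao_distensibility(strains, 143, 88)) > 0))
  pps <- seq(30, 80, by = 5)
  expect_true(all(diff(ao_distensibility(3, 90 + pps, 90)) < 0))
  # Du Bois and Mosteller agree closely for typical builds; the formulas
  # diverge by design at stature extremes, so the bound is distributional:
  # tight at the cohort mean, 3% for the bulk, bounded everywhere
  expect_lt(abs(compute_bsa(1.67, 74.16, "du_bois") /
                  compute_bsa(1.67, 74.16, "mosteller") - 1), 0.02)
  rel <- abs(compute_bsa(co$height, co$body_mass, "du_bois") /
               compute_bsa(co$height, co$body_mass, "mosteller") - 1)
  expect_gt(mean(rel < 0.03), 0.90)
  expect_lt(max(rel), 0.08)
})
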