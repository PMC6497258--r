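test_that("maternal anchor values reproduce the fitted curves", {
  expect_equal(maternal_mass(0), 61.103, tolerance = 1e-12)
  expect_equal(maternal_mass(40),
               horner(c(61.103, -0.010614, 0.029161, -5.0203e-4), 40),
               tolerance = 1e-12)
  expect_equal(maternal_mass(20), 68.539, tolerance = 1e-4)

  expect_equal(maternal_adipose_mass(0), 17.067, tolerance = 1e-12)
  expect_equal(maternal_adipose_mass(40), 17.067 + 0.14937 * 40,
               tolerance = 1e-12)
  expect_equal(maternal_adipose_volume(0), 17.067 / 0.95, tolerance = 1e-12)

  # adipose share of body mass at conception is 27.9%
  expect_equal(round(100 * maternal_adipose_mass(0) / maternal_mass(0), 1),
               27.9)

  # plasma: sigmoid midpoint and large-age plateau
  expect_equal(maternal_plasma_volume(17.813), 1.2406 / 2 + 2.4958,
               tolerance = 1e-12)
  expect_warning(
    expect_equal(maternal_plasma_volume(2000), 1.2406 + 2.4958,
                 tolerance = 1e-9),
    "outside the modelled range")

  expect_equal(maternal_cardiac_output(0), 301.78, tolerance = 1e-12)
  expect_equal(maternal_kidney_flow(0), 53.248, tolerance = 1e-12)
  expect_equal(maternal_hematocrit(0), 39.192, tolerance = 1e-12)
  expect_equal(maternal_hematocrit(40), 39.192 - 0.10562 * 40 -
                 7.1045e-4 * 1600, tolerance = 1e-12)
  expect_equal(maternal_gfr(0), 113.73, tolerance = 1e-12)
  expect_equal(amniotic_fluid_volume(20.150), 822.34 / 2, tolerance = 1e-12)
})

test_that("static compartment volumes reproduce the reference table", {
  v <- maternal_static_volumes()
  ref <- c(bran = 1.2749, thyr = 0.016469, kidn = 0.26653,
           gutx = 1.1110, livr = 1.3559, lung = 0.91945)
  expect_equal(signif(v[names(ref)], 5), ref, tolerance = 1e-9)
})

test_that("RBC volume from the hematocrit identity matches H/(1-H) * plasma", {
  t <- c(0, 10, 25, 40)
  h <- maternal_hematocrit(t) / 100
  expect_equal(maternal_rbc_volume(t),
               h / (1 - h) * maternal_plasma_volume(t), tolerance = 1e-14)
  expect_equal(maternal_rbc_volume(0), 0.39192 / (1 - 0.39192) *
                 maternal_plasma_volume(0), tolerance = 1e-12)
  # and the derived hematocrit is exactly self-consistent on a fine grid
  tt <- seq(0, 42, by = 0.1)
  vr <- maternal_rbc_volume(tt)
  vp <- maternal_plasma_volume(tt)
  expect_equal(100 * vr / (vp + vr), maternal_hematocrit(tt),
               tolerance = 1e-12)
})

test_that("ratio hematocrit runs strictly below the quadratic model", {
  tt <- seq(0, 40, by = 0.1)
  expect_true(all(maternal_hematocrit(tt, method = "ratio") <
                    maternal_hematocrit(tt)))
})

test_that("placenta volume is negative only before ~1.97 weeks", {
  thr <- placenta_positivity_threshold()
  expect_equal(thr, 1.97, tolerance = 0.005)
  expect_lt(placenta_volume(thr - 0.1), 0)
  expect_gt(placenta_volume(thr + 0.1), 0)
  expect_equal(placenta_volume(40),
               horner(c(0, -1.7646, 0.91775, -0.011543), 40),
               tolerance = 1e-12)
})

test_that("placental blood flow is gated, proportional to volume, and 39 L/h at term", {
  expect_identical(maternal_placenta_flow(3.0), 0)
  expect_equal(maternal_placenta_flow(20), 0.059176 * placenta_volume(20),
               tolerance = 1e-14)
  expect_equal(round(maternal_placenta_flow(40)), 39)
  tt <- seq(3.6, 40, by = 0.1)
  q <- maternal_placenta_flow(tt)
  expect_true(all(q >= 0))
  expect_true(all(diff(q) >= 0))
})

test_that("linear transition flows interpolate the cardiac-output shares", {
  expect_equal(maternal_transition_flow("adip", 0), 0.085 * 301.78,
               tolerance = 1e-12)
  expect_equal(maternal_transition_flow("thyr", 0), 0.015 * 301.78,
               tolerance = 1e-12)
  expect_equal(maternal_transition_flow("bran", 40),
               0.088 * maternal_cardiac_output(40), tolerance = 1e-12)
  expect_equal(maternal_kidney_flow(0, method = "transition"),
               0.17 * 301.78, tolerance = 1e-12)
  expect_error(maternal_transition_flow("lung", 10))
})

test_that("maternal flow conservation holds to machine precision", {
  tt <- seq(0, 42, by = 0.1)
  total <- maternal_transition_flow("adip", tt) +
    maternal_transition_flow("bran", tt) +
    maternal_kidney_flow(tt) +
    maternal_transition_flow("gutx", tt) +
    maternal_transition_flow("livr", tt) +
    maternal_transition_flow("thyr", tt) +
    maternal_placenta_flow(tt) +
    maternal_rest_of_body_flow(tt)
  expect_equal(total, maternal_cardiac_output(tt), tolerance = 1e-12)
})

test_that("rest-of-body volume stays within the 31-34 L band", {
  expect_equal(maternal_rest_of_body_volume(0), 31.1, tolerance = 0.05)
  tt <- seq(0, 40, by = 0.1)
  v <- maternal_rest_of_body_volume(tt)
  expect_true(all(v > 30 & v < 35))
  expect_equal(round(min(v)), 31)
  expect_equal(round(max(v)), 34)
  # the two RBC-model variants shift the balance by at most ~0.33 L
  # (their curves differ most, ~0.32 L, around 20 weeks) and both stay
  # inside the band
  v2 <- maternal_rest_of_body_volume(tt, rbc_method = "hematocrit")
  expect_lt(max(abs(v - v2)), 0.35)
  expect_true(all(v2 > 30 & v2 < 35))
})

test_that("fat-free-mass balance is nearly continuous at conception", {
  jump <- abs(maternal_fat_free_volume(2 - 1e-9) -
                maternal_fat_free_volume(2 + 1e-9))
  expect_lt(jump, 0.01)
})

test_that("rest-of-body flow spans roughly 47 to 97 L/h", {
  expect_equal(maternal_rest_of_body_flow(0), 49.4, tolerance = 0.1)
  tt <- seq(0, 40, by = 0.1)
  q <- maternal_rest_of_body_flow(tt)
  expect_equal(round(min(q)), 47)
  expect_equal(round(max(q)), 97)
})

test_that("allometric GFR recovers the 125 mL/min reference at 70 kg", {
  expect_equal(maternal_gfr(0, method = "allometric"),
               125 * (61.103 / 70)^0.75, tolerance = 1e-12)
  # at the age where maternal mass reaches 70 kg the allometric GFR is 125
  t70 <- uniroot(function(t) maternal_mass(t) - 70, c(10, 40))$root
  expect_equal(maternal_gfr(t70, method = "allometric"), 125,
               tolerance = 1e-6)
})
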