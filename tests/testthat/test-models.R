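test_that("field conversions follow the stated geometric rules", {
  expect_equal(field_to_deg2(field_geometry("rectangular", c(10, 20),
                                            allow_large_flat = TRUE)), 200)
  # frozen from independent high-precision evaluation of (pi/4) D^2
  expect_equal(
    field_to_deg2(field_geometry("circular", 53.13, allow_large_flat = TRUE)),
    2217.0195, tolerance = 1e-6)
  # frozen from independent evaluation of 6566 pi (1 - cos(D pi / 360))
  expect_equal(
    field_to_deg2(field_geometry("circular", 53.1,
                                 conversion = "spherical_cap")),
    2175.30125, tolerance = 1e-7)
  expect_warning(
    a <- field_to_deg2(field_geometry("circular", 10,
                                      conversion = "legacy_toolbox")),
    "legacy_toolbox")
  expect_equal(a, 10 / 2 * pi)
})

test_that("flat and spherical-cap conversions agree in the small-angle limit", {
  for (d in c(0.5, 1, 2, 5, 9.9)) {
    flat <- field_to_deg2(field_geometry("circular", d))
    cap <- field_to_deg2(field_geometry("circular", d,
                                        conversion = "spherical_cap"))
    expect_equal(cap / flat, 1, tolerance = 0.01)
  }
  # the limiting ratio is 6566 / ((180/pi)^2 * 2) = 1.0000594: the printed
  # steradian-to-deg^2 factor 6566 is itself rounded
  r_small <- field_to_deg2(field_geometry("circular", 0.01,
                                          conversion = "spherical_cap")) /
    field_to_deg2(field_geometry("circular", 0.01))
  expect_equal(r_small, 6566 / (2 * (180 / pi)^2), tolerance = 1e-6)
})

test_that("invalid field geometries are rejected", {
  expect_error(field_geometry("circular", 0), "invalid")
  expect_error(field_geometry("circular", -5), "invalid")
  expect_error(field_geometry("circular", 180), "invalid")
  expect_error(field_geometry("rectangular", 10), "2 angular")
  expect_warning(field_geometry("circular", 40), "spherical_cap")
})

test_that("limiting-case model values match the closed forms", {
  expect_equal(predict_diameter("moon_spencer", 1)$diameter_mm, 4.9)
  expect_equal(predict_diameter("holladay", 1e-12)$diameter_mm, 7,
               tolerance = 1e-3)
  expect_equal(predict_diameter("blackie_howland", 1)$diameter_mm, 5.697)
  expect_warning(predict_diameter("blackie_howland", 100), "10 cd/m")
})

test_that("the unified formula reduces to its base at the reference age", {
  cond <- viewing_conditions(100, benchmark_field(),
                             age_years = 28.58, eyes = 2)
  p <- predict_diameter("watson_yellott", cond)
  expect_equal(p$diameter_mm, p$intermediate_dsdw_mm)
})

test_that("binocular base diameter equals Stanley & Davies", {
  f <- benchmark_field()
  for (L in c(0.5, 10, 100, 5000)) {
    sd_ <- predict_diameter("stanley_davies", viewing_conditions(L, f))
    wy <- predict_diameter("watson_yellott",
                           viewing_conditions(L, f, age_years = 40,
                                              eyes = 2))
    expect_equal(wy$intermediate_dsdw_mm, sd_$diameter_mm)
  }
})

test_that("models needing extra parameters fail informatively without them", {
  expect_error(predict_diameter("stanley_davies", 100), "field")
  expect_error(predict_diameter("barten", 100), "field")
  expect_error(
    predict_diameter("watson_yellott", viewing_conditions(100,
                                                          benchmark_field())),
    "missing parameter")
  expect_error(viewing_conditions(-1), "positive")
  expect_error(viewing_conditions(100, eyes = 3), "1 or 2")
  expect_warning(viewing_conditions(100, age_years = 16.5), "17-83")
})

test_that("every model is strictly decreasing in luminance", {
  L <- 10^seq(log10(0.01), 4, length.out = 400)
  f <- benchmark_field()
  for (m in pupil_model_ids()) {
    if (m == "watson_yellott") {
      for (age in c(17, 50, 83)) {
        d <- vapply(L, function(l) predict_diameter(m,
          viewing_conditions(l, f, age_years = age, eyes = 2))$diameter_mm,
          numeric(1))
        expect_true(all(diff(d) < 0), info = paste(m, "age", age))
      }
    } else {
      d <- suppressWarnings(vapply(L, function(l) predict_diameter(m,
        viewing_conditions(l, f))$diameter_mm, numeric(1)))
      expect_true(all(diff(d) < 0), info = m)
    }
  }
})

test_that("model outputs respect their structural bounds", {
  L <- 10^seq(-4, 6, length.out = 200)
  crawford <- vapply(L, function(l)
    predict_diameter("crawford", l)$diameter_mm, numeric(1))
  expect_true(all(crawford > 2.8 & crawford < 7.2))
  ms <- vapply(L, function(l)
    predict_diameter("moon_spencer", l)$diameter_mm, numeric(1))
  expect_true(all(ms > 1.9 & ms < 7.9))
  for (alpha_d in c(1, 10, 53.13)) {
    f <- field_geometry("circular", alpha_d, allow_large_flat = TRUE)
    sd_ <- vapply(L, function(l)
      predict_diameter("stanley_davies",
                       viewing_conditions(l, f))$diameter_mm, numeric(1))
    expect_true(all(sd_ > 2.0 & sd_ <= 7.75))
    dsdw <- vapply(L, function(l)
      predict_diameter("watson_yellott",
                       viewing_conditions(l, f, age_years = 50,
                                          eyes = 1))$intermediate_dsdw_mm,
      numeric(1))
    expect_true(all(dsdw > 2.0 & dsdw <= 7.75))
  }
})

test_that("age sensitivity changes sign where the age term vanishes", {
  d_crit <- 0.02132 / 0.009562  # ~2.2297 mm
  # pick L*alpha values whose base diameter straddles the critical value
  f_small <- field_geometry("circular", 53.13, allow_large_flat = TRUE)
  dy <- function(L, age) predict_diameter("watson_yellott",
    viewing_conditions(L, f_small, age_years = age, eyes = 2))
  low <- dy(1e4, 40)   # D_SDW well below d_crit?
  expect_true(low$intermediate_dsdw_mm < d_crit)
  hi <- dy(10, 40)
  expect_true(hi$intermediate_dsdw_mm > d_crit)
  # below the critical base diameter, older -> larger predicted pupil
  expect_gt(dy(1e4, 60)$diameter_mm, dy(1e4, 30)$diameter_mm)
  # above it, older -> smaller
  expect_lt(dy(10, 60)$diameter_mm, dy(10, 30)$diameter_mm)
})
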