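test_that("glare kernel matches direct evaluation and is monotone", {
  obs <- default_observer()
  expect_equal(glare_function(1, obs), 15.319, tolerance = 1e-4)
  expect_equal(glare_function(0.5, obs), 101.17, tolerance = 1e-4)
  # pigment terms vanish at p = 0
  obs0 <- observer_profile(50, 0)
  expect_equal(glare_function(2, obs0),
               10 / 8 + (5 / 4) * (1 + (50 / 62.5)^4))
  thetas <- c(0.05, 0.1, 0.5, 1, 2, 5, 10, 30, 60, 90)
  for (p in c(0, 0.5, 1.2)) {
    g <- glare_function(thetas, observer_profile(40, p))
    expect_true(all(g > 0))
    expect_true(all(diff(g) < 0))
  }
  expect_error(glare_function(0, obs), "positive")
  expect_error(glare_function(-1, obs), "positive")
})

test_that("age factor branches, boundary policy and clamping", {
  expect_equal(age_factor(30), 1.04601, tolerance = 1e-5)
  expect_equal(age_factor(70), 2.97394, tolerance = 1e-5)
  expect_identical(age_factor(19), 0.99)
  # branch policy: first branch up to and including 64
  expect_equal(age_factor(64), (64 - 19)^2 / 2160 + 0.99)
  expect_equal(age_factor(64.01), (64.01 - 56.6)^2 / 116.3 + 1.43)
  ages1 <- seq(19, 64, by = 1)
  expect_true(all(diff(age_factor(ages1)) >= 0))
  ages2 <- seq(64.1, 75, by = 0.5)
  expect_true(all(diff(age_factor(ages2)) >= 0))
  expect_true(all(age_factor(seq(19, 75, by = 0.5)) >= 0.99))
  expect_warning(af <- age_factor(80), "clamped")
  expect_equal(af, age_factor(75))
  expect_warning(expect_equal(age_factor(10), age_factor(19)), "clamped")
})

test_that("corneal illuminance converts radiometric to photometric units", {
  calib <- glare_calibration()
  expect_identical(
    visual_corneal_illuminance(laser_exposure(532, 0, 1), calib), 0)
  # V(555) = 1: 0.1 mW/cm2 = 1 W/m2 -> 683 lux
  expect_equal(
    visual_corneal_illuminance(laser_exposure(555, 0.1, 1), calib), 683)
  # 532 nm against a direct table interpolation oracle
  v532 <- approx(seq(380, 780, 5),
                 dazzlesim:::cie_photopic_table()$efficiency, 532)$y
  expect_equal(
    visual_corneal_illuminance(laser_exposure(532, 0.1, 1), calib),
    683 * v532)
  expect_error(photopic_efficiency(300), "photopic")
  expect_error(laser_exposure(900, 1, 1), "photopic")
})

test_that("veiling luminance is linear in irradiance with the correct factor", {
  obs <- default_observer()
  sc <- scene_conditions(235, 0.89, 2.75)
  calib <- glare_calibration()
  # per-unit-illuminance factor at (Lb = 235, theta = 1, A = 30, p = 0.5)
  unit_e <- 1 / (683 * photopic_efficiency(532) * 10)  # E_v = 1 lux
  lv <- veiling_luminance(1, obs, sc, laser_exposure(532, unit_e, 1), calib)
  expect_equal(lv, 36.93, tolerance = 1e-3)
  # exact linearity: slope test at two points
  e1 <- veiling_luminance(1, obs, sc, laser_exposure(532, 0.4, 1), calib)
  e2 <- veiling_luminance(1, obs, sc, laser_exposure(532, 0.8, 1), calib)
  expect_identical(e2, 2 * e1)
  expect_identical(
    veiling_luminance(1, obs, sc, laser_exposure(532, 0, 1), calib), 0)
  # decreasing in angle
  lvs <- veiling_luminance(c(0.5, 1, 2, 4, 8), obs, sc,
                           laser_exposure(532, 1, 1), calib)
  expect_true(all(diff(lvs) < 0))
})

test_that("threshold contrast: age scaling, size monotonicity, glare invariance", {
  calib <- glare_calibration()
  sc <- reference_scene()
  # AF(19) = 0.99 factors out
  omega <- threshold_contrast(sc, observer_profile(19, 0.5), calib) / 0.99
  expect_equal(threshold_contrast(sc, observer_profile(30, 0.5), calib),
               omega * age_factor(30))
  # decreasing in target size for fixed Lb and A (oracle: grid evaluation)
  for (lb in c(0.05, 1, 13.14, 235)) {
    cthr <- vapply(c(0.5, 1, 2, 4, 8), function(a) {
      threshold_contrast(scene_conditions(lb, 0.89, a), default_observer(),
                         calib)
    }, numeric(1))
    expect_true(all(diff(cthr) < 0))
  }
  # no glare terms: independent of exposure by construction (signature takes
  # no exposure); sanity that value is positive and finite across regimes
  lbs <- c(0.001, 0.00418, 0.05, 0.6, 13.14, 491.52)
  vals <- vapply(lbs, function(lb) {
    threshold_contrast(scene_conditions(lb, 0.89, 2.75), default_observer(),
                       calib)
  }, numeric(1))
  expect_true(all(is.finite(vals) & vals > 0))
})

test_that("visibility calibration functions join continuously across branches", {
  for (f in list(adrian_sqrt_phi, adrian_sqrt_l)) {
    for (b in c(0.00418, 0.6)) {
      lo <- f(b * (1 - 1e-9)); hi <- f(b * (1 + 1e-9))
      expect_lt(abs(lo - hi) / hi, 0.02)
    }
    x <- f(10^seq(-3, 2.5, length.out = 50))
    expect_true(all(is.finite(x) & x > 0))
  }
})

test_that("effective contrast identities", {
  sc <- reference_scene()
  expect_identical(effective_contrast(sc, 0), sc$target_contrast)
  expect_equal(effective_contrast(sc, sc$ambient_luminance),
               sc$target_contrast / 2)
  expect_lt(effective_contrast(sc, 1e9), 1e-6)
  lvs <- seq(0, 100, by = 10)
  expect_true(all(diff(effective_contrast(sc, lvs)) < 0))
  expect_error(effective_contrast(sc, -1), ">= 0")
})

test_that("dazzle angle and MDE are mutual inverses over a parameter grid", {
  calib <- glare_calibration()
  cases <- expand.grid(theta = c(1, 2.75, 6), lb = c(0.5, 13.14, 235),
                       age = c(30, 55), p = c(0, 0.5), corig = c(0.4, 0.89))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    obs <- observer_profile(cs$age, cs$p)
    sc <- scene_conditions(cs$lb, cs$corig, 2.75)
    e <- mde(cs$theta, obs, sc, calib)
    u <- dazzle_angle(obs, sc, laser_exposure(532, e, 0.5), calib)
    expect_equal(u, cs$theta, tolerance = 1e-3)
  }
})

test_that("dazzle angle limits and monotonicity", {
  obs <- default_observer()
  sc <- reference_scene()
  expect_identical(dazzle_angle(obs, sc, laser_exposure(532, 0, 0.5)), 0)
  us <- vapply(c(0.1, 0.5, 1.537), function(p) {
    dazzle_angle(obs, sc, reference_exposure(p))
  }, numeric(1))
  expect_true(all(diff(us) > 0))      # non-decreasing in irradiance
  # non-increasing across the reference ambient-luminance grid
  lbs <- c(0.005, 0.05, 0.50, 4.55, 13.14, 49.76, 491.52)
  u_lb <- vapply(lbs, function(lb) {
    suppressWarnings(dazzle_angle(obs, scene_conditions(lb, 0.89, 2.75),
                                  reference_exposure()))
  }, numeric(1))
  expect_true(all(diff(u_lb) <= 1e-6))
  expect_gte(u_lb[1], u_lb[length(u_lb)])
})

test_that("MDE is increasing in angle and rejects degenerate scenes", {
  obs <- default_observer()
  sc <- reference_scene()
  m <- mde(c(1, 2, 4, 8), obs, sc)
  expect_true(all(diff(m) > 0))
  # unlit target already below threshold -> degenerate
  dim_scene <- scene_conditions(0.001, 0.02, 0.1)
  expect_gt(threshold_contrast(dim_scene, obs), dim_scene$target_contrast)
  expect_error(mde(1, obs, dim_scene), "degenerate")
})

test_that("beam irradiance follows the far-field divergence model", {
  src <- laser_source(100, 1.5)
  expect_equal(eye_irradiance_at_distance(src, 300), 0.0629, tolerance = 1e-3)
  expect_equal(eye_irradiance_at_distance(src, 60), 1.572, tolerance = 1e-3)
  expect_equal(eye_irradiance_at_distance(src, 100),
               4 * eye_irradiance_at_distance(src, 200))
  expect_error(eye_irradiance_at_distance(src, 0), "> 0")
})

test_that("MPE for visible CW aversion response", {
  expect_equal(mpe_visible_cw(0.25), 25.46, tolerance = 1e-3)
  expect_identical(mpe_visible_cw(1), 18)
  ts <- c(0.1, 0.25, 1, 5, 10)
  expect_true(all(diff(mpe_visible_cw(ts)) < 0))
  expect_error(mpe_visible_cw(0), "regime")
  expect_error(mpe_visible_cw(11), "regime")
})

test_that("NOHD inverts the irradiance model at the MPE", {
  src <- laser_source(100, 1.5)
  d <- nohd(src)
  expect_equal(d, 47.1, tolerance = 2e-3)   # printed to 0.1 m
  # round trip at 1e-6 relative tolerance
  expect_equal(eye_irradiance_at_distance(src, d) * 10, mpe_visible_cw(),
               tolerance = 1e-6)
  expect_lt(nohd(src, 1e12), 1e-3)
  # already below MPE at the aperture
  wide <- laser_source(1, 1.5, initial_beam_diameter_m = 0.5)
  expect_identical(nohd(wide), 0)
})

test_that("NODD matches its defining construction and ambient trend", {
  obs <- default_observer()
  sc <- reference_scene()
  src <- laser_source(100, 1.5)
  d <- nodd(src, obs, sc)
  e_ref <- mde(sc$target_size_deg / 2, obs, sc)
  expect_equal(eye_irradiance_at_distance(src, d), e_ref, tolerance = 1e-6)
  # brighter ambient -> dazzle harder to achieve -> shorter NODD
  d_bright <- nodd(src, obs, scene_conditions(491.52, 0.89, 2.75))
  d_dim <- nodd(src, obs, scene_conditions(0.05, 0.89, 2.75))
  expect_gt(d_dim, d_bright)
})
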