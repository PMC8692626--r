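p0 <- model_params()

test_that("respiration collapses to the allometric term at the base temperature", {
  set.seed(11)
  m <- runif(100, 10, 400)
  # T = T0 makes the Arrhenius exponent exactly zero
  expect_identical(respiration_rate(m, 0, p0), p0$b * m^0.75 * 86400)
  expect_equal(respiration_rate(100, 0, p0), 0.683052, tolerance = 1e-6)
})

test_that("the Arrhenius factor suppresses respiration in sub-zero water", {
  # 0.6831 * exp(-0.65 / (k * 272.15 * 273.15)), frozen from scalar evaluation
  expect_equal(respiration_rate(100, -1, p0), 0.6171441, tolerance = 1e-5)
  # E = 0 switches temperature dependence off entirely
  pe0 <- model_params(E_eV = 0)
  expect_equal(respiration_rate(50, -2, pe0), respiration_rate(50, 10, pe0))
})

test_that("respiration rejects impossible inputs and warns outside the oceanographic window", {
  expect_error(respiration_rate(0, 0, p0), "positive")
  expect_error(respiration_rate(-5, 0, p0), "positive")
  expect_error(respiration_rate(10, -300, p0), "absolute zero")
  expect_warning(respiration_rate(10, 35, p0), "sanity window")
})

test_that("diapause duration spends the reserve down to the retained fraction", {
  r <- respiration_rate(100, 0, p0)
  expect_equal(diapause_duration(150, r, p0), 120 / r)
  expect_equal(diapause_duration(150, r, p0), 175.6821, tolerance = 1e-4)
  expect_equal(diapause_duration(0, r, p0), 0)
  expect_equal(diapause_duration(300, r, p0), 2 * diapause_duration(150, r, p0))
  expect_error(diapause_duration(10, 0, p0), "positive")
})

test_that("post-diapause reserve equals the retained fraction of the pre-diapause reserve", {
  set.seed(12)
  w <- runif(500, 1, 300)
  r <- respiration_rate(runif(500, 10, 300), runif(500, -2, 6), p0)
  D <- diapause_duration(w, r, p0)
  expect_equal(w - r * D, p0$retained_fraction * w, tolerance = 1e-12)
})

test_that("capability boundary is closed at the duration threshold", {
  expect_false(is_overwinter_capable(149.999, p0))
  expect_true(is_overwinter_capable(150, p0))
  expect_true(is_overwinter_capable(212, p0))
  expect_error(is_overwinter_capable(-1, p0), "non-negative")
})

test_that("required reserve inverts the duration model", {
  r <- respiration_rate(100, 0, p0)
  expect_equal(required_reserve(r, p0), 150 * r / 0.8)
  expect_equal(required_reserve(r, p0), 128.0722, tolerance = 1e-4)
  p_ret0 <- model_params(retained_fraction = 0)
  expect_equal(required_reserve(2, p_ret0), p_ret0$D_threshold_days * 2)
  # round-trip over random rates
  set.seed(13)
  r_vec <- runif(1000, 0.05, 5)
  expect_equal(diapause_duration(required_reserve(r_vec, p0), r_vec, p0),
               rep(p0$D_threshold_days, 1000), tolerance = 1e-12)
})

test_that("required reserve agrees with bisection on the duration model", {
  set.seed(14)
  for (i in 1:25) {
    params <- model_params(retained_fraction = runif(1, 0, 0.5),
                           D_threshold_days = runif(1, 50, 300))
    r <- runif(1, 0.05, 5)
    # independent bisection: find w with duration(w, r) = threshold
    lo <- 0; hi <- 1e6
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (diapause_duration(mid, r, params) < params$D_threshold_days) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    expect_equal(required_reserve(r, params), (lo + hi) / 2, tolerance = 1e-9)
  }
})

test_that("duration increases with reserve and decreases with mass and temperature", {
  set.seed(15)
  w <- 150
  m_grid <- sort(runif(50, 10, 400))
  T_grid <- sort(runif(50, -3, 10))
  # r strictly increasing in m and in T (E > 0)
  expect_true(all(diff(respiration_rate(m_grid, 0, p0)) > 0))
  expect_true(all(diff(respiration_rate(100, T_grid, p0)) > 0))
  # hence D strictly decreasing in m and T, increasing in w
  D_m <- diapause_duration(w, respiration_rate(m_grid, 0, p0), p0)
  D_T <- diapause_duration(w, respiration_rate(100, T_grid, p0), p0)
  expect_true(all(diff(D_m) < 0))
  expect_true(all(diff(D_T) < 0))
  w_grid <- sort(runif(50, 0.1, 300))
  D_w <- diapause_duration(w_grid, respiration_rate(100, 0, p0), p0)
  expect_true(all(diff(D_w) > 0))
})

test_that("maximum diapause duration bounds the realised duration", {
  a <- lipid_allometry(20, 3)
  # hand calculation: 0.8 * 160 / 0.683052
  expect_equal(max_diapause_duration(2, 100, 0, a, p0), 187.3906,
               tolerance = 1e-4)
  r <- respiration_rate(100, 0, p0)
  w_max <- max_lipid_reserve(2, a)
  expect_equal(diapause_duration(w_max, r, p0),
               max_diapause_duration(2, 100, 0, a, p0))
  expect_equal(diapause_duration(0.5 * w_max, r, p0),
               0.5 * max_diapause_duration(2, 100, 0, a, p0))
  set.seed(16)
  w <- runif(200, 0, w_max)
  expect_true(all(diapause_duration(w, r, p0) <=
                    max_diapause_duration(2, 100, 0, a, p0) + 1e-12))
})

test_that("assess_individuals runs the whole chain and satisfies the profile invariants", {
  a <- lipid_allometry(20, 3)
  recs <- make_records(area = 2, M = 200, L = 2, n = 2)
  out <- assess_individuals(recs, temp_C = 0, allometry = a, params = p0)
  prof <- out$profiles
  expect_equal(nrow(prof), 2)
  # chained oracle values
  expect_equal(prof$lipid_carbon_ug[1], 0.3530256, tolerance = 1e-6)
  expect_equal(prof$structural_carbon_ug[1], 200 - 0.3530256, tolerance = 1e-6)
  # invariants: conservation, capability consistency, determinism
  expect_equal(prof$lipid_carbon_ug + prof$structural_carbon_ug,
               recs$total_carbon_ug, tolerance = 1e-9)
  expect_equal(prof$capable, prof$diapause_days >= p0$D_threshold_days)
  expect_identical(prof[1, -1], prof[2, -1])
  # empty lipid sac: zero duration, not capable
  empty <- assess_individuals(make_records(area = 0), temp_C = 0,
                              allometry = a, params = p0)
  expect_equal(empty$profiles$diapause_days, 0)
  expect_false(empty$profiles$capable)
})

test_that("assess_individuals excludes infeasible records rather than clamping", {
  a <- lipid_allometry(20, 3)
  recs <- make_records(area = c(2, 20), M = c(200, 5), n = 2)
  expect_message(
    out <- assess_individuals(recs, temp_C = 0, allometry = a, params = p0),
    "excluded"
  )
  expect_equal(nrow(out$profiles), 1)
  expect_equal(out$rejected$individual_id, "ind-002")
  expect_match(out$rejected$reason, "infeasible")
})

test_that("temperature assignment follows the configured mode", {
  prof <- ctd_profile(c(0, 100, 1000), c(10, 10, -1), station = "S1")
  recs <- make_records(n = 1, upper = 0, lower = 100)
  a <- lipid_allometry(20, 3)
  # stratum midpoint: 50 m on a constant 10 degC surface layer
  out_mid <- assess_individuals(recs, ctd = prof, allometry = a, params = p0)
  expect_equal(out_mid$profiles$assigned_temp_C, 10)
  # fixed overwintering temperature
  p_fix <- model_params(temperature_mode = "fixed", fixed_temp_C = -0.5)
  out_fix <- assess_individuals(recs, ctd = prof, allometry = a, params = p_fix)
  expect_equal(out_fix$profiles$assigned_temp_C, -0.5)
  # deep-layer mean below the cutoff
  p_deep <- model_params(temperature_mode = "deep_mean")
  out_deep <- assess_individuals(recs, ctd = prof, allometry = a, params = p_deep)
  expect_equal(out_deep$profiles$assigned_temp_C,
               mean_temperature(prof, 250, 1000))
})
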