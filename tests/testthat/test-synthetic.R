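test_that("generated CTD profiles honour the station archetype and the seed", {
  cfg <- small_config()
  prof <- generate_ctd(cfg, "X", seed = 5)
  expect_s3_class(prof, "ctd_profile")
  expect_true(all(diff(prof$samples$depth_m) > 0))
  expect_equal(mean_temperature(prof, 0, 125), 4.3, tolerance = 0.1)
  expect_equal(temperature_at_depth(prof, 900), -0.5, tolerance = 0.2)
  # determinism: identical seed, identical profile
  expect_identical(prof$samples, generate_ctd(cfg, "X", seed = 5)$samples)
  expect_false(identical(prof$samples, generate_ctd(cfg, "X", seed = 6)$samples))
})

test_that("default archetypes reproduce the three-station surface means", {
  cfg <- generator_config()
  for (st in names(cfg$stations)) {
    prof <- generate_ctd(cfg, st, seed = 3)
    expect_equal(mean_temperature(prof, 0, 125),
                 cfg$stations[[st]]$surface_mean_C, tolerance = 0.1)
  }
})

test_that("generated individuals pass every biometric precondition by construction", {
  cfg <- generator_config()
  pop <- generate_population(cfg, "S2", seed = 17, n = 300)
  out <- validate_individuals(pop$records)
  expect_equal(nrow(out$rejected), 0)
  # w < M always: the biometric pipeline accepts every record
  assessed <- assess_individuals(pop$records, ctd = pop$ctd)
  expect_equal(nrow(assessed$rejected), 0)
  expect_equal(nrow(assessed$profiles), 300)
  # determinism
  pop2 <- generate_population(cfg, "S2", seed = 17, n = 300)
  expect_identical(pop$records, pop2$records)
})

test_that("the biometric pipeline recovers the latent lipid carbon exactly", {
  cfg <- generator_config()
  pop <- generate_population(cfg, "S1", seed = 23, n = 200)
  assessed <- assess_individuals(pop$records, ctd = pop$ctd)
  expect_equal(assessed$profiles$lipid_carbon_ug,
               pop$ground_truth$latent$lipid_carbon_ug, tolerance = 1e-9)
  expect_equal(assessed$profiles$structural_carbon_ug,
               pop$ground_truth$latent$structural_carbon_ug, tolerance = 1e-9)
  # capability matches the latent threshold crossing
  lat <- pop$ground_truth$latent
  expect_equal(assessed$profiles$capable, lat$fullness >= lat$required_fullness)
})

test_that("saturated and empty fullness drive the capable fraction to its limits", {
  # a deep, cold, CV-only station isolates the fullness limit behaviour
  deep_station <- list(
    D = list(surface_mean_C = 4, deep_temp_C = -0.5, total_cv_ind_m2 = 5000,
             bands = tibble::tibble(upper_m = 250, lower_m = 1000, weight = 1))
  )
  # fullness concentrated near 1 in cold deep water: nearly everyone is capable
  cfg_full <- generator_config(stations = deep_station,
                               stage_mix = c(CV = 1),
                               fullness_shape1 = 400, fullness_shape2 = 1)
  pop_full <- generate_population(cfg_full, "D", seed = 31, n = 200)
  assessed <- assess_individuals(pop_full$records, ctd = pop_full$ctd)
  expect_gte(capable_fraction(assessed$profiles)$fraction, 0.95)
  expect_gte(pop_full$ground_truth$true_capable_fraction, 0.9)
  # fullness concentrated near 0: no one is capable and durations collapse
  cfg_empty <- generator_config(stations = deep_station,
                                stage_mix = c(CV = 1),
                                fullness_shape1 = 0.02, fullness_shape2 = 50)
  pop_empty <- generate_population(cfg_empty, "D", seed = 31, n = 200)
  assessed0 <- assess_individuals(pop_empty$records, ctd = pop_empty$ctd)
  expect_equal(capable_fraction(assessed0$profiles)$fraction, 0)
  expect_lt(max(assessed0$profiles$diapause_days), 150)
})

test_that("generated catch tables are seeded, validated and zero where the mixture is empty", {
  cfg <- generator_config()
  ct <- generate_catch_table(cfg, "S3", seed = 41)
  expect_identical(ct, generate_catch_table(cfg, "S3", seed = 41))
  expect_silent(validate_catch_table(ct))
  # a station whose vertical mixture stops at 250 m catches nothing deeper
  cfg_shallow <- generator_config(stations = list(
    Y = list(surface_mean_C = 3, deep_temp_C = -0.5, total_cv_ind_m2 = 5000,
             bands = tibble::tibble(upper_m = 5, lower_m = 250, weight = 1))
  ))
  ct_shallow <- generate_catch_table(cfg_shallow, "Y", seed = 41)
  deep_rows <- ct_shallow[ct_shallow$stratum_upper_m >= 250, ]
  expect_true(all(deep_rows$count == 0))
})

test_that("negative binomial overdispersion is available for catch counts", {
  cfg <- small_config(overdispersion = 2)
  ct <- generate_catch_table(cfg, "X", seed = 7)
  expect_true(all(ct$count >= 0))
  expect_identical(ct, generate_catch_table(cfg, "X", seed = 7))
})

test_that("artifact streams are independent: regenerating one leaves the others unchanged", {
  cfg <- generator_config()
  ct_before <- generate_catch_table(cfg, "S1", seed = 77)
  invisible(generate_population(cfg, "S1", seed = 77, n = 50))
  ct_after <- generate_catch_table(cfg, "S1", seed = 77)
  expect_identical(ct_before, ct_after)
})

test_that("generate_station writes the three CSVs plus ground truth JSON", {
  cfg <- generator_config()
  out_dir <- withr::local_tempdir()
  bundle <- generate_station(cfg, "S1", seed = 9, out_dir = out_dir)
  files <- list.files(out_dir)
  expect_setequal(files, c("individuals_S1.csv", "catch_S1.csv", "ctd_S1.csv",
                           "ground_truth_S1.json"))
  gt <- jsonlite::read_json(file.path(out_dir, "ground_truth_S1.json"))
  expect_equal(gt$true_capable_fraction,
               bundle$ground_truth$true_capable_fraction, tolerance = 1e-9)
  expect_equal(gt$true_total_cv_ind_m2, 2592)
  # the written CSVs reload into the same tables
  reread <- read_individuals(file.path(out_dir, "individuals_S1.csv"))
  expect_equal(nrow(reread$records), nrow(bundle$records))
})
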