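# Shared fixtures built in code.

# A linear 0-100 m profile: 0 degC at surface, 10 degC at 100 m.
linear_profile <- function() {
  ctd_profile(c(0, 100), c(0, 10), station = "lin")
}

# A wiggly multi-knot profile for integration oracles.
wiggly_profile <- function() {
  set.seed(424242)
  z <- sort(sample(0:500, 40))
  z <- unique(c(0, z, 500))
  ctd_profile(z, 5 * cos(z / 40) + stats::rnorm(length(z), 0, 0.3),
              station = "wiggle")
}

# A minimal valid individual-record table.
make_records <- function(area = 2, M = 200, L = 2, n = 1,
                         station = "S1", stage = "CV",
                         upper = 250, lower = 375) {
  tibble::tibble(
    individual_id = sprintf("ind-%03d", seq_len(n)),
    station = station,
    stage = stage,
    stratum_upper_m = upper,
    stratum_lower_m = lower,
    prosome_length_mm = L,
    lipid_area_mm2 = area,
    total_carbon_ug = M
  )
}

# One-stratum catch fixture: 50 individuals in 250 m^3 over 0-100 m.
make_catch <- function(upper = 0, lower = 100, volume = 250, count = 50,
                       stage = "CV", station = "S1") {
  tibble::tibble(
    station = station, season = "late",
    stratum_upper_m = upper, stratum_lower_m = lower,
    volume_filtered_m3 = volume,
    taxon = "C. finmarchicus", stage = stage, count = count
  )
}

# Small generator config for fast synthetic tests (two strata kept coarse
# where full 8-stratum resolution is not the point).
small_config <- function(...) {
  generator_config(
    stations = list(
      X = list(
        surface_mean_C = 4.3, deep_temp_C = -0.5, total_cv_ind_m2 = 15000,
        bands = tibble::tibble(upper_m = c(5, 250), lower_m = c(250, 1000),
                               weight = c(0.25, 0.75))
      )
    ),
    ...
  )
}
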