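#' Configuration for the synthetic station generator
#'
#' Describes the study conditions the generator emulates: late-summer Fram
#' Strait stations with a warm Atlantic-influenced surface layer over cold
#' deep water, depth-stratified multinet sampling with a 1 m\eqn{^2} net over
#' eight intervals between 5 and 1000 m, stage-structured vertical
#' distributions with a deep copepodite-V (CV) mode at the easternmost
#' station, and per-individual biometrics driven by a Beta-distributed lipid
#' fullness and allometric structural mass.
#'
#' Station archetypes default to three stations whose 0–125 m mean
#' temperatures (2.362, 3.643, 4.319 \eqn{^\circ}C), CV depth-integrated
#' abundances (2 592, 12 098, 15 710 ind m\eqn{^{-2}}) and deep
#' (> 250 m) abundance fractions (~0.19, ~0.26, ~0.78) mirror the published
#' late-summer population state these tools are designed to analyse.
#'
#' @param stations Named list of station archetypes; each a list with
#'   `surface_mean_C`, `deep_temp_C`, `total_cv_ind_m2` and `bands` (a data
#'   frame `upper_m`, `lower_m`, `weight` describing the CV vertical mixture;
#'   weights must sum to 1).
#' @param stratum_bounds Increasing vector of net-interval bounds, m.
#' @param net_area_m2 Mouth area of the net, m\eqn{^2}.
#' @param stage_mix Named weights over developmental stages for generated
#'   individuals and catches (must sum to 1).
#' @param length_mean_mm,length_sd_mm Stage-specific prosome-length normal
#'   parameters (mm); lengths are truncated at zero.
#' @param fullness_shape1,fullness_shape2 Beta parameters of lipid fullness.
#' @param structural_coefficient,structural_exponent,structural_sdlog
#'   Structural-carbon allometry \eqn{m = a L^{b}} (\eqn{\mu}g C) with
#'   multiplicative lognormal noise.
#' @param n_per_stratum Individuals sub-sampled per depth stratum for the
#'   body-condition table.
#' @param allometry [lipid_allometry()] used to place individual lipid
#'   reserves (`w = fullness * w_max(L)`).
#' @param surface_halfrange_C Half-range of the linear surface-layer
#'   temperature gradient (controls the 0–125 m SD).
#' @param thermocline_bottom_m Depth at which the profile reaches the deep
#'   temperature.
#' @param grid_dz_m CTD sampling interval, m.
#' @param noise_sd_C SD of the small-scale temperature noise.
#' @param overdispersion `NULL` for Poisson catch counts, or a negative
#'   binomial `size` parameter for overdispersed counts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(stations = default_station_archetypes(),
                             stratum_bounds = c(5, 125, 250, 375, 500, 625, 750, 875, 1000),
                             net_area_m2 = 1,
                             stage_mix = c(CIV = 0.35, CV = 0.5, CVI = 0.15),
                             length_mean_mm = c(CIV = 1.9, CV = 2.5, CVI = 2.8),
                             length_sd_mm = 0.15,
                             fullness_shape1 = 2,
                             fullness_shape2 = 2,
                             structural_coefficient = 6,
                             structural_exponent = 3,
                             structural_sdlog = 0.1,
                             n_per_stratum = 10,
                             allometry = lipid_allometry(),
                             surface_halfrange_C = 2.5,
                             thermocline_bottom_m = 400,
                             grid_dz_m = 5,
                             noise_sd_C = 0.05,
                             overdispersion = NULL) {
  stopifnot(
    is.list(stations), length(stations) >= 1, !is.null(names(stations)),
    is.numeric(stratum_bounds), length(stratum_bounds) >= 2,
    all(diff(stratum_bounds) > 0),
    net_area_m2 > 0,
    abs(sum(stage_mix) - 1) < 1e-9,
    all(names(stage_mix) %in% names(length_mean_mm)),
    length_sd_mm > 0, fullness_shape1 > 0, fullness_shape2 > 0,
    structural_coefficient > 0, structural_exponent > 0, structural_sdlog >= 0,
    n_per_stratum >= 1, inherits(allometry, "lipid_allometry"),
    surface_halfrange_C >= 0, thermocline_bottom_m > 0, grid_dz_m > 0,
    noise_sd_C >= 0
  )
  for (st in stations) {
    stopifnot(
      is.finite(st$surface_mean_C), is.finite(st$deep_temp_C),
      st$total_cv_ind_m2 >= 0,
      abs(sum(st$bands$weight) - 1) < 1e-9,
      all(st$bands$upper_m < st$bands$lower_m)
    )
  }
  structure(
    list(
      stations = stations, stratum_bounds = stratum_bounds,
      net_area_m2 = net_area_m2, stage_mix = stage_mix,
      length_mean_mm = length_mean_mm, length_sd_mm = length_sd_mm,
      fullness_shape1 = fullness_shape1, fullness_shape2 = fullness_shape2,
      structural_coefficient = structural_coefficient,
      structural_exponent = structural_exponent,
      structural_sdlog = structural_sdlog,
      n_per_stratum = n_per_stratum, allometry = allometry,
      surface_halfrange_C = surface_halfrange_C,
      thermocline_bottom_m = thermocline_bottom_m,
      grid_dz_m = grid_dz_m, noise_sd_C = noise_sd_C,
      overdispersion = overdispersion
    ),
    class = "generator_config"
  )
}

#' Default late-summer station archetypes
#'
#' Three stations spanning a west-to-east gradient of surface warming and
#' population size, with vertical CV distributions concentrated above 250 m
#' at the two western stations and a pronounced deep mode (375–625 m) at the
#' eastern station.
#'
#' @return Named list of station archetypes (see [generator_config()]).
#' @export
default_station_archetypes <- function() {
  band <- function(upper, lower, weight) {
    tibble::tibble(upper_m = upper, lower_m = lower, weight = weight)
  }
  list(
    S1 = list(
      surface_mean_C = 2.362, deep_temp_C = -0.5, total_cv_ind_m2 = 2592,
      bands = band(c(5, 125, 250, 500), c(125, 250, 500, 1000),
                   c(0.45, 0.36, 0.15, 0.04))
    ),
    S2 = list(
      surface_mean_C = 3.643, deep_temp_C = -0.5, total_cv_ind_m2 = 12098,
      bands = band(c(5, 125, 250, 500), c(125, 250, 500, 1000),
                   c(0.40, 0.344, 0.20, 0.056))
    ),
    S3 = list(
      surface_mean_C = 4.319, deep_temp_C = -0.5, total_cv_ind_m2 = 15710,
      bands = band(c(5, 250, 375, 625), c(250, 375, 625, 1000),
                   c(0.22, 0.18, 0.45, 0.15))
    )
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  stations :", paste(names(x$stations), collapse = ", "), "\n")
  cat("  strata   :", paste(x$stratum_bounds, collapse = ", "), "m\n")
  cat(sprintf("  fullness ~ Beta(%g, %g); %d individuals per stratum\n",
              x$fullness_shape1, x$fullness_shape2, x$n_per_stratum))
  invisible(x)
}

#' Generate a synthetic CTD profile
#'
#' Two-water-mass construction: a linear surface-layer gradient whose 0–125 m
#' mean equals the archetype's surface mean exactly (before small-scale
#' noise), a linear thermocline down to `thermocline_bottom_m`, and the
#' archetype's deep temperature below, with additive N(0, `noise_sd_C`)
#' noise. Deterministic for a fixed `seed`.
#'
#' @param config A [generator_config()].
#' @param station Station name (must be in `config$stations`).
#' @param seed Integer seed for this artifact's random stream.
#' @return A [ctd_profile()].
#' @export
generate_ctd <- function(config, station, seed) {
  st <- get_archetype(config, station)
  max_depth <- max(config$stratum_bounds)
  with_stream(derive_seed(seed, 1L, station_index(config, station)), {
    z <- seq(0, max_depth, by = config$grid_dz_m)
    surf <- st$surface_mean_C
    s <- config$surface_halfrange_C
    t125 <- surf - s
    temp <- ifelse(
      z <= 125,
      surf + s * (62.5 - z) / 62.5,
      ifelse(
        z < config$thermocline_bottom_m,
        t125 + (st$deep_temp_C - t125) * (z - 125) /
          (config$thermocline_bottom_m - 125),
        st$deep_temp_C
      )
    )
    temp <- temp + stats::rnorm(length(z), 0, config$noise_sd_C)
    ctd_profile(z, temp, station = station)
  })
}

#' Generate a synthetic body-condition sample with ground truth
#'
#' Draws `n` individuals (default `n_per_stratum` per depth stratum, depths
#' from the station's vertical mixture): stage from the stage mix, prosome
#' length from the stage-specific truncated normal, lipid fullness from the
#' Beta distribution, lipid carbon `w = fullness * w_max(L)`, structural
#' carbon from the lognormal allometry, total carbon `M = m + w`, and a lipid
#' sac area obtained by inverting the area-to-wax-ester calibration — so the
#' biometric pipeline recovers the latent masses exactly. No generated record
#' can violate `w < M` by construction.
#'
#' The returned ground truth contains the analytically computed capable
#' fraction: conditional on each individual's length, structural mass and
#' assigned temperature, capability is equivalent to fullness exceeding the
#' required-fullness threshold, whose probability under the Beta law is a
#' closed-form tail probability.
#'
#' @param config A [generator_config()].
#' @param station Station name.
#' @param seed Integer seed.
#' @param n Number of individuals (default `n_per_stratum` per stratum).
#' @param params [model_params()] used for the analytic ground truth.
#' @return A list with `records` (an individual-record tibble), `ctd` (the
#'   profile used for temperature assignment) and `ground_truth` (a list:
#'   `true_capable_fraction`, `true_fullness_mean`, `latent` tibble of
#'   per-individual latent values).
#' @export
generate_population <- function(config, station, seed, n = NULL,
                                params = model_params()) {
  st <- get_archetype(config, station)
  ctd <- generate_ctd(config, station, seed)
  bounds <- config$stratum_bounds
  n_strata <- length(bounds) - 1
  if (is.null(n)) n <- config$n_per_stratum * n_strata
  with_stream(derive_seed(seed, 2L, station_index(config, station)), {
    bands <- st$bands
    band_idx <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$weight)
    depth <- stats::runif(n, bands$upper_m[band_idx], bands$lower_m[band_idx])
    stratum <- findInterval(depth, bounds, rightmost.closed = TRUE)
    stage <- sample(names(config$stage_mix), n, replace = TRUE,
                    prob = config$stage_mix)
    mu <- config$length_mean_mm[stage]
    # truncated-at-zero normal via inverse CDF
    u <- stats::runif(n, stats::pnorm(0, mu, config$length_sd_mm), 1)
    L <- stats::qnorm(u, mu, config$length_sd_mm)
    fullness <- stats::rbeta(n, config$fullness_shape1, config$fullness_shape2)
    w_max <- max_lipid_reserve(L, config$allometry)
    w <- fullness * w_max
    m <- config$structural_coefficient * L^config$structural_exponent *
      stats::rlnorm(n, 0, config$structural_sdlog)
    M <- m + w
    area <- wax_ester_to_area(w)
    records <- tibble::tibble(
      individual_id = sprintf("%s-%04d", station, seq_len(n)),
      station = station,
      stage = stage,
      stratum_upper_m = bounds[stratum],
      stratum_lower_m = bounds[stratum + 1],
      prosome_length_mm = L,
      lipid_area_mm2 = area,
      total_carbon_ug = M
    )
    temp <- temperature_at_depth(
      ctd, (records$stratum_upper_m + records$stratum_lower_m) / 2
    )
    r <- respiration_rate(m, temp, params)
    w_req <- required_reserve(r, params)
    f_req <- w_req / w_max
    p_capable <- ifelse(f_req > 1, 0,
                        stats::pbeta(f_req, config$fullness_shape1,
                                     config$fullness_shape2,
                                     lower.tail = FALSE))
    ground_truth <- list(
      true_capable_fraction = mean(p_capable),
      true_fullness_mean = config$fullness_shape1 /
        (config$fullness_shape1 + config$fullness_shape2),
      latent = tibble::tibble(
        individual_id = records$individual_id,
        depth_m = depth,
        fullness = fullness,
        lipid_carbon_ug = w,
        structural_carbon_ug = m,
        assigned_temp_C = temp,
        required_fullness = f_req,
        p_capable = p_capable
      )
    )
    list(records = records, ctd = ctd, ground_truth = ground_truth)
  })
}

#' Generate a synthetic depth-stratified catch table
#'
#' Expected count in a stratum is the configured CV depth-integrated
#' abundance (scaled per stage by the stage mix relative to CV) times the
#' vertical-mixture mass falling in the stratum times the net mouth area
#' (volume filtered = area \eqn{\times} stratum thickness); realised counts
#' are Poisson (or negative binomial if `overdispersion` is set). The
#' depth-integration estimator applied to a generated table is therefore
#' unbiased for the configured CV total.
#'
#' @param config A [generator_config()].
#' @param station Station name.
#' @param seed Integer seed.
#' @param season Season label written to the table.
#' @return A catch tibble (see [read_catch_table()]).
#' @export
generate_catch_table <- function(config, station, seed, season = "late") {
  st <- get_archetype(config, station)
  bounds <- config$stratum_bounds
  with_stream(derive_seed(seed, 3L, station_index(config, station)), {
    upper <- utils::head(bounds, -1)
    lower <- utils::tail(bounds, -1)
    rows <- expand.grid(stratum = seq_along(upper),
                        stage = names(config$stage_mix),
                        stringsAsFactors = FALSE)
    mass <- vapply(rows$stratum, function(i) {
      band_mass_in(st$bands, upper[i], lower[i])
    }, numeric(1))
    # total_cv_ind_m2 is the CV depth-integrated abundance; other stages are
    # scaled relative to CV by the stage mix
    cv_w <- config$stage_mix[["CV"]]
    if (is.null(cv_w) || cv_w <= 0) {
      stop("stage_mix must give CV positive weight", call. = FALSE)
    }
    expected <- st$total_cv_ind_m2 * (config$stage_mix[rows$stage] / cv_w) *
      mass * config$net_area_m2
    counts <- if (is.null(config$overdispersion)) {
      stats::rpois(length(expected), expected)
    } else {
      stats::rnbinom(length(expected), size = config$overdispersion,
                     mu = expected)
    }
    tibble::tibble(
      station = station,
      season = season,
      stratum_upper_m = upper[rows$stratum],
      stratum_lower_m = lower[rows$stratum],
      volume_filtered_m3 = config$net_area_m2 * (lower - upper)[rows$stratum],
      taxon = "C. finmarchicus",
      stage = rows$stage,
      count = as.numeric(counts)
    )
  })
}

#' Generate the full synthetic bundle for one station
#'
#' Runs [generate_ctd()], [generate_population()] and
#' [generate_catch_table()] with independent random streams derived from one
#' seed, optionally writing `individuals.csv`, `catch.csv`,
#' `ctd_<station>.csv` and `ground_truth_<station>.json` to `out_dir`.
#'
#' @inheritParams generate_population
#' @param out_dir Optional output directory.
#' @return A list with `records`, `catch`, `ctd`, `ground_truth`.
#' @export
generate_station <- function(config, station, seed, n = NULL,
                             params = model_params(), out_dir = NULL) {
  pop <- generate_population(config, station, seed, n = n, params = params)
  catch <- generate_catch_table(config, station, seed)
  out <- list(records = pop$records, catch = catch, ctd = pop$ctd,
              ground_truth = pop$ground_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(pop$records,
                     file.path(out_dir, sprintf("individuals_%s.csv", station)))
    readr::write_csv(catch, file.path(out_dir, sprintf("catch_%s.csv", station)))
    readr::write_csv(pop$ctd$samples,
                     file.path(out_dir, sprintf("ctd_%s.csv", station)))
    gt <- out$ground_truth
    jsonlite::write_json(
      list(true_capable_fraction = gt$true_capable_fraction,
           true_fullness_mean = gt$true_fullness_mean,
           true_total_cv_ind_m2 = get_archetype(config, station)$total_cv_ind_m2),
      file.path(out_dir, sprintf("ground_truth_%s.json", station)),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}

# --- internals ---------------------------------------------------------------

get_archetype <- function(config, station) {
  stopifnot(inherits(config, "generator_config"))
  st <- config$stations[[station]]
  if (is.null(st)) {
    stop("unknown station: ", station, call. = FALSE)
  }
  st
}

station_index <- function(config, station) {
  match(station, names(config$stations))
}

# invert WE = 0.167 * A^1.42 and w = 0.79 * WE to place a lipid sac area
# that reproduces a target lipid carbon exactly
wax_ester_to_area <- function(w_ug, carbon_fraction = 0.79,
                              coefficient = 0.167, exponent = 1.42) {
  ((w_ug / carbon_fraction) / coefficient)^(1 / exponent)
}

# probability mass of the vertical mixture falling within [upper, lower)
band_mass_in <- function(bands, upper, lower) {
  overlap <- pmax(0, pmin(bands$lower_m, lower) - pmax(bands$upper_m, upper))
  sum(bands$weight * overlap / (bands$lower_m - bands$upper_m))
}

# deterministic sub-seed per artifact/station so artifacts regenerate
# independently from a single user seed
derive_seed <- function(seed, artifact, station_idx) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 97 + artifact * 1009 + station_idx * 10007) %%
               2147483647L)
}

# evaluate `code` under its own RNG stream, restoring the caller's RNG state
with_stream <- function(seed_int, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed_int)
  force(code)
}
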