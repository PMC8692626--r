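#' Read a depth-stratified catch table
#'
#' Expects columns `station`, `season`, `stratum_upper_m`, `stratum_lower_m`,
#' `volume_filtered_m3`, `taxon`, `stage`, `count`. Validates stratum bounds,
#' positive filtered volumes and non-negative integer counts, and checks that
#' strata do not overlap within a station/season/taxon/stage combination.
#'
#' @param path Path to the CSV file.
#' @return A tibble of catch rows.
#' @export
read_catch_table <- function(path) {
  cols <- readr::cols(
    station = readr::col_character(),
    season = readr::col_character(),
    stratum_upper_m = readr::col_double(),
    stratum_lower_m = readr::col_double(),
    volume_filtered_m3 = readr::col_double(),
    taxon = readr::col_character(),
    stage = readr::col_character(),
    count = readr::col_double()
  )
  catch <- suppressWarnings(readr::read_csv(path, col_types = cols,
                                            progress = FALSE))
  missing <- setdiff(names(cols$cols), names(catch))
  if (length(missing)) {
    stop("catch CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_catch_table(catch)
}

#' Validate a catch table
#'
#' @param catch A data frame of catch rows (see [read_catch_table()]).
#' @return The validated tibble (invisibly the same data).
#' @export
validate_catch_table <- function(catch) {
  catch <- tibble::as_tibble(catch)
  if (any(catch$stratum_upper_m < 0 |
            catch$stratum_upper_m >= catch$stratum_lower_m)) {
    stop("invalid stratum bounds (need 0 <= upper < lower)", call. = FALSE)
  }
  if (any(catch$volume_filtered_m3 <= 0)) {
    stop("volume filtered must be positive", call. = FALSE)
  }
  if (any(catch$count < 0 | catch$count != round(catch$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  split_keys <- interaction(catch$station, catch$season, catch$taxon, catch$stage,
                            drop = TRUE)
  for (grp in split(catch, split_keys)) {
    o <- order(grp$stratum_upper_m)
    up <- grp$stratum_upper_m[o]; lo <- grp$stratum_lower_m[o]
    if (nrow(grp) > 1 && any(up[-1] < lo[-nrow(grp)])) {
      stop("overlapping depth strata within a station/season/taxon/stage group",
           call. = FALSE)
    }
  }
  catch
}

#' Depth-integrated abundance from stratified net catches
#'
#' Converts per-stratum counts and filtered volumes into individuals per
#' square metre of sea surface over a depth range: each stratum contributes
#' its concentration (`count / volume_filtered_m3`, ind m\eqn{^{-3}}) times
#' the thickness of its overlap with \eqn{[z_{from}, z_{to}]}, assuming the
#' concentration is uniform within a stratum. Splitting a stratum into
#' sub-strata with proportionally split counts and volumes leaves the
#' integral unchanged.
#'
#' @param catch A catch tibble (see [read_catch_table()]); may contain
#'   multiple stations/seasons — filter beforehand if a single deployment is
#'   intended.
#' @param taxon,stage Selection of the rows to integrate.
#' @param z_from,z_to Depth range, m, `z_from < z_to`.
#' @return Depth-integrated abundance, ind m\eqn{^{-2}}.
#' @examples
#' catch <- tibble::tibble(
#'   station = "S", season = "late",
#'   stratum_upper_m = c(0, 100), stratum_lower_m = c(100, 200),
#'   volume_filtered_m3 = c(250, 300),
#'   taxon = "C. finmarchicus", stage = "CV", count = c(50, 30)
#' )
#' depth_integrated_abundance(catch, "C. finmarchicus", "CV", 0, 200)  # 30
#' @export
depth_integrated_abundance <- function(catch, taxon, stage, z_from, z_to) {
  catch <- validate_catch_table(catch)
  if (z_from >= z_to) {
    stop("need z_from < z_to", call. = FALSE)
  }
  rows <- catch[catch$taxon == taxon & catch$stage == stage, , drop = FALSE]
  overlap <- pmax(0, pmin(rows$stratum_lower_m, z_to) -
                    pmax(rows$stratum_upper_m, z_from))
  if (nrow(rows) == 0 || all(overlap == 0)) {
    warning("no strata overlap the requested depth range; abundance is 0",
            call. = FALSE)
    return(0)
  }
  sum(rows$count / rows$volume_filtered_m3 * overlap)
}

#' Abundance of the deep (candidate overwintering) population
#'
#' Depth-integrated abundance restricted to depths below the deep cutoff
#' (default 250 m). A stratum straddling the cutoff contributes pro rata to
#' the thickness of its part below the cutoff.
#'
#' @inheritParams depth_integrated_abundance
#' @param params A [model_params()] object (supplies `deep_cutoff_m`).
#' @return Deep abundance, ind m\eqn{^{-2}}.
#' @export
deep_abundance <- function(catch, taxon, stage, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  bottom <- max(catch$stratum_lower_m)
  if (bottom <= params$deep_cutoff_m) {
    return(0)
  }
  depth_integrated_abundance(catch, taxon, stage,
                             z_from = params$deep_cutoff_m, z_to = bottom)
}

#' Fraction of assessed individuals capable of successful diapause
#'
#' @param profiles A tibble of energetics profiles (from
#'   [assess_individuals()]) with a logical `capable` column, or a logical
#'   vector of capability flags.
#' @return A list with `fraction`, `n_capable`, `n_assessed`.
#' @export
capable_fraction <- function(profiles) {
  capable <- if (is.logical(profiles)) profiles else profiles$capable
  if (is.null(capable) || length(capable) == 0) {
    stop("no assessed individuals: cannot estimate a capable fraction",
         call. = FALSE)
  }
  list(
    fraction = mean(capable),
    n_capable = sum(capable),
    n_assessed = length(capable)
  )
}

#' Abundance of deep individuals capable of successful diapause
#'
#' Scales the deep abundance by the capable fraction of the assessed deep
#' subsample; reported as an integer (round half up), matching the convention
#' of station summary tables.
#'
#' @param deep_ind_m2 Deep abundance, ind m\eqn{^{-2}} (non-negative).
#' @param fraction Capable fraction in \eqn{[0, 1]}.
#' @return Capable abundance, integer ind m\eqn{^{-2}}.
#' @examples
#' capable_abundance(489, 59 / 489)  # 59
#' @export
capable_abundance <- function(deep_ind_m2, fraction) {
  check_numeric(deep_ind_m2, "deep_ind_m2")
  check_numeric(fraction, "fraction")
  if (any(deep_ind_m2 < 0) || any(fraction < 0 | fraction > 1)) {
    stop("need deep abundance >= 0 and fraction in [0, 1]", call. = FALSE)
  }
  round_half_up(deep_ind_m2 * fraction)
}

#' Summary statistics of diapause duration
#'
#' @param profiles A tibble with a `diapause_days` column, or a numeric
#'   vector of durations.
#' @return A list with `max`, `min`, `mean` (days).
#' @export
summarize_diapause <- function(profiles) {
  D <- if (is.numeric(profiles)) profiles else profiles$diapause_days
  if (is.null(D) || length(D) == 0) {
    stop("no diapause durations to summarize", call. = FALSE)
  }
  list(max = max(D), min = min(D), mean = mean(D))
}

#' Classify a Calanus individual to species by prosome length
#'
#' Applies stage-specific prosome-length intervals to separate
#' *C. finmarchicus*, *C. glacialis* and *C. hyperboreus*. Intervals are
#' closed on the lower bound and open on the upper
#' (\eqn{[lower, upper)}); lengths falling in no interval are `"ambiguous"`.
#' Thresholds are configuration input — the package ships no species-boundary
#' defaults because they are survey-specific calibrations.
#'
#' @param stage Developmental stage label(s), e.g. `"CV"`.
#' @param prosome_length_mm Prosome length(s), mm.
#' @param thresholds A data frame with columns `stage`, `species`,
#'   `lower_mm`, `upper_mm`.
#' @return Character vector in
#'   `c("finmarchicus", "glacialis", "hyperboreus", "ambiguous")`.
#' @export
classify_calanus_species <- function(stage, prosome_length_mm, thresholds) {
  thresholds <- tibble::as_tibble(thresholds)
  need <- c("stage", "species", "lower_mm", "upper_mm")
  if (!all(need %in% names(thresholds))) {
    stop("thresholds need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  n <- max(length(stage), length(prosome_length_mm))
  stage <- rep_len(stage, n)
  prosome_length_mm <- rep_len(prosome_length_mm, n)
  vapply(seq_len(n), function(i) {
    rows <- thresholds[thresholds$stage == stage[i], , drop = FALSE]
    if (nrow(rows) == 0) {
      stop("no species thresholds configured for stage ", stage[i], call. = FALSE)
    }
    hit <- which(prosome_length_mm[i] >= rows$lower_mm &
                   prosome_length_mm[i] < rows$upper_mm)
    if (length(hit) == 1) rows$species[hit] else "ambiguous"
  }, character(1))
}

#' Station summary of the deep overwintering stock
#'
#' Combines the catch-based deep abundance with the assessed energetics
#' profiles of deep-caught individuals into a station summary shaped like a
#' population-status table: deep abundance, diapause-duration range and mean,
#' capable fraction and capable abundance.
#'
#' @param catch Catch tibble for one station/season.
#' @param profiles Energetics profiles for the same station (only individuals
#'   captured below the deep cutoff are used; others are dropped with a
#'   message).
#' @param taxon,stage Selection for the abundance integration.
#' @param params A [model_params()] object.
#' @return A one-row tibble with columns `station`, `deep_abundance_ind_m2`,
#'   `D_max_days`, `D_min_days`, `D_mean_days`, `capable_fraction`,
#'   `n_capable`, `n_assessed`, `capable_abundance_ind_m2`.
#' @export
station_summary <- function(catch, profiles, taxon = "C. finmarchicus",
                            stage = "CV", params = model_params()) {
  deep <- deep_abundance(catch, taxon, stage, params)
  is_deep <- profiles$depth_m >= params$deep_cutoff_m
  if (!all(is_deep)) {
    message(sum(!is_deep), " assessed individual(s) above the deep cutoff dropped",
            " from the deep-population summary")
  }
  deep_profiles <- profiles[is_deep, , drop = FALSE]
  if (nrow(deep_profiles) == 0) {
    stop("no assessed individuals below the deep cutoff", call. = FALSE)
  }
  cf <- capable_fraction(deep_profiles)
  ds <- summarize_diapause(deep_profiles)
  tibble::tibble(
    station = unique(profiles$station)[1],
    deep_abundance_ind_m2 = round_half_up(deep),
    D_max_days = ds$max,
    D_min_days = ds$min,
    D_mean_days = ds$mean,
    capable_fraction = cf$fraction,
    n_capable = cf$n_capable,
    n_assessed = cf$n_assessed,
    capable_abundance_ind_m2 = capable_abundance(deep, cf$fraction)
  )
}

# round half away from zero (table convention), unlike base round()'s
# round-half-even
round_half_up <- function(x) {
  floor(x + 0.5)
}
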