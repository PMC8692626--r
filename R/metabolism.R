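#' Diapause respiration rate
#'
#' Respiration of a diapausing copepod scales with structural carbon mass to
#' the 3/4 power and with temperature through a Boltzmann–Arrhenius factor:
#' \deqn{r = b\, m^{3/4} \exp\!\left[E \frac{T - T_0}{k\,T\,T_0}\right]
#'       \times 86\,400,}
#' where \eqn{T = T_C + 273.15} K. Only the structural mass respires: the
#' lipid reserve is treated as inert fuel. At \eqn{T = T_0} the exponential is
#' exactly 1, so with the default base temperature (0 \eqn{^\circ}C) the rate
#' reduces to \eqn{b\,m^{3/4} \times 86\,400}.
#'
#' @param m_ug Structural carbon mass, \eqn{\mu}g C (vectorised, positive).
#' @param temp_C Temperature in \eqn{^\circ}C (vectorised or scalar). Values
#'   outside the oceanographic sanity window \eqn{[-3, 30]} \eqn{^\circ}C
#'   trigger a warning.
#' @param params A [model_params()] object.
#' @return Respiration rate \eqn{r}, \eqn{\mu}g C day\eqn{^{-1}}.
#' @examples
#' respiration_rate(100, 0)    # 0.6831 at the reference temperature
#' respiration_rate(100, -1)   # ~0.617: colder water, slower metabolism
#' @export
respiration_rate <- function(m_ug, temp_C, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  check_numeric(m_ug, "m_ug")
  check_numeric(temp_C, "temp_C")
  if (any(m_ug <= 0)) {
    stop("structural mass must be positive", call. = FALSE)
  }
  T_K <- temp_C + 273.15
  if (any(T_K <= 0)) {
    stop("temperature below absolute zero", call. = FALSE)
  }
  if (any(temp_C < -3 | temp_C > 30)) {
    warning("temperature outside the [-3, 30] degC sanity window", call. = FALSE)
  }
  arrhenius <- exp(params$E_eV * (T_K - params$T0_K) /
                     (params$k_eV_per_K * T_K * params$T0_K))
  params$b * m_ug^0.75 * arrhenius * params$seconds_per_day
}

#' Diapause duration
#'
#' The number of days an individual can remain in diapause before its lipid
#' reserve is drawn down to the retained fraction (default 20\%) of its
#' pre-diapause mass:
#' \deqn{D = \frac{w - f_{ret}\, w}{r} = \frac{(1 - f_{ret})\, w}{r}.}
#'
#' @param w_ug Lipid-reserve carbon \eqn{w}, \eqn{\mu}g C (non-negative).
#' @param r_ug_per_day Respiration rate \eqn{r}, \eqn{\mu}g C day\eqn{^{-1}}
#'   (positive).
#' @param params A [model_params()] object (supplies `retained_fraction`).
#' @return Diapause duration \eqn{D}, days.
#' @examples
#' diapause_duration(150, respiration_rate(100, 0))  # ~175.7 days
#' @export
diapause_duration <- function(w_ug, r_ug_per_day, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  check_numeric(w_ug, "w_ug")
  check_numeric(r_ug_per_day, "r_ug_per_day")
  if (any(w_ug < 0)) {
    stop("lipid carbon must be non-negative", call. = FALSE)
  }
  if (any(r_ug_per_day <= 0)) {
    stop("respiration rate must be positive", call. = FALSE)
  }
  (1 - params$retained_fraction) * w_ug / r_ug_per_day
}

#' Overwinter-capability classification
#'
#' An individual is capable of a successful diapause if its duration meets the
#' threshold, with a closed boundary: `D >= D_threshold_days`.
#'
#' @param D_days Diapause duration, days (non-negative, vectorised).
#' @param params A [model_params()] object.
#' @return Logical vector.
#' @examples
#' is_overwinter_capable(c(149.999, 150, 212))  # FALSE TRUE TRUE
#' @export
is_overwinter_capable <- function(D_days, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  check_numeric(D_days, "D_days")
  if (any(D_days < 0)) {
    stop("diapause duration must be non-negative", call. = FALSE)
  }
  D_days >= params$D_threshold_days
}

#' Lipid reserve required for a threshold-length diapause
#'
#' Closed-form inversion of the duration model: the reserve needed so that
#' the individual lasts exactly `D_threshold_days` at respiration rate `r`,
#' \deqn{w_{req} = \frac{D_{thr}\, r}{1 - f_{ret}}.}
#' By construction `diapause_duration(required_reserve(r), r)` equals the
#' threshold.
#'
#' @param r_ug_per_day Respiration rate, \eqn{\mu}g C day\eqn{^{-1}} (positive).
#' @param params A [model_params()] object.
#' @return Required lipid carbon \eqn{w_{req}}, \eqn{\mu}g C.
#' @examples
#' required_reserve(0.6831)  # ~128.1 ug C for a 150-day diapause
#' @export
required_reserve <- function(r_ug_per_day, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  check_numeric(r_ug_per_day, "r_ug_per_day")
  if (any(r_ug_per_day <= 0)) {
    stop("respiration rate must be positive", call. = FALSE)
  }
  params$D_threshold_days * r_ug_per_day / (1 - params$retained_fraction)
}

#' Theoretical maximum diapause duration
#'
#' The duration an individual would achieve if its lipid reserve were at the
#' allometric maximum for its prosome length, all else equal:
#' `diapause_duration(max_lipid_reserve(L), respiration_rate(m, T))`.
#' For any individual with the same length, structural mass and temperature,
#' the realised duration satisfies \eqn{D \le D_{max}} whenever
#' \eqn{w \le w_{max}}.
#'
#' @param prosome_length_mm Prosome length, mm (positive).
#' @param m_ug Structural carbon, \eqn{\mu}g C (positive).
#' @param temp_C Temperature, \eqn{^\circ}C.
#' @param allometry A [lipid_allometry()] object.
#' @param params A [model_params()] object.
#' @return Maximum duration \eqn{D_{max}}, days.
#' @export
max_diapause_duration <- function(prosome_length_mm, m_ug, temp_C,
                                  allometry = lipid_allometry(),
                                  params = model_params()) {
  w_max <- max_lipid_reserve(prosome_length_mm, allometry)
  r <- respiration_rate(m_ug, temp_C, params)
  diapause_duration(w_max, r, params)
}

#' Assess diapause capability for a table of individual records
#'
#' Runs the full per-individual chain on validated records: lipid sac area
#' \eqn{\to} wax-ester mass \eqn{\to} lipid carbon \eqn{w} \eqn{\to}
#' structural mass \eqn{m = M - w} \eqn{\to} respiration \eqn{r} at the
#' assigned temperature \eqn{\to} diapause duration \eqn{D} \eqn{\to}
#' capability, plus the allometric ceiling \eqn{w_{max}}, lipid fullness and
#' the theoretical maximum duration. Records whose lipid carbon meets or
#' exceeds total carbon are infeasible: they are excluded and reported, never
#' clamped.
#'
#' @param records A tibble of accepted individual records (see
#'   [read_individuals()]).
#' @param temp_C Temperature(s) in \eqn{^\circ}C entering the respiration
#'   model: a scalar, a vector of length `nrow(records)`, or `NULL` to derive
#'   temperatures from `ctd` according to `params$temperature_mode`.
#' @param ctd A [ctd_profile()] (or named list of profiles keyed by station)
#'   used when `temp_C` is `NULL`.
#' @param allometry A [lipid_allometry()] object.
#' @param params A [model_params()] object.
#' @return A list with elements `profiles` (tibble with columns
#'   `individual_id`, `station`, `stage`, `depth_m`, `assigned_temp_C`,
#'   `we_ug`, `lipid_carbon_ug`, `structural_carbon_ug`,
#'   `max_lipid_carbon_ug`, `fullness`, `over_ceiling`,
#'   `respiration_ug_per_day`, `diapause_days`, `max_diapause_days`,
#'   `capable`) and `rejected` (tibble `individual_id`, `reason`).
#' @export
assess_individuals <- function(records, temp_C = NULL, ctd = NULL,
                               allometry = lipid_allometry(),
                               params = model_params()) {
  stopifnot(inherits(params, "model_params"), inherits(allometry, "lipid_allometry"))
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    stop("no records to assess", call. = FALSE)
  }
  depth_mid <- (records$stratum_upper_m + records$stratum_lower_m) / 2
  if (is.null(temp_C)) {
    temp_C <- assign_temperatures(records$station, depth_mid, ctd, params)
  } else if (length(temp_C) == 1) {
    temp_C <- rep(temp_C, nrow(records))
  } else if (length(temp_C) != nrow(records)) {
    stop("`temp_C` must be scalar or one value per record", call. = FALSE)
  }

  we <- lipid_area_to_wax_ester(records$lipid_area_mm2)
  w <- wax_ester_to_carbon(we)
  infeasible <- w >= records$total_carbon_ug
  rejected <- tibble::tibble(
    individual_id = records$individual_id[infeasible],
    reason = rep("infeasible: lipid carbon >= total carbon", sum(infeasible))
  )
  if (any(infeasible)) {
    message(sum(infeasible), " record(s) excluded: lipid carbon >= total carbon")
  }
  keep <- !infeasible
  records <- records[keep, , drop = FALSE]
  we <- we[keep]; w <- w[keep]
  temp_C <- temp_C[keep]; depth_mid <- depth_mid[keep]
  if (nrow(records) == 0) {
    stop("all records infeasible; nothing to assess", call. = FALSE)
  }

  m <- partition_carbon(records$total_carbon_ug, w)
  w_max <- max_lipid_reserve(records$prosome_length_mm, allometry)
  fullness <- lipid_fullness(w, w_max)
  r <- respiration_rate(m, temp_C, params)
  # w = 0 gives D = 0 directly; duration is linear in w
  D <- diapause_duration(w, r, params)
  D_max <- diapause_duration(w_max, r, params)

  profiles <- tibble::tibble(
    individual_id = records$individual_id,
    station = records$station,
    stage = records$stage,
    depth_m = depth_mid,
    assigned_temp_C = temp_C,
    we_ug = we,
    lipid_carbon_ug = w,
    structural_carbon_ug = m,
    max_lipid_carbon_ug = w_max,
    fullness = as.numeric(fullness),
    over_ceiling = attr(fullness, "over_ceiling"),
    respiration_ug_per_day = r,
    diapause_days = D,
    max_diapause_days = D_max,
    capable = is_overwinter_capable(D, params)
  )
  list(profiles = profiles, rejected = rejected)
}

# Resolve per-individual temperatures from CTD profiles according to
# params$temperature_mode.
assign_temperatures <- function(station, depth_m, ctd, params) {
  if (params$temperature_mode == "fixed") {
    return(rep(params$fixed_temp_C, length(depth_m)))
  }
  if (is.null(ctd)) {
    stop("CTD profile(s) required for temperature_mode \"",
         params$temperature_mode, "\"", call. = FALSE)
  }
  profiles <- if (inherits(ctd, "ctd_profile")) {
    stats::setNames(list(ctd), unique(station))[unique(station)]
  } else {
    ctd
  }
  missing <- setdiff(unique(station), names(profiles))
  if (length(missing)) {
    stop("no CTD profile for station(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vapply(seq_along(depth_m), function(i) {
    prof <- profiles[[station[i]]]
    if (params$temperature_mode == "deep_mean") {
      deepest <- max(prof$samples$depth_m)
      mean_temperature(prof, params$deep_cutoff_m, deepest)
    } else {
      temperature_at_depth(prof, depth_m[i])
    }
  }, numeric(1))
}
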