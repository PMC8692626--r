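#' Convert lipid sac area to wax-ester mass
#'
#' Applies the empirical image-analysis calibration
#' \eqn{WE = 0.167 \, A^{1.42}} relating the projected area of the lipid sac
#' (mm\eqn{^2}) to its wax-ester content (\eqn{\mu}g). Wax esters are the
#' principal storage lipid of *Calanus*; the calibration coefficients are the
#' published standard for this conversion and are exposed as arguments only so
#' the relation can be inspected and stress-tested.
#'
#' @param area_mm2 Lipid sac area in mm\eqn{^2} (vectorised); must be
#'   non-negative.
#' @param coefficient,exponent Calibration constants (defaults 0.167, 1.42).
#' @return Wax-ester mass in \eqn{\mu}g.
#' @examples
#' lipid_area_to_wax_ester(1)    # 0.167
#' lipid_area_to_wax_ester(2)    # 0.4469
#' @export
lipid_area_to_wax_ester <- function(area_mm2, coefficient = 0.167, exponent = 1.42) {
  check_numeric(area_mm2, "area_mm2")
  if (any(area_mm2 < 0)) {
    stop("lipid sac area must be non-negative", call. = FALSE)
  }
  coefficient * area_mm2^exponent
}

#' Convert wax-ester mass to lipid carbon
#'
#' Wax-ester mass is 79\% carbon by mass, so the lipid-reserve carbon is
#' \eqn{w = 0.79 \, WE}.
#'
#' @param we_ug Wax-ester mass, \eqn{\mu}g (vectorised, non-negative).
#' @param carbon_fraction Carbon mass fraction of wax esters (default 0.79).
#' @return Lipid carbon \eqn{w}, \eqn{\mu}g C.
#' @examples
#' wax_ester_to_carbon(100)  # 79
#' @export
wax_ester_to_carbon <- function(we_ug, carbon_fraction = 0.79) {
  check_numeric(we_ug, "we_ug")
  if (any(we_ug < 0)) {
    stop("wax-ester mass must be non-negative", call. = FALSE)
  }
  carbon_fraction * we_ug
}

#' Partition total body carbon into structural and lipid carbon
#'
#' Structural mass is the metabolically active carbon: the total carbon from
#' elemental analysis minus the lipid-reserve carbon, \eqn{m = M - w}. A
#' record whose estimated lipid carbon meets or exceeds its measured total
#' carbon is physically infeasible (it would imply zero or negative structural
#' mass) and is an error here; the record-level pipeline excludes such
#' records rather than clamping them, because \eqn{m \to 0} would explode the
#' respiration-based duration.
#'
#' @param total_carbon_ug Total body carbon \eqn{M}, \eqn{\mu}g C (positive).
#' @param lipid_carbon_ug Lipid carbon \eqn{w}, \eqn{\mu}g C (non-negative).
#' @return Structural carbon \eqn{m = M - w}, \eqn{\mu}g C (strictly positive).
#' @examples
#' partition_carbon(200, 79)  # 121
#' @export
partition_carbon <- function(total_carbon_ug, lipid_carbon_ug) {
  check_numeric(total_carbon_ug, "total_carbon_ug")
  check_numeric(lipid_carbon_ug, "lipid_carbon_ug")
  if (any(total_carbon_ug <= 0)) {
    stop("total carbon must be positive", call. = FALSE)
  }
  if (any(lipid_carbon_ug < 0)) {
    stop("lipid carbon must be non-negative", call. = FALSE)
  }
  if (any(lipid_carbon_ug >= total_carbon_ug)) {
    stop("infeasible record: lipid carbon >= total carbon (structural mass would be <= 0)",
         call. = FALSE)
  }
  total_carbon_ug - lipid_carbon_ug
}

#' Maximum possible lipid reserve for a given prosome length
#'
#' Evaluates the allometric ceiling \eqn{w_{max} = c\,L^{e}} on lipid-reserve
#' carbon as a function of prosome length.
#'
#' @param prosome_length_mm Prosome length \eqn{L}, mm (vectorised, positive).
#' @param allometry A [lipid_allometry()] object.
#' @return \eqn{w_{max}}, \eqn{\mu}g C.
#' @examples
#' max_lipid_reserve(2, lipid_allometry(20, 3))  # 160
#' @export
max_lipid_reserve <- function(prosome_length_mm, allometry = lipid_allometry()) {
  stopifnot(inherits(allometry, "lipid_allometry"))
  check_numeric(prosome_length_mm, "prosome_length_mm")
  if (any(prosome_length_mm <= 0)) {
    stop("prosome length must be positive", call. = FALSE)
  }
  allometry$coefficient * prosome_length_mm^allometry$exponent
}

#' Lipid fullness: measured reserve relative to the allometric ceiling
#'
#' The fraction \eqn{w / w_{max}} of the maximum possible lipid reserve an
#' individual actually holds. Values above 1 (a measured reserve exceeding
#' the allometric ceiling) are retained, not truncated, so that population
#' averages of fullness are computed on untruncated values; set
#' `truncate = TRUE` to cap at 1.
#'
#' @param lipid_carbon_ug Lipid carbon \eqn{w}, \eqn{\mu}g C (non-negative).
#' @param max_lipid_carbon_ug Allometric maximum \eqn{w_{max}}, \eqn{\mu}g C
#'   (strictly positive).
#' @param truncate Cap fullness at 1? Default `FALSE`.
#' @return Dimensionless fullness, with attribute `over_ceiling` flagging
#'   entries whose untruncated value exceeds 1.
#' @examples
#' lipid_fullness(76, 100)  # 0.76
#' @export
lipid_fullness <- function(lipid_carbon_ug, max_lipid_carbon_ug, truncate = FALSE) {
  check_numeric(lipid_carbon_ug, "lipid_carbon_ug")
  check_numeric(max_lipid_carbon_ug, "max_lipid_carbon_ug")
  if (any(lipid_carbon_ug < 0)) {
    stop("lipid carbon must be non-negative", call. = FALSE)
  }
  if (any(max_lipid_carbon_ug <= 0)) {
    stop("maximum lipid reserve must be positive", call. = FALSE)
  }
  fullness <- lipid_carbon_ug / max_lipid_carbon_ug
  over <- fullness > 1
  if (truncate) fullness <- pmin(fullness, 1)
  structure(fullness, over_ceiling = over)
}

#' Read an individual-record table
#'
#' Reads the per-individual biometrics CSV with columns `individual_id`,
#' `station`, `stage`, `stratum_upper_m`, `stratum_lower_m`,
#' `prosome_length_mm`, `lipid_area_mm2`, `total_carbon_ug` and validates it
#' with [validate_individuals()].
#'
#' @param path Path to the CSV file (UTF-8, `.` decimal separator).
#' @return A list with elements `records` (tibble of accepted records) and
#'   `rejected` (tibble `individual_id`, `reason`).
#' @export
read_individuals <- function(path) {
  cols <- readr::cols(
    individual_id = readr::col_character(),
    station = readr::col_character(),
    stage = readr::col_character(),
    stratum_upper_m = readr::col_double(),
    stratum_lower_m = readr::col_double(),
    prosome_length_mm = readr::col_double(),
    lipid_area_mm2 = readr::col_double(),
    total_carbon_ug = readr::col_double()
  )
  records <- suppressWarnings(readr::read_csv(path, col_types = cols,
                                              progress = FALSE))
  missing <- setdiff(names(cols$cols), names(records))
  if (length(missing)) {
    stop("individuals CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_individuals(records)
}

#' Validate individual records against the biometry preconditions
#'
#' Splits a raw record table into accepted records and a rejection report.
#' Rejection reasons: non-positive prosome length, negative lipid sac area,
#' non-positive total carbon, invalid depth stratum (upper must be
#' non-negative and strictly above lower, depths positive downward),
#' unknown developmental stage, and missing values in any measured field.
#'
#' @param records A data frame of individual records (see [read_individuals()]
#'   for the column contract).
#' @return A list with elements `records` and `rejected` (see
#'   [read_individuals()]).
#' @export
validate_individuals <- function(records) {
  records <- tibble::as_tibble(records)
  stages <- c("CI", "CII", "CIII", "CIV", "CV", "CVI")
  reason <- rep(NA_character_, nrow(records))
  flag <- function(reason_vec, bad, msg) {
    ifelse(is.na(reason_vec) & bad, msg, reason_vec)
  }
  num_cols <- c("stratum_upper_m", "stratum_lower_m", "prosome_length_mm",
                "lipid_area_mm2", "total_carbon_ug")
  has_na <- Reduce(`|`, lapply(records[num_cols], function(x) !is.finite(x)))
  reason <- flag(reason, has_na, "missing or non-numeric measurement")
  reason <- flag(reason, !records$stage %in% stages,
                 "unknown developmental stage")
  reason <- flag(reason,
                 !has_na & (records$stratum_upper_m < 0 |
                              records$stratum_upper_m >= records$stratum_lower_m),
                 "invalid depth stratum (need 0 <= upper < lower)")
  reason <- flag(reason, !has_na & records$prosome_length_mm <= 0,
                 "non-positive prosome length")
  reason <- flag(reason, !has_na & records$lipid_area_mm2 < 0,
                 "negative lipid sac area")
  reason <- flag(reason, !has_na & records$total_carbon_ug <= 0,
                 "non-positive total carbon")
  rejected <- tibble::tibble(
    individual_id = records$individual_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  list(records = records[is.na(reason), , drop = FALSE], rejected = rejected)
}

# shared argument check: finite numeric vector
check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop("`", name, "` must be a finite numeric vector", call. = FALSE)
  }
  invisible(x)
}
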