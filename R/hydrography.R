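#' Construct a CTD temperature profile
#'
#' A depth-ordered record of temperature against depth for one station,
#' modelled as a piecewise-linear function of depth (positive downward).
#' Duplicate depths are averaged; samples are sorted on ingestion.
#'
#' @param depth_m Numeric vector of depths, m (non-negative).
#' @param temperature_C Numeric vector of temperatures, \eqn{^\circ}C.
#' @param station Station label.
#' @return An object of class `ctd_profile` with elements `station` and
#'   `samples` (tibble `depth_m`, `temperature_C`, strictly increasing depth).
#' @examples
#' prof <- ctd_profile(c(0, 100), c(0, 10))
#' temperature_at_depth(prof, 50)  # 5
#' @export
ctd_profile <- function(depth_m, temperature_C, station = "station") {
  check_numeric(depth_m, "depth_m")
  check_numeric(temperature_C, "temperature_C")
  if (length(depth_m) != length(temperature_C)) {
    stop("depth and temperature must have equal length", call. = FALSE)
  }
  if (any(depth_m < 0)) {
    stop("depths must be non-negative (positive downward)", call. = FALSE)
  }
  agg <- stats::aggregate(
    list(temperature_C = temperature_C),
    by = list(depth_m = depth_m),
    FUN = mean
  )
  agg <- agg[order(agg$depth_m), , drop = FALSE]
  if (nrow(agg) < 2) {
    stop("a CTD profile needs at least 2 distinct depths", call. = FALSE)
  }
  structure(
    list(station = station, samples = tibble::as_tibble(agg)),
    class = "ctd_profile"
  )
}

#' @export
print.ctd_profile <- function(x, ...) {
  rng <- range(x$samples$depth_m)
  cat(sprintf("<ctd_profile> station %s: %d samples, %g-%g m, %.2f to %.2f degC\n",
              x$station, nrow(x$samples), rng[1], rng[2],
              min(x$samples$temperature_C), max(x$samples$temperature_C)))
  invisible(x)
}

#' Read a CTD profile from CSV
#'
#' Expects columns `depth_m` and `temperature_C`; a `salinity` column is
#' accepted and ignored. Rows are sorted by depth and duplicate depths
#' averaged; the raw row count is reported via `message()`.
#'
#' @param path Path to the CSV file.
#' @param station Station label (defaults to the file name).
#' @return A [ctd_profile()].
#' @export
read_ctd_profile <- function(path, station = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("depth_m", "temperature_C")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("CTD CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at data line ", bad[1], " of ", path,
           call. = FALSE)
    }
    raw[[col]] <- vals
  }
  message("read ", nrow(raw), " CTD rows from ", path)
  if (is.null(station)) station <- sub("\\.csv$", "", basename(path))
  ctd_profile(raw$depth_m, raw$temperature_C, station = station)
}

#' Temperature at a given depth
#'
#' Linear interpolation between the bracketing samples of the piecewise-linear
#' profile. Outside the sampled depth range the nearest-endpoint value is
#' returned with a warning (no extrapolation).
#'
#' @param profile A [ctd_profile()].
#' @param depth_m Depth(s), m (non-negative, vectorised).
#' @return Temperature(s), \eqn{^\circ}C.
#' @export
temperature_at_depth <- function(profile, depth_m) {
  stopifnot(inherits(profile, "ctd_profile"))
  check_numeric(depth_m, "depth_m")
  if (any(depth_m < 0)) {
    stop("depth must be non-negative", call. = FALSE)
  }
  s <- profile$samples
  if (any(depth_m < min(s$depth_m) | depth_m > max(s$depth_m))) {
    warning("depth outside sampled range; using nearest-endpoint temperature",
            call. = FALSE)
  }
  stats::approx(s$depth_m, s$temperature_C, xout = depth_m, rule = 2)$y
}

#' Depth-averaged temperature over a layer
#'
#' Mean temperature of the piecewise-linear profile over \eqn{[z_1, z_2]},
#' computed as the exact trapezoidal integral divided by the layer thickness.
#' The integration range is clipped to the sampled depth range; a layer
#' entirely outside the profile is an error.
#'
#' @param profile A [ctd_profile()].
#' @param z1,z2 Layer bounds, m, with \eqn{0 \le z_1 < z_2}.
#' @return Layer-mean temperature, \eqn{^\circ}C.
#' @examples
#' mean_temperature(ctd_profile(c(0, 100), c(0, 10)), 0, 100)  # 5
#' @export
mean_temperature <- function(profile, z1, z2) {
  stopifnot(inherits(profile, "ctd_profile"))
  check_numeric(z1, "z1"); check_numeric(z2, "z2")
  if (length(z1) != 1 || length(z2) != 1 || z1 < 0 || z1 >= z2) {
    stop("need scalar bounds with 0 <= z1 < z2", call. = FALSE)
  }
  s <- profile$samples
  lo <- max(z1, min(s$depth_m))
  hi <- min(z2, max(s$depth_m))
  if (lo >= hi) {
    stop("layer [", z1, ", ", z2, "] lies entirely outside the sampled profile",
         call. = FALSE)
  }
  # knots: profile depths inside the layer plus the (clipped) bounds
  z <- sort(unique(c(lo, hi, s$depth_m[s$depth_m > lo & s$depth_m < hi])))
  temp <- stats::approx(s$depth_m, s$temperature_C, xout = z, rule = 2)$y
  integral <- sum(diff(z) * (utils::head(temp, -1) + utils::tail(temp, -1)) / 2)
  integral / (hi - lo)
}
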