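#' Model parameters for the diapause-capability model
#'
#' Bundles every constant of the diapause respiration and duration model:
#' the metabolic scaling constant, the Arrhenius temperature correction,
#' the fraction of the lipid reserve that must remain after diapause, the
#' duration threshold for a successful overwintering, and the depth cutoff
#' that defines the "deep" (candidate overwintering) population.
#'
#' The respiration model is
#' \deqn{r = b \, m^{3/4} \exp\!\left[E \frac{T - T_0}{k\,T\,T_0}\right] \times 86\,400}
#' with \eqn{r} in \eqn{\mu}g C day\eqn{^{-1}}, \eqn{m} the structural carbon
#' mass (\eqn{\mu}g C) and \eqn{T} in Kelvin. The base temperature defaults to
#' `T0_K = 273.15` K (0 \eqn{^\circ}C) so the exponential factor is exactly 1
#' at 0 \eqn{^\circ}C; the activation energy defaults to the standard
#' metabolic-theory value 0.65 eV. Both are configurable because neither is
#' pinned down unambiguously by published diapause studies.
#'
#' @param b Metabolic scaling constant, \eqn{\mu}g C\eqn{^{1/4}} s\eqn{^{-1}}.
#' @param E_eV Activation energy, eV. `E_eV = 0` switches the temperature
#'   dependence off.
#' @param k_eV_per_K Boltzmann constant, eV K\eqn{^{-1}}.
#' @param T0_K Base (reference) temperature, Kelvin.
#' @param seconds_per_day Unit conversion from \eqn{\mu}g C s\eqn{^{-1}} to
#'   \eqn{\mu}g C day\eqn{^{-1}}.
#' @param retained_fraction Fraction of the pre-diapause lipid reserve that
#'   must remain at emergence (default 0.2, i.e. 20\% retained to fuel the
#'   moult and spring reproduction).
#' @param D_threshold_days Minimum diapause duration (days) counted as a
#'   successful overwintering; the boundary is closed (`D >= threshold`).
#' @param deep_cutoff_m Depth (m) below which individuals belong to the
#'   candidate overwintering stock.
#' @param temperature_mode How the temperature entering the respiration model
#'   is assigned to an individual: `"stratum_midpoint"` (CTD temperature at
#'   the capture-stratum midpoint), `"deep_mean"` (CTD mean below
#'   `deep_cutoff_m`), or `"fixed"` (a constant supplied as `fixed_temp_C`).
#' @param fixed_temp_C Overwintering temperature in \eqn{^\circ}C, used only
#'   when `temperature_mode = "fixed"`.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' respiration_rate(100, 0, p)  # Arrhenius factor is 1 at 0 degC
#' @export
model_params <- function(b = 2.5e-7,
                         E_eV = 0.65,
                         k_eV_per_K = 8.617333e-5,
                         T0_K = 273.15,
                         seconds_per_day = 86400,
                         retained_fraction = 0.2,
                         D_threshold_days = 150,
                         deep_cutoff_m = 250,
                         temperature_mode = c("stratum_midpoint", "deep_mean", "fixed"),
                         fixed_temp_C = NA_real_) {
  temperature_mode <- match.arg(temperature_mode)
  stopifnot(
    is.numeric(b), length(b) == 1, b > 0,
    is.numeric(E_eV), length(E_eV) == 1, E_eV >= 0,
    is.numeric(k_eV_per_K), k_eV_per_K > 0,
    is.numeric(T0_K), T0_K > 0,
    is.numeric(seconds_per_day), seconds_per_day > 0,
    is.numeric(retained_fraction), retained_fraction >= 0, retained_fraction < 1,
    is.numeric(D_threshold_days), D_threshold_days > 0,
    is.numeric(deep_cutoff_m), deep_cutoff_m >= 0
  )
  if (temperature_mode == "fixed" && !is.finite(fixed_temp_C)) {
    stop("`fixed_temp_C` must be a finite temperature when temperature_mode = \"fixed\"",
         call. = FALSE)
  }
  structure(
    list(
      b = b, E_eV = E_eV, k_eV_per_K = k_eV_per_K, T0_K = T0_K,
      seconds_per_day = seconds_per_day,
      retained_fraction = retained_fraction,
      D_threshold_days = D_threshold_days,
      deep_cutoff_m = deep_cutoff_m,
      temperature_mode = temperature_mode,
      fixed_temp_C = fixed_temp_C
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  b                 : %.3e ug C^(1/4) s^-1\n", x$b))
  cat(sprintf("  E                 : %.3f eV\n", x$E_eV))
  cat(sprintf("  k                 : %.6e eV K^-1\n", x$k_eV_per_K))
  cat(sprintf("  T0                : %.2f K (%.2f degC)\n", x$T0_K, x$T0_K - 273.15))
  cat(sprintf("  retained fraction : %.2f\n", x$retained_fraction))
  cat(sprintf("  D threshold       : %g days (closed boundary)\n", x$D_threshold_days))
  cat(sprintf("  deep cutoff       : %g m\n", x$deep_cutoff_m))
  cat(sprintf("  temperature mode  : %s\n", x$temperature_mode))
  invisible(x)
}

#' Maximum-lipid-reserve allometry
#'
#' Power-law relation between prosome length and the maximum lipid-reserve
#' carbon an individual of that size can hold:
#' \eqn{w_{max} = c \, L^{e}} (\eqn{\mu}g C, \eqn{L} in mm).
#'
#' The defaults (`coefficient = 10`, `exponent = 3`) encode volumetric scaling
#' of the lipid sac with body length at a magnitude plausible for
#' *Calanus finmarchicus* CV (a 2.5 mm animal can hold ~156 \eqn{\mu}g lipid
#' carbon). They are package defaults, not literature-calibrated constants;
#' analyses aiming at a specific population should supply coefficients fitted
#' to that population.
#'
#' @param coefficient \eqn{\mu}g C mm\eqn{^{-e}}; must be positive.
#' @param exponent Dimensionless; must be positive.
#' @return An object of class `lipid_allometry`.
#' @examples
#' a <- lipid_allometry(coefficient = 20, exponent = 3)
#' max_lipid_reserve(2, a)  # 160 ug C
#' @export
lipid_allometry <- function(coefficient = 10, exponent = 3) {
  stopifnot(
    is.numeric(coefficient), length(coefficient) == 1, coefficient > 0,
    is.numeric(exponent), length(exponent) == 1, exponent > 0
  )
  structure(
    list(coefficient = coefficient, exponent = exponent),
    class = "lipid_allometry"
  )
}

#' @export
print.lipid_allometry <- function(x, ...) {
  cat(sprintf("<lipid_allometry> w_max = %g * L^%g  (ug C, L in mm)\n",
              x$coefficient, x$exponent))
  invisible(x)
}

#' Read model parameters from a YAML-like key-value file
#'
#' Accepts a plain-text file of `key: value` lines (comments with `#`).
#' Recognised keys: `b`, `E_eV`, `k_eV_per_K`, `T0_K`, `retained_fraction`,
#' `D_threshold_days`, `deep_cutoff_m`, `temperature_mode`, `fixed_temp_C`,
#' `max_lipid_coefficient`, `max_lipid_exponent`. Unknown keys are an error.
#'
#' @param path Path to the parameter file.
#' @return A list with elements `params` (a [model_params()]) and
#'   `allometry` (a [lipid_allometry()]).
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  known <- c("b", "E_eV", "k_eV_per_K", "T0_K", "retained_fraction",
             "D_threshold_days", "deep_cutoff_m", "temperature_mode",
             "fixed_temp_C", "max_lipid_coefficient", "max_lipid_exponent")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[match(key, keys)]) else default
  }
  mode <- if ("temperature_mode" %in% keys) {
    vals[match("temperature_mode", keys)]
  } else {
    "stratum_midpoint"
  }
  params <- model_params(
    b = get_num("b", 2.5e-7),
    E_eV = get_num("E_eV", 0.65),
    k_eV_per_K = get_num("k_eV_per_K", 8.617333e-5),
    T0_K = get_num("T0_K", 273.15),
    retained_fraction = get_num("retained_fraction", 0.2),
    D_threshold_days = get_num("D_threshold_days", 150),
    deep_cutoff_m = get_num("deep_cutoff_m", 250),
    temperature_mode = mode,
    fixed_temp_C = get_num("fixed_temp_C", NA_real_)
  )
  allometry <- lipid_allometry(
    coefficient = get_num("max_lipid_coefficient", 10),
    exponent = get_num("max_lipid_exponent", 3)
  )
  list(params = params, allometry = allometry)
}
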