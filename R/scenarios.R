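# Benthic scenario construction and Monte-Carlo parameter sampling.

scenario_fields <- c(
  "temperature", "salinity", "ppO2", "c_oc", "q10_production",
  "q10_respiration", "day_length", "light_fraction", "dbl_thickness",
  "sediment_depth", "grid_spacing", "p_max_ref", "r_max_ref", "k_o2",
  "production_efolding", "t_ref")

# Shared defaults for every preset.  Geometry and cycle follow the shelf
# setting modelled here: a 0.05 cm diffusive boundary layer over 1.25 cm of
# sandy sediment under a 21-h diel cycle split evenly between light and
# dark.  The reference rates p_max_ref and r_max_ref are package calibration
# constants, fixed once by inst/scripts/calibrate-benthic.R (see the methods
# vignette) and anchored at the cold preset temperature (t_ref = 5 C).
scenario_defaults <- list(
  salinity = 35,
  ppO2 = 30,
  c_oc = 0.25,
  q10_production = 3,
  q10_respiration = 3,
  day_length = 21,
  light_fraction = 0.5,
  dbl_thickness = 0.05,
  sediment_depth = 1.25,
  grid_spacing = 0.025,
  p_max_ref = 1700,
  r_max_ref = 3600,
  k_o2 = 0.03,
  production_efolding = 0.1,
  t_ref = 5
)

scenario_presets <- list(cold = 5, warm = 25, hot = 40)

validate_scenario <- function(s) {
  missing <- setdiff(scenario_fields, names(s))
  if (length(missing))
    stop_field(missing[1], "missing from scenario")
  check_number(s$temperature, "temperature", -2, 60)
  check_number(s$salinity, "salinity", 0, 45)
  check_number(s$ppO2, "ppO2", 0, 150, open_lower = TRUE)
  check_number(s$c_oc, "c_oc", 0, 2, open_lower = TRUE)
  check_number(s$q10_production, "q10_production", 1, Inf)
  check_number(s$q10_respiration, "q10_respiration", 1, Inf)
  check_number(s$day_length, "day_length", 0, Inf, open_lower = TRUE)
  check_number(s$light_fraction, "light_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(s$dbl_thickness, "dbl_thickness", 0, Inf, open_lower = TRUE)
  check_number(s$sediment_depth, "sediment_depth", 0, Inf, open_lower = TRUE)
  check_number(s$grid_spacing, "grid_spacing", 0, Inf, open_lower = TRUE)
  check_number(s$p_max_ref, "p_max_ref", 0, Inf)
  check_number(s$r_max_ref, "r_max_ref", 0, Inf)
  check_number(s$k_o2, "k_o2", 0, Inf, open_lower = TRUE)
  check_number(s$production_efolding, "production_efolding", 0, Inf,
               open_lower = TRUE)
  check_number(s$t_ref, "t_ref", -2, 60)
  s <- s[scenario_fields]
  class(s) <- "benthic_scenario"
  s
}

#' Construct a benthic scenario
#'
#' A `benthic_scenario` bundles the full parameterisation of one
#' sediment-water simulation: environmental state (temperature, salinity,
#' ppO2, organic-carbon load), Q10 temperature sensitivities, diel cycle
#' geometry, spatial domain and rate constants.  Three presets mimic cold
#' (5 C), warm (25 C) and hot (40 C) shelf conditions; any field can be
#' overridden per call.
#'
#' @param preset one of `"cold"`, `"warm"`, `"hot"`, or `NULL` to supply
#'   all fields explicitly.
#' @param ... named field overrides (see Details).
#' @details Fields: `temperature` (C), `salinity` (PSU), `ppO2` (%PAL),
#'   `c_oc` (TOC load relative to the Phanerozoic mean), `q10_production`,
#'   `q10_respiration` (dimensionless Q10 factors), `day_length` (h, full
#'   diel cycle), `light_fraction` (lit fraction of the cycle),
#'   `dbl_thickness` (cm), `sediment_depth` (cm), `grid_spacing` (cm,
#'   target cell size; each layer is always resolved with at least five
#'   cells), `p_max_ref` (uM h-1 gross production at the sediment surface at
#'   `t_ref`), `r_max_ref` (uM h-1 oxygen-saturated respiration at `t_ref`
#'   and `c_oc = 1`), `k_o2` (uM half-saturation of respiration),
#'   `production_efolding` (cm, light attenuation depth of production),
#'   `t_ref` (C, Q10 reference temperature).
#' @return an object of class `benthic_scenario` (a named list).
#' @examples
#' make_scenario("cold")
#' make_scenario("warm", ppO2 = 20, c_oc = 1)
#' @export
make_scenario <- function(preset = NULL, ...) {
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides)))
    stop("scenario overrides must be named", call. = FALSE)
  bad <- setdiff(names(overrides), scenario_fields)
  if (length(bad))
    stop_field(bad[1], "not a scenario field")
  if (!is.null(preset)) {
    if (!is.character(preset) || !preset %in% names(scenario_presets))
      stop(sprintf("unknown preset '%s'; use one of %s",
                   as.character(preset)[1],
                   paste(names(scenario_presets), collapse = ", ")),
           call. = FALSE)
    s <- c(list(temperature = scenario_presets[[preset]]), scenario_defaults)
  } else {
    s <- scenario_defaults
  }
  s[names(overrides)] <- overrides
  validate_scenario(s)
}

#' @export
print.benthic_scenario <- function(x, ...) {
  cat("<benthic_scenario>\n")
  cat(sprintf("  T = %g C, S = %g PSU, ppO2 = %g %%PAL, c_oc = %g\n",
              x$temperature, x$salinity, x$ppO2, x$c_oc))
  cat(sprintf("  Q10 production/respiration = %g / %g (ref %g C)\n",
              x$q10_production, x$q10_respiration, x$t_ref))
  cat(sprintf("  domain: %g cm DBL + %g cm sediment, %g-h cycle (%.0f%% lit)\n",
              x$dbl_thickness, x$sediment_depth, x$day_length,
              100 * x$light_fraction))
  invisible(x)
}

#' Parameter ranges for Monte-Carlo sampling
#'
#' Closed intervals for the five environmental parameters varied in the
#' robustness ensemble.  The defaults cover cold-to-hot shelf conditions
#' (5-40 C), 20-50 %PAL atmospheric oxygen and 0.1-1 times the Phanerozoic
#' organic-carbon load; the Q10 intervals (1.5-3 for both production and
#' respiration) span the sensitivity commonly reported for benthic
#' photosynthesis and sediment respiration.
#'
#' @param temperature,ppO2,c_oc,q10_production,q10_respiration length-2
#'   numeric `c(low, high)` intervals in the parameter's units.
#' @return an object of class `parameter_ranges`.
#' @examples
#' default_ranges()
#' default_ranges(temperature = c(20, 30))
#' @export
default_ranges <- function(temperature = c(5, 40),
                           ppO2 = c(20, 50),
                           c_oc = c(0.1, 1),
                           q10_production = c(1.5, 3),
                           q10_respiration = c(1.5, 3)) {
  r <- list(temperature = temperature, ppO2 = ppO2, c_oc = c_oc,
            q10_production = q10_production,
            q10_respiration = q10_respiration)
  bounds <- list(temperature = c(-2, 60), ppO2 = c(1e-9, 150),
                 c_oc = c(1e-9, 2), q10_production = c(1, Inf),
                 q10_respiration = c(1, Inf))
  for (nm in names(r)) {
    iv <- r[[nm]]
    if (!is.numeric(iv) || length(iv) != 2L || any(!is.finite(iv)))
      stop_field(nm, "must be a finite numeric interval c(low, high)")
    if (iv[1] > iv[2]) stop_field(nm, "interval has low > high")
    if (iv[1] < bounds[[nm]][1] || iv[2] > bounds[[nm]][2])
      stop_field(nm, "interval outside admissible scenario bounds")
  }
  class(r) <- "parameter_ranges"
  r
}

#' Draw scenarios for a Monte-Carlo ensemble
#'
#' Samples `n` benthic scenarios with each varied parameter drawn
#' independently and uniformly from its interval.  All non-varied fields are
#' taken from `base`.  Identical `(ranges, n, seed)` give bit-identical
#' output.
#'
#' @param ranges a [default_ranges()] object.
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @param base scenario supplying the non-varied fields.
#' @return a list of `n` `benthic_scenario` objects, with the drawn values
#'   attached as a data frame in `attr(, "draws")`.
#' @examples
#' draws <- sample_parameters(default_ranges(), 5, seed = 1)
#' attr(draws, "draws")
#' @export
sample_parameters <- function(ranges, n, seed,
                              base = make_scenario("warm")) {
  if (!inherits(ranges, "parameter_ranges"))
    ranges <- do.call(default_ranges, unclass(ranges))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  draws <- with_seed(derive_seed(seed, 1L), {
    as.data.frame(lapply(ranges, function(iv) stats::runif(n, iv[1], iv[2])))
  })
  scenarios <- lapply(seq_len(n), function(i) {
    s <- unclass(base)
    s[names(draws)] <- as.list(draws[i, ])
    validate_scenario(s)
  })
  attr(scenarios, "draws") <- draws
  scenarios
}
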