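# Redox classification of oxygen time series and diel summary metrics.

#' Redox class thresholds
#'
#' Concentration bounds separating the four redox classes used throughout:
#' anoxic below `anoxic_max`, severely hypoxic up to `severe_hypoxic_max`,
#' hypoxic up to `hypoxic_max`, oxic above.  Class intervals are closed
#' below and open above, so exactly 22 uM is hypoxic and exactly 65 uM is
#' oxic.
#'
#' @param anoxic_max,severe_hypoxic_max,hypoxic_max class upper bounds, uM;
#'   defaults 0.02, 22 and 65.
#' @return an object of class `redox_thresholds`.
#' @examples
#' redox_thresholds()
#' @export
redox_thresholds <- function(anoxic_max = 0.02, severe_hypoxic_max = 22,
                             hypoxic_max = 65) {
  check_number(anoxic_max, "anoxic_max", 0, Inf, open_lower = TRUE)
  check_number(severe_hypoxic_max, "severe_hypoxic_max", anoxic_max, Inf,
               open_lower = TRUE)
  check_number(hypoxic_max, "hypoxic_max", severe_hypoxic_max, Inf,
               open_lower = TRUE)
  structure(list(anoxic_max = anoxic_max,
                 severe_hypoxic_max = severe_hypoxic_max,
                 hypoxic_max = hypoxic_max),
            class = "redox_thresholds")
}

redox_levels <- c("anoxic", "severely_hypoxic", "hypoxic", "oxic")

#' Classify oxygen concentrations into redox classes
#'
#' Partitions `[0, Inf)` into `anoxic`, `severely_hypoxic`, `hypoxic` and
#' `oxic`.  Boundaries are closed below, open above (a concentration equal
#' to a class's upper bound belongs to the next class up).
#'
#' @param concentration oxygen concentration(s), uM, non-negative.
#' @param thresholds a [redox_thresholds()] object.
#' @return factor with levels `anoxic < severely_hypoxic < hypoxic < oxic`.
#' @examples
#' classify_redox(c(0.01, 5, 30, 80))
#' @export
classify_redox <- function(concentration, thresholds = redox_thresholds()) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("`concentration` must be finite and non-negative", call. = FALSE)
  cut(concentration,
      breaks = c(-Inf, thresholds$anoxic_max, thresholds$severe_hypoxic_max,
                 thresholds$hypoxic_max, Inf),
      labels = redox_levels, right = FALSE, ordered_result = TRUE)
}

#' Extract a single-depth oxygen time series from a field
#'
#' `interface_series()` returns the trace at the sediment-water interface:
#' the shallowest sediment cell (the benthic side of the z = 0 face), which
#' is where organisms sitting on or in the sediment experience the diel
#' oxygen swings.  `depth_series()` returns the trace at the cell whose
#' centre is nearest an arbitrary depth, e.g. the DBL mid-point used by the
#' Monte-Carlo ensemble criterion.
#'
#' @param field an [simulate_diel()] result.
#' @param depth target depth in cm (negative = above the interface).
#' @return data frame with columns `time` (h) and `o2` (uM), with the
#'   extraction depth in `attr(, "depth")`.
#' @export
interface_series <- function(field) {
  sed <- which(field$depths > 0)
  if (!length(sed))
    stop("field contains no sediment cells", call. = FALSE)
  i <- sed[1]
  if (field$depths[i] > diff(range(field$depths)) / 2)
    stop("interface not inside the field domain", call. = FALSE)
  structure(data.frame(time = field$times, o2 = field$concentration[i, ]),
            depth = field$depths[i])
}

#' @rdname interface_series
#' @export
depth_series <- function(field, depth) {
  if (depth < min(field$depths) || depth > max(field$depths))
    stop("`depth` outside the field domain", call. = FALSE)
  i <- which.min(abs(field$depths - depth))
  structure(data.frame(time = field$times, o2 = field$concentration[i, ]),
            depth = field$depths[i])
}

# Linear-interpolated crossing times and below-threshold residence time.
# `time_below` integrates the indicator {o2 < thr} with exact interpolation
# at crossings.
time_below <- function(time, o2, thr) {
  n <- length(time)
  below <- o2 < thr
  total <- 0
  for (i in seq_len(n - 1L)) {
    dt <- time[i + 1L] - time[i]
    if (below[i] && below[i + 1L]) {
      total <- total + dt
    } else if (below[i] != below[i + 1L]) {
      frac <- (thr - o2[i]) / (o2[i + 1L] - o2[i])
      total <- total + if (below[i]) frac * dt else (1 - frac) * dt
    }
  }
  total
}

cross_time <- function(time, o2, i, thr) {
  # crossing of `thr` between samples i and i+1 (linear interpolation)
  time[i] + (thr - o2[i]) / (o2[i + 1L] - o2[i]) * (time[i + 1L] - time[i])
}

# Duration of the evening traverse: from the last time C >= upper to the
# first subsequent time C < lower.  Returns 0 when the series never reaches
# `upper` or never subsequently drops below `lower`.
evening_traverse <- function(time, o2, upper, lower) {
  ge <- which(o2 >= upper)
  if (!length(ge)) return(0)
  i <- ge[length(ge)]
  if (i == length(o2)) return(0)
  t_hi <- if (o2[i + 1L] < upper) cross_time(time, o2, i, upper) else time[i]
  lo <- which(o2 < lower)
  lo <- lo[lo > i]
  if (!length(lo)) return(0)
  j <- lo[1]
  t_lo <- cross_time(time, o2, j - 1L, lower)
  max(t_lo - t_hi, 0)
}

# Morning traverse: mirror image (first time C >= upper, backwards to the
# last preceding time C < lower).
morning_traverse <- function(time, o2, upper, lower) {
  rev_t <- -rev(time)
  rev_o2 <- rev(o2)
  evening_traverse(rev_t, rev_o2, upper, lower)
}

#' Diel metrics of an interface oxygen series
#'
#' Summarises each full diel cycle of a single-depth oxygen series:
#' day/night maxima and their redox classes, the transition time spent
#' traversing the hypoxic band, and the hours of anoxia.  The transition
#' time is the duration of the evening traverse from the last time the
#' series is oxic (`C >= hypoxic_max`) to the first subsequent time it
#' drops below `severe_hypoxic_max`, plus (by default) the symmetric
#' morning traverse; set `traverse = "evening"` for the evening leg only,
#' the interpretation used when comparing against a single-transition
#' criterion such as "< 1 h from daytime oxic to night-time severe
#' hypoxia".  Crossing times are linearly interpolated between samples.
#'
#' @param series data frame with columns `time` (h, strictly increasing)
#'   and `o2` (uM), e.g. from [interface_series()]; must cover at least one
#'   full cycle.  Cycle k spans `[k * day_length, (k + 1) * day_length)`
#'   with the lit phase first.
#' @param day_length cycle length in h.
#' @param light_fraction lit fraction of the cycle.
#' @param thresholds a [redox_thresholds()] object.
#' @param traverse `"both"` (evening + morning, default) or `"evening"`.
#' @return data frame, one row per complete cycle, with columns `cycle`,
#'   `max_day_o2`, `max_night_o2`, `day_class`, `night_class`,
#'   `transition_time` (h per day) and `anoxia_hours` (h per day).
#' @examples
#' s <- data.frame(time = seq(0, 21, 0.05),
#'                 o2 = 80 * pmax(sin(2 * pi * seq(0, 21, 0.05) / 21), 0))
#' compute_diel_metrics(s, 21, 0.5)
#' @export
compute_diel_metrics <- function(series, day_length, light_fraction,
                                 thresholds = redox_thresholds(),
                                 traverse = c("both", "evening")) {
  traverse <- match.arg(traverse)
  time <- series$time
  o2 <- series$o2
  if (any(diff(time) <= 0))
    stop("`series` time grid must be strictly increasing", call. = FALSE)
  n_cycles <- floor((time[length(time)] - time[1]) / day_length + 1e-9)
  if (n_cycles < 1)
    stop("`series` must cover at least one full cycle", call. = FALSE)
  lit_len <- light_fraction * day_length
  t0 <- time[1]
  rows <- lapply(seq_len(n_cycles), function(k) {
    lo <- t0 + (k - 1) * day_length
    hi <- lo + day_length
    sel <- time >= lo - 1e-9 & time <= hi + 1e-9
    tt <- time[sel] - lo
    oo <- o2[sel]
    day <- tt < lit_len
    max_day <- max(oo[day])
    max_night <- max(oo[!day])
    tr <- evening_traverse(tt, oo, thresholds$hypoxic_max,
                           thresholds$severe_hypoxic_max)
    if (traverse == "both")
      tr <- tr + morning_traverse(tt, oo, thresholds$hypoxic_max,
                                  thresholds$severe_hypoxic_max)
    data.frame(cycle = k,
               max_day_o2 = max_day,
               max_night_o2 = max_night,
               day_class = as.character(classify_redox(max_day, thresholds)),
               night_class = as.character(classify_redox(max_night, thresholds)),
               transition_time = min(tr, day_length),
               anoxia_hours = min(time_below(tt, oo, thresholds$anoxic_max),
                                  day_length))
  })
  do.call(rbind, rows)
}
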