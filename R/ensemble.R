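# Monte-Carlo robustness ensemble: solve the diel model over sampled
# parameter sets and summarise the fraction of parameter space that meets a
# redox-stress criterion.

# A criterion predicate receives the extracted oxygen series (one diel
# cycle, data frame time/o2) plus thresholds and returns TRUE/FALSE.
# All registered criteria ask for the diel redox-stress pattern: oxic by
# day, below a lower redox bound by night, with a fast evening transition.
criterion_registry <- function() {
  make_crit <- function(lower_field, max_hours) {
    force(lower_field); force(max_hours)
    function(series, thresholds) {
      lower <- thresholds[[lower_field]]
      if (max(series$o2) < thresholds$hypoxic_max) return(FALSE)
      if (min(series$o2) >= lower) return(FALSE)
      tr <- evening_traverse(series$time, series$o2,
                             thresholds$hypoxic_max, lower)
      tr > 0 && tr < max_hours
    }
  }
  list(
    fast_transition_severe = make_crit("severe_hypoxic_max", 1),
    fast_transition_anoxic = make_crit("anoxic_max", 1)
  )
}

#' Monte-Carlo ensemble of diel benthic simulations
#'
#' Draws `n` scenarios from `ranges` ([sample_parameters()]), solves each
#' with a spin-up-reduced coarse configuration (3 spin-up cycles, 0.05 cm
#' target grid, one reported cycle), extracts the oxygen series at the
#' evaluation depth and tests a redox-stress criterion: daytime oxic
#' conditions (`>= hypoxic_max`) giving way to night-time conditions below
#' a lower redox bound via an evening transition shorter than one hour.
#' Reports the per-draw metrics and the fraction of successful draws with
#' a 95% binomial (normal-approximation) confidence interval.
#'
#' @param ranges a [default_ranges()] object.
#' @param n number of draws.
#' @param seed integer seed (draws are deterministic in `(ranges, n, seed)`).
#' @param criterion `"fast_transition_severe"` (night below the severe
#'   hypoxia bound, 22 uM; default) or `"fast_transition_anoxic"` (night
#'   below the anoxia bound, 0.02 uM).
#' @param eval_depth `"interface"` (shallowest sediment cell, default) or
#'   `"dbl_mid"` (mid-point of the diffusive boundary layer).
#' @param thresholds a [redox_thresholds()] object.
#' @param base scenario supplying non-varied fields.
#' @param max_failure_fraction solves may fail for extreme parameter draws;
#'   failures are flagged, excluded from the fraction and counted, and the
#'   run errors if their fraction exceeds this bound (default 0.01).
#' @return an object of class `ensemble_result`: list with `table` (one row
#'   per draw: parameters, day max, night min, evening transition time,
#'   `criterion_met`, `failed`), `fraction`, `ci` (95% CI), `n`, `n_failed`,
#'   `criterion`, `eval_depth`.
#' @examples
#' \donttest{
#' res <- run_ensemble(default_ranges(), n = 20, seed = 1)
#' res$fraction
#' }
#' @export
run_ensemble <- function(ranges = default_ranges(), n, seed,
                         criterion = c("fast_transition_severe",
                                       "fast_transition_anoxic"),
                         eval_depth = c("interface", "dbl_mid"),
                         thresholds = redox_thresholds(),
                         base = make_scenario("warm", grid_spacing = 0.05),
                         max_failure_fraction = 0.01) {
  criterion <- match.arg(criterion)
  eval_depth <- match.arg(eval_depth)
  pred <- criterion_registry()[[criterion]]
  scenarios <- sample_parameters(ranges, n, seed, base = base)
  draws <- attr(scenarios, "draws")
  rows <- lapply(seq_len(n), function(i) {
    sc <- scenarios[[i]]
    f <- try(simulate_diel(sc, n_cycles = 1, spinup_cycles = 3,
                           rtol = 1e-5, atol = 1e-3), silent = TRUE)
    if (inherits(f, "try-error"))  # retry stiff draws at the default tolerances
      f <- try(simulate_diel(sc, n_cycles = 1, spinup_cycles = 3),
               silent = TRUE)
    if (inherits(f, "try-error")) {
      return(data.frame(draws[i, ], day_max = NA_real_, night_min = NA_real_,
                        transition = NA_real_, criterion_met = NA,
                        failed = TRUE))
    }
    s <- if (eval_depth == "interface") interface_series(f)
         else depth_series(f, -sc$dbl_thickness / 2)
    lower <- if (criterion == "fast_transition_anoxic")
      thresholds$anoxic_max else thresholds$severe_hypoxic_max
    data.frame(draws[i, ],
               day_max = max(s$o2), night_min = min(s$o2),
               transition = evening_traverse(s$time, s$o2,
                                             thresholds$hypoxic_max, lower),
               criterion_met = pred(s, thresholds), failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_failed <- sum(tab$failed)
  if (n_failed > max_failure_fraction * n)
    stop(sprintf("%d of %d ensemble solves failed (> %.0f%% allowed)",
                 n_failed, n, 100 * max_failure_fraction), call. = FALSE)
  ok <- tab$criterion_met[!tab$failed]
  p_hat <- mean(ok)
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / length(ok))
  structure(list(table = tab, fraction = p_hat,
                 ci = c(max(0, p_hat - half), min(1, p_hat + half)),
                 n = n, n_failed = n_failed, criterion = criterion,
                 eval_depth = eval_depth),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result>\n")
  cat(sprintf("  n = %d draws (%d failed), criterion = %s at %s\n",
              x$n, x$n_failed, x$criterion, x$eval_depth))
  cat(sprintf("  fraction meeting criterion: %.3f (95%% CI %.3f-%.3f)\n",
              x$fraction, x$ci[1], x$ci[2]))
  invisible(x)
}
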