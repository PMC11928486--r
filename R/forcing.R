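# Environmental forcing for the eco-evolutionary model: the optimal-strategy
# series gamma(t), a sinusoid (diel oxygen periodicity) plus Gaussian noise
# (stochastic oxygen events), with a step change ("flooding switch") in
# amplitude and/or noise at a fixed pseudo-time.

#' Configuration of the gamma(t) forcing
#'
#' gamma(t) is the environmentally optimal metabolic strategy, driven by
#' dissolved-oxygen fluctuations.  It is composed of a sinusoid with period
#' `period` pseudo-steps (one "pseudo-day"), i.i.d. Gaussian noise per step,
#' and a switch event at `switch_time` after which the sinusoid amplitude
#' and/or the noise standard deviation are multiplied by the post-switch
#' factors, emulating the intensification of periodic and stochastic oxygen
#' fluctuations when continental flooding expands the shallow benthic
#' habitat.
#'
#' Baseline amplitude and noise defaults were fixed by the package
#' calibration (inst/scripts/calibrate-ecoevo.R, methods vignette) so that
#' pre-switch fluctuations are mild and the post-switch regimes reproduce
#' the three qualitative competition outcomes.
#'
#' @param baseline_amplitude sinusoid amplitude A, strategy units.
#' @param period sinusoid period, pseudo-steps.
#' @param noise_sd baseline noise standard deviation, strategy units.
#' @param mean_gamma mean of gamma.
#' @param switch_time pseudo-step of the flooding switch.
#' @param amplitude_multiplier_post factor applied to A from the switch on
#'   (>= 1).
#' @param noise_multiplier_post factor applied to `noise_sd` from the switch
#'   on (>= 1).
#' @param seed integer seed for the noise stream.
#' @return an object of class `forcing_config`.
#' @examples
#' forcing_config()
#' forcing_config(noise_multiplier_post = 1)  # periodic-only switch
#' @export
forcing_config <- function(baseline_amplitude = 0.095,
                           period = 21,
                           noise_sd = 0.016,
                           mean_gamma = 0,
                           switch_time = 500,
                           amplitude_multiplier_post = 7,
                           noise_multiplier_post = 7,
                           seed = 1L) {
  check_number(baseline_amplitude, "baseline_amplitude", 0, Inf)
  check_number(period, "period", 0, Inf, open_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0, Inf)
  check_number(mean_gamma, "mean_gamma")
  check_number(switch_time, "switch_time", 0, Inf)
  check_number(amplitude_multiplier_post, "amplitude_multiplier_post", 1, Inf)
  check_number(noise_multiplier_post, "noise_multiplier_post", 1, Inf)
  check_number(seed, "seed")
  cfg <- list(baseline_amplitude = baseline_amplitude, period = period,
              noise_sd = noise_sd, mean_gamma = mean_gamma,
              switch_time = switch_time,
              amplitude_multiplier_post = amplitude_multiplier_post,
              noise_multiplier_post = noise_multiplier_post,
              seed = as.integer(seed))
  class(cfg) <- "forcing_config"
  cfg
}

#' Generate the optimal-strategy forcing series gamma(t)
#'
#' Evaluates gamma(t) = mean + A(t) sin(2 pi t / period) + eps(t) on the
#' integer pseudo-time grid t = 0, ..., n_steps - 1, where eps(t) are
#' independent Gaussian draws with standard deviation sigma(t).  A(t) and
#' sigma(t) take their baseline values for t < switch_time and baseline
#' times the post-switch multiplier thereafter.  The series is a pure
#' function of `(config, n_steps)`, including the seed.
#'
#' @param config a [forcing_config()].
#' @param n_steps number of pseudo-steps (>= 1).
#' @return a data frame of class `forcing_series` with columns `time` and
#'   `gamma`.
#' @examples
#' f <- gamma_forcing(forcing_config(noise_sd = 0), 42)
#' plot(f$time, f$gamma, type = "l")
#' @export
gamma_forcing <- function(config, n_steps) {
  if (!inherits(config, "forcing_config"))
    stop("`config` must be a forcing_config", call. = FALSE)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("`n_steps` must be >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  t <- seq_len(n_steps) - 1L
  post <- t >= config$switch_time
  amp <- config$baseline_amplitude *
    ifelse(post, config$amplitude_multiplier_post, 1)
  sd_t <- config$noise_sd * ifelse(post, config$noise_multiplier_post, 1)
  eps <- with_seed(config$seed, stats::rnorm(n_steps)) * sd_t
  gamma <- config$mean_gamma + amp * sin(2 * pi * t / config$period) + eps
  structure(data.frame(time = t, gamma = gamma),
            class = c("forcing_series", "data.frame"),
            config = config)
}
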