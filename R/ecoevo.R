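# Fitness-generating (G) function model of competition between species with
# efficient and poor cellular oxygen sensing (eOSM / pOSM).
#
# Population dynamics  dx_i/dt = x_i * G(v, u, x) |_{v = u_i}
# Per-capita growth    G(v, u, x) = (r / K(v)) [K(v) - sum_j x_j] - d s
# Carrying capacity    K(v) = K_m exp( -(v - gamma)^2 / (2 sigma_k^2) )
# Strategy dynamics    du_i/dt = s_i * dG/dv |_{v = u_i}
#
# The strategy v is an abstract cellular-metabolism phenotype along an
# anaerobic-aerobic continuum; gamma(t) is the environmentally optimal
# strategy driven by dissolved-oxygen fluctuations; s_i is the species'
# oxygen-sensing capacity (how fast its strategy tracks the fitness
# gradient) and d the linear per-capita cost per unit sensing capacity.
# Competition is strategy-independent: all individuals suppress each other
# equally through the unweighted population sum.

#' G-function model parameters
#'
#' Defaults were fixed once by the package calibration
#' (inst/scripts/calibrate-ecoevo.R; methods vignette): the eOSM species
#' senses ten times faster than the pOSM species, the carrying-capacity
#' kernel width sets the penalty for mistracking the optimum, and the
#' default cost `d` sits between the periodic-forcing and
#' stochastic-forcing win thresholds so that the forcing regime, not the
#' cost alone, decides the competition.
#'
#' @param r intrinsic growth rate per pseudo-time step.
#' @param K_m maximum carrying capacity, population units.
#' @param sigma_k width of the Gaussian carrying-capacity kernel, strategy
#'   units.
#' @param d cost coefficient per unit sensing capacity.
#' @param species data frame with one row per species and columns `name`,
#'   `s` (sensing capacity, >= 0), `x0` (initial population, >= 0) and `u0`
#'   (initial strategy).
#' @return an object of class `gfun_params`.
#' @examples
#' gfun_params()
#' gfun_params(d = 0)  # costless sensing
#' @export
gfun_params <- function(r = 0.25, K_m = 100, sigma_k = 0.45, d = 0.04,
                        species = data.frame(
                          name = c("pOSM", "eOSM"),
                          s = c(0.025, 0.25),
                          x0 = c(45, 45),
                          u0 = c(0, 0))) {
  check_number(r, "r", 0, Inf, open_lower = TRUE)
  check_number(K_m, "K_m", 0, Inf, open_lower = TRUE)
  check_number(sigma_k, "sigma_k", 0, Inf, open_lower = TRUE)
  check_number(d, "d", 0, Inf)
  if (!is.data.frame(species) ||
      !all(c("name", "s", "x0", "u0") %in% names(species)))
    stop("`species` needs columns name, s, x0, u0", call. = FALSE)
  if (any(species$s < 0)) stop_field("s", "sensing capacity must be >= 0")
  if (any(species$x0 < 0)) stop_field("x0", "initial population must be >= 0")
  structure(list(r = r, K_m = K_m, sigma_k = sigma_k, d = d,
                 species = species),
            class = "gfun_params")
}

#' Gaussian carrying capacity
#'
#' `K(v) = K_m exp(-(v - gamma)^2 / (2 sigma_k^2))`: maximal (`K_m`) when
#' the focal strategy matches the environmental optimum, falling off
#' symmetrically in the mismatch.
#'
#' @param v focal strategy (vectorised).
#' @param gamma environmental optimum strategy.
#' @param params a [gfun_params()] object.
#' @return carrying capacity in population units.
#' @examples
#' p <- gfun_params()
#' carrying_capacity(0, 0, p)            # K_m
#' carrying_capacity(p$sigma_k, 0, p)    # K_m * exp(-1/2)
#' @export
carrying_capacity <- function(v, gamma, params) {
  params$K_m * exp(-(v - gamma)^2 / (2 * params$sigma_k^2))
}

#' Per-capita growth rate (the G function)
#'
#' `G = (r / K(v)) [K(v) - sum_j x_j] - d s`: logistic growth towards the
#' strategy-dependent carrying capacity, equal density dependence from all
#' individuals, minus the linear sensing cost of the focal species.
#'
#' @inheritParams carrying_capacity
#' @param u resident strategy vector (unused by the strategy-independent
#'   competition kernel; retained for the canonical signature).
#' @param x population vector (>= 0).
#' @param s sensing capacity of the focal species.
#' @return per-capita growth rate per pseudo-step.
#' @examples
#' p <- gfun_params(r = 0.25, d = 0.01)
#' g_function(0, 0, 50, 0, p, s = 1)  # 0.25 * (1 - 50/100) - 0.01
#' @export
g_function <- function(v, u, x, gamma, params, s) {
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  k <- carrying_capacity(v, gamma, params)
  params$r * (1 - sum(x) / k) - params$d * s
}

#' Closed-form fitness gradient dG/dv
#'
#' `dG/dv = -r sum_j x_j (v - gamma) / (sigma_k^2 K(v))`: zero at the
#' optimum or in an empty population, and always pointing the focal
#' strategy towards gamma when populations are present.  Because K(v)
#' underflows far from the optimum, the returned magnitude is capped at
#' `10 * sigma_k * s^-1`-equivalent via [simulate_ecoevo()]'s strategy-rate
#' cap; the raw closed form is returned here with K floored at
#' `K_m * exp(-60)` to keep it finite.
#'
#' @inheritParams g_function
#' @return gradient of per-capita growth per strategy unit.
#' @examples
#' p <- gfun_params()
#' fitness_gradient(0.1, 50, 0, p)  # negative: pulls back towards gamma = 0
#' @export
fitness_gradient <- function(v, x, gamma, params) {
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  k <- pmax(carrying_capacity(v, gamma, params), params$K_m * exp(-60))
  -params$r * sum(x) * (v - gamma) / (params$sigma_k^2 * k)
}

#' Simulate coupled population and strategy dynamics
#'
#' Integrates the G-function model against a piecewise-constant gamma(t)
#' forcing (gamma is held constant within each integer pseudo-step, the
#' resolution at which the forcing is defined) with a fixed-step classical
#' 4th-order Runge-Kutta scheme.  Populations falling below the extinction
#' floor are clamped to zero and stay extinct.  The result is deterministic
#' given `(params, forcing)`.
#'
#' @param params a [gfun_params()] object.
#' @param forcing a [gamma_forcing()] series covering the horizon.
#' @param dt integrator step in pseudo-time units (default 0.1).
#' @param extinction_floor populations below this are set to 0 (default
#'   `1e-4 * K_m`).
#' @return an object of class `ecoevo_trajectory`: data frame with columns
#'   `time`, `gamma`, and per-species `x_<name>` and `u_<name>` columns,
#'   sampled at integer pseudo-steps; parameters in `attr(, "params")`.
#' @examples
#' f <- gamma_forcing(forcing_config(seed = 7), 200)
#' traj <- simulate_ecoevo(gfun_params(), f)
#' @export
simulate_ecoevo <- function(params, forcing, dt = 0.1,
                            extinction_floor = 1e-4 * params$K_m) {
  if (!inherits(params, "gfun_params"))
    stop("`params` must be a gfun_params", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  sp <- params$species
  n_sp <- nrow(sp)
  n_sub <- max(1L, as.integer(round(1 / dt)))
  res <- .ecoevo_rk4(as.numeric(sp$x0), as.numeric(sp$u0),
                     as.numeric(sp$s), as.numeric(forcing$gamma),
                     params$r, params$K_m, params$sigma_k, params$d,
                     n_sub, extinction_floor)
  out <- data.frame(time = forcing$time, gamma = forcing$gamma)
  for (i in seq_len(n_sp)) out[[paste0("x_", sp$name[i])]] <- res$x[, i]
  for (i in seq_len(n_sp)) out[[paste0("u_", sp$name[i])]] <- res$u[, i]
  structure(out, class = c("ecoevo_trajectory", "data.frame"),
            params = params, extinction_floor = extinction_floor)
}

#' Annotate competition outcomes on a trajectory
#'
#' Scans a simulated trajectory for, per species, the first pseudo-step at
#' and after which its population stays below the extinction floor, and for
#' the first pseudo-step after which a single species' share of the total
#' population stays above `dominance_share` through the end of the
#' trajectory.
#'
#' @param trajectory an [simulate_ecoevo()] result.
#' @param extinction_floor population threshold (defaults to the floor used
#'   in the simulation).
#' @param dominance_share sustained share of total population that counts
#'   as dominance (default 0.9).
#' @return list with `extinction_time` (named numeric, `NA` if never),
#'   `dominance_time` (pseudo-step or `NA`) and `dominant_species`.
#' @export
detect_outcomes <- function(trajectory,
                            extinction_floor =
                              attr(trajectory, "extinction_floor"),
                            dominance_share = 0.9) {
  xcols <- grep("^x_", names(trajectory), value = TRUE)
  nm <- sub("^x_", "", xcols)
  xmat <- as.matrix(trajectory[xcols])
  times <- trajectory$time
  n <- nrow(xmat)
  if (is.null(extinction_floor)) extinction_floor <- 1e-4
  ext <- vapply(seq_along(xcols), function(i) {
    below <- xmat[, i] < extinction_floor
    # first index from which `below` holds through the end
    run <- rev(cumprod(rev(below)))
    idx <- which(run == 1)
    if (length(idx)) times[idx[1]] else NA_real_
  }, numeric(1))
  names(ext) <- nm
  tot <- rowSums(xmat)
  share <- xmat / ifelse(tot > 0, tot, NA_real_)
  dom_time <- NA_real_
  dom_sp <- NA_character_
  for (i in seq_along(xcols)) {
    above <- !is.na(share[, i]) & share[, i] > dominance_share
    run <- rev(cumprod(rev(above)))
    idx <- which(run == 1)
    if (length(idx) && idx[1] < n) {
      cand <- times[idx[1]]
      if (is.na(dom_time) || cand < dom_time) {
        dom_time <- cand
        dom_sp <- nm[i]
      }
    }
  }
  list(extinction_time = ext, dominance_time = dom_time,
       dominant_species = dom_sp)
}

# Build the forcing for one of the three named flooding regimes.
mode_forcing <- function(mode = c("combined", "periodic_only",
                                  "stochastic_only"),
                         seed, n_steps = 1500, base = forcing_config()) {
  mode <- match.arg(mode)
  amp_mult <- if (mode == "stochastic_only") 1 else base$amplitude_multiplier_post
  noise_mult <- if (mode == "periodic_only") 1 else base$noise_multiplier_post
  cfg <- forcing_config(
    baseline_amplitude = base$baseline_amplitude, period = base$period,
    noise_sd = base$noise_sd, mean_gamma = base$mean_gamma,
    switch_time = base$switch_time,
    amplitude_multiplier_post = amp_mult,
    noise_multiplier_post = noise_mult, seed = seed)
  gamma_forcing(cfg, n_steps)
}

#' Run one competition experiment under a named forcing regime
#'
#' Convenience wrapper: builds the gamma(t) forcing for one of the three
#' flooding regimes (`periodic_only`, `stochastic_only`, `combined`),
#' simulates the two-species competition and annotates outcomes.
#'
#' @param mode forcing regime.
#' @param seed integer seed for the forcing noise.
#' @param n_steps simulation horizon in pseudo-steps (default 1500:
#'   500 pre-switch plus 1000 post-switch).
#' @param params a [gfun_params()] object.
#' @param base_config baseline [forcing_config()] whose multipliers define
#'   the switch severity.
#' @return list with `trajectory`, `outcomes` and `forcing_mode`.
#' @export
run_competition <- function(mode = c("combined", "periodic_only",
                                     "stochastic_only"),
                            seed = 1L, n_steps = 1500,
                            params = gfun_params(),
                            base_config = forcing_config()) {
  mode <- match.arg(mode)
  f <- mode_forcing(mode, seed = seed, n_steps = n_steps, base = base_config)
  traj <- simulate_ecoevo(params, f)
  list(trajectory = traj, outcomes = detect_outcomes(traj),
       forcing_mode = mode)
}

# Winner of one run: sole survivor, else the species with the larger
# time-averaged population over the final quarter of the run.
run_winner <- function(traj) {
  xcols <- grep("^x_", names(traj), value = TRUE)
  nm <- sub("^x_", "", xcols)
  n <- nrow(traj)
  tail_idx <- seq.int(floor(3 * n / 4) + 1, n)
  final <- as.matrix(traj[xcols])[n, ]
  alive <- final > 0
  if (sum(alive) == 1) return(nm[alive])
  means <- colMeans(as.matrix(traj[tail_idx, xcols]))
  nm[which.max(means)]
}

#' Sweep the oxygen-sensing cost coefficient
#'
#' For each cost `d`, runs replicate two-species competitions under the
#' given forcing regime with independent forcing seeds, declares a winner
#' per run (sole survivor, or the larger time-averaged population over the
#' final quarter when both survive) and reports the majority winner and its
#' win fraction.  Deterministic for a fixed `base_seed`.
#'
#' @param d_values cost coefficients to test.
#' @param forcing_mode one of `"stochastic_only"`, `"periodic_only"`,
#'   `"combined"`.
#' @param replicates runs per cost value (default 25).
#' @param base_seed integer; replicate seeds are derived from it.
#' @param params template [gfun_params()]; its `d` is overridden per sweep
#'   point.
#' @param n_steps horizon per run.
#' @param base_config baseline [forcing_config()].
#' @return data frame with one row per `d`: `d`, `winner`, `win_fraction`
#'   (majority winner's share of replicates) and `eosm_wins` /
#'   `posm_wins` counts.
#' @examples
#' \donttest{
#' cost_sweep(c(0.02, 0.1), "periodic_only", replicates = 5, base_seed = 1)
#' }
#' @export
cost_sweep <- function(d_values, forcing_mode = c("stochastic_only",
                                                  "periodic_only",
                                                  "combined"),
                       replicates = 25, base_seed = 1L,
                       params = gfun_params(), n_steps = 1500,
                       base_config = forcing_config()) {
  forcing_mode <- match.arg(forcing_mode)
  if (!length(d_values)) stop("`d_values` must be non-empty", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  rows <- lapply(seq_along(d_values), function(i) {
    d <- d_values[i]
    p <- params
    p$d <- d
    winners <- vapply(seq_len(replicates), function(rep) {
      f <- mode_forcing(forcing_mode,
                        seed = derive_seed(base_seed, rep),
                        n_steps = n_steps, base = base_config)
      run_winner(simulate_ecoevo(p, f))
    }, character(1))
    ne <- sum(winners == "eOSM")
    np <- sum(winners == "pOSM")
    data.frame(d = d,
               winner = if (ne >= np) "eOSM" else "pOSM",
               win_fraction = max(ne, np) / replicates,
               eosm_wins = ne, posm_wins = np)
  })
  do.call(rbind, rows)
}
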