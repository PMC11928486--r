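# Independent oracles used across the suite.

# Independent steady-state oracle: classical shooting on the steady
# two-point boundary-value problem, written directly from the continuous
# equations (not the package's finite-volume system).  The steady equation
#   d/dz ( D(z) dC/dz ) + P(z) - R(C) = 0
# is integrated downward in depth as a first-order system in (C, F) with
# F = D(z) dC/dz (the flux, continuous across the DBL/sediment interface):
#   dC/dz = F / D(z)
#   dF/dz = R(C) - P(z)
# from C(-dbl) = csat with unknown top flux F0, and F0 is located by
# bisection so that the bottom boundary is zero-flux.  Shots whose
# concentration would go negative are classified as too steep (the (0, 0)
# state is invariant, so C is clamped there and the remaining column stays
# anoxic, which satisfies the bottom condition exactly).
oracle_steady_profile <- function(scenario, lit, n_out = 400) {
  csat <- o2_saturation(scenario$temperature, scenario$salinity,
                        scenario$ppO2)
  d_mol <- o2_diffusivity(scenario$temperature, scenario$salinity)
  q10 <- function(q) q^((scenario$temperature - scenario$t_ref) / 10)
  p0 <- if (lit) scenario$p_max_ref * q10(scenario$q10_production) else 0
  rmax <- scenario$r_max_ref * scenario$c_oc * q10(scenario$q10_respiration)
  k <- scenario$k_o2
  zs <- seq(-scenario$dbl_thickness, scenario$sediment_depth,
            length.out = n_out)
  rhs <- function(z, y, parms) {
    in_sed <- z > 0
    d_here <- if (in_sed) 0.7 * d_mol else d_mol
    c_here <- max(y[1], 0)
    prod <- if (in_sed) p0 * exp(-z / scenario$production_efolding) else 0
    resp <- if (in_sed) rmax * c_here / (c_here + k) else 0
    list(c(y[2] / d_here, resp - prod))
  }
  shoot <- function(f0) {
    out <- deSolve::ode(c(csat, f0), zs, rhs, NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-9 * max(csat, 1))
    c_prof <- out[, 2]
    f_prof <- out[, 3]
    neg <- which(c_prof < -1e-9 * csat)
    list(c = c_prof, f = f_prof,
         hit_zero = length(neg) > 0,
         f_bottom = f_prof[length(f_prof)])
  }
  # total possible column demand bounds the downward flux magnitude
  f_lo <- -(rmax * scenario$sediment_depth +
              p0 * scenario$production_efolding + 1)
  f_hi <- p0 * scenario$production_efolding + 1
  for (it in 1:200) {
    f0 <- (f_lo + f_hi) / 2
    s <- shoot(f0)
    if (s$hit_zero || s$f_bottom < 0) f_lo <- f0 else f_hi <- f0
    if (f_hi - f_lo < 1e-12 * max(abs(f_lo), 1)) break
  }
  s <- shoot(f_hi)
  prof <- pmax(s$c, 0)
  # anoxic tail: the (0, 0) state is an invariant of the steady equations
  # but is unstable under forward-z integration, so once the shot passes
  # through the front (concentration below 1e-3 of saturation) the rest of
  # the column is anoxic
  i_min <- which.min(prof)
  if (prof[i_min] < 1e-3 * csat)
    prof[seq(i_min, length(prof))] <- 0
  data.frame(depth = zs, o2 = prof)
}

# interpolate an oracle profile onto another profile's depth grid
oracle_on_grid <- function(oracle_prof, depths) {
  stats::approx(oracle_prof$depth, oracle_prof$o2, depths, rule = 2)$y
}

# Brute-force diel metric oracle: resample the series on a fine regular
# grid by linear interpolation and count/scan sample-by-sample.
oracle_time_below <- function(time, o2, thr, dt = 1e-3) {
  tt <- seq(min(time), max(time), by = dt)
  oo <- stats::approx(time, o2, tt)$y
  sum(oo < thr) * dt
}

oracle_evening_traverse <- function(time, o2, upper, lower, dt = 1e-3) {
  tt <- seq(min(time), max(time), by = dt)
  oo <- stats::approx(time, o2, tt)$y
  ge <- which(oo >= upper)
  if (!length(ge)) return(0)
  i <- ge[length(ge)]
  lo <- which(oo < lower)
  lo <- lo[lo > i]
  if (!length(lo)) return(0)
  (lo[1] - i) * dt
}

# Reference RK4 integrator for the eco-evolutionary model, written directly
# from the model equations in plain R (independent of the compiled core).
oracle_ecoevo <- function(params, forcing, dt = 0.1,
                          extinction_floor = 1e-4 * params$K_m) {
  sp <- params$species
  x <- as.numeric(sp$x0)
  u <- as.numeric(sp$u0)
  s <- as.numeric(sp$s)
  n_sub <- round(1 / dt)
  h <- 1 / n_sub
  deriv <- function(x, u, gam) {
    xp <- pmax(x, 0)
    tot <- sum(xp)
    k <- pmax(params$K_m * exp(-(u - gam)^2 / (2 * params$sigma_k^2)),
              params$K_m * exp(-60))
    g <- pmax(params$r * (1 - tot / k) - params$d * s, -100)
    du <- s * (-params$r * tot * (u - gam) / (params$sigma_k^2 * k))
    cap <- 10 * params$sigma_k
    list(dx = xp * g, du = pmin(pmax(du, -cap), cap))
  }
  xs <- matrix(NA_real_, nrow(forcing), length(x))
  us <- xs
  for (kk in seq_len(nrow(forcing))) {
    gam <- forcing$gamma[kk]
    for (j in seq_len(n_sub)) {
      k1 <- deriv(x, u, gam)
      k2 <- deriv(x + h / 2 * k1$dx, u + h / 2 * k1$du, gam)
      k3 <- deriv(x + h / 2 * k2$dx, u + h / 2 * k2$du, gam)
      k4 <- deriv(x + h * k3$dx, u + h * k3$du, gam)
      x <- x + h / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
      u <- u + h / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
      x[x < extinction_floor] <- 0
    }
    xs[kk, ] <- x
    us[kk, ] <- u
  }
  list(x = xs, u = us)
}
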