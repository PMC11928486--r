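# Reaction-diffusion model: rate laws, conservation, steady states.

test_that("production follows the Q10 law and is confined to lit sediment", {
  sc <- make_scenario("cold")
  expect_equal(production_rate(0.05, 15, sc), 0)        # dark phase
  expect_equal(production_rate(-0.02, 2, sc), 0)        # DBL
  sc10 <- make_scenario("cold", temperature = sc$t_ref + 10)
  scref <- make_scenario("cold", temperature = sc$t_ref)
  expect_equal(production_rate(0.05, 2, sc10) / production_rate(0.05, 2, scref),
               sc$q10_production)
  # exponential depth attenuation
  expect_equal(production_rate(0.2, 2, scref) / production_rate(0.1, 2, scref),
               exp(-0.1 / sc$production_efolding))
})

test_that("respiration is Michaelis-Menten in O2 and linear in c_oc", {
  sc <- make_scenario("warm")
  expect_equal(respiration_rate(0.05, 0, sc), 0)
  expect_equal(respiration_rate(-0.02, 100, sc), 0)     # DBL
  half <- respiration_rate(0.05, sc$k_o2, sc)
  sat <- respiration_rate(0.05, 1e9, sc)
  expect_equal(half, sat / 2, tolerance = 1e-6)
  sc_lo <- make_scenario("warm", c_oc = 0.1)
  sc_hi <- make_scenario("warm", c_oc = 1)
  expect_equal(respiration_rate(0.05, 50, sc_hi) /
                 respiration_rate(0.05, 50, sc_lo), 10)
  expect_error(respiration_rate(0.05, -1, sc), "non-negative")
})

test_that("pure diffusion relaxes to the saturation boundary value", {
  sc <- make_scenario("warm", p_max_ref = 0, r_max_ref = 0)
  f <- simulate_diel(sc, n_cycles = 1, spinup_cycles = 3)
  csat <- o2_saturation(sc$temperature, sc$salinity, sc$ppO2)
  expect_lt(max(abs(f$concentration - csat)) / csat, 0.001)
})

test_that("steady profiles agree with an independent shooting boundary-value solve", {
  # refined grid so that finite-volume truncation at the sharp production
  # lens / anoxic front sits well below the comparison tolerance
  for (temperature in c(5, 25, 40)) {
    for (c_oc in c(0.1, 0.25, 1)) {
      sc <- make_scenario(NULL, temperature = temperature, c_oc = c_oc,
                          grid_spacing = 0.005)
      for (lit in c(TRUE, FALSE)) {
        got <- steady_profile(sc, lit = lit)
        want <- oracle_on_grid(oracle_steady_profile(sc, lit = lit),
                               got$depth)
        csat <- o2_saturation(sc$temperature, sc$salinity, sc$ppO2)
        rms <- sqrt(mean((got$o2 - want)^2))
        expect_lt(rms / csat, 0.01)
      }
    }
  }
})

test_that("lit steady profile dominates dark and has the reported shapes", {
  sc <- make_scenario("warm")
  lit <- steady_profile(sc, lit = TRUE)
  dark <- steady_profile(sc, lit = FALSE)
  expect_true(all(lit$o2 >= dark$o2 - 1e-6))
  csat <- o2_saturation(sc$temperature, sc$salinity, sc$ppO2)
  # daylight: subsurface maximum above the boundary saturation value
  expect_gt(max(lit$o2), csat)
  expect_gt(lit$depth[which.max(lit$o2)], 0)
  # night: monotone non-increasing with depth
  expect_true(all(diff(dark$o2) <= 1e-6))
  # no sinks: dark profile uniform at saturation
  sc0 <- make_scenario("warm", r_max_ref = 0)
  flat <- steady_profile(sc0, lit = FALSE)
  expect_equal(flat$o2, rep(csat, length(flat$o2)), tolerance = 1e-4)
})

test_that("the diel field conserves mass and reaches a periodic limit cycle", {
  for (preset in c("cold", "warm")) {
    f <- simulate_diel(make_scenario(preset), n_cycles = 2)
    expect_gte(min(f$concentration), 0)
    mb <- mass_balance(f)
    expect_lt(mb$residual_fraction, 0.01)
    # consecutive cycles pointwise within 0.5% (relative to the field scale)
    dl <- f$scenario$day_length
    c1 <- f$concentration[, f$times < dl - 1e-9]
    c2 <- f$concentration[, f$times >= dl - 1e-9 & f$times < 2 * dl - 1e-9]
    k <- min(ncol(c1), ncol(c2))
    expect_lt(max(abs(c1[, 1:k] - c2[, 1:k])) / max(f$concentration), 0.005)
  }
})

test_that("anoxia lengthens with organic load and saturation falls with warmth", {
  anox <- vapply(c(0.1, 0.25, 1), function(c_oc) {
    f <- simulate_diel(make_scenario("warm", c_oc = c_oc), n_cycles = 1)
    s <- interface_series(f)
    benthox:::time_below(s$time, s$o2, redox_thresholds()$anoxic_max)
  }, numeric(1))
  expect_true(all(diff(anox) >= -1e-6))
  sats <- vapply(c(5, 25, 40), function(temperature)
    o2_saturation(temperature, 35, 30), numeric(1))
  expect_true(all(diff(sats) < 0))
})

test_that("the coarse ensemble configuration tracks the fine configuration", {
  sc_fine <- make_scenario("warm")
  sc_coarse <- make_scenario("warm", grid_spacing = 0.05)
  f_fine <- simulate_diel(sc_fine, n_cycles = 1)
  f_coarse <- simulate_diel(sc_coarse, n_cycles = 1, spinup_cycles = 3,
                            rtol = 1e-5, atol = 1e-2)
  s_coarse <- interface_series(f_coarse)
  # compare the duration metrics the ensemble criterion consumes, at the
  # same physical depth (fine field interpolated to the coarse
  # interface-cell centre); instantaneous extremes carry a known
  # coarse-grid truncation bias in the steep production lens and are
  # compared at class level only
  z <- attr(s_coarse, "depth")
  fine_at_z <- apply(f_fine$concentration, 2, function(col)
    stats::approx(f_fine$depths, col, z)$y)
  th <- redox_thresholds()
  b_fine <- benthox:::time_below(f_fine$times, fine_at_z, th$hypoxic_max)
  b_coarse <- benthox:::time_below(s_coarse$time, s_coarse$o2, th$hypoxic_max)
  expect_lt(abs(b_fine - b_coarse), 0.05 * b_fine)
  a_fine <- benthox:::time_below(f_fine$times, fine_at_z, th$anoxic_max)
  a_coarse <- benthox:::time_below(s_coarse$time, s_coarse$o2, th$anoxic_max)
  expect_lt(abs(a_fine - a_coarse), 0.05 * a_fine)
  ev_fine <- benthox:::evening_traverse(f_fine$times, fine_at_z,
                                        th$hypoxic_max, th$severe_hypoxic_max)
  ev_coarse <- benthox:::evening_traverse(s_coarse$time, s_coarse$o2,
                                          th$hypoxic_max,
                                          th$severe_hypoxic_max)
  expect_lt(abs(ev_fine - ev_coarse), 0.05)
  # both configurations agree on the redox classes that drive the criterion
  expect_equal(as.character(classify_redox(max(s_coarse$o2))), "oxic")
  expect_equal(as.character(classify_redox(max(fine_at_z))), "oxic")
  expect_equal(as.character(classify_redox(min(s_coarse$o2))), "anoxic")
  expect_equal(as.character(classify_redox(min(fine_at_z))), "anoxic")
})
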