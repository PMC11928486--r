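# Redox classification and diel metrics.

test_that("classify_redox partitions [0, Inf) with documented boundaries", {
  x <- c(0, 0.0199, 0.02, 5, 21.99, 22, 30, 64.99, 65, 300)
  got <- as.character(classify_redox(x))
  expect_equal(got, c("anoxic", "anoxic", "severely_hypoxic",
                      "severely_hypoxic", "severely_hypoxic", "hypoxic",
                      "hypoxic", "hypoxic", "oxic", "oxic"))
  # every non-negative value maps to exactly one class
  set.seed(1)
  r <- c(runif(500, 0, 200), 0.02, 22, 65)
  expect_false(anyNA(classify_redox(r)))
  expect_error(classify_redox(-1), "non-negative")
  expect_error(redox_thresholds(anoxic_max = 30, severe_hypoxic_max = 22),
               "severe_hypoxic_max")
})

test_that("interface and depth extraction pick the right cells", {
  f <- simulate_diel(make_scenario("cold", p_max_ref = 0, r_max_ref = 0),
                     n_cycles = 1, spinup_cycles = 2)
  s <- interface_series(f)
  # uniform field: constant series at saturation
  csat <- o2_saturation(5, 35, 30)
  expect_equal(s$o2, rep(s$o2[1], length(s$o2)), tolerance = 1e-6)
  expect_equal(s$o2[1], csat, tolerance = 1e-3 * csat)
  expect_gt(attr(s, "depth"), 0)                 # benthic side of the face
  expect_lt(attr(s, "depth"), f$scenario$grid_spacing)
  d <- depth_series(f, -0.025)
  expect_equal(attr(d, "depth"), -0.025, tolerance = 0.006)
  expect_error(depth_series(f, 5), "outside")
})

test_that("a linear evening/morning ramp gives the analytic transition time", {
  # morning ramp 0 -> 100 over 2 h, plateau to dusk, evening ramp 100 -> 0
  # over 2 h, anoxic for the rest of the dark phase
  tt <- seq(0, 21, by = 0.01)
  o2 <- ifelse(tt < 2, 50 * tt,
        ifelse(tt < 10.5, 100,
        ifelse(tt < 12.5, 100 - 50 * (tt - 10.5), 0)))
  m <- compute_diel_metrics(data.frame(time = tt, o2 = o2), 21, 0.5)
  # each traverse spans (65 - 22)/100 of the 2-h ramp: 0.86 h; both: 1.72 h
  expect_equal(m$transition_time, 1.72, tolerance = 0.02)
  m_ev <- compute_diel_metrics(data.frame(time = tt, o2 = o2), 21, 0.5,
                               traverse = "evening")
  expect_equal(m_ev$transition_time, 0.86, tolerance = 0.01)
  # anoxia: below 0.02 uM from the end of the evening ramp to dawn
  expect_equal(m$anoxia_hours, 8.5, tolerance = 0.02)
  expect_equal(m$max_day_o2, 100)
  expect_equal(m$day_class, "oxic")
})

test_that("an instantaneous dusk collapse yields a sub-resolution transition", {
  dt <- 0.05
  tt <- seq(0, 21, by = dt)
  o2 <- ifelse(tt < 10.5, 100, 0)
  m <- compute_diel_metrics(data.frame(time = tt, o2 = o2), 21, 0.5)
  expect_lte(m$transition_time, 2 * dt)
  expect_equal(m$anoxia_hours, 10.5, tolerance = 2 * dt)
})

test_that("metrics agree with a brute-force resampling scan on random series", {
  set.seed(42)
  th <- redox_thresholds()
  for (rep in 1:100) {
    tt <- seq(0, 21, by = 0.05)
    base <- 80 * pmax(sin(2 * pi * (tt - runif(1, 0, 21)) / 21), 0)
    o2 <- pmax(base + cumsum(rnorm(length(tt), 0, 2)), 0)
    ev <- benthox:::evening_traverse(tt, o2, th$hypoxic_max,
                                     th$severe_hypoxic_max)
    ev_oracle <- oracle_evening_traverse(tt, o2, th$hypoxic_max,
                                         th$severe_hypoxic_max)
    expect_equal(ev, ev_oracle, tolerance = 0.01)
    tb <- benthox:::time_below(tt, o2, th$anoxic_max)
    tb_oracle <- oracle_time_below(tt, o2, th$anoxic_max)
    expect_lt(abs(tb - tb_oracle), 0.01)
    m <- compute_diel_metrics(data.frame(time = tt, o2 = o2), 21, 0.5)
    expect_lte(m$anoxia_hours, 21)
    expect_lte(m$transition_time, 21)
  }
})

test_that("metrics are stable under time-grid refinement of a smooth series", {
  f <- function(tt) 50 + 49 * cos(2 * pi * (tt + 10.5) / 21)
  m_coarse <- compute_diel_metrics(
    data.frame(time = seq(0, 21, 0.1), o2 = f(seq(0, 21, 0.1))), 21, 0.5)
  m_fine <- compute_diel_metrics(
    data.frame(time = seq(0, 21, 0.005), o2 = f(seq(0, 21, 0.005))), 21, 0.5)
  expect_lt(abs(m_coarse$transition_time - m_fine$transition_time), 0.1)
  expect_lt(abs(m_coarse$anoxia_hours - m_fine$anoxia_hours), 0.1)
  expect_lt(abs(m_coarse$max_day_o2 - m_fine$max_day_o2), 0.1)
})
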