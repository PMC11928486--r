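# G-function eco-evolutionary model.

test_that("carrying capacity is Gaussian in the strategy mismatch", {
  p <- gfun_params()
  expect_equal(carrying_capacity(0.3, 0.3, p), p$K_m)
  expect_equal(carrying_capacity(0.3 + p$sigma_k, 0.3, p),
               p$K_m * exp(-0.5))
  for (delta in c(0.1, 0.5, 2))
    expect_equal(carrying_capacity(0.3 + delta, 0.3, p),
                 carrying_capacity(0.3 - delta, 0.3, p))
})

test_that("the G function evaluates the logistic-minus-cost form", {
  p <- gfun_params(r = 0.25, K_m = 100, d = 0.01)
  # K(v) = 100 at v = gamma; sum x = 50; d s = 0.01
  expect_equal(g_function(0, 0, 50, 0, p, s = 1), 0.25 * 0.5 - 0.01)
  # logistic equilibrium: G = 0 at sum x = K(v) with d = 0
  p0 <- gfun_params(d = 0)
  expect_equal(g_function(0.2, 0.2, p0$K_m * exp(-0.5) *
                            c(0.4, 0.6), 0.2 + p0$sigma_k, p0, s = 2), 0)
  # low-density growth: G = r when x = 0, d = 0
  expect_equal(g_function(0.1, 0.1, c(0, 0), 0.4, p0, s = 1), p0$r)
  expect_error(g_function(0, 0, -1, 0, p, s = 1), "non-negative")
})

test_that("closed-form fitness gradient matches numerical differentiation", {
  set.seed(7)
  p <- gfun_params()
  for (case in 1:25) {
    v <- runif(1, -1, 1)
    gam <- runif(1, -1, 1)
    x <- runif(2, 0, 120)
    closed <- fitness_gradient(v, x, gam, p)
    eps <- 1e-6 * max(1, abs(v))
    num <- (g_function(v + eps, 0, x, gam, p, s = 1) -
            g_function(v - eps, 0, x, gam, p, s = 1)) / (2 * eps)
    expect_equal(closed, num, tolerance = 1e-6)
  }
  expect_equal(fitness_gradient(0.4, c(10, 5), 0.4, p), 0)  # at optimum
  expect_equal(fitness_gradient(0.9, c(0, 0), 0.2, p), 0)   # empty population
  # gradient points towards gamma
  expect_lt(fitness_gradient(0.5, 50, 0, p), 0)
  expect_gt(fitness_gradient(-0.5, 50, 0, p), 0)
})

constant_forcing <- function(gamma, n) {
  structure(data.frame(time = seq_len(n) - 1, gamma = rep(gamma, n)),
            class = c("forcing_series", "data.frame"))
}

one_species <- function(s, x0, u0, ...) {
  gfun_params(..., species = data.frame(name = "sp", s = s, x0 = x0, u0 = u0))
}

test_that("single species recovers the logistic and cost-discounted equilibria", {
  # d = 0, u0 = gamma: plain logistic to K_m
  p <- one_species(s = 0.1, x0 = 5, u0 = 0.3, d = 0)
  traj <- simulate_ecoevo(p, constant_forcing(0.3, 300))
  expect_equal(traj$x_sp[300], p$K_m, tolerance = 1e-3)
  expect_equal(traj$u_sp[300], 0.3, tolerance = 1e-9)
  # x* = K_m (1 - d s / r) across a (d, s) grid
  for (d in c(0, 0.02, 0.05, 0.08)) {
    for (s in c(0.025, 0.1, 0.25, 0.5)) {
      p <- one_species(s = s, x0 = 20, u0 = 0.1, d = d)
      traj <- simulate_ecoevo(p, constant_forcing(0.1, 400))
      expect_equal(traj$x_sp[400], p$K_m * (1 - d * s / p$r),
                   tolerance = 1e-3)
    }
  }
})

test_that("identical species stay identical; sensing speed sets tracking rate", {
  p <- gfun_params(species = data.frame(name = c("a", "b"),
                                        s = c(0.25, 0.25),
                                        x0 = c(30, 30), u0 = c(0.1, 0.1)))
  f <- gamma_forcing(forcing_config(noise_sd = 0, seed = 3), 400)
  traj <- simulate_ecoevo(p, f)
  expect_lt(max(abs(traj$x_a - traj$x_b), abs(traj$u_a - traj$u_b)), 1e-10)
  # under constant gamma the strategy mismatch decays monotonically, faster
  # for the better senser
  p2 <- gfun_params(species = data.frame(name = c("slow", "fast"),
                                         s = c(0.025, 0.25),
                                         x0 = c(30, 30), u0 = c(0, 0)))
  traj2 <- simulate_ecoevo(p2, constant_forcing(0.4, 150))
  mis_slow <- abs(traj2$u_slow - 0.4)
  mis_fast <- abs(traj2$u_fast - 0.4)
  expect_true(all(diff(mis_slow) <= 1e-12))
  expect_true(all(diff(mis_fast) <= 1e-12))
  expect_true(all(mis_fast[-1] < mis_slow[-1]))
})

test_that("compiled integrator reproduces a plain-R reference integrator", {
  p <- gfun_params()
  f <- gamma_forcing(forcing_config(seed = 11), 250)
  got <- simulate_ecoevo(p, f)
  ref <- oracle_ecoevo(p, f)
  expect_equal(as.numeric(got$x_pOSM), ref$x[, 1], tolerance = 1e-12)
  expect_equal(as.numeric(got$x_eOSM), ref$x[, 2], tolerance = 1e-12)
  expect_equal(as.numeric(got$u_pOSM), ref$u[, 1], tolerance = 1e-12)
  expect_equal(as.numeric(got$u_eOSM), ref$u[, 2], tolerance = 1e-12)
})

test_that("states stay finite and non-negative under randomised parameters", {
  set.seed(9)
  for (case in 1:5) {
    p <- gfun_params(r = runif(1, 0.1, 0.5), sigma_k = runif(1, 0.2, 1),
                     d = runif(1, 0, 0.1),
                     species = data.frame(name = c("a", "b"),
                                          s = runif(2, 0, 1),
                                          x0 = runif(2, 1, 80),
                                          u0 = runif(2, -2, 2)))
    f <- gamma_forcing(forcing_config(noise_sd = 0.5, seed = case), 2000)
    traj <- simulate_ecoevo(p, f)
    expect_true(all(is.finite(as.matrix(traj[c("x_a", "x_b", "u_a", "u_b")]))))
    expect_true(all(traj$x_a >= 0 & traj$x_b >= 0))
  }
})

test_that("outcome detection matches a hand-built trajectory", {
  n <- 600
  x1 <- rep(50, n)
  x2 <- c(seq(40, 0.5, length.out = 311), rep(0, n - 311))  # extinct at 312
  traj <- data.frame(time = seq_len(n) - 1, gamma = 0,
                     x_a = x1, x_b = x2, u_a = 0, u_b = 0)
  out <- detect_outcomes(traj, extinction_floor = 0.01, dominance_share = 0.9)
  expect_equal(unname(out$extinction_time["b"]), 311)  # time index 311 = step 312
  expect_equal(out$dominant_species, "a")
  expect_lte(out$dominance_time, 311)
  # perpetual tie: no dominance, no extinction
  tie <- data.frame(time = 0:99, gamma = 0, x_a = 50, x_b = 50,
                    u_a = 0, u_b = 0)
  out_tie <- detect_outcomes(tie, extinction_floor = 0.01)
  expect_true(is.na(out_tie$dominance_time))
  expect_true(all(is.na(out_tie$extinction_time)))
})

test_that("costless sensing wins under fluctuating forcing", {
  sw <- cost_sweep(0, "combined", replicates = 5, base_seed = 2)
  expect_equal(sw$winner, "eOSM")
  expect_equal(sw$win_fraction, 1)
})
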