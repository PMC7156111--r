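test_that("one deterministic step matches exact rational arithmetic", {
  p <- gfg_params(s = 0.5, c_H = 0.05, c_P = 0.1)
  st <- gfg_step(c(R = 0.2, a1 = 0.2), p)
  # golden values from exact rational evaluation of the recursions
  expect_equal(st$a2, 9 / 41, tolerance = 1e-14)
  expect_equal(st$a1, 2169 / 8729, tolerance = 1e-14)
  expect_equal(st$R, 6669 / 23069, tolerance = 1e-14)
})

test_that("boundary states behave as fixed points or cost-free fixation", {
  p <- gfg_params(s = 0.5, c_H = 0.05, c_P = 0.2)
  st <- gfg_step(c(R = 0, a1 = 0), p)
  expect_identical(unlist(st), c(R = 0, a1 = 0, a2 = 0))

  p0 <- gfg_params(s = 0.5, c_H = 0.05, c_P = 0)
  st <- gfg_step(c(R = 0.5, a1 = 1), p0)
  expect_equal(st$a2, 1)
  expect_equal(st$a1, 1)

  # fully degenerate corner: resistant hosts fixed, no infective parasites
  expect_error(gfg_step(c(R = 1, a1 = 0), p), "degenerate")
})

test_that("closed-form equilibrium satisfies its algebraic identity", {
  set.seed(42)
  for (i in 1:200) {
    p <- gfg_params(s = runif(1, 0.05, 0.9), c_H = runif(1, 0, 0.35),
                    c_P = runif(1, 0.01, 0.35))
    eq <- gfg_equilibrium(p)
    if (isTRUE(eq$valid))
      expect_equal(eq$R_hat * (2 - p$c_P - eq$a_hat), p$c_P,
                   tolerance = 1e-12)
  }
})

test_that("without a resistance cost the infective allele fixes (no interior equilibrium)", {
  eq <- gfg_equilibrium(gfg_params(s = 0.4, c_H = 0, c_P = 0.1))
  expect_equal(eq$a_hat, 1, tolerance = 1e-12)
  expect_false(eq$valid)
})

test_that("closed form is near the iterated long-run equilibrium at reference costs", {
  p <- gfg_params(s = 0.5, c_H = 0.05, c_P = 0.1)
  eq <- gfg_equilibrium(p)
  expect_true(eq$valid)
  traj <- gfg_iterate(p, R0 = 0.2, a0 = 0.2, g_max = 30000)
  it <- equilibrium_from_trajectory(traj)
  # frozen oracle values from an independent 30,000-generation iteration
  expect_equal(it$a_hat, 0.9040221, tolerance = 1e-5)
  expect_equal(it$R_hat, 0.0920550, tolerance = 1e-4)
  expect_lt(abs(it$a_hat - eq$a_hat), 0.05)
  expect_lt(abs(it$R_hat - eq$R_hat), 0.05)
})

test_that("a refined fixed point is invariant under iteration", {
  p <- gfg_params(s = 0.4, c_H = 0.05, c_P = 0.1)
  # converge to the attracting fixed point, then check invariance
  traj <- gfg_iterate(p, g_max = 200000)
  R <- traj$R[200001]; a1 <- traj$a1[200001]
  st <- gfg_step(c(R = R, a1 = a1), p)
  expect_lt(abs(st$R - R), 1e-9)
  expect_lt(abs(st$a1 - a1), 1e-9)
  short <- gfg_iterate(p, R0 = R, a0 = a1, g_max = 50)
  expect_true(all(abs(short$R - R) < 1e-9))
  expect_true(all(abs(short$a1 - a1) < 1e-9))
})

test_that("when infection costs less than resistance, the susceptible allele fixes", {
  p <- gfg_params(s = 0.04, c_H = 0.05, c_P = 0.1)
  traj <- gfg_iterate(p, g_max = 2000)
  expect_true(all(diff(traj$R) < 0))
  expect_lt(traj$R[2001], 1e-4)
})

test_that("iterated infective equilibrium is non-decreasing in the cost of infection", {
  a_hats <- vapply(seq(0.2, 0.8, by = 0.1), function(s) {
    traj <- gfg_iterate(gfg_params(s, 0.05, 0.1), g_max = 30000)
    equilibrium_from_trajectory(traj)$a_hat
  }, numeric(1))
  expect_true(all(diff(a_hats) >= -1e-9))
})

test_that("frequencies stay in [0,1] for randomized states and parameters", {
  set.seed(7)
  for (i in 1:20000) {
    p <- gfg_params(s = runif(1), c_H = runif(1, 0, 0.99),
                    c_P = runif(1, 0, 0.99))
    R <- runif(1); a1 <- runif(1)
    st <- gfg_step(c(R = R, a1 = a1), p)
    ok <- all(unlist(st) >= 0) && all(unlist(st) <= 1)
    if (!ok) fail(sprintf("out of [0,1] at R=%g a1=%g s=%g cH=%g cP=%g",
                          R, a1, p$s, p$c_H, p$c_P))
  }
  succeed()
})

test_that("dynamics classification distinguishes fixation, polymorphism and degeneracy", {
  cfg <- population_config(500, 500)
  prm <- gfg_params(0.5, 0.05, 0.1)

  # stochastic path ending with INF fixed
  pth <- simulate_frequency_path(prm, cfg, sim_settings(g_max = 50, seed = 1))
  pth$parasite$count[51] <- 500L
  expect_identical(classify_dynamics(pth), "arms_race")

  # both species segregating at the end
  pth$parasite$count[51] <- 250L
  pth$host$count[51] <- 250L
  expect_identical(classify_dynamics(pth), "trench_warfare")

  # polymorphism never established
  pth0 <- simulate_frequency_path(
    gfg_params(0.5, 0.05, 0.1, mu_rtoR = 0, mu_ntoI = 0), cfg,
    sim_settings(R0 = 0, a0 = 0, g_max = 50, seed = 1))
  expect_identical(classify_dynamics(pth0), "degenerate")

  # deterministic trajectory uses the 1/(2N) threshold
  traj <- gfg_iterate(prm, g_max = 1000)
  expect_identical(classify_dynamics(traj, N_H = 10000, N_P = 10000),
                   "trench_warfare")
})

test_that("arms-race fraction increases with the cost of infection", {
  # 200 seeded stochastic paths at s = 0.3 vs s = 0.85 (c_H=0.05, c_P=0.1);
  # scaled population so the forward runs stay cheap
  frac_ar <- function(s, seed) {
    cfg <- population_config(1000, 1000)
    prm <- gfg_params(s, 0.05, 0.1)
    set.seed(seed)
    mean(vapply(1:200, function(i) {
      classify_dynamics(simulate_frequency_path(prm, cfg,
                                                sim_settings(g_max = 3000))) ==
        "arms_race"
    }, logical(1)))
  }
  expect_gt(frac_ar(0.85, 11), frac_ar(0.3, 11))
})
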