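test_that("prior draws respect their supports and distributions", {
  set.seed(1)
  p2 <- scenario_prior(2)
  d2 <- replicate(20000, unlist(draw_prior(p2, "coevolution")["s"]))
  expect_true(all(d2 > 0.1 & d2 < 0.9))
  ch <- replicate(5000, draw_prior(p2, "coevolution")$c_H)
  cp <- replicate(5000, draw_prior(p2, "coevolution")$c_P)
  expect_true(all(ch > 0.01 & ch < 0.35))
  expect_true(all(cp > 0.01 & cp < 0.35))
  expect_true(all(vapply(1:50, function(i) {
    n <- draw_prior(p2, "neutral")
    is.na(n$s) && n$N_H == 10000
  }, logical(1))))

  p1 <- scenario_prior(1)
  NH <- replicate(100000, draw_prior(p1, "coevolution")$N_H)
  expect_gte(min(NH), 2000)
  expect_lte(max(NH), 40000)
  # log-uniformity against the analytic CDF
  ks <- suppressWarnings(ks.test(log(NH), "punif",
                                 log(2000), log(40000)))
  expect_gt(ks$p.value, 0.01)
  # scenario-1 neutral draws carry only population sizes
  nd <- draw_prior(p1, "neutral")
  expect_true(is.na(nd$s) && is.na(nd$c_H) && !is.na(nd$N_H))
})

test_that("neutral reference entries reproduce the Watterson expectation", {
  set.seed(2)
  pri <- scenario_prior(2)
  d <- list(s = NA, c_H = NA, c_P = NA, N_H = 10000L, N_P = 10000L)
  e <- t(vapply(1:200, function(i)
    simulate_reference_entry(d, pri, "neutral", r = 30),
    setNames(numeric(17), sumstat_names())))
  se <- sd(e[, "host_thetaW"]) / sqrt(nrow(e))
  expect_lt(abs(mean(e[, "host_thetaW"]) - 5), 4 * se)
})

test_that("reference entries are reproducible from a seed", {
  pri <- scenario_prior(2)
  d <- list(s = 0.4, c_H = 0.05, c_P = 0.1, N_H = 500L, N_P = 500L)
  set.seed(11)
  e1 <- simulate_reference_entry(d, pri, "coevolution", r = 3, g_max = 500)
  set.seed(11)
  e2 <- simulate_reference_entry(d, pri, "coevolution", r = 3, g_max = 500)
  expect_identical(e1, e2)
})

test_that("model choice recovers a distance-zero observation and normalises posteriors", {
  set.seed(3)
  n <- 300
  stats_a <- matrix(rnorm(n * 17), n, 17)
  stats_b <- matrix(rnorm(n * 17, mean = 10), n, 17)
  tab <- synth_table(rep(c("coevolution", "neutral"), each = n),
                     data.frame(s = runif(2 * n)),
                     rbind(stats_a, stats_b))
  cols <- sumstat_names()

  obs <- unlist(as.data.frame(tab)[5, cols])
  mc <- model_choice(obs, tab, tolerance = 0.01)
  expect_equal(sum(mc$posterior), 1)
  expect_equal(mc$posterior[["coevolution"]], 1.0)
  expect_identical(mc$n_retained, as.integer(ceiling(0.01 * 2 * n)))

  # separated clouds: observation at the origin
  mc0 <- model_choice(setNames(rep(0, 17), cols), tab, tolerance = 0.05)
  expect_gte(mc0$posterior[["coevolution"]], 0.99)

  # posteriors always sum to one
  for (i in 1:10) {
    obs <- setNames(rnorm(17, 5), cols)
    expect_equal(sum(model_choice(obs, tab)$posterior), 1)
  }
})

test_that("model choice is invariant to row order and column rescaling", {
  set.seed(4)
  n <- 200
  stats <- matrix(rnorm(2 * n * 17), 2 * n, 17)
  stats[seq_len(n), 1] <- stats[seq_len(n), 1] + 2
  tab <- synth_table(rep(c("coevolution", "neutral"), each = n),
                     data.frame(s = runif(2 * n)), stats)
  cols <- sumstat_names()
  obs <- setNames(rnorm(17), cols)
  ref <- model_choice(obs, tab)$posterior

  perm <- sample(2 * n)
  tab_perm <- as_reference_table(as.data.frame(tab)[perm, ],
                                 scenario_prior(2), 1)
  expect_equal(model_choice(obs, tab_perm)$posterior, ref)

  tab_scaled <- as.data.frame(tab)
  tab_scaled[[cols[3]]] <- tab_scaled[[cols[3]]] * 1000
  obs_scaled <- obs
  obs_scaled[cols[3]] <- obs_scaled[cols[3]] * 1000
  mc_scaled <- model_choice(obs_scaled,
                            as_reference_table(tab_scaled, scenario_prior(2), 1))
  expect_equal(mc_scaled$posterior, ref)
})

test_that("zero-spread statistics are dropped from model choice with a warning", {
  set.seed(5)
  n <- 100
  stats <- matrix(rnorm(2 * n * 17), 2 * n, 17)
  stats[, 17] <- 1  # constant PMD column
  tab <- synth_table(rep(c("coevolution", "neutral"), each = n),
                     data.frame(s = runif(2 * n)), stats)
  obs <- setNames(c(rnorm(16), 1), sumstat_names())
  expect_warning(mc <- model_choice(obs, tab), "zero-MAD")
  expect_equal(sum(mc$posterior), 1)
})

test_that("cross-validation of indistinguishable models is at chance level", {
  # a single finite table can genuinely favour one label over the bulk of the
  # space, so chance behaviour is asserted on the average over table
  # realizations, with a wide band per realization
  set.seed(6)
  n <- 250
  fnr <- fpr <- numeric(3)
  for (k in 1:3) {
    stats <- matrix(rnorm(2 * n * 17), 2 * n, 17)
    tab <- synth_table(rep(c("coevolution", "neutral"), each = n),
                       data.frame(s = runif(2 * n)), stats)
    cv <- cross_validate(tab, n_val = 60, tolerance = 0.02, seed = 7 + k)
    expect_identical(sum(cv$counts["coevolution", ]), 60L)
    expect_identical(sum(cv$counts["neutral", ]), 60L)
    expect_gt(cv$FNR, 20); expect_lt(cv$FNR, 80)
    expect_gt(cv$FPR, 20); expect_lt(cv$FPR, 80)
    fnr[k] <- cv$FNR; fpr[k] <- cv$FPR
  }
  expect_gt(mean(fnr), 35); expect_lt(mean(fnr), 65)
  expect_gt(mean(fpr), 35); expect_lt(mean(fpr), 65)
})

test_that("an informative statistic drives the posterior median to the truth", {
  set.seed(8)
  n <- 4000
  s <- runif(n, 0.1, 0.9)
  stats <- matrix(rnorm(n * 17, sd = 0.5), n, 17)
  stats[, 4] <- s + rnorm(n, sd = 0.01)  # one statistic equals the parameter
  tab <- synth_table(rep("coevolution", n), data.frame(s = s), stats)
  obs <- setNames(numeric(17), sumstat_names())
  obs[4] <- 0.47
  est <- estimate_parameters(obs, tab, n_retain = 500, stat_subset = "joint")
  expect_lt(abs(est$median[["s"]] - 0.47), 0.02)
})

test_that("constant statistic columns are ignored by the regression adjustment", {
  set.seed(9)
  n <- 2000
  s <- runif(n, 0.1, 0.9)
  stats <- matrix(rnorm(n * 17, sd = 0.5), n, 17)
  stats[, 4] <- s + rnorm(n, sd = 0.02)
  tab1 <- synth_table(rep("coevolution", n), data.frame(s = s), stats)
  stats2 <- stats
  stats2[, 9] <- 7  # constant column
  tab2 <- synth_table(rep("coevolution", n), data.frame(s = s), stats2)
  obs <- setNames(numeric(17), sumstat_names()); obs[4] <- 0.5
  obs2 <- obs; obs2[9] <- 7
  e1 <- estimate_parameters(obs, tab1, n_retain = 300)
  e2 <- NULL
  expect_warning(e2 <- estimate_parameters(obs2, tab2, n_retain = 300),
                 "constant")
  expect_lt(abs(e1$median[["s"]] - e2$median[["s"]]), 0.02)
})

test_that("estimation is equivariant under affine reparametrisation", {
  set.seed(10)
  n <- 2000
  s <- runif(n, 0, 1)
  stats <- matrix(rnorm(n * 17, sd = 0.3), n, 17)
  stats[, 2] <- s + rnorm(n, sd = 0.05)
  obs <- setNames(numeric(17), sumstat_names()); obs[2] <- 0.6

  tab_a <- synth_table(rep("coevolution", n), data.frame(s = s), stats,
                       prior = synth_prior(0, 1))
  tab_b <- synth_table(rep("coevolution", n), data.frame(s = 2 * s + 1), stats,
                       prior = synth_prior(1, 3))
  m_a <- estimate_parameters(obs, tab_a, n_retain = 300)$median[["s"]]
  m_b <- estimate_parameters(obs, tab_b, n_retain = 300)$median[["s"]]
  expect_equal(m_b, 2 * m_a + 1, tolerance = 1e-8)
})

test_that("posterior medians are clamped to the prior support", {
  set.seed(11)
  n <- 1500
  s <- runif(n, 0.1, 0.9)
  stats <- matrix(rnorm(n * 17, sd = 0.2), n, 17)
  stats[, 4] <- s + rnorm(n, sd = 0.01)
  tab <- synth_table(rep("coevolution", n), data.frame(s = s), stats)
  obs <- setNames(numeric(17), sumstat_names())
  obs[4] <- 2.5  # far outside the prior: adjustment would overshoot
  est <- estimate_parameters(obs, tab, n_retain = 300)
  expect_gte(est$median[["s"]], 0.1)
  expect_lte(est$median[["s"]], 0.9)
})
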