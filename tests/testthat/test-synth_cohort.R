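# Phenotype-level and time-series-level synthetic twin cohorts.

test_that("ace_spec validates variance fractions", {
  expect_s3_class(ace_spec(0.5, 0.1, 0.4), "ace_spec")
  expect_error(ace_spec(0.5, 0.1, 0.5), "sum to 1")
  expect_error(ace_spec(-0.1, 0.5, 0.6), "non-negative")
  expect_error(cohort_shape(0, 0), "at least one pair")
})

test_that("phenotype generator reproduces the expected twin correlations", {
  # degenerate corners
  ph <- simulate_ace_phenotypes(ace_spec(1, 0, 0), cohort_shape(10000, 0, seed = 3))
  expect_gt(cor(ph$twin1, ph$twin2), 0.99)
  ph <- simulate_ace_phenotypes(ace_spec(0, 0, 1), cohort_shape(10000, 0, seed = 3))
  expect_lt(abs(cor(ph$twin1, ph$twin2)), 0.05)

  # rMZ -> a2 + c2, rDZ -> a2/2 + c2
  ph <- simulate_ace_phenotypes(ace_spec(0.5, 0.1, 0.4),
                                cohort_shape(20000, 20000, seed = 11))
  mz <- ph$zygosity == "MZ"
  r_mz <- intraclass_correlation(ph$twin1[mz], ph$twin2[mz])
  r_dz <- intraclass_correlation(ph$twin1[!mz], ph$twin2[!mz])
  expect_lt(abs(r_mz - 0.6), 0.02)
  expect_lt(abs(r_dz - 0.35), 0.02)
  # marginal variance ~ 1
  expect_lt(abs(var(c(ph$twin1, ph$twin2)) - 1), 0.03)
})

test_that("ADE generation gives rMZ > 2 rDZ when dominance is strong", {
  ph <- simulate_ace_phenotypes(ade_spec(0.2, 0.5, 0.3),
                                cohort_shape(20000, 20000, seed = 5))
  mz <- ph$zygosity == "MZ"
  r_mz <- intraclass_correlation(ph$twin1[mz], ph$twin2[mz])
  r_dz <- intraclass_correlation(ph$twin1[!mz], ph$twin2[!mz])
  # expectations: rMZ = a2 + d2 = 0.7, rDZ = a2/2 + d2/4 = 0.225
  expect_lt(abs(r_mz - 0.7), 0.02)
  expect_lt(abs(r_dz - 0.225), 0.02)
  expect_equal(choose_family(r_mz, r_dz), "ADE")
})

test_that("phenotype generation is deterministic given the seed", {
  a <- simulate_ace_phenotypes(ace_spec(0.4, 0.2, 0.4), cohort_shape(50, 50, seed = 9))
  b <- simulate_ace_phenotypes(ace_spec(0.4, 0.2, 0.4), cohort_shape(50, 50, seed = 9))
  expect_identical(a, b)
})

test_that("Markov planting matches run-length and occupancy expectations", {
  map <- default_network_map()
  nets <- setNames(unname(unclass(map)), names(map))
  cov1 <- network_block_corr(nets, 0.5, 0.2)
  plan <- state_plan(list(cov1, cov1), stay_prob = c(0.9, 0.9))

  states <- plant_markov_states(plan, 100000, seed = 21)
  runs <- rle(states)
  for (s in 1:2) {
    expect_lt(abs(mean(runs$lengths[runs$values == s]) - 10), 0.5)
  }

  plan5 <- state_plan(list(cov1, cov1), stay_prob = c(0.5, 0.5))
  states5 <- plant_markov_states(plan5, 100000, seed = 22)
  expect_lt(abs(mean(states5 == 1) - 0.5), 0.02)

  expect_identical(plant_markov_states(plan, 500, seed = 7),
                   plant_markov_states(plan, 500, seed = 7))
  expect_error(plant_markov_states(plan, 0, seed = 1), ">= 1")
})

test_that("asymmetric stay probabilities match the analytic stationary law", {
  map <- default_network_map()
  nets <- setNames(unname(unclass(map)), names(map))
  cov1 <- network_block_corr(nets, 0.5, 0.2)
  plan <- state_plan(list(cov1, cov1), stay_prob = c(0.95, 0.8))
  # stationary: pi1 = (1-p22)/((1-p11)+(1-p22)) = 0.2/0.25 = 0.8
  expect_equal(markov_stationary(matrix(c(0.95, 0.05, 0.2, 0.8), 2, 2,
                                        byrow = TRUE)),
               c(0.8, 0.2), tolerance = 1e-10)
  states <- plant_markov_states(plan, 100000, seed = 13)
  expect_lt(abs(mean(states == 1) - 0.8), 0.02)
})

test_that("simulated time series converge to the planted covariance", {
  labels <- c("A", "B", "C", "D")
  nets <- setNames(c("Default", "Default", "Visual", "Visual"), labels)
  corr <- network_block_corr(nets, 0.6, 0.2)
  plan <- state_plan(list(corr), stay_prob = 0)
  manifest <- default_manifest(1, 0)  # single MZ pair, no condition effect
  design <- task_design(data.frame(onset = 0, duration = 7200, condition = "0bk"))
  sim <- simulate_twin_timeseries(manifest, design, plan, effects = NULL,
                                  seed = 4, tr = 0.72, n_runs = 1,
                                  n_frames = 10000)
  x <- sim$timeseries[[1]][[1]]$data
  expect_lt(max(abs(cor(x) - corr)), 0.05)
})

test_that("planted 2-back increments produce an MZ > DZ differential edge", {
  map <- default_network_map()
  nets <- setNames(unname(unclass(map)), names(map))
  corr <- network_block_corr(nets, 0.3, 0.1)
  plan <- state_plan(list(corr), stay_prob = 0)
  manifest <- default_manifest(100, 100)
  design <- default_task_design()
  target <- "L-p9-46v|L-PGi"
  eff <- edge_effect_spec(target, ace_spec(0.8, 0, 0.2),
                          effect_mean = 0.25, effect_sd = 0.15)
  sim <- simulate_twin_timeseries(manifest, design, plan, effects = eff,
                                  seed = 17, n_runs = 1)
  params <- window_params()
  res <- cohort_edge_phenotypes(sim$timeseries, design, params)
  vals <- res$tables$staticFC$values[, target]
  zyg <- manifest$pairs$zygosity
  v1 <- vals[manifest$pairs$subject1]
  v2 <- vals[manifest$pairs$subject2]
  r_mz <- intraclass_correlation(v1[zyg == "MZ"], v2[zyg == "MZ"])
  r_dz <- intraclass_correlation(v1[zyg == "DZ"], v2[zyg == "DZ"])
  expect_gt(r_mz, r_dz)
})

test_that("time-series simulation is deterministic given the seed", {
  map <- default_network_map()
  nets <- setNames(unname(unclass(map)), names(map))
  corr <- network_block_corr(nets, 0.4, 0.1)
  plan <- state_plan(list(corr, corr), stay_prob = c(0.9, 0.9))
  manifest <- default_manifest(2, 2)
  design <- default_task_design()
  s1 <- simulate_twin_timeseries(manifest, design, plan, seed = 3, n_runs = 1)
  s2 <- simulate_twin_timeseries(manifest, design, plan, seed = 3, n_runs = 1)
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(s1$ground_truth$states, s2$ground_truth$states)
})

test_that("covariance repair returns a positive-definite unit-diagonal matrix", {
  m <- matrix(0.9, 3, 3); diag(m) <- 1
  m[1, 2] <- m[2, 1] <- -0.9  # breaks positive definiteness
  fixed <- nearest_pd_corr(m)
  expect_true(all(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_equal(diag(fixed), rep(1, 3))
})
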