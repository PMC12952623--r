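# Network averaging, state clustering, temporal metrics, state comparisons.

toy_conn <- function(vals, labels) {
  m <- diag(length(labels))
  m[upper.tri(m)] <- vals
  m <- m + t(m); diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

test_that("network averaging matches hand block means", {
  labels <- c("r1", "r2", "r3", "r4")
  map <- network_map(setNames(c("Default", "Default", "Visual", "Visual"),
                              labels))
  conn <- matrix(0.1, 4, 4, dimnames = list(labels, labels))
  conn["r1", "r2"] <- conn["r2", "r1"] <- 0.6
  conn["r3", "r4"] <- conn["r4", "r3"] <- 0.2
  diag(conn) <- 1
  nm <- network_average(conn, map)
  expect_equal(nm["Default", "Default"], 0.6)
  expect_equal(nm["Visual", "Visual"], 0.2)
  expect_equal(nm["Default", "Visual"], 0.1)

  allc <- toy_conn(rep(0.3, 6), labels)
  nm2 <- network_average(allc, map)
  expect_true(all(abs(nm2 - 0.3) < 1e-12))

  expect_error(network_average(conn, network_map(c("r1" = "Visual"))),
               "missing from network map")
})

test_that("pooled features have dimension 7(7+1)/2 and unit scale", {
  map <- default_network_map()
  nets <- setNames(unname(unclass(map)), names(map))
  corr <- network_block_corr(nets, 0.5, 0.2)
  stacks <- list()
  for (s in c("S1", "S2")) {
    ts <- random_timeseries(200, names(map), seed = match(s, c("S1", "S2")),
                            corr = corr)
    stacks[[s]] <- dynamic_fc(ts, single_block_design(duration = 144), "0bk",
                              window_params())
  }
  sf <- state_features(stacks, map)
  expect_equal(ncol(sf$features), 28)
  expect_lt(max(abs(colMeans(sf$features))), 1e-10)
  expect_lt(max(abs(apply(sf$features, 2, sd) - 1)), 1e-10)
})

test_that("k-means separates well-separated blobs and is seed-deterministic", {
  set.seed(99)
  blob1 <- matrix(rnorm(200, 0), 100, 2)
  blob2 <- matrix(rnorm(160, 8), 80, 2)
  x <- rbind(blob1, blob2)
  truth <- rep(1:2, c(100, 80))
  cl <- cluster_states(x, k = 2, seed = 5, n_init = 5)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1.0)
  cl2 <- cluster_states(x, k = 2, seed = 5, n_init = 5)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_states(x[1:2, ], k = 3), "exceeds")
})

test_that("occupancy and dwell match the hand run enumeration", {
  od <- occupancy_dwell(c(1, 1, 2, 2, 2, 1), n_states = 2)
  expect_equal(od$occupancy, c(0.5, 0.5))
  expect_equal(od$dwell, c(1.5, 3))  # runs of 1: (2, 1); runs of 2: (3)
  expect_equal(od$transitions, 2)

  od <- occupancy_dwell(rep(2, 6), n_states = 2)
  expect_equal(od$occupancy, c(0, 1))
  expect_true(is.na(od$dwell[1]))
  expect_equal(od$dwell[2], 6)

  od <- occupancy_dwell(rep(c(1, 2), 5), n_states = 2)
  expect_equal(od$dwell, c(1, 1))
  expect_error(occupancy_dwell(integer(0)), "empty")
})

test_that("within/between summaries match hand values", {
  nm <- matrix(0.1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  diag(nm) <- c(0.6, 0.2)
  wb <- within_between_connectivity(nm)
  expect_equal(wb$within_mean, 0.4)
  expect_equal(wb$between_mean, 0.1)

  allc <- matrix(0.3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  wb2 <- within_between_connectivity(allc)
  expect_equal(wb2$within_mean, wb2$between_mean)
})

test_that("state relabeling puts the transient state first", {
  # asymmetric chain: state with stay 0.95 dominates
  map <- default_network_map()
  nets <- setNames(unname(unclass(map)), names(map))
  cov_hi <- network_block_corr(nets, 0.6, 0.25)
  cov_lo <- network_block_corr(nets, 0.1, 0.0)
  plan <- state_plan(list(cov_hi, cov_lo), stay_prob = c(0.97, 0.85))
  manifest <- default_manifest(3, 2)
  design <- single_block_design(duration = 360)
  sim <- simulate_twin_timeseries(manifest, design, plan, seed = 6,
                                  n_runs = 1, n_frames = 500)
  stacks <- lapply(sim$timeseries, function(runs)
    dynamic_fc(runs, design, "0bk", window_params()))
  decomp <- state_decomposition(stacks, map, k = 2, seed = 2, n_init = 5)
  occ1 <- mean(decomp$metrics$occupancy_state1)
  occ2 <- mean(decomp$metrics$occupancy_state2)
  expect_lt(occ1, occ2)  # State 1 = transient by convention
  # occupancies sum to 1 per subject and recover integer counts
  expect_equal(decomp$metrics$occupancy_state1 + decomp$metrics$occupancy_state2,
               rep(1, nrow(decomp$metrics)))
  n_win <- table(decomp$index$subject)[decomp$metrics$subject]
  counts <- decomp$metrics$occupancy_state1 * as.numeric(n_win)
  expect_equal(counts, round(counts))
})

test_that("paired state comparison matches the hand t statistic", {
  labels <- c("A", "B")
  mk <- function(d1, d2) {
    m <- matrix(0.1, 2, 2, dimnames = list(labels, labels))
    diag(m) <- c(d1, d2)
    m
  }
  # 4 subjects, within_A differences (0.2, 0.1, 0.3, 0.2)
  d <- c(0.2, 0.1, 0.3, 0.2)
  decomp <- structure(list(
    k = 2, networks = labels,
    state_matrices = setNames(lapply(1:4, function(i)
      list(mk(0.5 + d[i], 0.4), mk(0.5, 0.4))), paste0("S", 1:4))
  ), class = "state_decomposition")
  out <- compare_states(decomp)
  row <- out[out$metric == "within_A", ]
  expect_equal(row$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)

  # identical states -> t = 0, p = 1 for every metric
  decomp$state_matrices <- setNames(lapply(1:4, function(i)
    list(mk(0.5, 0.4), mk(0.5, 0.4))), paste0("S", 1:4))
  out <- compare_states(decomp)
  expect_true(all(out$t == 0) && all(out$p == 1))

  # constant nonzero differences are degenerate, not infinite
  decomp$state_matrices <- setNames(lapply(1:3, function(i)
    list(mk(0.6, 0.4), mk(0.5, 0.4))), paste0("S", 1:3))
  out <- compare_states(decomp)
  expect_true(out$degenerate[out$metric == "within_A"])
  expect_true(is.na(out$p[out$metric == "within_A"]))
})

test_that("state-metric heritability flags generator-driven patterns", {
  n_mz <- 2000; n_dz <- 2000
  manifest <- default_manifest(n_mz, n_dz)
  herit <- simulate_ace_phenotypes(ace_spec(0.6, 0, 0.4),
                                   cohort_shape(n_mz, n_dz, seed = 44))
  null <- simulate_ace_phenotypes(ace_spec(0, 0, 1),
                                  cohort_shape(n_mz, n_dz, seed = 45))
  metrics <- data.frame(
    subject = c(manifest$pairs$subject1, manifest$pairs$subject2),
    occupancy_like = c(herit$twin1, herit$twin2),
    null_like = c(null$twin1, null$twin2)
  )
  out <- state_metric_heritability(metrics, manifest)
  occ <- out[out$metric == "occupancy_like", ]
  expect_true(occ$positive_genetic_pattern)
  expect_lt(abs(occ$h2_ae - 0.6), 0.1)
  nul <- out[out$metric == "null_like", ]
  expect_lte(nul$h2_ae, 0.05)

  out2 <- state_metric_heritability(metrics, manifest)
  expect_identical(out, out2)  # deterministic
})
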