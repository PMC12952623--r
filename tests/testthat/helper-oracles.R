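# Independent oracles and fixture builders. These deliberately avoid the
# package's likelihood and windowing code paths: the grid search works from
# its own algebra of the bivariate-normal density, and fixtures are built
# with plain base R.

# Exhaustive AE profile-likelihood grid search. For fixed path coefficients
# (a, e) the covariance is [[v, c_z], [c_z, v]] with v = a^2 + e^2,
# c_MZ = a^2, c_DZ = a^2 / 2; the shared mean is profiled out in closed
# form (GLS weighted mean, weight 2 / (v + c_z) per pair). Returns the grid
# maximum of the log-likelihood and the (a2, e2) at the maximum, on the
# cohort-standardized phenotype scale.
oracle_ae_grid <- function(pairs, step = 0.001, amax = 1.5) {
  pool <- c(pairs$twin1, pairs$twin2)
  x1 <- (pairs$twin1 - mean(pool)) / sd(pool)
  x2 <- (pairs$twin2 - mean(pool)) / sd(pool)
  mz <- pairs$zygosity == "MZ"
  n_mz <- sum(mz); n_dz <- sum(!mz)
  sum_mz <- sum(x1[mz] + x2[mz]); sum_dz <- sum(x1[!mz] + x2[!mz])
  sq_mz <- sum(x1[mz]^2 + x2[mz]^2); sq_dz <- sum(x1[!mz]^2 + x2[!mz]^2)
  cp_mz <- sum(x1[mz] * x2[mz]); cp_dz <- sum(x1[!mz] * x2[!mz])

  a_grid <- seq(0, amax, by = step)
  e_grid <- seq(step, amax, by = step)  # e = 0 is singular
  best <- list(logL = -Inf, a2 = NA, e2 = NA)
  for (a in a_grid) {
    a2 <- a^2
    v <- a2 + e_grid^2
    c_m <- a2
    c_d <- a2 / 2
    w_m <- 2 / (v + c_m); w_d <- 2 / (v + c_d)
    mu <- (w_m / 2 * sum_mz + w_d / 2 * sum_dz) / (n_mz * w_m + n_dz * w_d)
    det_m <- v^2 - c_m^2; det_d <- v^2 - c_d^2
    q_m <- sq_mz - 2 * mu * sum_mz + 2 * n_mz * mu^2
    p_m <- cp_mz - mu * sum_mz + n_mz * mu^2
    q_d <- sq_dz - 2 * mu * sum_dz + 2 * n_dz * mu^2
    p_d <- cp_dz - mu * sum_dz + n_dz * mu^2
    ll <- -(n_mz + n_dz) * log(2 * pi) -
      n_mz / 2 * log(det_m) - (v * q_m - 2 * c_m * p_m) / (2 * det_m) -
      n_dz / 2 * log(det_d) - (v * q_d - 2 * c_d * p_d) / (2 * det_d)
    ll[det_m <= 0 | det_d <= 0] <- -Inf
    i <- which.max(ll)
    if (ll[i] > best$logL) {
      best <- list(logL = ll[i], a2 = a2, e2 = e_grid[i]^2)
    }
  }
  best
}

# Random small cohort of twin-pair phenotypes (arbitrary ACE truth).
random_small_cohort <- function(n_mz = 8, n_dz = 8, seed = 1) {
  set.seed(seed)
  a2 <- runif(1, 0, 0.7)
  c2 <- runif(1, 0, 0.9 - a2)
  simulate_ace_phenotypes(ace_spec(a2, c2, 1 - a2 - c2),
                          cohort_shape(n_mz, n_dz, seed = seed + 1))
}

# A stationary multivariate-normal roi_timeseries fixture.
random_timeseries <- function(n_frames, labels, seed, tr = 0.72,
                              corr = NULL) {
  set.seed(seed)
  p <- length(labels)
  z <- matrix(rnorm(n_frames * p), n_frames, p)
  if (!is.null(corr)) z <- z %*% chol(corr)
  colnames(z) <- labels
  roi_timeseries(z, tr = tr, roi_labels = labels)
}

# Design with a single long task block (for windowing fixtures).
single_block_design <- function(condition = "0bk", onset = 0, duration = 360) {
  task_design(data.frame(onset = onset, duration = duration,
                         condition = condition))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
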