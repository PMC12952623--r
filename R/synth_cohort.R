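# Synthetic twin-cohort generator.
#
# Two levels of ground truth are supported: (a) phenotype-level ACE/ADE draws
# for exact parameter-recovery tests of the variance-component engine, and
# (b) time-series-level block-design "BOLD" with planted Markov covariance
# regimes and heritable condition-dependent edges for end-to-end tests.

#' Specify an ACE variance decomposition
#'
#' The classical twin decomposition V = A + C + E: additive genetic variance
#' (shared completely by monozygotic twins, 50% on average by dizygotic
#' twins), common-environment variance (shared by both members of a pair)
#' and unique-environment variance (independent across twins, includes
#' measurement error). Fractions are of a unit-variance phenotype.
#'
#' @param a2 additive-genetic variance fraction.
#' @param c2 shared-environment variance fraction.
#' @param e2 unique-environment variance fraction.
#' @return an object of class `ace_spec`.
#' @examples
#' ace_spec(0.5, 0.1, 0.4)
#' @export
ace_spec <- function(a2, c2, e2) {
  check_variance_fractions(a2, c2, e2, c("a2", "c2", "e2"))
  structure(list(a2 = a2, c2 = c2, e2 = e2), class = "ace_spec")
}

#' Specify an ADE variance decomposition
#'
#' Variant of [ace_spec()] replacing the shared environment with dominance
#' genetic variance (correlated 1 between MZ co-twins and 0.25 between DZ
#' co-twins). Used to exercise the ACE-vs-ADE family decision.
#'
#' @param a2 additive-genetic variance fraction.
#' @param d2 dominance-genetic variance fraction.
#' @param e2 unique-environment variance fraction.
#' @return an object of class `ade_spec`.
#' @export
ade_spec <- function(a2, d2, e2) {
  check_variance_fractions(a2, d2, e2, c("a2", "d2", "e2"))
  structure(list(a2 = a2, d2 = d2, e2 = e2), class = "ade_spec")
}

check_variance_fractions <- function(x, y, z, names) {
  vals <- c(x, y, z)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop2("variance fractions (%s) must be finite and non-negative",
          paste(names, collapse = ", "))
  }
  if (abs(sum(vals) - 1) > 1e-9) {
    stop2("variance fractions must sum to 1 (got %.12g)", sum(vals))
  }
  invisible(TRUE)
}

#' Describe the size of a twin cohort
#'
#' Defaults mirror the study cohort: 134 monozygotic and 78 dizygotic
#' same-sex pairs.
#'
#' @param n_mz number of MZ pairs.
#' @param n_dz number of DZ pairs.
#' @param seed integer seed for cohort-level draws.
#' @return an object of class `cohort_shape`.
#' @export
cohort_shape <- function(n_mz = 134, n_dz = 78, seed = 1) {
  if (n_mz < 0 || n_dz < 0 || n_mz + n_dz < 1) {
    stop2("cohort must contain at least one pair (n_mz, n_dz >= 0)")
  }
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 seed = as.integer(seed)),
            class = "cohort_shape")
}

#' Simulate paired twin phenotypes under an ACE or ADE model
#'
#' Per pair, additive factors are bivariate standard normal with correlation
#' 1 (MZ) or 0.5 (DZ); the shared environment C is one standard-normal draw
#' per pair; E is independent per twin. Under an `ade_spec` the dominance
#' factor replaces C with co-twin correlation 1 (MZ) / 0.25 (DZ). The
#' phenotype is `sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E`, so its marginal
#' variance is 1 in expectation and the expected intraclass correlations are
#' `rMZ = a2 + c2` and `rDZ = a2/2 + c2`.
#'
#' @param spec an [ace_spec()] or [ade_spec()].
#' @param cohort a [cohort_shape()].
#' @return data.frame with columns `pair_id`, `zygosity`, `twin1`, `twin2`.
#' @examples
#' ph <- simulate_ace_phenotypes(ace_spec(0.5, 0.1, 0.4), cohort_shape(50, 30, seed = 7))
#' head(ph)
#' @export
simulate_ace_phenotypes <- function(spec, cohort = cohort_shape()) {
  if (!inherits(spec, c("ace_spec", "ade_spec"))) {
    stop2("`spec` must be an ace_spec or ade_spec")
  }
  dominance <- inherits(spec, "ade_spec")
  shared2 <- if (dominance) spec$d2 else spec$c2
  set.seed(substream_seed(cohort$seed, 11))
  n_mz <- cohort$n_mz
  n_dz <- cohort$n_dz
  n <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))

  # Additive factors: correlation 1 within MZ, 0.5 within DZ.
  a_shared <- stats::rnorm(n)
  a1 <- a_shared
  a2f <- a_shared
  if (n_dz > 0) {
    i <- which(zyg == "DZ")
    u1 <- stats::rnorm(n_dz); u2 <- stats::rnorm(n_dz)
    a1[i] <- sqrt(0.5) * a_shared[i] + sqrt(0.5) * u1
    a2f[i] <- sqrt(0.5) * a_shared[i] + sqrt(0.5) * u2
  }

  # Shared factor: C (correlation 1 in both zygosities) or D (1 MZ, 0.25 DZ).
  s_shared <- stats::rnorm(n)
  s1 <- s_shared
  s2 <- s_shared
  if (dominance && n_dz > 0) {
    i <- which(zyg == "DZ")
    v1 <- stats::rnorm(n_dz); v2 <- stats::rnorm(n_dz)
    s1[i] <- 0.5 * s_shared[i] + sqrt(0.75) * v1
    s2[i] <- 0.5 * s_shared[i] + sqrt(0.75) * v2
  }

  e1 <- stats::rnorm(n)
  e2f <- stats::rnorm(n)

  sa <- sqrt(spec$a2); ss <- sqrt(shared2); se <- sqrt(spec$e2)
  data.frame(
    pair_id = sprintf("P%04d", seq_len(n)),
    zygosity = zyg,
    twin1 = sa * a1 + ss * s1 + se * e1,
    twin2 = sa * a2f + ss * s2 + se * e2f,
    stringsAsFactors = FALSE
  )
}

#' Plan the dynamic-state structure of a synthetic cohort
#'
#' @param state_cov list of per-state ROI correlation matrices (symmetric,
#'   positive definite, unit diagonal), all sharing dimnames.
#' @param stay_prob per-state probability of remaining in the same state at
#'   the next frame; each must lie in `[0, 1)`.
#' @return an object of class `state_plan`.
#' @export
state_plan <- function(state_cov, stay_prob) {
  k <- length(state_cov)
  if (k < 1) stop2("need at least one state")
  if (length(stay_prob) != k) stop2("`stay_prob` must have one entry per state")
  if (any(stay_prob < 0 | stay_prob >= 1)) stop2("stay probabilities must be in [0, 1)")
  labels <- NULL
  for (s in seq_len(k)) {
    m <- state_cov[[s]]
    assert_conn_matrix(m, sprintf("state %d covariance", s))
    if (!is_pd(m)) stop2("state %d covariance is not positive definite", s)
    if (is.null(labels)) labels <- colnames(m)
    if (!identical(colnames(m), labels)) stop2("state covariances must share ROI labels")
  }
  structure(list(n_states = k, stay_prob = stay_prob, state_cov = state_cov,
                 roi_labels = labels),
            class = "state_plan")
}

#' Build a network-block ROI correlation matrix
#'
#' Correlation is `within_r` (plus an optional per-network boost) between
#' ROIs of the same network and `between_r` otherwise; repaired to the
#' nearest positive-definite correlation matrix if needed.
#'
#' @param networks named character vector: ROI label -> network name.
#' @param within_r within-network correlation.
#' @param between_r between-network correlation.
#' @param boost optional named numeric vector of per-network additive boosts.
#' @return correlation matrix with ROI dimnames.
#' @export
network_block_corr <- function(networks, within_r, between_r, boost = NULL) {
  rois <- names(networks)
  n <- length(rois)
  mat <- matrix(between_r, n, n, dimnames = list(rois, rois))
  for (net in unique(networks)) {
    i <- which(networks == net)
    r <- within_r + (if (!is.null(boost) && net %in% names(boost)) boost[[net]] else 0)
    mat[i, i] <- r
  }
  diag(mat) <- 1
  if (!is_pd(mat)) mat <- nearest_pd_corr(mat)
  mat
}

#' Sample a frame-level Markov state sequence
#'
#' States follow a first-order Markov chain whose diagonal holds the
#' per-state stay probabilities and whose off-diagonal mass is split evenly
#' among the other states. The first frame is drawn from the stationary
#' distribution, so empirical occupancy matches the analytic stationary
#' occupancy and mean run length of state s is `1/(1 - stay_prob[s])`.
#'
#' @param plan a [state_plan()] (only `stay_prob` is used).
#' @param n_frames number of frames to sample.
#' @param seed integer seed.
#' @return integer vector of state labels in `1..n_states`.
#' @export
plant_markov_states <- function(plan, n_frames, seed) {
  if (n_frames < 1) stop2("`n_frames` must be >= 1")
  k <- plan$n_states
  set.seed(substream_seed(seed, 23))
  if (k == 1) return(rep(1L, n_frames))
  trans <- matrix(0, k, k)
  for (s in seq_len(k)) {
    trans[s, ] <- (1 - plan$stay_prob[s]) / (k - 1)
    trans[s, s] <- plan$stay_prob[s]
  }
  pi0 <- markov_stationary(trans)
  states <- integer(n_frames)
  states[1] <- sample.int(k, 1, prob = pi0)
  if (n_frames > 1) {
    u <- stats::runif(n_frames - 1)
    cum <- t(apply(trans, 1, cumsum))
    for (t in 2:n_frames) {
      states[t] <- findInterval(u[t - 1], cum[states[t - 1], ]) + 1L
    }
  }
  states
}

#' Stationary distribution of a Markov transition matrix
#' @param trans row-stochastic transition matrix.
#' @return stationary probability vector.
#' @export
markov_stationary <- function(trans) {
  es <- eigen(t(trans))
  i <- which.min(abs(es$values - 1))
  v <- Re(es$vectors[, i])
  v / sum(v)
}

#' Describe planted heritable condition effects on connectivity edges
#'
#' Each listed edge receives, during 2-back frames only, a per-subject
#' additive increment to its correlation. The increment is
#' `effect_mean + effect_sd * g` where `g` is a standard ACE phenotype drawn
#' per pair via [simulate_ace_phenotypes()], so MZ co-twins receive more
#' similar increments than DZ co-twins whenever `a2 > 0`.
#'
#' @param edges character vector of edge keys `"roi1|roi2"`.
#' @param spec [ace_spec()] governing the increments' twin structure.
#' @param effect_mean mean correlation increment during 2-back frames.
#' @param effect_sd between-subject SD of the increment.
#' @return an object of class `edge_effect_spec`.
#' @export
edge_effect_spec <- function(edges, spec, effect_mean = 0.2, effect_sd = 0.15) {
  if (!inherits(spec, "ace_spec")) stop2("`spec` must be an ace_spec")
  structure(list(edges = edges, spec = spec, effect_mean = effect_mean,
                 effect_sd = effect_sd),
            class = "edge_effect_spec")
}

#' Simulate ROI time series for a twin cohort
#'
#' Every frame of every run is drawn from the zero-mean multivariate normal
#' whose correlation matrix is the planted Markov state's matrix, with the
#' subject's heritable condition increments added on target edges during
#' 2-back frames. Covariances broken by an increment are repaired to the
#' nearest positive-definite correlation matrix; increments that would push
#' `|r|` beyond 0.99 are clipped with a warning.
#'
#' @param manifest a `twin_manifest` (see [read_twin_manifest()]).
#' @param design a `task_design` (see [read_task_design()]); one run's
#'   blocks, replicated across `n_runs`.
#' @param plan a [state_plan()].
#' @param effects an [edge_effect_spec()] or `NULL` for no condition effect.
#' @param seed integer seed.
#' @param tr repetition time in seconds (default 0.72).
#' @param n_runs runs per subject (default 2).
#' @param n_frames frames per run; default covers the design duration.
#' @return list with `timeseries` (nested list subject -> run ->
#'   `roi_timeseries`) and `ground_truth` (planted increments, per-run state
#'   sequences, the specs and seed used).
#' @export
simulate_twin_timeseries <- function(manifest, design, plan, effects = NULL,
                                     seed = 1, tr = 0.72, n_runs = 2,
                                     n_frames = NULL) {
  subjects <- c(rbind(manifest$pairs$subject1, manifest$pairs$subject2))
  labels <- plan$roi_labels
  n_roi <- length(labels)
  if (is.null(n_frames)) {
    end_t <- max(design$blocks$onset + design$blocks$duration)
    n_frames <- as.integer(floor(end_t / tr)) + 1L
  }

  # Per-subject heritable increments on target edges (paired draws).
  increments <- NULL
  if (!is.null(effects)) {
    if (!all(effects$edges %in% edge_keys(labels))) {
      bad <- setdiff(effects$edges, edge_keys(labels))
      stop2("effect edges not present among ROI labels: %s",
            paste(bad, collapse = ", "))
    }
    increments <- list()
    for (e_i in seq_along(effects$edges)) {
      ph <- simulate_ace_phenotypes(
        effects$spec,
        cohort_shape(sum(manifest$pairs$zygosity == "MZ"),
                     sum(manifest$pairs$zygosity == "DZ"),
                     seed = substream_seed(seed, 100 + e_i))
      )
      # phenotype rows follow manifest order: MZ pairs first then DZ
      ord <- order(match(manifest$pairs$zygosity, c("MZ", "DZ")))
      delta <- numeric(length(subjects))
      names(delta) <- subjects
      for (r in seq_len(nrow(manifest$pairs))) {
        row <- manifest$pairs[ord[r], ]
        delta[row$subject1] <- effects$effect_mean + effects$effect_sd * ph$twin1[r]
        delta[row$subject2] <- effects$effect_mean + effects$effect_sd * ph$twin2[r]
      }
      increments[[effects$edges[e_i]]] <- delta
    }
  }

  frame_cond <- condition_at_frames(design, n_frames, tr)
  is_2bk <- frame_cond == "2bk"

  ts_out <- vector("list", length(subjects))
  names(ts_out) <- subjects
  states_out <- vector("list", length(subjects))
  names(states_out) <- subjects
  n_clipped <- 0L

  for (s_i in seq_along(subjects)) {
    subj <- subjects[s_i]
    # Subject-specific state covariances, with and without 2-back increments.
    chol_base <- lapply(plan$state_cov, chol)
    chol_task <- chol_base
    if (!is.null(increments)) {
      for (st in seq_len(plan$n_states)) {
        m <- plan$state_cov[[st]]
        for (ek in names(increments)) {
          pair <- split_edge_key(ek)
          r_new <- m[pair$roi1, pair$roi2] + increments[[ek]][[subj]]
          if (abs(r_new) > 0.99) {
            r_new <- sign(r_new) * 0.99
            n_clipped <- n_clipped + 1L
          }
          m[pair$roi1, pair$roi2] <- r_new
          m[pair$roi2, pair$roi1] <- r_new
        }
        if (!is_pd(m)) m <- nearest_pd_corr(m)
        chol_task[[st]] <- chol(m)
      }
    }
    runs <- vector("list", n_runs)
    st_runs <- vector("list", n_runs)
    for (r_i in seq_len(n_runs)) {
      st_seed <- substream_seed(seed, 1000 + 7 * s_i + 100000 * r_i)
      states <- plant_markov_states(plan, n_frames, st_seed)
      set.seed(substream_seed(seed, 2000 + 7 * s_i + 100000 * r_i))
      z <- matrix(stats::rnorm(n_frames * n_roi), n_frames, n_roi)
      x <- matrix(0, n_frames, n_roi, dimnames = list(NULL, labels))
      for (st in seq_len(plan$n_states)) {
        for (task in c(FALSE, TRUE)) {
          rows <- which(states == st & is_2bk == task)
          if (!length(rows)) next
          ch <- if (task) chol_task[[st]] else chol_base[[st]]
          x[rows, ] <- z[rows, , drop = FALSE] %*% ch
        }
      }
      runs[[r_i]] <- roi_timeseries(x, tr = tr, subject = subj,
                                    run = sprintf("run%d", r_i),
                                    roi_labels = labels)
      st_runs[[r_i]] <- states
    }
    ts_out[[subj]] <- runs
    states_out[[subj]] <- st_runs
  }
  if (n_clipped > 0) {
    warning(sprintf("%d planted correlation increment(s) clipped at |r| = 0.99",
                    n_clipped), call. = FALSE)
  }
  list(
    timeseries = ts_out,
    ground_truth = list(
      seed = seed, tr = tr, n_frames = n_frames, n_runs = n_runs,
      stay_prob = plan$stay_prob,
      effects = effects,
      increments = increments,
      states = states_out,
      frame_condition = frame_cond,
      n_clipped = n_clipped
    )
  )
}

# Condition label of each frame (0-based frames, time = frame*tr),
# half-open block membership [onset, onset + duration).
condition_at_frames <- function(design, n_frames, tr) {
  cond <- rep("rest", n_frames)
  for (b in seq_len(nrow(design$blocks))) {
    row <- design$blocks[b, ]
    fr <- frames_in_interval(row$onset, row$onset + row$duration, tr, n_frames)
    cond[fr + 1L] <- row$condition
  }
  cond
}
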