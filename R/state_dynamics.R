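# Network-level dynamic-state analysis: window matrices are averaged into
# Yeo-7 network blocks, pooled features are z-scored and clustered with
# k-means (k-means++ seeding, best of n_init restarts), and each subject's
# window-label sequence yields occupancy, dwell and transition metrics.

#' Average an ROI connectivity matrix within/between networks
#'
#' Entry (m, n) is the mean of `conn[i, j]` over ROI pairs with `i` in
#' network m and `j` in network n (excluding the diagonal when m = n). A
#' network with fewer than two ROIs has an undefined (NA) diagonal entry.
#'
#' @param conn ROI x ROI connectivity matrix with dimnames.
#' @param map a `network_map` covering every ROI in `conn`.
#' @return 7 x 7 (or fewer) network matrix in canonical Yeo-7 order.
#' @export
network_average <- function(conn, map) {
  rois <- colnames(conn)
  unmapped <- setdiff(rois, names(map))
  if (length(unmapped)) {
    stop2("ROI(s) missing from network map: %s", paste(unmapped, collapse = ", "))
  }
  nets <- intersect(YEO7_NETWORKS, unique(unname(unclass(map[rois]))))
  k <- length(nets)
  out <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  members <- lapply(nets, function(n) which(unclass(map[rois]) == n))
  for (m in seq_len(k)) {
    for (n in m:k) {
      i <- members[[m]]; j <- members[[n]]
      if (m == n) {
        if (length(i) < 2) next
        vals <- conn[i, i][upper.tri(diag(length(i)))]
      } else {
        vals <- conn[i, j, drop = FALSE]
      }
      out[m, n] <- mean(vals)
      out[n, m] <- out[m, n]
    }
  }
  out
}

#' Pooled network-level window features
#'
#' Every window of every subject becomes one feature row: the network
#' matrix's diagonal (within-network means) followed by its upper triangle
#' (between-network means); with 7 networks that is 7 + 21 = 28 features.
#' Features are z-scored over the pooled (all subjects x all windows)
#' sample.
#'
#' @param stacks_by_subject named list subject -> `dfc_stack` (or list of
#'   stacks to be concatenated, e.g. one per condition).
#' @param map a `network_map`.
#' @return list: `features` (pooled windows x features, z-scored), `raw`
#'   (unscaled), `index` (data.frame subject, window), `networks`.
#' @export
state_features <- function(stacks_by_subject, map) {
  rows <- list(); raw <- list(); idx <- list()
  networks <- NULL
  for (subj in names(stacks_by_subject)) {
    entry <- stacks_by_subject[[subj]]
    stacks <- if (inherits(entry, "dfc_stack")) list(entry) else entry
    w_i <- 0L
    for (stack in stacks) {
      for (m in stack$matrices) {
        nm <- network_average(m, map)
        if (is.null(networks)) networks <- colnames(nm)
        if (anyNA(nm)) {
          stop2("network matrix has undefined entries (network with < 2 ROIs?)")
        }
        w_i <- w_i + 1L
        raw[[length(raw) + 1]] <- nm
        rows[[length(rows) + 1]] <- c(diag(nm), upper_tri_vector(nm))
        idx[[length(idx) + 1]] <- data.frame(subject = subj, window = w_i)
      }
    }
  }
  if (length(rows) < 2) stop2("need at least 2 pooled windows")
  feats <- do.call(rbind, rows)
  colnames(feats) <- c(paste0("within_", networks),
                       paste0("between_", edge_keys(networks)))
  mu <- colMeans(feats)
  sdv <- apply(feats, 2, stats::sd)
  if (any(sdv <= 0)) stop2("constant feature across all pooled windows")
  list(features = scale(feats, mu, sdv), raw = raw,
       index = do.call(rbind, idx), networks = networks)
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (c_i in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1, prob = probs)
      centers[c_i, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

#' Cluster pooled window features into recurring states
#'
#' k-means with k-means++ seeding; the best of `n_init` restarts (lowest
#' total within-cluster sum of squares) is kept. Deterministic given
#' `seed`. Raw cluster ids are arbitrary; see [state_decomposition()] for
#' the occupancy-based relabeling convention.
#'
#' @param features pooled feature matrix (rows = windows).
#' @param k number of states (default 2).
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @return list `labels`, `centroids`, `tot_withinss`.
#' @export
cluster_states <- function(features, k = 2, seed = 1, n_init = 10) {
  if (k > nrow(features)) {
    stop2("k = %d exceeds the %d available windows", k, nrow(features))
  }
  set.seed(substream_seed(seed, 31))
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(features, k)
    km <- suppressWarnings(
      stats::kmeans(features, centers = centers, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(labels = unname(best$cluster), centroids = best$centers,
       tot_withinss = best$tot.withinss)
}

#' Occupancy and dwell time of a state-label sequence
#'
#' Occupancy is the fraction of windows spent in each state; dwell is the
#' mean length (in windows) of maximal consecutive runs of the state. A
#' never-visited state has occupancy 0 and missing dwell.
#'
#' @param labels integer state labels of one subject's windows, in temporal
#'   order.
#' @param n_states total number of states.
#' @return list with vectors `occupancy`, `dwell`, and `transitions` (count
#'   of label changes).
#' @export
occupancy_dwell <- function(labels, n_states = max(labels)) {
  if (!length(labels)) stop2("empty label sequence")
  occ <- dwell <- numeric(n_states)
  runs <- rle(labels)
  for (s in seq_len(n_states)) {
    occ[s] <- mean(labels == s)
    lens <- runs$lengths[runs$values == s]
    dwell[s] <- if (length(lens)) mean(lens) else NA_real_
  }
  list(occupancy = occ, dwell = dwell,
       transitions = length(runs$lengths) - 1L)
}

#' Full state decomposition of a cohort's window stacks
#'
#' Clusters pooled features, relabels states by ascending group-mean
#' occupancy (State 1 = the transient state, State 2 = the dominant one),
#' and computes per-subject occupancy, dwell, transition counts and
#' per-state mean network matrices (from the unscaled network averages).
#'
#' @param stacks_by_subject named list subject -> `dfc_stack`(s).
#' @param map a `network_map`.
#' @param k number of states.
#' @param seed integer seed.
#' @param n_init k-means restarts.
#' @return object of class `state_decomposition`: `labels` (per pooled
#'   window), `index`, `centroids`, `metrics` (data.frame per subject:
#'   occupancy/dwell per state, transitions), `state_matrices` (subject ->
#'   state -> network matrix, NULL when unvisited), `networks`.
#' @export
state_decomposition <- function(stacks_by_subject, map, k = 2, seed = 1,
                                n_init = 10) {
  sf <- state_features(stacks_by_subject, map)
  cl <- cluster_states(sf$features, k = k, seed = seed, n_init = n_init)
  subjects <- unique(sf$index$subject)

  # group-mean occupancy per raw cluster id -> relabel ascending
  occ_by_subj <- vapply(subjects, function(s) {
    lab <- cl$labels[sf$index$subject == s]
    vapply(seq_len(k), function(st) mean(lab == st), numeric(1))
  }, numeric(k))
  group_occ <- rowMeans(matrix(occ_by_subj, nrow = k))
  remap <- match(seq_len(k), order(group_occ))
  labels <- remap[cl$labels]
  centroids <- cl$centroids[order(group_occ), , drop = FALSE]
  rownames(centroids) <- paste0("State", seq_len(k))

  metrics <- list()
  state_matrices <- list()
  for (s in subjects) {
    sel <- sf$index$subject == s
    lab <- labels[sel]
    od <- occupancy_dwell(lab, n_states = k)
    metrics[[s]] <- data.frame(
      subject = s,
      t(stats::setNames(od$occupancy, paste0("occupancy_state", seq_len(k)))),
      t(stats::setNames(od$dwell, paste0("dwell_state", seq_len(k)))),
      transitions = od$transitions,
      stringsAsFactors = FALSE
    )
    mats <- vector("list", k)
    raw_s <- sf$raw[sel]
    for (st in seq_len(k)) {
      in_state <- which(lab == st)
      if (length(in_state)) {
        mats[[st]] <- Reduce(`+`, raw_s[in_state]) / length(in_state)
      }
    }
    state_matrices[[s]] <- mats
  }
  structure(list(labels = labels, index = sf$index, centroids = centroids,
                 metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
                 state_matrices = state_matrices, networks = sf$networks,
                 k = k),
            class = "state_decomposition")
}

#' Within- and between-network connectivity of a network matrix
#'
#' @param net_mat a network x network matrix.
#' @return list: `within` (named diagonal), `within_mean`, `between_mean`.
#' @export
within_between_connectivity <- function(net_mat) {
  w <- diag(net_mat)
  names(w) <- colnames(net_mat)
  list(within = w, within_mean = mean(w),
       between_mean = mean(upper_tri_vector(net_mat)))
}

#' Paired comparison of two states' connectivity across subjects
#'
#' For each network's within-network connectivity (and for the
#' between-network mean), a paired t-test of State 1 vs State 2 over
#' subjects observed in both states. Zero-variance nonzero differences are
#' reported as degenerate (NA statistic); identically zero differences give
#' t = 0, p = 1.
#'
#' @param decomp a [state_decomposition()] with k = 2.
#' @return data.frame per metric: `metric`, `n`, `mean_state1`,
#'   `mean_state2`, `sem_state1`, `sem_state2`, `t`, `p`, `degenerate`.
#' @export
compare_states <- function(decomp) {
  if (decomp$k != 2) stop2("state comparison expects k = 2")
  subjects <- names(decomp$state_matrices)
  complete <- Filter(function(s) {
    m <- decomp$state_matrices[[s]]
    !is.null(m[[1]]) && !is.null(m[[2]])
  }, subjects)
  if (length(complete) < 2) stop2("fewer than 2 subjects visit both states")
  metrics <- c(paste0("within_", decomp$networks), "between_mean")
  value_of <- function(mat, metric) {
    if (metric == "between_mean") mean(upper_tri_vector(mat))
    else diag(mat)[sub("^within_", "", metric)]
  }
  rows <- lapply(metrics, function(met) {
    v1 <- vapply(complete, function(s)
      value_of(decomp$state_matrices[[s]][[1]], met), numeric(1))
    v2 <- vapply(complete, function(s)
      value_of(decomp$state_matrices[[s]][[2]], met), numeric(1))
    d <- v1 - v2
    n <- length(d)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        tstat <- 0; pval <- 1; degen <- FALSE
      } else {
        tstat <- NA_real_; pval <- NA_real_; degen <- TRUE
      }
    } else {
      tt <- stats::t.test(v1, v2, paired = TRUE)
      tstat <- unname(tt$statistic); pval <- tt$p.value; degen <- FALSE
    }
    data.frame(metric = met, n = n,
               mean_state1 = mean(v1), mean_state2 = mean(v2),
               sem_state1 = sem(v1), sem_state2 = sem(v2),
               t = tstat, p = pval, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Heritability of per-subject state metrics
#'
#' For each temporal metric (occupancy, dwell, transition count), computes
#' intraclass correlations by zygosity, the AE heritability, and the
#' positive-genetic-pattern flag `r_mz > r_dz`.
#'
#' @param metrics the `metrics` data.frame of a [state_decomposition()]
#'   (or any per-subject metric table with a `subject` column).
#' @param manifest a [twin_manifest()].
#' @return data.frame per metric: `metric`, `r_mz`, `r_dz`, `h2_ae`
#'   (fraction), `positive_genetic_pattern`.
#' @export
state_metric_heritability <- function(metrics, manifest) {
  i1 <- match(manifest$pairs$subject1, metrics$subject)
  i2 <- match(manifest$pairs$subject2, metrics$subject)
  if (anyNA(i1) || anyNA(i2)) stop2("manifest subjects missing from metrics")
  zyg <- manifest$pairs$zygosity
  cols <- setdiff(names(metrics), "subject")
  rows <- list()
  for (col in cols) {
    x1 <- metrics[[col]][i1]; x2 <- metrics[[col]][i2]
    ok <- is.finite(x1) & is.finite(x2)
    if (sum(ok & zyg == "MZ") < 4 || sum(ok & zyg == "DZ") < 4) {
      stop2("metric `%s`: fewer than 4 complete pairs per zygosity", col)
    }
    r_mz <- intraclass_correlation(x1[ok & zyg == "MZ"], x2[ok & zyg == "MZ"])
    r_dz <- intraclass_correlation(x1[ok & zyg == "DZ"], x2[ok & zyg == "DZ"])
    pairs <- data.frame(zygosity = zyg[ok], twin1 = x1[ok], twin2 = x2[ok])
    h2 <- if (stats::sd(c(pairs$twin1, pairs$twin2)) > 0) {
      fit <- fit_variance_components(pairs, "AE")
      fit$a2 / fit$v
    } else NA_real_
    rows[[col]] <- data.frame(metric = col, r_mz = r_mz, r_dz = r_dz,
                              h2_ae = h2,
                              positive_genetic_pattern = r_mz > r_dz,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
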