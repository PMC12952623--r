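# Edge-level connectivity phenotypes: static FC, sliding-window dynamic FC
# (summarised per edge by mean and variance across windows), and the
# 2-back minus 0-back differential phenotype.
#
# Frame indices in the public interface are 0-based; the time of frame k is
# k * tr seconds. Block membership is half-open: [onset, onset + duration).

#' Sliding-window parameters
#'
#' The window length is given in seconds and converted to a whole number of
#' frames as `round(window_seconds / tr)`; the step is in frames. Defaults
#' follow the task dFC convention of an 18-s window (25 frames at
#' TR = 0.72 s) sliding by 3 frames.
#'
#' @param window_seconds window length in seconds (default 18).
#' @param step_frames step between window starts, in frames (default 3).
#' @param tr repetition time in seconds (default 0.72).
#' @return object of class `window_params` with `window_frames` resolved.
#' @export
window_params <- function(window_seconds = 18, step_frames = 3, tr = 0.72) {
  w <- as.integer(round(window_seconds / tr))
  if (w < 2) stop2("window of %.3g s is under 2 frames at TR %.3g s",
                   window_seconds, tr)
  if (step_frames < 1) stop2("`step_frames` must be >= 1")
  structure(list(window_seconds = window_seconds, step_frames = as.integer(step_frames),
                 tr = tr, window_frames = w),
            class = "window_params")
}

#' Z-score ROI time series columns
#'
#' Each ROI column is scaled to mean 0 and sample (n-1) standard deviation 1
#' over the selected frames. A zero-variance ROI is an error naming the ROI;
#' nothing is dropped silently.
#'
#' @param ts a [roi_timeseries()] or a frames x ROI matrix.
#' @param frames optional 0-based frame indices to standardize over;
#'   default all frames.
#' @return standardized matrix over the selected frames.
#' @export
standardize_timeseries <- function(ts, frames = NULL) {
  mat <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  if (!is.null(frames)) mat <- mat[frames + 1L, , drop = FALSE]
  if (nrow(mat) < 2) stop2("need at least 2 frames to standardize")
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, stats::sd)
  zero <- which(sdv <= 0 | !is.finite(sdv))
  if (length(zero)) {
    stop2("zero-variance ROI over selected frames: %s",
          paste(colnames(mat)[zero], collapse = ", "))
  }
  scale(mat, center = mu, scale = sdv)[, , drop = FALSE]
}

#' Frames belonging to a task condition, grouped by block
#'
#' A frame belongs to a block when its time `frame * tr` falls in
#' `[onset + lag, onset + duration + lag)`. The optional lag shifts block
#' boundaries to account for hemodynamic delay (default 0: the windows
#' follow the stimulus timing exactly).
#'
#' @param ts a [roi_timeseries()] (supplies `tr` and the frame count).
#' @param design a [task_design()].
#' @param condition condition to select (e.g. `"0bk"`, `"2bk"`).
#' @param lag shift in seconds applied to block boundaries.
#' @return list of 0-based integer frame vectors, one per block, ordered by
#'   onset.
#' @export
select_condition_frames <- function(ts, design, condition, lag = 0) {
  blocks <- design$blocks[design$blocks$condition == condition, , drop = FALSE]
  if (!nrow(blocks)) stop2("no blocks of condition `%s` in design", condition)
  n <- nrow(ts$data)
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    lo <- blocks$onset[b] + lag
    hi <- blocks$onset[b] + blocks$duration[b] + lag
    out[[b]] <- frames_in_interval(lo, hi, ts$tr, n)
  }
  out
}

# 0-based frames whose time k*tr falls in [lo, hi), robust to floating-point
# representation of block boundaries that sit exactly on a frame time.
frames_in_interval <- function(lo, hi, tr, n_frames) {
  eps <- 1e-9
  first <- max(0L, as.integer(ceiling(lo / tr - eps)))
  last <- min(n_frames - 1L, as.integer(ceiling(hi / tr - eps)) - 1L)
  if (last < first) integer(0) else seq.int(first, last)
}

#' Static functional connectivity over a set of frames
#'
#' Pearson correlation between every pair of ROI series over the selected
#' frames; or shrinkage-regularized partial correlation (covariance shrunk
#' toward the identity, Ledoit-Wolf-style intensity, then the standardized
#' negated off-diagonal of the precision matrix).
#'
#' @param ts a [roi_timeseries()] or frames x ROI matrix.
#' @param frames optional 0-based frame indices (pooled across blocks/runs);
#'   default all frames.
#' @param method `"pearson"` (default) or `"partial"`.
#' @return ROI x ROI correlation matrix (symmetric, unit diagonal).
#' @export
static_fc <- function(ts, frames = NULL, method = c("pearson", "partial")) {
  method <- match.arg(method)
  z <- standardize_timeseries(ts, frames)
  if (nrow(z) < 3) stop2("need at least 3 frames for a correlation")
  mat <- if (method == "pearson") stats::cor(z) else partial_corr_shrunk(z)
  mat[mat > 1] <- 1; mat[mat < -1] <- -1
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 1
  assert_conn_matrix(mat)
  mat
}

# Schafer-Strimmer estimate of the shrinkage intensity toward the identity
# target on the correlation scale, then partial correlations from the
# shrunk precision.
partial_corr_shrunk <- function(z) {
  n <- nrow(z); p <- ncol(z)
  r <- stats::cor(z)
  w <- array(0, dim = c(p, p))
  # var of each off-diagonal correlation estimate
  zc <- scale(z)  # unit variance columns
  var_r <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      wk <- zc[, i] * zc[, j]
      var_r[i, j] <- n / ((n - 1)^3) * sum((wk - mean(wk))^2)
    }
  }
  off <- upper.tri(r)
  lambda <- sum(var_r[off]) / sum(r[off]^2)
  lambda <- min(1, max(0, lambda))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  prec <- solve(rs)
  d <- sqrt(diag(prec))
  pc <- -prec / tcrossprod(d)
  diag(pc) <- 1
  pc
}

#' Sliding-window start/end indices
#'
#' Windows are half-open 0-based `[start, start + window_frames)` and never
#' extend past `n_frames`; there are `floor((n - w)/step) + 1` of them when
#' `n >= w`, otherwise none (a legal, reported outcome).
#'
#' @param n_frames number of frames available.
#' @param params a [window_params()].
#' @return data.frame with columns `start`, `end` (0-based, half-open).
#' @export
window_indices <- function(n_frames, params) {
  w <- params$window_frames
  s <- params$step_frames
  if (n_frames < w) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- seq.int(0L, n_frames - w, by = s)
  data.frame(start = starts, end = starts + w)
}

#' Windowed dynamic functional connectivity for one condition
#'
#' Windows are computed within each block of the condition (never crossing
#' block boundaries) and pooled across blocks and runs. Each window's time
#' series is re-standardized within the window before correlating, so every
#' window matrix equals [static_fc()] restricted to that window's frames.
#' Windows containing a zero-variance ROI segment are dropped and counted
#' in the `dropped` attribute.
#'
#' @param runs a single [roi_timeseries()] or a list of them (runs).
#' @param design a [task_design()].
#' @param condition condition tag.
#' @param params a [window_params()].
#' @param lag block-boundary shift in seconds (see
#'   [select_condition_frames()]).
#' @param method correlation method passed to [static_fc()].
#' @return object of class `dfc_stack`: list with `matrices` (list of
#'   ROI x ROI matrices), `windows` (data.frame run, block_onset,
#'   start_frame, end_frame), `roi_labels`; attribute `dropped` counts
#'   degenerate windows.
#' @export
dynamic_fc <- function(runs, design, condition, params, lag = 0,
                       method = "pearson") {
  if (inherits(runs, "roi_timeseries")) runs <- list(runs)
  mats <- list()
  desc <- list()
  dropped <- 0L
  for (r_i in seq_along(runs)) {
    ts <- runs[[r_i]]
    blocks <- select_condition_frames(ts, design, condition, lag)
    onsets <- design$blocks$onset[design$blocks$condition == condition]
    for (b_i in seq_along(blocks)) {
      fr <- blocks[[b_i]]
      wins <- window_indices(length(fr), params)
      for (w_i in seq_len(nrow(wins))) {
        idx <- fr[(wins$start[w_i] + 1L):wins$end[w_i]]
        slice <- ts$data[idx + 1L, , drop = FALSE]
        sdv <- apply(slice, 2, stats::sd)
        if (any(sdv <= 0 | !is.finite(sdv))) {
          dropped <- dropped + 1L
          next
        }
        mats[[length(mats) + 1]] <- static_fc(slice, method = method)
        desc[[length(desc) + 1]] <- data.frame(
          run = ts$run, block_onset = onsets[b_i],
          start_frame = idx[1], end_frame = idx[length(idx)] + 1L)
      }
    }
  }
  if (!length(mats)) {
    stop2("no usable windows for condition `%s` (%d dropped as degenerate)",
          condition, dropped)
  }
  structure(list(matrices = mats, windows = do.call(rbind, desc),
                 roi_labels = runs[[1]]$roi_labels),
            class = "dfc_stack", dropped = dropped)
}

#' Per-edge mean and variance of a windowed connectivity stack
#'
#' @param stack a `dfc_stack` from [dynamic_fc()].
#' @return list with named vectors `mean` and `var` (unbiased, n-1) over
#'   edges `"roi1|roi2"`, plus `n_windows`.
#' @export
dfc_summary <- function(stack) {
  n_win <- length(stack$matrices)
  if (n_win < 1) stop2("empty window stack")
  keys <- edge_keys(stack$roi_labels)
  vals <- vapply(stack$matrices, upper_tri_vector,
                 numeric(length(keys)))
  vals <- matrix(vals, nrow = length(keys))
  m <- rowMeans(vals)
  v <- if (n_win >= 2) apply(vals, 1, stats::var) else rep(NA_real_, length(keys))
  if (n_win < 2) warning("fewer than 2 windows: variance undefined", call. = FALSE)
  list(mean = stats::setNames(m, keys), var = stats::setNames(v, keys),
       n_windows = n_win)
}

#' Assemble an edge-phenotype table
#'
#' @param values subjects x edges numeric matrix; rownames are subject ids,
#'   colnames edge keys `"roi1|roi2"`.
#' @param measure one of `staticFC`, `dfcMean`, `dfcVar`.
#' @param condition one of `0bk`, `2bk`, `diff`.
#' @return object of class `edge_phenotypes`.
#' @export
edge_phenotypes <- function(values, measure = c("staticFC", "dfcMean", "dfcVar"),
                            condition = c("0bk", "2bk", "diff")) {
  measure <- match.arg(measure)
  condition <- match.arg(condition)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("phenotype matrix needs subject rownames and edge colnames")
  }
  structure(list(values = values, measure = measure, condition = condition),
            class = "edge_phenotypes")
}

#' Differential (2-back minus 0-back) edge phenotype
#'
#' Subtracting the 0-back value removes perceptual/motor components shared
#' by both task loads, isolating the working-memory-specific signal.
#'
#' @param table_2bk,table_0bk [edge_phenotypes()] for the same measure,
#'   subjects and edges.
#' @return an [edge_phenotypes()] with condition `"diff"`.
#' @export
differential_phenotype <- function(table_2bk, table_0bk) {
  if (table_2bk$measure != table_0bk$measure) {
    stop2("measure mismatch: %s vs %s", table_2bk$measure, table_0bk$measure)
  }
  if (!identical(rownames(table_2bk$values), rownames(table_0bk$values))) {
    stop2("subject sets differ between the 2-back and 0-back tables")
  }
  if (!identical(colnames(table_2bk$values), colnames(table_0bk$values))) {
    stop2("edge sets differ between the 2-back and 0-back tables")
  }
  edge_phenotypes(table_2bk$values - table_0bk$values,
                  measure = table_2bk$measure, condition = "diff")
}

#' Compute all three edge phenotypes for one subject
#'
#' For each condition (0bk, 2bk): static FC over the pooled condition
#' frames of all runs, and window-stack mean/variance per edge.
#'
#' @param runs list of [roi_timeseries()] for the subject's runs.
#' @param design a [task_design()].
#' @param params a [window_params()].
#' @param method correlation method.
#' @param lag hemodynamic lag in seconds.
#' @param fisher_z apply `atanh` to staticFC and dfcMean values (not dfcVar).
#' @param keep_stacks also return the per-condition `dfc_stack`s (needed for
#'   state analysis).
#' @return nested list `[[condition]][[measure]]` of named edge vectors.
#' @export
subject_edge_phenotypes <- function(runs, design, params, method = "pearson",
                                    lag = 0, fisher_z = FALSE,
                                    keep_stacks = FALSE) {
  if (inherits(runs, "roi_timeseries")) runs <- list(runs)
  out <- list()
  for (cond in c("0bk", "2bk")) {
    pooled <- list()
    for (ts in runs) {
      fr <- unlist(select_condition_frames(ts, design, cond, lag))
      pooled[[length(pooled) + 1]] <- ts$data[fr + 1L, , drop = FALSE]
    }
    pooled <- do.call(rbind, pooled)
    sfc <- static_fc(pooled, method = method)
    keys <- edge_keys(runs[[1]]$roi_labels)
    static_vec <- stats::setNames(upper_tri_vector(sfc), keys)
    stack <- dynamic_fc(runs, design, cond, params, lag, method)
    ds <- dfc_summary(stack)
    mean_vec <- ds$mean
    if (fisher_z) {
      static_vec <- atanh(pmin(pmax(static_vec, -0.999999), 0.999999))
      mean_vec <- atanh(pmin(pmax(mean_vec, -0.999999), 0.999999))
    }
    out[[cond]] <- list(staticFC = static_vec, dfcMean = mean_vec,
                        dfcVar = ds$var)
    if (keep_stacks) out[[cond]]$stack <- stack
  }
  out
}

#' Build cohort-level differential phenotype tables
#'
#' @param ts_by_subject nested list subject -> list of run
#'   [roi_timeseries()].
#' @param design,params,method,lag,fisher_z see
#'   [subject_edge_phenotypes()].
#' @param keep_stacks keep per-subject window stacks (for state analysis).
#' @return list with `tables` (named list staticFC/dfcMean/dfcVar of
#'   [edge_phenotypes()] with condition `"diff"`) and, if requested,
#'   `stacks` (subject -> condition -> `dfc_stack`).
#' @export
cohort_edge_phenotypes <- function(ts_by_subject, design, params,
                                   method = "pearson", lag = 0,
                                   fisher_z = FALSE, keep_stacks = FALSE) {
  subjects <- names(ts_by_subject)
  per_subj <- lapply(ts_by_subject, subject_edge_phenotypes, design = design,
                     params = params, method = method, lag = lag,
                     fisher_z = fisher_z, keep_stacks = keep_stacks)
  tables <- list()
  for (meas in c("staticFC", "dfcMean", "dfcVar")) {
    tabs <- list()
    for (cond in c("0bk", "2bk")) {
      vals <- t(vapply(per_subj, function(s) s[[cond]][[meas]],
                       per_subj[[1]][[cond]][[meas]]))
      rownames(vals) <- subjects
      tabs[[cond]] <- edge_phenotypes(vals, measure = meas, condition = cond)
    }
    tables[[meas]] <- differential_phenotype(tabs[["2bk"]], tabs[["0bk"]])
  }
  out <- list(tables = tables)
  if (keep_stacks) {
    out$stacks <- lapply(per_subj, function(s)
      list(`0bk` = s[["0bk"]]$stack, `2bk` = s[["2bk"]]$stack))
  }
  out
}
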