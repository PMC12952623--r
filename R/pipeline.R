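# End-to-end orchestration: simulate -> connectivity -> heritability ->
# states, from a single config, with cached stage outputs and a report
# bundle of plain-text tables. Rerunning with the same config and seed is
# byte-identical.

#' Default block-design task layout
#'
#' One run: alternating 0-back/2-back task blocks (2.5 s cue, then 25 s of
#' trials), with 15-s fixation blocks after every second task block —
#' eight task blocks per run, four per condition.
#'
#' @return a [task_design()] for one run.
#' @export
default_task_design <- function() {
  rows <- list()
  t <- 0
  conds <- rep(c("0bk", "2bk"), 4)
  for (b in seq_along(conds)) {
    rows[[length(rows) + 1]] <- data.frame(onset = t, duration = 2.5,
                                           condition = "cue")
    t <- t + 2.5
    rows[[length(rows) + 1]] <- data.frame(onset = t, duration = 25,
                                           condition = conds[b])
    t <- t + 25
    if (b %% 2 == 0) {
      rows[[length(rows) + 1]] <- data.frame(onset = t, duration = 15,
                                             condition = "fixation")
      t <- t + 15
    }
  }
  task_design(do.call(rbind, rows))
}

#' Default synthetic ROI set and Yeo-7 network map
#'
#' Fourteen working-memory-related cortical area labels, two per Yeo-7
#' network, hemisphere-prefixed. The network assignment is a synthetic
#' convenience for the generator, not an atlas lookup.
#'
#' @return a `network_map`.
#' @export
default_network_map <- function() {
  network_map(c(
    "L-POS1" = "Visual", "R-POS1" = "Visual",
    "L-Ig" = "Somatomotor", "R-Ig" = "Somatomotor",
    "L-LIPd" = "DorsalAttention", "R-LIPd" = "DorsalAttention",
    "L-AVI" = "VentralAttention", "R-AVI" = "VentralAttention",
    "L-TE2a" = "Limbic", "R-TE2a" = "Limbic",
    "L-p9-46v" = "Frontoparietal", "R-p9-46v" = "Frontoparietal",
    "L-PGi" = "Default", "R-PGi" = "Default"
  ))
}

#' Default anatomical region groups for the synthetic ROI set
#' @return a `region_group_map`.
#' @export
default_region_groups <- function() {
  region_group_map(c(
    "L-p9-46v" = "DLPFC/LPFC/FEF", "R-p9-46v" = "DLPFC/LPFC/FEF",
    "L-LIPd" = "IPS/SPL", "R-LIPd" = "IPS/SPL",
    "L-POS1" = "Precuneus/MedialParietal", "R-POS1" = "Precuneus/MedialParietal",
    "L-PGi" = "PCC", "R-PGi" = "PCC",
    "L-TE2a" = "Temporal", "R-TE2a" = "Temporal",
    "L-AVI" = "Insula", "R-AVI" = "Insula",
    "L-Ig" = "Insula", "R-Ig" = "Insula"
  ))
}

#' Default pipeline configuration
#'
#' A desk-scale synthetic cohort: 20 MZ + 12 DZ pairs, 14 ROIs (two per
#' Yeo-7 network), TR 0.72 s, two runs of the default block design, an
#' 18-s/3-frame sliding window, two planted Markov covariance regimes
#' (stay probability 0.9 each) and one strongly heritable 2-back edge.
#'
#' @param seed master seed.
#' @return named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    n_mz = 20, n_dz = 12,
    tr = 0.72, n_runs = 2,
    window_seconds = 18, step_frames = 3,
    method = "pearson", lag = 0, fisher_z = FALSE,
    family = "auto", correction = "bonferroni", alpha = 0.05,
    k = 2, n_init = 10,
    stay_prob = c(0.9, 0.9),
    state_within_r = c(0.55, 0.15),
    state_between_r = c(0.25, 0.05),
    effect_edges = "L-p9-46v|L-PGi",
    effect_a2 = 0.6, effect_c2 = 0, effect_mean = 0.25, effect_sd = 0.12
  )
}

config_state_plan <- function(config, map) {
  nets <- stats::setNames(unname(unclass(map)), names(map))
  covs <- lapply(seq_along(config$stay_prob), function(s) {
    network_block_corr(nets, config$state_within_r[s], config$state_between_r[s])
  })
  state_plan(covs, config$stay_prob)
}

config_effects <- function(config) {
  if (is.null(config$effect_edges) || !length(config$effect_edges)) return(NULL)
  edge_effect_spec(config$effect_edges,
                   ace_spec(config$effect_a2, config$effect_c2,
                            1 - config$effect_a2 - config$effect_c2),
                   effect_mean = config$effect_mean,
                   effect_sd = config$effect_sd)
}

#' Simulate stage: write a synthetic cohort to disk
#'
#' Writes per-subject/run ROI time-series TSVs, event files, the twin
#' manifest, network and region-group maps, and a ground-truth JSON.
#'
#' @param config pipeline config (see [default_pipeline_config()]).
#' @param dir output directory.
#' @return invisibly, the simulation object from
#'   [simulate_twin_timeseries()].
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- default_network_map()
  manifest <- default_manifest(config$n_mz, config$n_dz)
  design <- default_task_design()
  plan <- config_state_plan(config, map)
  sim <- simulate_twin_timeseries(manifest, design, plan,
                                  effects = config_effects(config),
                                  seed = config$seed, tr = config$tr,
                                  n_runs = config$n_runs)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  for (subj in names(sim$timeseries)) {
    for (ts in sim$timeseries[[subj]]) {
      write_roi_timeseries(ts, file.path(ts_dir,
                                         sprintf("%s_%s.tsv", subj, ts$run)))
    }
  }
  write_task_design(design, dir)
  write_twin_manifest(manifest, file.path(dir, "manifest.csv"))
  write_network_map(map, file.path(dir, "network_map.tsv"))
  write_region_groups(default_region_groups(), file.path(dir, "region_groups.tsv"))
  gt <- sim$ground_truth
  gt$states <- lapply(gt$states, function(runs) lapply(runs, as.integer))
  gt$effects <- if (!is.null(gt$effects)) unclass(gt$effects) else NULL
  if (!is.null(gt$effects)) gt$effects$spec <- unclass(gt$effects$spec)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

load_cohort <- function(dir) {
  ts_dir <- file.path(dir, "timeseries")
  files <- sort(list.files(ts_dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop2("no time-series files under %s", ts_dir)
  all_ts <- lapply(files, read_roi_timeseries)
  by_subject <- split(all_ts, vapply(all_ts, `[[`, character(1), "subject"))
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop2("missing manifest: %s", manifest_path)
  conds <- c("0bk", "2bk", "fixation", "cue")
  ev <- stats::setNames(file.path(dir, paste0(conds, ".txt")), conds)
  ev <- ev[file.exists(ev)]
  list(
    timeseries = by_subject,
    manifest = read_twin_manifest(manifest_path),
    design = read_task_design(ev),
    network_map = read_network_map(file.path(dir, "network_map.tsv")),
    region_groups = read_region_groups(file.path(dir, "region_groups.tsv"))
  )
}

#' Connectivity stage: differential phenotype tables from a cohort on disk
#'
#' @param config pipeline config.
#' @param dir cohort directory (as written by [stage_simulate()] or in the
#'   same layout).
#' @return list with `tables`, `stacks`, and the loaded cohort.
#' @export
stage_connectivity <- function(config, dir) {
  cohort <- load_cohort(dir)
  params <- window_params(config$window_seconds, config$step_frames, config$tr)
  res <- cohort_edge_phenotypes(cohort$timeseries, cohort$design, params,
                                method = config$method, lag = config$lag,
                                fisher_z = isTRUE(config$fisher_z),
                                keep_stacks = TRUE)
  pheno_dir <- file.path(dir, "phenotypes")
  dir.create(pheno_dir, showWarnings = FALSE)
  for (meas in names(res$tables)) {
    tab <- res$tables[[meas]]$values
    df <- data.frame(subject = rownames(tab), tab, check.names = FALSE)
    for (col in colnames(tab)) df[[col]] <- fmt_num(df[[col]])
    utils::write.table(df, file.path(pheno_dir, paste0(meas, "_diff.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  c(res, cohort = list(cohort))
}

#' Heritability stage: edge tables, summary, and region contributions
#'
#' @param tables named list of differential [edge_phenotypes()].
#' @param cohort loaded cohort (manifest + region groups).
#' @param config pipeline config.
#' @param dir output directory.
#' @return list of `edge_genetics` tables by measure plus `summary` and
#'   `region_contributions`.
#' @export
stage_heritability <- function(tables, cohort, config, dir) {
  results <- list()
  for (meas in c("staticFC", "dfcMean", "dfcVar")) {
    res <- edge_genetics(tables[[meas]], cohort$manifest,
                         family = config$family,
                         correction = config$correction,
                         alpha = config$alpha)
    write_edge_results(res, file.path(dir, paste0("heritability_", meas, ".tsv")))
    results[[meas]] <- res
  }
  summary <- make_summary(results)
  utils::write.table(format_numeric_df(summary),
                     file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  contrib <- list()
  for (meas in names(results)) {
    rc <- region_contribution_summary(results[[meas]], cohort$region_groups)
    rc$measure <- meas
    contrib[[meas]] <- rc
  }
  contrib <- do.call(rbind, c(contrib, make.row.names = FALSE))
  utils::write.table(format_numeric_df(contrib),
                     file.path(dir, "region_contributions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  c(results, list(summary = summary, region_contributions = contrib))
}

#' States stage: state decomposition, comparisons and metric heritability
#'
#' @param stacks per-subject window stacks from [stage_connectivity()].
#' @param cohort loaded cohort.
#' @param config pipeline config.
#' @param dir output directory.
#' @return list with the `state_decomposition`, `comparison` table and
#'   `heritability` table.
#' @export
stage_states <- function(stacks, cohort, config, dir) {
  decomp <- state_decomposition(stacks, cohort$network_map, k = config$k,
                                seed = config$seed, n_init = config$n_init)
  utils::write.table(format_numeric_df(decomp$metrics),
                     file.path(dir, "state_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  comp <- compare_states(decomp)
  utils::write.table(format_numeric_df(comp),
                     file.path(dir, "state_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  herit <- state_metric_heritability(decomp$metrics, cohort$manifest)
  utils::write.table(format_numeric_df(herit),
                     file.path(dir, "state_heritability.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(decomposition = decomp, comparison = comp, heritability = herit)
}

format_numeric_df <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- fmt_num(df[[col]])
  }
  df
}

#' Run the full pipeline
#'
#' simulate (unless `dir` already holds a cohort and `config$simulate` is
#' FALSE) -> connectivity -> heritability -> states, writing every table
#' under `dir` plus a run manifest with the config hash and seed.
#'
#' @param config pipeline config; see [default_pipeline_config()].
#' @param dir working/output directory.
#' @return object of class `report_bundle`: the three edge tables, the
#'   summary, region contributions, state results and the run manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), dir = tempfile("twinconn_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!isFALSE(config$simulate %||% TRUE)) {
    stage_simulate(config, dir)
  }
  conn <- stage_connectivity(config, dir)
  genet <- stage_heritability(conn$tables, conn$cohort, config, dir)
  states <- stage_states(conn$stacks, conn$cohort, config, dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("twinconn")),
    seed = config$seed,
    config_hash = config_hash(config),
    config = config
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(
    edge_tables = genet[c("staticFC", "dfcMean", "dfcVar")],
    summary = genet$summary,
    region_contributions = genet$region_contributions,
    states = states,
    tables = conn$tables,
    manifest = manifest,
    dir = dir
  ), class = "report_bundle")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ord <- config[order(names(config))]
  jsonlite::write_json(ord, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Summary table across the three connectivity phenotypes
#'
#' Per measure (ordered staticFC, dfcMean, dfcVar): the range of the top-10
#' significant A fractions, the count of significant edges, and the top
#' edge.
#'
#' @param results named list of `edge_genetics` tables.
#' @return data.frame with one row per measure.
#' @export
make_summary <- function(results) {
  measures <- c("staticFC", "dfcMean", "dfcVar")
  missing_m <- setdiff(measures, names(results))
  if (length(missing_m)) stop2("missing result set(s): %s",
                               paste(missing_m, collapse = ", "))
  rows <- lapply(measures, function(meas) {
    res <- results[[meas]]
    if (!nrow(res)) stop2("empty result set for %s", meas)
    top <- rank_top_edges(res, k = 10)
    data.frame(
      measure = meas,
      n_significant = sum(res$significant),
      a_top10_min = if (nrow(top)) min(top$a_effect) else NA_real_,
      a_top10_max = if (nrow(top)) max(top$a_effect) else NA_real_,
      top_edge = if (nrow(top)) top$edge[1] else NA_character_,
      top_a = if (nrow(top)) top$a_effect[1] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
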