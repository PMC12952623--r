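# Readers and writers for every file the pipeline touches. All formats are
# plain text: ROI time-series TSV with a one-line metadata header comment,
# FSL three-column event files, and CSV/TSV tables for manifests and maps.
# Every reader validates and fails with a located, message-bearing error.

#' Construct an ROI time-series object
#'
#' @param data frames x ROI numeric matrix.
#' @param tr repetition time in seconds.
#' @param subject subject identifier.
#' @param run run identifier.
#' @param roi_labels ROI labels; defaults to `colnames(data)`.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr, subject = "S1", run = "run1",
                           roi_labels = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(roi_labels)) stop2("ROI labels are required")
  if (length(roi_labels) != ncol(data)) {
    stop2("label count (%d) differs from column count (%d)",
          length(roi_labels), ncol(data))
  }
  if (anyDuplicated(roi_labels)) {
    stop2("duplicate ROI labels: %s",
          paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  }
  if (nrow(data) < 2) stop2("need at least 2 frames")
  if (anyNA(data) || !is.numeric(data)) stop2("time series contains missing or non-numeric values")
  if (!is.numeric(tr) || tr <= 0) stop2("`tr` must be a positive number of seconds")
  colnames(data) <- roi_labels
  rownames(data) <- NULL
  structure(list(subject = subject, run = run, data = data, tr = tr,
                 roi_labels = roi_labels),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s, %s; %d frames x %d ROIs; TR %.3g s\n",
              x$subject, x$run, nrow(x$data), length(x$roi_labels), x$tr))
  invisible(x)
}

#' Write an ROI time series as TSV
#'
#' Format: a first comment line `# subject=<id> run=<id> tr=<seconds>`, a
#' tab-separated header row of ROI labels, then one row per frame with
#' values at 10 significant digits.
#'
#' @param ts a [roi_timeseries()].
#' @param path output path.
#' @export
write_roi_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject=%s run=%s tr=%s", ts$subject, ts$run,
                     fmt_num(ts$tr)), con)
  writeLines(paste(ts$roi_labels, collapse = "\t"), con)
  body <- apply(ts$data, 1, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an ROI time series written by [write_roi_timeseries()]
#'
#' @param path input path.
#' @return a [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop2("%s: too short to be an ROI time-series file", path)
  meta_line <- lines[1]
  if (!startsWith(meta_line, "#")) stop2("%s: missing metadata comment line", path)
  meta <- parse_kv_line(sub("^#\\s*", "", meta_line))
  for (key in c("subject", "run", "tr")) {
    if (is.na(meta[key])) stop2("%s: metadata line lacks `%s`", path, key)
  }
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(labels)) {
    stop2("%s: duplicate ROI label in header: %s", path,
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  body <- lines[-(1:2)]
  n <- length(body)
  mat <- matrix(NA_real_, n, length(labels))
  for (i in seq_len(n)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(labels)) {
      stop2("%s: row %d has %d cells, expected %d", path, i,
            length(cells), length(labels))
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals) || any(!nzchar(trimws(cells)))) {
      bad <- which(is.na(vals) | !nzchar(trimws(cells)))[1]
      stop2("%s: non-numeric or missing cell at row %d, column %s",
            path, i, labels[bad])
    }
    mat[i, ] <- vals
  }
  roi_timeseries(mat, tr = as.numeric(meta["tr"]), subject = meta[["subject"]],
                 run = meta[["run"]], roi_labels = labels)
}

parse_kv_line <- function(line) {
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_,
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

#' Construct a task design from a block table
#'
#' @param blocks data.frame with columns `onset` (s), `duration` (s) and
#'   `condition` (one of `0bk`, `2bk`, `fixation`, `cue`).
#' @return object of class `task_design` with blocks sorted by onset.
#' @export
task_design <- function(blocks) {
  required <- c("onset", "duration", "condition")
  if (!all(required %in% names(blocks))) {
    stop2("block table needs columns %s", paste(required, collapse = ", "))
  }
  valid <- c("0bk", "2bk", "fixation", "cue")
  bad <- setdiff(unique(blocks$condition), valid)
  if (length(bad)) stop2("unknown condition(s): %s", paste(bad, collapse = ", "))
  if (any(blocks$onset < 0)) stop2("negative onset in task design")
  if (any(blocks$duration <= 0)) stop2("non-positive block duration")
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks) > 1) {
    ends <- blocks$onset + blocks$duration
    overlap <- which(blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9)
    if (length(overlap)) {
      stop2("overlapping blocks at onsets %g and %g",
            blocks$onset[overlap[1]], blocks$onset[overlap[1] + 1])
    }
  }
  structure(list(blocks = blocks), class = "task_design")
}

#' Read a task design from FSL three-column event files
#'
#' One whitespace-delimited file per condition with columns onset, duration
#' and weight (the weight is ignored). Files may be empty (no blocks of that
#' condition).
#'
#' @param paths named character vector, names being conditions (`0bk`,
#'   `2bk`, `fixation`, `cue`) and values file paths.
#' @return a [task_design()] with all conditions merged and sorted.
#' @export
read_task_design <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop2("`paths` must be named by condition")
  }
  rows <- list()
  for (cond in names(paths)) {
    lines <- readLines(paths[[cond]])
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) next
    for (i in seq_along(lines)) {
      cells <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(cells) < 2) {
        stop2("%s: line %d has fewer than 2 columns", paths[[cond]], i)
      }
      vals <- suppressWarnings(as.numeric(cells[1:2]))
      if (anyNA(vals)) stop2("%s: non-numeric onset/duration at line %d",
                             paths[[cond]], i)
      rows[[length(rows) + 1]] <- data.frame(onset = vals[1], duration = vals[2],
                                             condition = cond)
    }
  }
  if (!length(rows)) stop2("no blocks found in any event file")
  task_design(do.call(rbind, rows))
}

#' Write a task design as FSL three-column event files
#'
#' @param design a [task_design()].
#' @param dir output directory; one file `<condition>.txt` per condition.
#' @return named vector of written paths.
#' @export
write_task_design <- function(design, dir) {
  conds <- unique(design$blocks$condition)
  paths <- character(0)
  for (cond in conds) {
    b <- design$blocks[design$blocks$condition == cond, , drop = FALSE]
    path <- file.path(dir, paste0(cond, ".txt"))
    writeLines(sprintf("%s\t%s\t1", fmt_num(b$onset), fmt_num(b$duration)), path)
    paths[cond] <- path
  }
  paths
}

#' Construct / read a twin-pair manifest
#'
#' CSV columns: `pair_id`, `subject1`, `subject2`, `zygosity` (MZ or DZ).
#' No subject may appear twice.
#'
#' @param pairs data.frame with the columns above.
#' @return object of class `twin_manifest`.
#' @export
twin_manifest <- function(pairs) {
  required <- c("pair_id", "subject1", "subject2", "zygosity")
  if (!all(required %in% names(pairs))) {
    stop2("manifest needs columns %s", paste(required, collapse = ", "))
  }
  bad <- setdiff(unique(pairs$zygosity), c("MZ", "DZ"))
  if (length(bad)) stop2("unknown zygosity: %s", paste(bad, collapse = ", "))
  subj <- c(pairs$subject1, pairs$subject2)
  if (anyDuplicated(subj)) {
    stop2("subject appears in more than one slot: %s",
          paste(unique(subj[duplicated(subj)]), collapse = ", "))
  }
  if (anyDuplicated(pairs$pair_id)) stop2("duplicate pair ids")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "twin_manifest")
}

#' @rdname twin_manifest
#' @param path CSV path.
#' @export
read_twin_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  twin_manifest(df)
}

#' Write a twin manifest as CSV
#' @param manifest a [twin_manifest()].
#' @param path output path.
#' @export
write_twin_manifest <- function(manifest, path) {
  utils::write.csv(manifest$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a default MZ/DZ manifest of a given size
#' @param n_mz,n_dz pair counts.
#' @return a [twin_manifest()].
#' @export
default_manifest <- function(n_mz, n_dz) {
  n <- n_mz + n_dz
  twin_manifest(data.frame(
    pair_id = sprintf("P%04d", seq_len(n)),
    subject1 = sprintf("S%04dA", seq_len(n)),
    subject2 = sprintf("S%04dB", seq_len(n)),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    stringsAsFactors = FALSE
  ))
}

#' Read an ROI -> Yeo-7 network map
#'
#' TSV with columns `roi` and `network`; network names must come from the
#' canonical seven (Visual, Somatomotor, DorsalAttention, VentralAttention,
#' Limbic, Frontoparietal, Default). VentralAttention covers the salience
#' system.
#'
#' @param path TSV path.
#' @return named character vector ROI -> network, class `network_map`.
#' @export
read_network_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("roi", "network") %in% names(df))) {
    stop2("%s: needs columns roi, network", path)
  }
  network_map(stats::setNames(df$network, df$roi))
}

#' @rdname read_network_map
#' @param map named character vector ROI -> network.
#' @export
network_map <- function(map) {
  bad <- setdiff(unique(unname(map)), YEO7_NETWORKS)
  if (length(bad)) {
    stop2("unknown network name(s): %s (must be one of %s)",
          paste(bad, collapse = ", "), paste(YEO7_NETWORKS, collapse = ", "))
  }
  if (anyDuplicated(names(map))) stop2("duplicate ROI in network map")
  structure(map, class = "network_map")
}

#' Write a network map as TSV
#' @param map a `network_map`.
#' @param path output path.
#' @export
write_network_map <- function(map, path) {
  utils::write.table(data.frame(roi = names(map), network = unname(unclass(map))),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI -> anatomical group map
#'
#' TSV with columns `roi` and `group` (e.g. DLPFC/LPFC/FEF, IPS/SPL, PCC,
#' dACC, Temporal, Insula). An ROI belongs to at most one group; not every
#' ROI needs a group.
#'
#' @param path TSV path.
#' @return named character vector ROI -> group, class `region_group_map`.
#' @export
read_region_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("roi", "group") %in% names(df))) {
    stop2("%s: needs columns roi, group", path)
  }
  region_group_map(stats::setNames(df$group, df$roi))
}

#' @rdname read_region_groups
#' @param map named character vector ROI -> group.
#' @export
region_group_map <- function(map) {
  if (any(!nzchar(map))) stop2("empty group name in region-group map")
  if (anyDuplicated(names(map))) stop2("ROI mapped to more than one group")
  structure(map, class = "region_group_map")
}

#' Write a region-group map as TSV
#' @param map a `region_group_map`.
#' @param path output path.
#' @export
write_region_groups <- function(map, path) {
  utils::write.table(data.frame(roi = names(map), group = unname(unclass(map))),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write edge-level heritability results as TSV
#'
#' Rows are ordered by descending A effect, ties broken by lexicographic
#' edge label, so output is deterministic.
#'
#' @param results data.frame with at least columns `roi1`, `roi2`,
#'   `a_effect`, `p`, `p_adjusted`, `model`.
#' @param path output path.
#' @export
write_edge_results <- function(results, path) {
  required <- c("roi1", "roi2", "a_effect", "p", "p_adjusted", "model")
  missing_cols <- setdiff(required, names(results))
  if (length(missing_cols)) {
    stop2("results lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(results)) {
    key <- paste(results$roi1, results$roi2, sep = "|")
    ord <- order(-results$a_effect, key, method = "radix")
    results <- results[ord, , drop = FALSE]
  }
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration (YAML or JSON by extension)
#' @param path config path ending in `.yaml`, `.yml` or `.json`.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop2("unsupported config extension: .%s", ext)
  }
}
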