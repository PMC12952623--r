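# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic component of the pipeline (phenotype draws, Markov state
#' sequences, observation noise, clustering restarts, ...) consumes its own
#' sub-stream so that components are independently reproducible. Sub-seeds
#' stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer identifying the sub-stream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, offset) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop2("`seed` must be a single integer")
  }
  m <- 2147483629
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + as.numeric(offset) * 104729 + 1) %% m)
}

#' Canonical Yeo-7 network names, in fixed order
#' @export
YEO7_NETWORKS <- c(
  "Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
  "Limbic", "Frontoparietal", "Default"
)

# Edge keys "roi_i|roi_j" for i < j in ROI order.
edge_keys <- function(labels) {
  n <- length(labels)
  if (n < 2) return(character(0))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  paste(labels[idx[, "row"]], labels[idx[, "col"]], sep = "|")
}

split_edge_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    roi1 = vapply(parts, `[`, character(1), 1L),
    roi2 = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

upper_tri_vector <- function(mat) mat[upper.tri(mat)]

# Numeric formatting policy for text outputs: 10 significant digits.
fmt_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Repair a correlation matrix to the nearest positive-definite form
#'
#' Eigenvalues are clipped at a small floor and the matrix rescaled back to
#' unit diagonal; this is the repair applied when planted condition effects
#' push a synthetic correlation structure off the positive-definite cone.
#'
#' @param mat symmetric matrix.
#' @param eps eigenvalue floor (default `1e-6`).
#' @return positive-definite matrix with unit diagonal.
#' @export
nearest_pd_corr <- function(mat, eps = 1e-6) {
  mat <- (mat + t(mat)) / 2
  es <- eigen(mat, symmetric = TRUE)
  vals <- pmax(es$values, eps)
  out <- es$vectors %*% (vals * t(es$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(mat)
  (out + t(out)) / 2
}

is_pd <- function(mat, tol = 1e-10) {
  ev <- eigen((mat + t(mat)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}

assert_conn_matrix <- function(mat, what = "connectivity matrix") {
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8))) {
    stop2("%s is not symmetric", what)
  }
  if (any(abs(diag(mat) - 1) > 1e-8)) stop2("%s diagonal is not 1", what)
  if (any(mat < -1 - 1e-8 | mat > 1 + 1e-8)) {
    stop2("%s has entries outside [-1, 1]", what)
  }
  invisible(TRUE)
}
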