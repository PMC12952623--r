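# Variance-component engine for twin-pair phenotypes.
#
# A pair's two phenotype values are modelled as bivariate normal with a
# common free mean and exchangeable covariance
#   [[v, c_z], [c_z, v]]
# where the total variance v and co-twin covariance c_z depend on the model:
#   ACE: v = a2+c2+e2, c_MZ = a2+c2,    c_DZ = a2/2+c2
#   ADE: v = a2+d2+e2, c_MZ = a2+d2,    c_DZ = a2/2+d2/4
#   AE : v = a2+e2,    c_MZ = a2,       c_DZ = a2/2
#   E  : v = e2,       c_MZ = c_DZ = 0
# Parameters are optimized on the path-coefficient scale (a, c, e
# unconstrained; variances are their squares), so variance components are
# non-negative by construction. The log-likelihood is computed from
# per-zygosity sufficient statistics, so a fit costs the same whether a
# cohort has 16 or 40000 pairs.

MODEL_PATHS <- list(ACE = c("a", "c", "e"), ADE = c("a", "d", "e"),
                    AE = c("a", "e"), E = "e")

pair_suffstats <- function(x1, x2) {
  list(n = length(x1), s1 = sum(x1), s2 = sum(x2),
       q11 = sum(x1^2), q22 = sum(x2^2), q12 = sum(x1 * x2))
}

# Exact bivariate-normal log-likelihood for one zygosity group from
# sufficient statistics.
ll_group <- function(mu, v, cv, st) {
  if (st$n == 0) return(0)
  det <- v * v - cv * cv
  if (!is.finite(det) || det <= 0 || v <= 0) return(-Inf)
  q11 <- st$q11 - 2 * mu * st$s1 + st$n * mu^2
  q22 <- st$q22 - 2 * mu * st$s2 + st$n * mu^2
  q12 <- st$q12 - mu * (st$s1 + st$s2) + st$n * mu^2
  quad <- (v * (q11 + q22) - 2 * cv * q12) / det
  -st$n * log(2 * pi) - st$n / 2 * log(det) - quad / 2
}

model_cov <- function(model, paths) {
  sq <- paths^2
  switch(model,
    ACE = list(v = sq[1] + sq[2] + sq[3], c_mz = sq[1] + sq[2],
               c_dz = sq[1] / 2 + sq[2]),
    ADE = list(v = sq[1] + sq[2] + sq[3], c_mz = sq[1] + sq[2],
               c_dz = sq[1] / 2 + sq[2] / 4),
    AE = list(v = sq[1] + sq[2], c_mz = sq[1], c_dz = sq[1] / 2),
    E = list(v = sq[1], c_mz = 0, c_dz = 0)
  )
}

twin_loglik <- function(par, model, st_mz, st_dz) {
  cv <- model_cov(model, par[-1])
  ll_group(par[1], cv$v, cv$c_mz, st_mz) + ll_group(par[1], cv$v, cv$c_dz, st_dz)
}

check_pairs <- function(pairs, min_per_zyg = 4) {
  required <- c("zygosity", "twin1", "twin2")
  if (!all(required %in% names(pairs))) {
    stop2("paired phenotypes need columns %s", paste(required, collapse = ", "))
  }
  vals <- c(pairs$twin1, pairs$twin2)
  if (anyNA(vals) || any(!is.finite(vals))) stop2("non-finite phenotype values")
  n_mz <- sum(pairs$zygosity == "MZ")
  n_dz <- sum(pairs$zygosity == "DZ")
  if (n_mz < min_per_zyg || n_dz < min_per_zyg) {
    stop2("need at least %d pairs of each zygosity (got %d MZ, %d DZ)",
          min_per_zyg, n_mz, n_dz)
  }
  invisible(list(n_mz = n_mz, n_dz = n_dz))
}

#' Intraclass correlation of twin-pair values
#'
#' One-way random-effects ANOVA ICC for groups of size two:
#' `(MSB - MSW) / (MSB + MSW)`, clipped to `[-1, 1]`.
#'
#' @param twin1,twin2 paired phenotype values (one zygosity).
#' @return the ICC.
#' @examples
#' intraclass_correlation(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
intraclass_correlation <- function(twin1, twin2) {
  n <- length(twin1)
  if (n < 3 || length(twin2) != n) stop2("need at least 3 complete pairs")
  means <- (twin1 + twin2) / 2
  grand <- mean(c(twin1, twin2))
  msb <- 2 * sum((means - grand)^2) / (n - 1)
  msw <- sum((twin1 - means)^2 + (twin2 - means)^2) / n
  r <- (msb - msw) / (msb + msw)
  min(1, max(-1, r))
}

#' Choose between the ACE and ADE model families
#'
#' ADE when `r_mz > 2 * r_dz` (excess MZ similarity suggesting dominance or
#' epistasis); ACE otherwise, including on the boundary `r_mz = 2 * r_dz`
#' where additive effects alone explain the pattern.
#'
#' @param r_mz,r_dz intraclass correlations by zygosity.
#' @return `"ACE"` or `"ADE"`.
#' @export
choose_family <- function(r_mz, r_dz) {
  if (!is.finite(r_mz) || !is.finite(r_dz)) stop2("correlations must be finite")
  if (r_mz > 2 * r_dz) "ADE" else "ACE"
}

#' Maximum-likelihood variance-component fit on twin pairs
#'
#' The phenotype is z-standardized cohort-wide before fitting, the shared
#' mean is a free parameter, and the optimizer (BFGS) is multi-started from
#' a Falconer-derived point, an equal split, and an E-dominant point; in
#' addition each model is warm-started from its nested submodel's solution
#' so the nested likelihood ordering ACE >= AE >= E holds numerically.
#'
#' @param pairs data.frame with columns `zygosity` (`MZ`/`DZ`), `twin1`,
#'   `twin2`; at least 4 pairs per zygosity.
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"E"`.
#' @param standardize z-standardize the pooled phenotype first (default
#'   TRUE).
#' @return object of class `vc_fit`: model, variance components (`a2`, `c2`
#'   or `d2`, `e2`), total variance `v`, standardized fractions, `mu`,
#'   `logL`, `n_params`, `aic`, `heritability_percent` (a2/v x 100) and a
#'   `converged` flag.
#' @export
fit_variance_components <- function(pairs, model = c("AE", "ACE", "ADE", "E"),
                                    standardize = TRUE) {
  model <- match.arg(model)
  check_pairs(pairs)
  x1 <- pairs$twin1; x2 <- pairs$twin2
  if (standardize) {
    pool <- c(x1, x2)
    mu0 <- mean(pool); sd0 <- stats::sd(pool)
    if (sd0 <= 0) stop2("phenotype has zero variance")
    x1 <- (x1 - mu0) / sd0; x2 <- (x2 - mu0) / sd0
  }
  mz <- pairs$zygosity == "MZ"
  st_mz <- pair_suffstats(x1[mz], x2[mz])
  st_dz <- pair_suffstats(x1[!mz], x2[!mz])
  fit_vc_standardized(st_mz, st_dz, model)
}

fit_vc_standardized <- function(st_mz, st_dz, model) {
  n_pairs <- st_mz$n + st_dz$n
  pool_mean <- (st_mz$s1 + st_mz$s2 + st_dz$s1 + st_dz$s2) / (2 * n_pairs)
  pool_ss <- st_mz$q11 + st_mz$q22 + st_dz$q11 + st_dz$q22
  v_ml <- pool_ss / (2 * n_pairs) - pool_mean^2

  if (model == "E") {
    # Closed form: mu = grand mean, e2 = ML variance.
    par <- c(pool_mean, sqrt(v_ml))
    ll <- twin_loglik(par, "E", st_mz, st_dz)
    return(vc_fit_result("E", par, ll, st_mz, st_dz, converged = TRUE))
  }

  # Falconer-style starting values from moment correlations.
  r_mz <- suff_corr(st_mz)
  r_dz <- suff_corr(st_dz)
  a2_f <- min(0.9, max(0.05, 2 * (r_mz - r_dz))) * v_ml
  c2_f <- min(0.9, max(0.01, 2 * r_dz - r_mz)) * v_ml
  starts <- list()
  k <- length(MODEL_PATHS[[model]])
  if (model %in% c("ACE", "ADE")) {
    starts[[1]] <- c(pool_mean, sqrt(a2_f), sqrt(c2_f),
                     sqrt(max(0.05 * v_ml, v_ml - a2_f - c2_f)))
    starts[[2]] <- c(pool_mean, rep(sqrt(v_ml / 3), 3))
    starts[[3]] <- c(pool_mean, sqrt(0.05 * v_ml), sqrt(0.05 * v_ml),
                     sqrt(0.9 * v_ml))
    # warm start from the nested AE solution
    ae <- fit_vc_standardized(st_mz, st_dz, "AE")
    starts[[4]] <- c(ae$mu, sqrt(ae$a2), 1e-4, sqrt(ae$e2))
  } else {  # AE
    starts[[1]] <- c(pool_mean, sqrt(max(0.05 * v_ml, a2_f + c2_f)),
                     sqrt(max(0.05 * v_ml, v_ml - a2_f - c2_f)))
    starts[[2]] <- c(pool_mean, sqrt(v_ml / 2), sqrt(v_ml / 2))
    starts[[3]] <- c(pool_mean, sqrt(0.02 * v_ml), sqrt(0.98 * v_ml))
  }

  best <- NULL
  for (par0 in starts) {
    opt <- stats::optim(par0, function(p) -twin_loglik(p, model, st_mz, st_dz),
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  vc_fit_result(model, best$par, -best$value, st_mz, st_dz,
                converged = best$convergence == 0)
}

suff_corr <- function(st) {
  if (st$n < 2) return(0)
  m1 <- st$s1 / st$n; m2 <- st$s2 / st$n
  v1 <- st$q11 / st$n - m1^2; v2 <- st$q22 / st$n - m2^2
  cv <- st$q12 / st$n - m1 * m2
  if (v1 <= 0 || v2 <= 0) return(0)
  min(0.999, max(-0.999, cv / sqrt(v1 * v2)))
}

vc_fit_result <- function(model, par, ll, st_mz, st_dz, converged) {
  paths <- MODEL_PATHS[[model]]
  comps <- stats::setNames(par[-1]^2, paste0(paths, "2"))
  v <- sum(comps)
  n_params <- 1 + length(paths)
  a2 <- if ("a2" %in% names(comps)) comps[["a2"]] else 0
  structure(list(
    model = model,
    components = comps,
    a2 = a2,
    c2 = if ("c2" %in% names(comps)) comps[["c2"]] else NA_real_,
    d2 = if ("d2" %in% names(comps)) comps[["d2"]] else NA_real_,
    e2 = comps[["e2"]],
    v = v,
    fractions = comps / v,
    mu = par[1],
    logL = ll,
    n_params = n_params,
    aic = 2 * n_params - 2 * ll,
    heritability_percent = if (v > 0) 100 * a2 / v else NA_real_,
    n_mz = st_mz$n, n_dz = st_dz$n,
    converged = converged
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("%s fit (logL %.4f, AIC %.4f)%s\n", x$model, x$logL, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  fr <- paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
              collapse = ", ")
  cat(sprintf("  variance fractions: %s; heritability %.1f%%\n", fr,
              x$heritability_percent))
  invisible(x)
}

#' Select between two nested fits by AIC
#'
#' @param fit_full,fit_reduced converged [fit_variance_components()] fits;
#'   ties go to the model with fewer parameters.
#' @return the preferred `vc_fit`.
#' @export
select_model <- function(fit_full, fit_reduced) {
  if (!fit_full$converged || !fit_reduced$converged) {
    stop2("cannot select between unconverged fits")
  }
  if (fit_reduced$aic <= fit_full$aic) fit_reduced else fit_full
}

#' Heritability from an AE fit
#'
#' @param fit an AE `vc_fit`.
#' @return `a2 / (a2 + e2) * 100`.
#' @export
heritability_percent <- function(fit) {
  if (fit$model != "AE") stop2("heritability_percent expects an AE fit")
  denom <- fit$a2 + fit$e2
  if (denom <= 0) stop2("a2 + e2 is zero")
  100 * fit$a2 / denom
}

#' Likelihood-ratio test of the additive genetic effect
#'
#' Drops A from the AE model and compares fits:
#' `chi2 = 2 (logL_AE - logL_E)` (clipped at 0). By default the p-value
#' uses a chi-square reference with 1 df, which is conservative because the
#' null value a2 = 0 lies on the boundary of the parameter space; the
#' `boundary_mixture` option uses the 0.5 chi2(0) + 0.5 chi2(1) mixture
#' instead (less conservative).
#'
#' @param pairs paired phenotypes (see [fit_variance_components()]).
#' @param boundary_mixture use the boundary mixture reference.
#' @return list with `chi2`, `p`, and the two fits.
#' @export
test_genetic_effect <- function(pairs, boundary_mixture = FALSE) {
  fit_ae <- fit_variance_components(pairs, "AE")
  fit_e <- fit_variance_components(pairs, "E")
  if (!fit_ae$converged || !fit_e$converged) stop2("fits did not converge")
  chi2 <- max(0, 2 * (fit_ae$logL - fit_e$logL))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p <- if (chi2 == 0) 1 else p / 2
  if (chi2 == 0) p <- 1
  list(chi2 = chi2, p = p, fit_ae = fit_ae, fit_e = fit_e)
}

#' Multiple-testing adjustment with significance flags
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` (min(1, m p)) or `"bh"`
#'   (Benjamini-Hochberg step-up).
#' @param alpha significance level for the flags (adjusted p < alpha).
#' @return data.frame with `p`, `p_adjusted`, `significant`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0) {
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop2("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
  data.frame(p = p, p_adjusted = adj, significant = !is.na(adj) & adj < alpha)
}

#' Compare MZ and DZ similarity of one edge via Fisher's z
#'
#' `z = (atanh r_mz - atanh r_dz) / sqrt(1/(n_mz-3) + 1/(n_dz-3))` with a
#' two-sided normal p-value. Correlations at exactly +-1 are clipped to
#' +-0.999999 with a warning.
#'
#' @param r_mz,r_dz intraclass correlations.
#' @param n_mz,n_dz pair counts (> 3).
#' @return list with `z` and `p`.
#' @export
compare_mz_dz_similarity <- function(r_mz, r_dz, n_mz, n_dz) {
  if (n_mz <= 3 || n_dz <= 3) stop2("need more than 3 pairs per zygosity")
  clip <- function(r) {
    if (abs(r) >= 1) {
      warning("correlation at |r| = 1 clipped to 0.999999", call. = FALSE)
      r <- sign(r) * 0.999999
    }
    r
  }
  z <- (atanh(clip(r_mz)) - atanh(clip(r_dz))) /
    sqrt(1 / (n_mz - 3) + 1 / (n_dz - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Edge-level genetic analysis of a phenotype table
#'
#' Per edge: intraclass correlations by zygosity, ACE/ADE family choice
#' (or a forced model), the full-family fit and the AE fit compared by AIC,
#' the AE-vs-E likelihood-ratio test of the genetic effect, and
#' multiple-testing adjustment across edges.
#'
#' @param pheno an [edge_phenotypes()] table.
#' @param manifest a [twin_manifest()]; subjects must appear in the table.
#' @param family `"auto"` (ICC-based choice), `"ACE"`, `"ADE"` or `"AE"`.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha significance level on adjusted p-values.
#' @return data.frame (class `edge_genetics`) with one row per edge:
#'   `roi1`, `roi2`, `edge`, `r_mz`, `r_dz`, `family`, `model`, `a_effect`
#'   (the AE model's additive variance fraction a2/(a2+e2), the quantity
#'   published per edge regardless of which model the AIC prefers), `chi2`,
#'   `p`, `p_adjusted`, `significant`.
#' @export
edge_genetics <- function(pheno, manifest, family = c("auto", "ACE", "ADE", "AE"),
                          correction = "bonferroni", alpha = 0.05) {
  family <- match.arg(family)
  vals <- pheno$values
  miss <- setdiff(c(manifest$pairs$subject1, manifest$pairs$subject2),
                  rownames(vals))
  if (length(miss)) {
    stop2("manifest subjects missing from phenotype table: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  edges <- colnames(vals)
  zyg <- manifest$pairs$zygosity
  i1 <- match(manifest$pairs$subject1, rownames(vals))
  i2 <- match(manifest$pairs$subject2, rownames(vals))

  rows <- vector("list", length(edges))
  for (e_i in seq_along(edges)) {
    x1 <- vals[i1, e_i]; x2 <- vals[i2, e_i]
    pairs <- data.frame(zygosity = zyg, twin1 = x1, twin2 = x2)
    r_mz <- intraclass_correlation(x1[zyg == "MZ"], x2[zyg == "MZ"])
    r_dz <- intraclass_correlation(x1[zyg == "DZ"], x2[zyg == "DZ"])
    fam <- if (family == "auto") choose_family(r_mz, r_dz)
           else if (family == "AE") "ACE" else family
    fit_full <- fit_variance_components(pairs, fam)
    fit_ae <- fit_variance_components(pairs, "AE")
    chosen <- if (family == "AE") fit_ae else select_model(fit_full, fit_ae)
    lrt <- test_genetic_effect(pairs)
    pair_info <- split_edge_key(edges[e_i])
    rows[[e_i]] <- data.frame(
      roi1 = pair_info$roi1, roi2 = pair_info$roi2, edge = edges[e_i],
      r_mz = r_mz, r_dz = r_dz, family = fam, model = chosen$model,
      a_effect = unname(fit_ae$a2 / fit_ae$v),
      chi2 = lrt$chi2, p = lrt$p,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, method = correction, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  class(out) <- c("edge_genetics", "data.frame")
  out
}

#' Top heritable edges
#'
#' The `k` significant edges with the largest A fractions, ties broken by
#' lexicographic edge label.
#'
#' @param results an [edge_genetics()] table.
#' @param k number of edges (default 10).
#' @param significant_only restrict to flagged edges (default TRUE).
#' @return the selected rows, ordered.
#' @export
rank_top_edges <- function(results, k = 10, significant_only = TRUE) {
  if (!nrow(results)) stop2("empty results")
  keep <- if (significant_only) results[results$significant, , drop = FALSE]
          else results
  if (!nrow(keep)) return(keep)
  ord <- order(-keep$a_effect, keep$edge, method = "radix")
  utils::head(keep[ord, , drop = FALSE], k)
}

#' Anatomical-group contribution to significant edges
#'
#' For each anatomical group, the percentage of significant edges with at
#' least one endpoint in the group; a both-endpoint edge counts once, and
#' one edge may contribute to two groups. Hemisphere prefixes (`L-`/`R-`)
#' on ROI labels are stripped before matching if the bare label is mapped.
#'
#' @param results an [edge_genetics()] table with significance flags.
#' @param groups a `region_group_map` (see [read_region_groups()]).
#' @return data.frame `group`, `n_edges`, `percent`; all-`NA` percentages
#'   (with zero rows of significant edges) when nothing is significant.
#' @export
region_contribution_summary <- function(results, groups) {
  sig <- results[results$significant, , drop = FALSE]
  group_names <- sort(unique(unname(unclass(groups))))
  lookup <- function(roi) {
    if (roi %in% names(groups)) return(groups[[roi]])
    bare <- sub("^[LR]-", "", roi)
    if (bare %in% names(groups)) return(groups[[bare]]) else NA_character_
  }
  if (!nrow(sig)) {
    return(data.frame(group = group_names, n_edges = 0L,
                      percent = NA_real_))
  }
  g1 <- vapply(sig$roi1, lookup, character(1))
  g2 <- vapply(sig$roi2, lookup, character(1))
  counts <- vapply(group_names, function(g)
    sum(g1 == g | g2 == g, na.rm = TRUE), integer(1))
  data.frame(group = group_names, n_edges = counts,
             percent = 100 * counts / nrow(sig))
}
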