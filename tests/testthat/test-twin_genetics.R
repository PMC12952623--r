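# Variance-component engine: ICC, family choice, ML fits, model selection,
# LRT, multiple testing, MZ/DZ comparison, summaries.

test_that("ICC matches the one-way ANOVA hand computation", {
  expect_equal(intraclass_correlation(c(1, 2, 3), c(1, 2, 3)), 1)

  # pairs {(0,1),(1,0),(2,3),(3,2)}: MSB = 8/3, MSW = 1/2 -> 13/19
  expect_equal(intraclass_correlation(c(0, 1, 2, 3), c(1, 0, 3, 2)), 13 / 19)

  set.seed(1)
  expect_lt(abs(intraclass_correlation(rnorm(10000), rnorm(10000))), 0.05)
  expect_error(intraclass_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("family choice follows the twice-rDZ rule with ACE on the boundary", {
  expect_equal(choose_family(0.6, 0.2), "ADE")
  expect_equal(choose_family(0.6, 0.3), "ACE")   # boundary -> ACE
  expect_equal(choose_family(0.4, 0.35), "ACE")
  expect_error(choose_family(NA, 0.2), "finite")
})

test_that("AE fits recover generator extremes", {
  ph <- simulate_ace_phenotypes(ace_spec(1, 0, 0), cohort_shape(5000, 5000, seed = 2))
  fit <- fit_variance_components(ph, "AE")
  expect_gte(fit$a2 / (fit$a2 + fit$e2), 0.95)

  ph <- simulate_ace_phenotypes(ace_spec(0, 0, 1), cohort_shape(5000, 5000, seed = 2))
  fit <- fit_variance_components(ph, "AE")
  expect_lte(fit$a2 / (fit$a2 + fit$e2), 0.05)
})

test_that("optimizer matches the exhaustive grid-search oracle", {
  for (seed in 1:20) {
    pairs <- random_small_cohort(8, 8, seed = 100 + seed)
    fit <- fit_variance_components(pairs, "AE")
    oracle <- oracle_ae_grid(pairs)
    expect_lt(abs(fit$logL - oracle$logL), 1e-4)
    expect_lt(abs(fit$a2 - oracle$a2), 2e-3)
  }
})

test_that("ACE estimates satisfy Falconer's relations at large n", {
  ph <- simulate_ace_phenotypes(ace_spec(0.5, 0.1, 0.4),
                                cohort_shape(20000, 20000, seed = 1))
  fit <- fit_variance_components(ph, "ACE")
  expect_true(fit$converged)
  expect_lt(abs(fit$fractions[["a2"]] - 0.5), 0.02)
  expect_lt(abs(fit$fractions[["c2"]] - 0.1), 0.02)
  expect_lt(abs(fit$fractions[["e2"]] - 0.4), 0.02)
})

test_that("nested likelihood ordering holds on assorted cohorts", {
  for (seed in c(3, 14, 159)) {
    pairs <- random_small_cohort(20, 20, seed = seed)
    ll <- vapply(c("ACE", "AE", "E"), function(m)
      fit_variance_components(pairs, m)$logL, numeric(1))
    expect_gte(ll[["ACE"]], ll[["AE"]] - 1e-6)
    expect_gte(ll[["AE"]], ll[["E"]] - 1e-6)
  }
})

test_that("AE a2 is invariant to sign flip and affine rescaling", {
  pairs <- random_small_cohort(30, 30, seed = 5)
  f0 <- fit_variance_components(pairs, "AE")
  flip <- transform(pairs, twin1 = -twin1, twin2 = -twin2)
  expect_equal(fit_variance_components(flip, "AE")$a2, f0$a2, tolerance = 1e-5)
  aff <- transform(pairs, twin1 = 3 * twin1 + 10, twin2 = 3 * twin2 + 10)
  expect_equal(fit_variance_components(aff, "AE")$a2, f0$a2, tolerance = 1e-5)
})

test_that("model selection prefers the lower AIC, ties to fewer parameters", {
  pairs <- random_small_cohort(30, 30, seed = 6)
  ace <- fit_variance_components(pairs, "ACE")
  ae <- fit_variance_components(pairs, "AE")
  chosen <- select_model(ace, ae)
  expect_equal(chosen$model,
               if (ae$aic <= ace$aic) "AE" else "ACE")

  # under c2 = 0 truth, AE wins the AIC contest in most replicates
  wins <- 0
  for (rep in 1:40) {
    ph <- simulate_ace_phenotypes(ace_spec(0.5, 0, 0.5),
                                  cohort_shape(134, 78, seed = 700 + rep))
    ace <- fit_variance_components(ph, "ACE")
    ae <- fit_variance_components(ph, "AE")
    if (select_model(ace, ae)$model == "AE") wins <- wins + 1
  }
  expect_gt(wins / 40, 0.5)
})

test_that("heritability percentage follows a2/(a2+e2) x 100", {
  fit <- structure(list(model = "AE", a2 = 0.36, e2 = 0.64), class = "vc_fit")
  expect_equal(heritability_percent(fit), 36)
  fit$a2 <- 0
  expect_equal(heritability_percent(fit), 0)
  fit$a2 <- 0.5; fit$e2 <- 0
  expect_equal(heritability_percent(fit), 100)
})

test_that("genetic-effect LRT is calibrated and powered", {
  # conservative under the boundary null
  set.seed(31)
  rejections <- 0
  for (rep in 1:120) {
    ph <- simulate_ace_phenotypes(ace_spec(0, 0, 1),
                                  cohort_shape(134, 78, seed = 3000 + rep))
    if (test_genetic_effect(ph)$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 120, 0.075 + 0.03)  # MC slack at 120 reps

  # powered under strong additive signal
  hits <- 0
  for (rep in 1:60) {
    ph <- simulate_ace_phenotypes(ace_spec(0.6, 0, 0.4),
                                  cohort_shape(134, 78, seed = 4000 + rep))
    if (test_genetic_effect(ph)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
})

test_that("identical AE and E likelihoods give chi2 = 0, p = 1", {
  # phenotype with zero twin resemblance at tiny n: AE collapses to a2 ~ 0
  pairs <- data.frame(zygosity = rep(c("MZ", "DZ"), each = 4),
                      twin1 = c(1, -1, 2, -2, 1.5, -1.5, 0.5, -0.5),
                      twin2 = c(-1, 1, -2, 2, -1.5, 1.5, -0.5, 0.5))
  res <- test_genetic_effect(pairs)
  expect_gte(res$chi2, 0)
  if (res$chi2 == 0) expect_equal(res$p, 1)
})

test_that("p-value adjustment matches bonferroni and BH references", {
  out <- adjust_pvalues(rep(0.01, 10), "bonferroni")
  expect_equal(out$p_adjusted, rep(0.1, 10))
  out <- adjust_pvalues(c(0.01, 0.02, 0.04), "bh")
  expect_equal(out$p_adjusted, c(0.03, 0.03, 0.04))
  expect_equal(nrow(adjust_pvalues(numeric(0), "bh")), 0)
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
  expect_true(all(out$p_adjusted >= out$p))
})

test_that("Fisher z comparison of MZ/DZ similarity matches the hand value", {
  res <- compare_mz_dz_similarity(0.6, 0.6, 134, 78)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  res <- compare_mz_dz_similarity(0.6, 0.2, 134, 78)
  expect_equal(res$z, (atanh(0.6) - atanh(0.2)) / sqrt(1 / 131 + 1 / 75))
  expect_equal(res$z, 3.387, tolerance = 1e-3)

  expect_warning(compare_mz_dz_similarity(1, 0.2, 134, 78), "clipped")
  expect_error(compare_mz_dz_similarity(0.5, 0.2, 134, 3), "more than 3")
})

test_that("top-edge ranking respects significance, order and ties", {
  res <- data.frame(roi1 = c("a", "b", "c"), roi2 = c("x", "y", "z"),
                    edge = c("a|x", "b|y", "c|z"),
                    a_effect = c(0.1, 0.3, 0.2),
                    significant = TRUE)
  top <- rank_top_edges(res, k = 2)
  expect_equal(top$a_effect, c(0.3, 0.2))

  res$a_effect <- 0.2
  expect_equal(rank_top_edges(res, k = 3)$edge, c("a|x", "b|y", "c|z"))

  expect_equal(nrow(rank_top_edges(res, k = 10)), 3)
  res$significant <- c(TRUE, FALSE, FALSE)
  expect_equal(nrow(rank_top_edges(res, k = 10)), 1)
})

test_that("region contributions count edges with >= 1 endpoint per group", {
  groups <- region_group_map(c("r1" = "G1", "r2" = "G1", "r3" = "G2",
                               "r4" = "G3"))
  res <- data.frame(roi1 = c("r1", "r1", "r3", "r4"),
                    roi2 = c("r2", "r3", "r4", "r4"),
                    significant = c(TRUE, TRUE, TRUE, TRUE))
  out <- region_contribution_summary(res, groups)
  # hand count: G1 touches edges 1,2 -> 50%; G2 edges 2,3 -> 50%; G3 edges 3,4 -> 50%
  expect_equal(out$percent[out$group == "G1"], 50)
  expect_equal(out$percent[out$group == "G2"], 50)
  expect_equal(out$percent[out$group == "G3"], 50)
  # both-endpoint edge counts once
  res2 <- data.frame(roi1 = c("r1", "r3"), roi2 = c("r2", "r4"),
                     significant = TRUE)
  out2 <- region_contribution_summary(res2, groups)
  expect_equal(out2$percent[out2$group == "G1"], 50)

  none <- region_contribution_summary(
    data.frame(roi1 = "r1", roi2 = "r2", significant = FALSE), groups)
  expect_true(all(is.na(none$percent)))
})

test_that("edge_genetics assembles per-edge results with adjusted p-values", {
  set.seed(77)
  n_mz <- 60; n_dz <- 40
  manifest <- default_manifest(n_mz, n_dz)
  herit <- simulate_ace_phenotypes(ace_spec(0.6, 0, 0.4),
                                   cohort_shape(n_mz, n_dz, seed = 8))
  null <- simulate_ace_phenotypes(ace_spec(0, 0, 1),
                                  cohort_shape(n_mz, n_dz, seed = 9))
  vals <- matrix(0, 2 * (n_mz + n_dz), 2,
                 dimnames = list(c(manifest$pairs$subject1, manifest$pairs$subject2),
                                 c("a|b", "a|c")))
  vals[manifest$pairs$subject1, "a|b"] <- herit$twin1
  vals[manifest$pairs$subject2, "a|b"] <- herit$twin2
  vals[manifest$pairs$subject1, "a|c"] <- null$twin1
  vals[manifest$pairs$subject2, "a|c"] <- null$twin2
  pheno <- edge_phenotypes(vals, "staticFC", "diff")
  res <- edge_genetics(pheno, manifest)
  expect_equal(nrow(res), 2)
  expect_gt(res$a_effect[res$edge == "a|b"], res$a_effect[res$edge == "a|c"])
  expect_true(all(res$p_adjusted >= res$p))
  expect_true(all(res$a_effect >= 0 & res$a_effect <= 1))
})
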