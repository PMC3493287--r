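test_that("log-normal fit reproduces the pooled IL-6 summary and its quantiles", {
  m <- biomarker_marginal(6.4, 2.8, 14.4, lod = 0.7, name = "il6")
  fit <- fit_lognormal_from_quartiles(m)
  # frozen closed-form evaluations
  expect_equal(fit$mu, 1.85629799, tolerance = 1e-7)
  expect_equal(fit$sigma, 1.21396121, tolerance = 1e-7)
  # the fitted distribution's quartiles land on the printed ones within the
  # stated 15% asymmetry tolerance
  expect_equal(qlnorm(0.25, fit$mu, fit$sigma), 2.8, tolerance = 0.15)
  expect_equal(qlnorm(0.75, fit$mu, fit$sigma), 14.4, tolerance = 0.15)
  expect_false(fit$asymmetric)
})

test_that("log-normal fit handles degenerate and log-symmetric cases", {
  fit0 <- fit_lognormal_from_quartiles(biomarker_marginal(1, 1, 1))
  expect_identical(fit0$sigma, 0)
  expect_identical(fit0$mu, 0)
  # log-symmetric quartiles are matched exactly for any spread
  for (k in c(1.5, 3, 10)) {
    fit <- fit_lognormal_from_quartiles(biomarker_marginal(10, 10 / k, 10 * k))
    expect_equal(qlnorm(0.25, fit$mu, fit$sigma), 10 / k, tolerance = 1e-12)
    expect_equal(qlnorm(0.75, fit$mu, fit$sigma), 10 * k, tolerance = 1e-12)
    expect_false(fit$asymmetric)
  }
})

test_that("invalid marginals are rejected with the biomarker named", {
  expect_error(biomarker_marginal(5, 0, 10, name = "il6"), "il6")
  expect_error(biomarker_marginal(5, -1, 10, name = "tnfa"), "tnfa")
  expect_error(biomarker_marginal(5, 6, 10), "q1 <= median")
  expect_error(biomarker_marginal(5, 2, 10, lod = -1), "lod")
})

test_that("strongly log-asymmetric printed quartiles are flagged", {
  # GOLD I IL-6: q1 far below what any median-pinned log-normal can reach
  fit <- fit_lognormal_from_quartiles(biomarker_marginal(4.0, 0.4, 17.5))
  expect_true(fit$asymmetric)
})

test_that("Spearman-to-Pearson conversion matches the Gaussian-copula identity", {
  expect_identical(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1, tolerance = 1e-12)
  expect_equal(spearman_to_pearson(-1), -1, tolerance = 1e-12)
  expect_equal(spearman_to_pearson(0.51), 0.52774610, tolerance = 1e-7)
  grid <- seq(-1, 1, by = 0.05)
  out <- spearman_to_pearson(grid)
  expect_true(all(diff(out) > 0))          # monotone
  expect_true(all(abs(out) <= 1 + 1e-12))  # bounds preserved
  expect_error(spearman_to_pearson(1.2), "\\[-1, 1\\]")
})

test_that("correlation repair yields a valid correlation matrix", {
  bad <- matrix(0.99, 3, 3)
  bad[1, 3] <- bad[3, 1] <- -0.99  # wildly non-PSD
  expect_true(min(eigen(bad)$values) < 0)
  fixed <- nearest_correlation(bad)
  expect_true(min(eigen(fixed)$values) >= 0)
  expect_equal(diag(fixed), rep(1, 3))
  expect_equal(fixed, t(fixed))
})

test_that("detection-limit censoring follows its policy", {
  out <- apply_detection_limit(c(0.1, 5.0), lod = 0.70)
  expect_equal(as.numeric(out), c(0.70, 5.0))
  expect_identical(attr(out, "n_censored"), 1L)

  half <- apply_detection_limit(c(0.1, 5.0), lod = 0.70, policy = "half_lod")
  expect_equal(as.numeric(half), c(0.35, 5.0))

  none <- apply_detection_limit(c(0.1, 5.0), lod = 0)
  expect_equal(as.numeric(none), c(0.1, 5.0))
  expect_identical(attr(none, "n_censored"), 0L)
})

test_that("panel sampler recovers marginals and independence", {
  cal <- get_calibration()
  n <- 2000
  ident <- copula_spec(cal$biomarkers, diag(8))
  panel <- sample_biomarker_panel(ident, cal$overall_marginals, n, seed = 11)
  r <- spearman_matrix(panel, cal$biomarkers)$r
  offdiag <- r[upper.tri(r)]
  expect_true(all(abs(offdiag) < 3 / sqrt(n)))
  for (b in cal$biomarkers) {
    m <- cal$overall_marginals[[b]]
    fit <- fit_lognormal_from_quartiles(m)
    expect_equal(median(panel[[b]]), m$median, tolerance = 0.05)
    expect_equal(unname(quantile(panel[[b]], 0.25)),
                 qlnorm(0.25, fit$mu, fit$sigma), tolerance = 0.08)
    expect_equal(unname(quantile(panel[[b]], 0.75)),
                 qlnorm(0.75, fit$mu, fit$sigma), tolerance = 0.08)
  }
})

test_that("panel sampler hits the published rank-correlation target", {
  cal <- get_calibration()
  panel <- sample_biomarker_panel(cal$copula, cal$overall_marginals, 2000,
                                  seed = 11)
  r <- spearman_matrix(panel, cal$biomarkers)$r
  expect_lt(max(abs(r - cal$copula$spearman)), 0.03)
  # reproducibility for a fixed seed
  again <- sample_biomarker_panel(cal$copula, cal$overall_marginals, 2000,
                                  seed = 11)
  expect_identical(panel, again)
})

test_that("panel sampler validates its inputs", {
  cal <- get_calibration()
  expect_error(sample_biomarker_panel(cal$copula,
                                      cal$overall_marginals[1:3], 50, 1),
               "no marginal supplied")
  expect_error(copula_spec(c("a", "b"), matrix(c(1, 0.5, 0.4, 1), 2, 2)),
               "symmetric")
  expect_error(copula_spec(c("a", "b"), matrix(c(2, 0.5, 0.5, 2), 2, 2)),
               "unit diagonal")
})

test_that("generated cohorts are deterministic and match the stage mixture", {
  co <- make_cohort(2530, seed = 42)
  cal <- get_calibration()
  cfg <- cohort_config(2530, 42, cal$stage_profiles, cal$copula,
                       overall_marginals = cal$overall_marginals)
  expect_identical(co, generate_cohort(cfg))  # bit-identical under same seed

  frac <- as.numeric(table(factor(co$gold, 1:4))) / nrow(co) * 100
  expect_true(all(abs(frac - c(7, 29, 42, 23)) <= 2))

  expected_death <- sum(vapply(cal$stage_profiles,
                               function(p) p$n_frac * p$mortality_3y,
                               numeric(1)))
  expect_equal(mean(co$dead_3y), expected_death, tolerance = 0.10)

  # schema: every mandatory analysis column present, BODE consistent
  expect_true(all(c("id", "gold", "fev1_l", "bode", "dead_3y",
                    cal$biomarkers) %in% names(co)))
  expect_equal(co$bode,
               compute_bode(co$fev1_pct, co$smwd, co$mmrc, co$bmi))
})

test_that("a stage with zero mixture weight warns instead of failing", {
  cal <- get_calibration()
  profs <- cal$stage_profiles
  profs[[1]]$n_frac <- 0
  profs[[2]]$n_frac <- profs[[2]]$n_frac + cal$stage_profiles[[1]]$n_frac
  cfg <- cohort_config(20, 5, profs, cal$copula,
                       overall_marginals = cal$overall_marginals)
  expect_warning(co <- generate_cohort(cfg), "GOLD stage")
  expect_equal(nrow(co), 20)
})

test_that("stage-linked coupling gives the published association signs", {
  co <- make_cohort(2000, seed = 3)
  sp <- function(a, b) cor(co[[a]], co[[b]], method = "spearman")
  # markers whose medians rise with stage track worse disease
  for (b in c("il6", "tnfa")) {
    expect_gt(sp(b, "bode"), 0)
    expect_lt(sp(b, "fev1_pct"), 0)
  }
  # injury-and-repair markers fall with stage: signs flip
  for (b in c("mmp9", "vegf")) {
    expect_lt(sp(b, "bode"), 0)
    expect_gt(sp(b, "fev1_pct"), 0)
  }
})

test_that("independent coupling decouples biomarkers from outcomes", {
  co <- make_cohort(2000, seed = 3, coupling = "independent")
  r <- abs(cor(co$il6, co$bode, method = "spearman"))
  expect_lt(r, 0.08)
})

test_that("detection limits floor the generated panel", {
  co <- make_cohort(2000, seed = 3)
  cal <- get_calibration()
  for (b in cal$biomarkers) {
    expect_true(all(co[[b]] >= cal$lod[[b]]))
  }
  # the uncensored world can dip below LOD (sub-LOD published quartiles)
  raw <- make_cohort(2000, seed = 3, lod_policy = "none")
  expect_true(any(raw$il6 < cal$lod[["il6"]]))
})
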