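test_that("identical phantom specs give bit-identical output", {
  sp <- phantomSpec(grid_shape = c(48, 48, 48), seed = 11)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(a$volume@values, b$volume@values)
  expect_identical(a$tumor@values, b$tumor@values)
  expect_identical(a$truth$centerlines, b$truth$centerlines)
})

test_that("degenerate texture settings give a perfectly uniform tumor", {
  ph <- generatePhantom(phantomSpec(grid_shape = c(48, 48, 48),
                                    heterogeneity = 0, noise_sd = 0,
                                    seed = 2))
  tv <- ph$volume@values[ph$tumor@values]
  expect_equal(length(unique(tv)), 1L)
})

test_that("phantom masks are coherent: tumor connected, lung encloses all", {
  ph <- generatePhantom(phantomSpec(grid_shape = c(48, 48, 48), seed = 3))
  lab <- periSurv:::.label_components(ph$tumor@values, 26L)
  expect_equal(max(lab), 1L)
  expect_true(all(ph$lung@values[ph$tumor@values]))
  expect_true(all(ph$lung@values[ph$truth$vessel_mask@values]))
})

test_that("a tumor crossing the grid boundary is rejected with a bounds message", {
  expect_error(phantomSpec(grid_shape = c(24, 24, 24),
                           tumor_center_mm = c(2, 12, 12),
                           tumor_radius_mm = 8),
               "bounds")
})

test_that("zero tortuosity gives straight centerlines with zero curvature", {
  ph <- generatePhantom(phantomSpec(grid_shape = c(48, 48, 48),
                                    tortuosity = 0, seed = 4))
  expect_true(all(ph$truth$curvature == 0))
  for (cl in ph$truth$centerlines) {
    g <- branchGeometry(cl)
    expect_lt(g$mean_curvature, 1e-8)
    expect_equal(g$straightness, 1, tolerance = 1e-9)
  }
})

test_that("helix branches match closed-form Frenet geometry", {
  # a = 5, b = 2: curvature 5/29, torsion 2/29 per mm
  h <- generateVesselBranch(c(0, 0, 0), c(0, 0, 1), 60, 5, 2)
  steps <- sqrt(rowSums(diff(h)^2))
  expect_true(all(steps <= 0.5 + 1e-9))
  g <- branchGeometry(h)
  expect_equal(g$mean_curvature, 5 / 29, tolerance = 0.05)
  expect_equal(g$mean_torsion, 2 / 29, tolerance = 0.05)
  # independent finite-difference oracle on the raw sampled points
  fr <- oracle_frenet(h)
  expect_equal(median(fr$kappa), 5 / 29, tolerance = 0.02)
  expect_equal(median(fr$tau), 2 / 29, tolerance = 0.02)

  # a = 0: straight line
  s <- generateVesselBranch(c(1, 2, 3), c(1, 1, 0), 20, 0, 1)
  gs <- branchGeometry(s)
  expect_lt(gs$mean_curvature, 1e-9)
  expect_equal(gs$mean_torsion, 0, tolerance = 1e-9)

  # b -> 0 limit: planar circle, torsion ~ 0, curvature ~ 1/a
  p <- generateVesselBranch(c(0, 0, 0), c(0, 0, 1), 25, 5, 0.01)
  gp <- branchGeometry(p)
  expect_lt(gp$mean_torsion, 0.005)
  expect_equal(gp$mean_curvature, 1 / 5, tolerance = 0.05)

  expect_error(generateVesselBranch(c(0, 0, 0), c(0, 0, 1), -3, 1, 1),
               "positive")
  expect_error(generateVesselBranch(c(0, 0, 0), c(0, 0, 1), 10, 2, 0),
               "pitch")
})

test_that("clinical table reproduces the cohort marginals", {
  tab <- generateClinicalTable(10000, seed = 5)
  expect_equal(mean(tab$smoking == "smoker"), 0.568, tolerance = 0.03)
  expect_equal(mean(tab$stage == "IVB"), 0.587, tolerance = 0.03)
  expect_equal(mean(tab$sex == "female"), 0.316, tolerance = 0.05)
  expect_equal(mean(tab$histology == "adenocarcinoma"), 0.713,
               tolerance = 0.03)
  expect_equal(mean(tab$total_protein == "high"), 0.981, tolerance = 0.01)
  expect_equal(mean(tab$mcv == "normal"), 0.913, tolerance = 0.02)
  expect_equal(median(tab$age), 62.2, tolerance = 1)
})

test_that("clinical table is deterministic, validates marginals, handles n = 1", {
  expect_identical(generateClinicalTable(50, seed = 7),
                   generateClinicalTable(50, seed = 7))
  one <- generateClinicalTable(1, seed = 8)
  expect_equal(nrow(one), 1L)
  expect_true(all(!is.na(unlist(one))))
  bad <- clinicalMarginals()
  bad$sex <- c(female = 0.4, male = 0.4)
  expect_error(generateClinicalTable(10, marginals = bad), "sum to 1")
})

test_that("survival generator honours censoring settings", {
  o0 <- generateSurvival(rnorm(200), censoring_rate = 0, seed = 9)
  expect_true(all(o0$event == 1))
  o3 <- generateSurvival(rnorm(2000), censoring_rate = 0.3, seed = 10)
  # binomial sampling error around the target event fraction
  expect_equal(mean(o3$event), 0.7, tolerance = 3 * sqrt(0.21 / 2000) + 0.02)
  expect_error(generateSurvival(rnorm(5), censoring_rate = 1.2),
               "censoring_rate")
  expect_identical(generateSurvival(rep(0, 20), seed = 3),
                   generateSurvival(rep(0, 20), seed = 3))
})

test_that("univariate Cox recovers a planted hazard ratio of 2", {
  covered <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    x <- rbinom(500, 1, 0.5)
    o <- generateSurvival(log(2) * x, censoring_rate = 0.25,
                          seed = 200 + r)
    fit <- univariateCox(x, o)
    ci_lo <- exp(fit$beta - 1.96 * fit$se)
    ci_hi <- exp(fit$beta + 1.96 * fit$se)
    if (ci_lo <= 2 && 2 <= ci_hi) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.9)
})

test_that("fitting Cox to the true linear predictor recovers coefficient 1", {
  coh <- generateCohort(500, seed = 12)
  fit <- univariateCox(coh$truth$lp, coh$outcome)
  expect_equal(fit$beta, 1, tolerance = 0.15)
})

test_that("cohort generator is deterministic and carries ground truth", {
  a <- generateCohort(60, seed = 13)
  b <- generateCohort(60, seed = 13)
  expect_identical(a$features, b$features)
  expect_identical(a$outcome, b$outcome)
  expect_equal(length(a$truth$lp), 60L)
  expect_true(all(c("tumor_volume_cm3", "tumor_heterogeneity",
                    "vessel_mean_torsion", "total_protein", "mcv")
                  %in% names(a$features)))
})

test_that("measured branch torsion increases with the tortuosity parameter", {
  levels <- c(0.5, 1, 2)
  n_per <- 8
  level_means <- vapply(levels, function(tort) {
    vals <- vapply(seq_len(n_per), function(s) {
      ph <- generatePhantom(phantomSpec(tortuosity = tort,
                                        seed = 7000 + s))
      tr <- extractCenterlines(ph$truth$vessel_mask)
      taus <- vapply(branches(tr), function(b) {
        g <- tryCatch(branchGeometry(b, smoothing_mm = 1.5),
                      error = function(e) NULL)
        if (is.null(g) || is.na(g$mean_torsion)) NA_real_
        else g$mean_torsion
      }, numeric(1))
      mean(taus, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(cor(level_means, levels, method = "spearman"), 1)
})
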