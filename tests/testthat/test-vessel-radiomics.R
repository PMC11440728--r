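# rasterize a tube along a segment into an existing logical array
seg_tube <- function(m, p0, p1, radius, spacing = c(1, 1, 1)) {
  n <- ceiling(sqrt(sum((p1 - p0)^2)) / 0.4) + 1
  for (t in seq(0, 1, length.out = n))
    m <- periSurv:::.rasterize_tube(m, matrix(p0 + t * (p1 - p0), 1),
                                    radius, spacing)
  m
}

test_that("vesselness is zero on uniform volumes and peaks on the tube axis", {
  expect_equal(max(abs(vesselness(imageVolume(array(3, c(10, 10, 10))),
                                  2)@values)), 0)
  v <- array(0, c(40, 20, 20))
  m <- seg_tube(array(FALSE, c(40, 20, 20)), c(3, 10, 10), c(37, 10, 10), 3)
  v[m] <- 1
  resp <- vesselness(imageVolume(v), scales_mm = c(1, 2, 3, 4, 5))
  rv <- resp@values
  expect_true(all(rv >= 0 & rv <= 1))
  # axis voxels outrank voxels > 2 radii off-axis everywhere along the tube
  for (x in 10:30)
    expect_gt(rv[x, 10, 10], rv[x, 17, 17])
})

test_that("the per-voxel best scale matches the tube radius", {
  v <- array(0, c(40, 24, 24))
  m <- seg_tube(array(FALSE, c(40, 24, 24)), c(3, 12, 12), c(37, 12, 12), 3)
  v[m] <- 1
  scales <- c(1, 2, 3, 4, 5)
  # brute-force scale sweep at the axis
  per_scale <- vapply(scales, function(s)
    mean(periSurv:::.frangi_single_scale(v, c(1, 1, 1), s, 0.5, 0.5,
                                         NULL)[15:25, 12, 12]),
    numeric(1))
  expect_lte(abs(scales[which.max(per_scale)] - 3), 1)
})

test_that("Otsu threshold maximizes between-class variance", {
  x <- c(rep(0.1, 40), rep(0.9, 60))
  thr <- otsuThreshold(x)
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  set.seed(5)
  y <- c(rnorm(400, 0, 0.5), rnorm(300, 6, 0.5))
  thr2 <- otsuThreshold(y)
  # exhaustive search over candidate thresholds on the same 256-bin grid
  edges <- seq(min(y), max(y), length.out = 257)
  bcv <- vapply(edges[2:256], function(cand) {
    lo <- y[y <= cand]; hi <- y[y > cand]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) / length(y) * length(hi) / length(y) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  best <- edges[2:256][which.max(bcv)]
  expect_lt(abs(thr2 - best), diff(range(y)) / 256 + 1e-9)
  expect_equal(otsuThreshold(sample(y)), thr2)
  expect_error(otsuThreshold(rep(2, 10)), "constant")
})

test_that("morphological cleanup removes speckles but keeps tubes intact", {
  m <- array(FALSE, c(30, 20, 20))
  m <- seg_tube(m, c(3, 10, 10), c(27, 10, 10), 2.5)
  tube_vox <- sum(m)
  set.seed(6)
  speck <- m
  ones <- sample(which(!speck), 15)
  speck[ones] <- TRUE
  cl <- morphologicalCleanup(roiMask(speck), min_component_voxels = 27,
                             opening_radius_mm = 1)
  expect_false(any(cl@values[ones]))
  expect_gt(sum(cl@values & m), 0.5 * tube_vox)
  # 2-voxel appendage sticking out of the tube end: removed, tube kept
  app <- seg_tube(array(FALSE, c(30, 20, 20)), c(3, 10, 10),
                  c(20, 10, 10), 2.5)
  app[25, 11, 11] <- TRUE; app[26, 11, 11] <- TRUE
  cl2 <- morphologicalCleanup(roiMask(app), 10, 1)
  expect_false(cl2@values[26, 11, 11])
  expect_gt(sum(cl2@values), 100)
  # empty in, empty out with flag
  cle <- morphologicalCleanup(roiMask(array(FALSE, c(5, 5, 5))))
  expect_true(attr(cle, "empty"))
})

test_that("the peritumoral cube extends the tumor bbox by 25 mm, clipped", {
  m <- array(FALSE, c(100, 100, 100))
  m[41:61, 41:61, 41:61] <- TRUE   # bbox [40, 60] mm at 1 mm spacing
  cb <- peritumoralCube(roiMask(m))
  expect_equal(cb$lo, c(16, 16, 16))   # 15 mm in 0-based = index 16
  expect_equal(cb$hi, c(86, 86, 86))
  m2 <- array(FALSE, c(30, 30, 30)); m2[1:5, 1:5, 1:5] <- TRUE
  cb2 <- peritumoralCube(roiMask(m2))
  expect_equal(cb2$lo, c(1, 1, 1))
  cb3 <- peritumoralCube(roiMask(m), extension_mm = 0)
  expect_equal(cb3$lo, c(41, 41, 41)); expect_equal(cb3$hi, c(61, 61, 61))
  expect_error(peritumoralCube(roiMask(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("a straight tube skeletonizes to one axial branch with correct radius", {
  m <- seg_tube(array(FALSE, c(40, 15, 15)), c(4, 7, 7), c(36, 7, 7), 3)
  tr <- extractCenterlines(roiMask(m))
  expect_equal(length(branches(tr)), 1L)
  b <- branches(tr)[[1]]
  expect_true(all(abs(b[, 2] - 7) <= 1))
  expect_true(all(abs(b[, 3] - 7) <= 1))
  expect_equal(mean(branchRadii(tr)[[1]]), 3, tolerance = 0.7 / 3)
  expect_equal(nrow(junctions(tr)), 0L)
})

test_that("a Y-shaped tube yields 3 branches and 1 junction", {
  m <- array(FALSE, c(40, 40, 13))
  m <- seg_tube(m, c(5, 20, 6), c(20, 20, 6), 2)
  m <- seg_tube(m, c(20, 20, 6), c(33, 30, 6), 2)
  m <- seg_tube(m, c(20, 20, 6), c(33, 10, 6), 2)
  tr <- extractCenterlines(roiMask(m))
  expect_equal(length(branches(tr)), 3L)
  expect_equal(nrow(junctions(tr)), 1L)
  # empty input gives an empty, flagged tree
  tre <- extractCenterlines(roiMask(array(FALSE, c(6, 6, 6))))
  expect_true(attr(tre, "empty"))
  expect_equal(length(branches(tre)), 0L)
})

test_that("branch geometry matches closed forms on analytic curves", {
  pts <- cbind(seq(0, 20, 0.5), seq(0, 20, 0.5) * 2, seq(0, 20, 0.5) * 0.5)
  g <- branchGeometry(pts)
  expect_lt(g$mean_curvature, 1e-9)
  expect_equal(g$mean_torsion, 0, tolerance = 1e-9)
  expect_equal(g$straightness, 1)
  # planar arc radius 10: curvature 0.1, torsion ~ 0
  t <- seq(0, 1.8 * pi / 2, length.out = 60)
  arcp <- cbind(10 * cos(t), 10 * sin(t), rep(2, 60))
  ga <- branchGeometry(arcp)
  expect_equal(ga$mean_curvature, 0.1, tolerance = 0.05)
  expect_lt(ga$mean_torsion, 0.005)
  expect_error(branchGeometry(pts[1:2, ]), "too-short")
})

test_that("the vessel feature vector always has 91 entries (61 + 30)", {
  man <- vesselManifest()
  expect_equal(nrow(man), 91L)
  expect_equal(sum(man$block == "morphology"), 61L)
  expect_equal(sum(man$block == "organization"), 30L)
  # empty tree: all zero, flagged
  tre <- extractCenterlines(roiMask(array(FALSE, c(6, 6, 6))))
  fe <- extractVesselFeatures(tre, 1000)
  expect_equal(length(fe), 91L)
  expect_true(all(fe == 0))
  expect_true(attr(fe, "empty"))
  # single straight branch
  m <- seg_tube(array(FALSE, c(40, 15, 15)), c(4, 7, 7), c(36, 7, 7), 3)
  tr <- extractCenterlines(roiMask(m))
  fv <- extractVesselFeatures(tr, 40 * 15 * 15)
  expect_equal(length(fv), 91L)
  expect_identical(names(fv), man$name)
  expect_equal(unname(fv["org_branch_count"]), 1)
  expect_equal(unname(fv["org_junction_count"]), 0)
  expect_lt(fv["morph_mean_curvature_mean"], 0.02)
})

test_that("vessel features are invariant under rigid phantom translation", {
  sh <- c(4, 8, 3)   # integer shift, both tubes well inside the grid
  base <- array(FALSE, c(46, 46, 22))
  a <- seg_tube(base, c(6, 10, 8), c(20, 14, 10), 2.5)
  a <- seg_tube(a, c(20, 14, 10), c(30, 22, 12), 2.5)
  b <- array(FALSE, c(46, 46, 22))
  b <- seg_tube(b, c(6, 10, 8) + sh, c(20, 14, 10) + sh, 2.5)
  b <- seg_tube(b, c(20, 14, 10) + sh, c(30, 22, 12) + sh, 2.5)
  fa <- extractVesselFeatures(extractCenterlines(roiMask(a)), 1e4)
  fb <- extractVesselFeatures(extractCenterlines(roiMask(b)), 1e4)
  expect_equal(unname(fa), unname(fb), tolerance = 1e-6)
})

test_that("lung fallback recovers the phantom lung and honours bypass", {
  ph <- generatePhantom(phantomSpec(seed = 31))
  vol <- zscoreStandardize(ph$volume)
  lm <- lungMaskFallback(vol, ph$tumor)
  gt <- ph$lung@values
  dice <- 2 * sum(lm@values & gt) / (sum(lm@values) + sum(gt))
  expect_gte(dice, 0.95)
  # externally supplied mask short-circuits the fallback
  seg <- segmentVessels(vol, ph$tumor, lung_mask = ph$lung)
  expect_identical(seg$lung_mask@values, ph$lung@values)
  expect_error(lungMaskFallback(imageVolume(array(0.5, c(8, 8, 8)))),
               "constant|lung")
})

test_that("high-tortuosity phantoms score higher mean torsion than low", {
  lo_vals <- hi_vals <- numeric(0)
  for (s in 1:3) {
    pl <- generatePhantom(phantomSpec(tortuosity = 0.3, seed = 300 + s))
    phh <- generatePhantom(phantomSpec(tortuosity = 1.8, seed = 300 + s))
    fl <- extractVesselRadiomics(zscoreStandardize(pl$volume), pl$tumor)
    fh <- extractVesselRadiomics(zscoreStandardize(phh$volume), phh$tumor)
    lo_vals <- c(lo_vals, fl["morph_mean_torsion_mean"])
    hi_vals <- c(hi_vals, fh["morph_mean_torsion_mean"])
  }
  expect_gt(mean(hi_vals), mean(lo_vals))
})

test_that("the outlier filter uses reference statistics and a strict 20% rule", {
  set.seed(7)
  n <- 100
  ref <- 1:60
  tab <- data.frame(ok = rnorm(n), shifted = rnorm(n), boundary = rnorm(n),
                    flat = rep(1, n))
  # 25% of ALL rows pushed 10 reference-SDs out
  out_rows <- 61:85
  tab$shifted[out_rows] <- tab$shifted[out_rows] + 10
  # exactly 20% outliers: kept (strictly "exceeding")
  tab$boundary[81:100] <- 50
  res <- outlierFilter(tab, reference_rows = ref)
  expect_true("ok" %in% res$kept)
  expect_false("shifted" %in% res$kept)
  expect_true("boundary" %in% res$kept)
  expect_false("flat" %in% res$kept)   # zero reference SD
  expect_true("zero reference SD" %in% res$report$reason)
  frac <- res$report$fraction[res$report$feature == "shifted"]
  expect_equal(frac, 0.25)
})
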