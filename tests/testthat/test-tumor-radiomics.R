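test_that("the feature manifest has 593 entries with the right subtotals", {
  m <- intratumoralManifest()
  expect_equal(nrow(m), 593L)
  expect_equal(anyDuplicated(m$name), 0L)
  tab <- table(m$family)
  expect_equal(as.vector(tab[c("histogram", "glcm", "glrlm", "lbp")]),
               c(9 * 14, 9 * 22, 9 * 11, 9 * 17))
  expect_equal(as.vector(tab["geometry"]), 17L)
  expect_true(all(m$image_set[m$family == "geometry"] == "n/a"))
})

test_that("quantization is an identity on already-integer ranges", {
  x <- rep(0:63, 2)
  expect_equal(quantize(x, 64), rep(1:64, 2))
  expect_equal(unique(quantize(rep(3.3, 10), 64)), 1L)
  # bin counts agree with a direct histogram
  set.seed(1)
  y <- runif(500)
  q <- quantize(y, 16)
  br <- seq(min(y), max(y), length.out = 17)
  hh <- hist(y, breaks = br, plot = FALSE, include.lowest = TRUE)$counts
  expect_equal(tabulate(q, 16), hh)
})

test_that("histogram features match hand computation", {
  v <- array(0, c(4, 1, 1)); v[] <- c(1, 2, 3, 4)
  m <- array(TRUE, c(4, 1, 1))
  f <- histogramFeatures(v, m)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["variance"]), 1.25)   # population convention
  expect_equal(unname(f["min"]), 1)
  expect_equal(unname(f["range"]), 3)
  expect_equal(unname(f["energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["skewness"]), 0, tolerance = 1e-9)
  # constant region conventions
  vc <- array(5, c(3, 3, 3))
  fc <- histogramFeatures(vc, array(TRUE, c(3, 3, 3)))
  expect_equal(unname(fc[c("variance", "entropy", "skewness", "kurtosis")]),
               c(0, 0, 0, 0))
  expect_error(histogramFeatures(v, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("geometry features match analytic solids", {
  cb <- array(FALSE, c(14, 14, 14)); cb[3:12, 3:12, 3:12] <- TRUE
  g <- geometryFeatures(roiMask(cb))
  expect_equal(unname(g["volume_mm3"]), 1000)
  expect_equal(unname(g["extent_x_mm"]), 10)
  expect_equal(unname(g["bbox_fill_fraction"]), 1)

  # digitized ball radius 10 mm: sphericity within 5% of 1
  n <- 27; ctr <- rep((n + 1) / 2, 3)
  a <- array(FALSE, c(n, n, n))
  idx <- which(a | TRUE, arr.ind = TRUE)
  a[] <- colSums((t(idx) - ctr)^2) <= 100
  gb <- geometryFeatures(roiMask(a))
  expect_equal(unname(gb["sphericity"]), 1, tolerance = 0.05)
  expect_equal(unname(gb["volume_mm3"]), 4 / 3 * pi * 1000,
               tolerance = 0.02)
  expect_equal(unname(gb["max_diameter_3d_mm"]), 20, tolerance = 0.10)
  expect_equal(unname(gb["elongation"]), 1, tolerance = 0.02)

  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  gs <- geometryFeatures(roiMask(sv, spacing = c(1, 2, 3)))
  expect_equal(unname(gs["volume_mm3"]), 6)
  expect_equal(unname(gs["max_diameter_3d_mm"]), sqrt(1 + 4 + 9))
})

test_that("GLCM equals exhaustive pair enumeration and normalizes to 1", {
  set.seed(2)
  q <- array(sample(1:4, 5^3, TRUE), c(5, 5, 5))
  q[sample(125, 30)] <- NA   # irregular mask
  P <- glcmMatrix(q, 4)
  expect_equal(sum(P), 1, tolerance = 1e-12)
  O <- oracle_glcm(q, 4, periSurv:::.directions13())
  expect_equal(P, O, tolerance = 1e-12)
  # 3D checkerboard of two levels
  chk <- array(1L, c(4, 4, 4))
  idx <- which(chk == 1, arr.ind = TRUE)
  chk[] <- 1L + (rowSums(idx) %% 2L)
  Pc <- glcmMatrix(chk, 2)
  Oc <- oracle_glcm(chk, 2, periSurv:::.directions13())
  expect_equal(Pc, Oc, tolerance = 1e-12)
})

test_that("GLCM features behave on degenerate input", {
  vc <- array(1, c(4, 4, 4))
  f <- glcmFeatures(vc, array(TRUE, c(4, 4, 4)), n_bins = 8)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["correlation"]), 1)
  expect_equal(length(f), 22L)
})

test_that("GLRLM equals direct run scanning in every direction", {
  set.seed(3)
  q <- array(sample(1:3, 4^3, TRUE), c(4, 4, 4))
  q[sample(64, 12)] <- NA
  dirs <- periSurv:::.directions13()
  for (r in seq_len(nrow(dirs))) {
    R <- glrlmMatrix(q, dirs[r, ], 3)
    O <- oracle_glrlm(q, dirs[r, ], 3)
    # pad to common width
    w <- max(ncol(R), ncol(O))
    Rp <- cbind(R, matrix(0, nrow(R), w - ncol(R)))
    Op <- cbind(O, matrix(0, nrow(O), w - ncol(O)))
    expect_equal(Rp, Op, tolerance = 1e-12)
  }
})

test_that("GLRLM features capture run structure", {
  # constant line: single run of length L, LRE = L^2
  ln <- array(1L, c(6, 1, 1))
  R <- glrlmMatrix(ln, c(1, 0, 0), 2)
  f <- periSurv:::.glrlm_features_from_matrix(R, 6)
  expect_equal(unname(f["lre"]), 36)
  expect_equal(unname(f["rp"]), 1 / 6)
  # strictly alternating line: all runs length 1, SRE = 1
  alt <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  fa <- periSurv:::.glrlm_features_from_matrix(
    glrlmMatrix(alt, c(1, 0, 0), 2), 8)
  expect_equal(unname(fa["sre"]), 1)
  expect_equal(unname(fa["rp"]), 1)
})

test_that("LBP codes equal per-voxel enumeration; histogram sums to 1", {
  set.seed(4)
  v <- array(rnorm(6^3), c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  f <- lbpFeatures(v, m)
  expect_equal(sum(f[1:16]), 1, tolerance = 1e-12)
  cnt <- oracle_lbp_counts(v, m)
  bins <- pmin(floor(cnt * 16 / 27) + 1, 16)
  expect_equal(unname(f[1:16]), tabulate(bins, 16) / length(bins),
               tolerance = 1e-12)
  # monotone ramp: interior voxels all see 13 greater neighbors
  rv <- array(as.numeric(1:216), c(6, 6, 6))
  fr <- lbpFeatures(rv, m)
  expect_equal(unname(fr[floor(13 * 16 / 27) + 1]), 1)
  # constant: all mass in bin 1, zero entropy
  fc <- lbpFeatures(array(1, c(5, 5, 5)), array(TRUE, c(5, 5, 5)))
  expect_equal(unname(fc["bin_01"]), 1)
  expect_equal(unname(fc["entropy"]), 0)
  expect_error(lbpFeatures(v, array(FALSE, c(6, 6, 6))), "interior")
})

test_that("the intratumoral extractor returns 593 finite named features", {
  ph <- generatePhantom(phantomSpec(grid_shape = c(48, 48, 48),
                                    tumor_radius_mm = 7, seed = 21))
  vol <- zscoreStandardize(ph$volume)
  fv <- extractIntratumoral(vol, ph$tumor)
  expect_equal(length(fv), 593L)
  expect_identical(names(fv), intratumoralManifest()$name)
  expect_true(all(is.finite(fv)))
  fv2 <- extractIntratumoral(vol, ph$tumor)
  expect_identical(fv, fv2)
})

test_that("heterogeneity changes texture but not geometry for a fixed mask", {
  base <- phantomSpec(grid_shape = c(48, 48, 48), tumor_radius_mm = 7,
                      heterogeneity = 0.05, noise_sd = 0, seed = 22)
  hi <- phantomSpec(grid_shape = c(48, 48, 48), tumor_radius_mm = 7,
                    heterogeneity = 0.6, noise_sd = 0, seed = 22)
  fa <- extractIntratumoral(zscoreStandardize(generatePhantom(base)$volume),
                            generatePhantom(base)$tumor)
  fb <- extractIntratumoral(zscoreStandardize(generatePhantom(hi)$volume),
                            generatePhantom(hi)$tumor)
  geom <- grepl("^geometry_", names(fa))
  expect_equal(fa[geom], fb[geom], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fa[!geom], fb[!geom])))
})

test_that("intensity features are invariant under ROI translation", {
  set.seed(23)
  patch <- array(rnorm(6^3), c(6, 6, 6))
  v1 <- array(0, c(20, 20, 20)); m1 <- array(FALSE, c(20, 20, 20))
  v1[3:8, 3:8, 3:8] <- patch; m1[3:8, 3:8, 3:8] <- TRUE
  v2 <- array(0, c(20, 20, 20)); m2 <- array(FALSE, c(20, 20, 20))
  v2[11:16, 12:17, 10:15] <- patch; m2[11:16, 12:17, 10:15] <- TRUE
  f1 <- extractIntratumoral(imageVolume(v1), roiMask(m1))
  f2 <- extractIntratumoral(imageVolume(v2), roiMask(m2))
  intensity <- !grepl("^geometry_", names(f1))
  expect_equal(f1[intensity], f2[intensity], tolerance = 1e-9)
})
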