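test_that("phenotype presets carry the cohort mean outcome targets", {
  h <- phantomPreset("healthy")
  expect_equal(h@ccRatio, 1.72)
  expect_equal(h@areaRatio, 2.54)
  expect_equal(h@ccApRatio, 1.38)
  expect_equal(h@daRatio, 0.91)
  expect_equal(h@dhRatio, 0.82)
  expect_equal(h@postDisplacementMM, 70.7)
  n <- phantomPreset("normal_spiro_pompe")
  expect_equal(c(n@ccRatio, n@areaRatio, n@ccApRatio, n@daRatio, n@dhRatio,
                 n@postDisplacementMM), c(1.60, 2.57, 1.22, 1.34, 1.08, 70.6))
  d <- phantomPreset("decreased_spiro_pompe")
  expect_equal(c(d@ccRatio, d@areaRatio, d@ccApRatio, d@daRatio, d@dhRatio,
                 d@postDisplacementMM), c(1.32, 1.95, 1.04, 1.79, 1.41, 35.6))
  expect_equal(phantomPreset("severe")@ccRatio, 1.0)
  expect_error(phantomPreset("mild"))
})

test_that("power-dome fullness solve is exact and range-checked", {
  for (F in c(0.1, 0.35, 2 / 3, 0.9)) {
    m <- diaphragmotion:::powerDomeExponent(F)
    expect_equal(diaphragmotion:::powerDomeFullness(m), F, tolerance = 1e-9)
  }
  expect_equal(diaphragmotion:::powerDomeExponent(2 / 3), 1, tolerance = 1e-6)
  expect_error(diaphragmotion:::powerDomeExponent(0.97), "fullness")
  # shape-level: polygon area matches the closed-form lung area
  xy <- diaphragmotion:::buildLungPolygon(100, 150, 30, 0.5, 0.9, 400L)
  expect_equal(abs(polygonArea(xy)),
               diaphragmotion:::lungPolygonArea(100, 150, 30, 0.5, 0.9),
               tolerance = 0.002)
})

test_that("inconsistent phantom targets error rather than silently clamp", {
  expect_error(phantomParams(daRatio = 3.5), "fullness")
  expect_error(phantomParams(areaRatio = 5), "cap fraction")
  expect_error(phantomParams(postDisplacementMM = 5), "displacement")
  expect_error(phantomParams(domeHeightExpMM = 130), "dome height")
})

test_that("unit-ratio parameters give a motionless ground truth and pipeline", {
  p <- phantomParams(ccRatio = 1, ccApRatio = 1, areaRatio = 1, daRatio = 1,
                     dhRatio = 1, postDisplacementMM = 3, nFrames = 4L)
  ph <- generatePhantomSeries(p)
  expect_equal(unlist(ph$truth[c("cc_ratio", "ap_ratio", "cc_ap_ratio",
                                 "area_ratio", "da_ratio", "dh_ratio")]),
               rep(1, 6), ignore_attr = TRUE)
  m <- measureSeries(ph$series)
  expect_equal(m$record$cc_ratio, 1, tolerance = 1e-6)
  expect_equal(m$record$da_ratio, 1, tolerance = 1e-6)
})

test_that("pipeline on exact polygons recovers analytic truth within 0.5%", {
  for (ps in c("healthy", "normal_spiro_pompe", "decreased_spiro_pompe",
               "severe")) {
    ph <- generatePhantomSeries(phantomPreset(ps, nFrames = 7L))
    m <- measureSeries(ph$series)$record
    for (nm in c("cc_ratio", "ap_ratio", "cc_ap_ratio", "area_ratio",
                 "da_ratio", "dh_ratio", "ant_displacement_mm",
                 "post_displacement_mm"))
      expect_equal(m[[nm]], ph$truth[[nm]], tolerance = 0.005,
                   info = paste(ps, nm))
  }
})

test_that("pipeline on 1 mm rasterized masks tracks truth to the
           discretization floor", {
  # per series: 2% for extent/area/displacement outcomes; DA/DH ratios are
  # limited by half-pixel quantization of the flat chord and apex levels
  # (worst case (h_i -+ 0.7)/(h_e +- 0.7) ~ 7% on 25-40 mm heights), so
  # they are asserted at 7.5% per series and 1.5% on the mean over grid
  # phases
  daErr <- dhErr <- numeric(0)
  for (i in 1:10) {
    ps <- c("healthy", "decreased_spiro_pompe")[(i %% 2) + 1]
    ph <- generatePhantomSeries(phantomPreset(ps, nFrames = 5L,
                                              jitterSdMM = 0.25,
                                              seed = 40 + i),
                                output = "mask")
    m <- measureSeries(ph$series)$record
    for (nm in c("cc_ratio", "ap_ratio", "cc_ap_ratio", "area_ratio"))
      expect_equal(m[[nm]], ph$truth[[nm]], tolerance = 0.02,
                   info = paste(i, nm))
    for (nm in c("ant_displacement_mm", "post_displacement_mm"))
      expect_lt(abs(m[[nm]] - ph$truth[[nm]]), 1.0)
    daErr <- c(daErr, m$da_ratio / ph$truth$da_ratio - 1)
    dhErr <- c(dhErr, m$dh_ratio / ph$truth$dh_ratio - 1)
  }
  expect_lt(max(abs(daErr)), 0.075)
  expect_lt(max(abs(dhErr)), 0.075)
  expect_lt(abs(mean(daErr)), 0.015)
  expect_lt(abs(mean(dhErr)), 0.015)
})

test_that("identical seeds reproduce identical phantoms and cohorts", {
  p <- phantomPreset("healthy", nFrames = 5L, jitterSdMM = 0.4, seed = 9L)
  a <- generatePhantomSeries(p, output = "mask")
  b <- generatePhantomSeries(p, output = "mask")
  expect_identical(lapply(a$masks, methods::slot, "pixels"),
                   lapply(b$masks, methods::slot, "pixels"))
  spec <- cohortSpec(groups = data.frame(label = "healthy", n = 3L,
                                         preset = "healthy"))
  c1 <- generateCohort(spec, seed = 5, nFrames = 3L)
  c2 <- generateCohort(spec, seed = 5, nFrames = 3L)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$series, contours), lapply(c2$series, contours))
  c3 <- generateCohort(spec, seed = 6, nFrames = 3L)
  expect_false(identical(c1$metadata, c3$metadata))
})

test_that("cohort draws respect group means within sampling error", {
  spec <- cohortSpec(groups = data.frame(
    label = c("healthy", "decreased_spiro_pompe"), n = c(20L, 20L),
    preset = c("healthy", "decreased_spiro_pompe")))
  ch <- generateCohort(spec, seed = 11, nFrames = 2L)
  sdCC <- sqrt(sum(spec@betweenSubjectSd[c("latent", "cc")]^2))
  mh <- mean(ch$truth$cc_ratio[ch$truth$group == "healthy"])
  md <- mean(ch$truth$cc_ratio[ch$truth$group == "decreased_spiro_pompe"])
  expect_lt(abs(mh - 1.72), 3 * sdCC / sqrt(20) + 0.01)  # +0.01 truncation
  expect_lt(abs(md - 1.32), 3 * sdCC / sqrt(20) + 0.01)
  expect_gt(mh, md)
  # metadata is internally consistent
  expect_equal(ch$metadata$delta_fvc_pct,
               ch$metadata$fvc_upright_pct - ch$metadata$fvc_supine_pct,
               tolerance = 1e-9)
})

test_that("measured CC ratio correlates strongly with simulated supine FVC", {
  ch <- generateCohort(seed = 3, nFrames = 5L)
  expect_equal(nrow(ch$metadata), 53)
  mo <- measureCohort(ch$series)
  rho <- spearmanRho(mo$cc_ratio, ch$metadata$fvc_supine_pct)
  expect_gt(rho, 0.5)
  # weakness direction: patients with decreased spirometry sit lowest
  agg <- tapply(mo$cc_ratio, ch$metadata$group, mean)
  expect_lt(agg[["decreased_spiro_pompe"]], agg[["normal_spiro_pompe"]])
  expect_lt(agg[["normal_spiro_pompe"]], agg[["healthy"]] + 0.05)
})

test_that("rater simulation reproduces agreement structure", {
  truth <- seq(1, 2, length.out = 40)
  same <- simulateRaters(truth, raterBias = 0, noiseSd = 0, seed = 1)
  expect_identical(same[, 1], same[, 2])
  expect_equal(iccAbsoluteAgreement(same)@icc, 1)

  biased <- simulateRaters(truth, raterBias = 0.4, noiseSd = 0.01, seed = 2)
  ba <- blandAltman(biased[, 1], biased[, 2])
  expect_equal(ba$bias, -0.4, tolerance = 0.02)

  # closed-form target: icc = var_subject / (var_subject + var_noise)
  set.seed(33)
  subj <- rnorm(50, 1.5, 0.3)
  m <- simulateRaters(subj, raterBias = 0, noiseSd = 0.1, seed = 77)
  est <- iccAbsoluteAgreement(m)@icc
  expect_equal(est, 0.9, tolerance = 0.1)
})
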