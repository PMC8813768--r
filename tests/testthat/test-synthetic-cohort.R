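test_that("phantom volumes match the truncated-ellipsoid closed form", {
  # half-ellipsoid: truncation at the equator
  s <- phantomSpec(endoAxes = c(25, 25, 60), baseTruncation = 0,
                   esContraction = 0)
  g <- generatePhantom(s, "ED")
  expect_equal(g$cavityML, 2 / 3 * pi * 25 * 25 * 60 / 1000, tolerance = 1e-10)
  # es_contraction = 0: ED and ES identical
  expect_equal(generatePhantom(s, "ES")$cavityML, g$cavityML)
  # myocardial volume = epi closed form - cavity closed form
  s8 <- phantomSpec(endoAxes = c(25, 25, 60), wallThickness = 8,
                    baseTruncation = 0)
  gm <- generatePhantom(s8, "ED")
  expect_equal(gm$myocardiumML,
               2 / 3 * pi * 33 * 33 * 68 / 1000 - g$cavityML, tolerance = 1e-10)
})

test_that("invalid phantom parameters are rejected naming the field", {
  expect_error(phantomSpec(endoAxes = c(-1, 25, 60)), "endoAxes")
  expect_error(phantomSpec(baseTruncation = 1.2), "baseTruncation")
  expect_error(phantomSpec(esContraction = 1), "esContraction")
  expect_error(phantomSpec(wallThickness = 0), "wallThickness")
})

test_that("rendered studies carry the legacy protocol geometry", {
  r <- noiselessStudy()
  sax <- saxIndices(r$study)
  origins <- t(vapply(sax, function(k) r$study@slices[[k]]$geometry@origin,
                      numeric(3)))
  gaps <- sqrt(rowSums(diff(origins)^2))
  # thickness 6 + gap 4 -> 10 mm inter-slice origin spacing
  expect_equal(gaps, rep(10, length(sax) - 1), tolerance = 1e-9)
  # exactly 2 MV landmarks per LAX view per frame
  lm <- r$truth@landmarks
  for (v in c("2CH", "4CH")) for (f in 1:3)
    expect_identical(sum(lm$view == v & lm$frame_id == f), 2L)
})

test_that("slice-summation volume from rendered masks matches the closed form", {
  r <- noiselessStudy()
  sax <- saxIndices(r$study)
  px <- r$study@slices[[sax[1]]]$geometry@pixelSpacing
  areas <- vapply(sax, function(k) sum(r$truth@masks[[k]][[1]] == 2) *
                    px[1] * px[2], numeric(1))
  v <- sliceSummationVolume(areas, 6, 4)
  expect_lt(abs(v - r$truth@volumes$edCavity) / r$truth@volumes$edCavity, 0.03)
})

test_that("volume error decreases monotonically under grid refinement", {
  errs <- vapply(0:2, function(lev) {
    n <- 8 * 2^lev
    slab <- 90 / n
    img <- imagingParams(nSax = n, matrixSize = 64 * 2^lev,
                         pixelSpacing = 3 / 2^lev,
                         thickness = 0.6 * slab, gap = 0.4 * slab, nFrames = 1)
    r <- renderCineStudy(phantomSpec(noiseSd = 0), img)
    px <- r$study@slices[[1]]$geometry@pixelSpacing
    areas <- vapply(saxIndices(r$study), function(k)
      sum(r$truth@masks[[k]][[1]] == 2) * px[1] * px[2], numeric(1))
    abs(sliceSummationVolume(areas, 0.6 * slab, 0.4 * slab) -
          r$truth@volumes$edCavity)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("rendering is bit-identical under a fixed seed", {
  s <- phantomSpec(noiseSd = 0.1, seed = 33L)
  r1 <- renderCineStudy(s, imagingParams(nSax = 4, matrixSize = 48, nFrames = 2))
  r2 <- renderCineStudy(s, imagingParams(nSax = 4, matrixSize = 48, nFrames = 2))
  expect_identical(r1$study@slices[[1]]$frames, r2$study@slices[[1]]$frames)
  expect_identical(r1$truth@landmarks, r2$truth@landmarks)
})

test_that("ground-truth pixel landmarks map to their patient points", {
  r <- posedStudy()
  lm <- r$truth@landmarks
  for (i in seq_len(nrow(lm))) {
    g <- r$study@slices[[lm$slice_id[i]]]$geometry
    p <- pixelToPatient(c(lm$row[i], lm$col[i]), g)
    expect_lt(max(abs(p - c(lm$x[i], lm$y[i], lm$z[i]))), 1e-6)
  }
})

test_that("breath-hold shifts are in-plane, bounded and reproducible", {
  r <- noiselessStudy()
  # max_shift = 0: unchanged
  s0 <- applyBreathholdShifts(r$study, 0)
  expect_identical(s0$study@slices[[1]]$geometry@origin,
                   r$study@slices[[1]]$geometry@origin)
  expect_true(all(s0$shifts == 0))
  s1 <- applyBreathholdShifts(r$study, 8, seed = 9L)
  s2 <- applyBreathholdShifts(r$study, 8, seed = 9L)
  expect_identical(s1$shifts, s2$shifts)
  expect_true(all(abs(s1$shifts) <= 8))
  sax <- saxIndices(r$study)
  for (i in seq_along(sax)) {
    g0 <- r$study@slices[[sax[i]]]$geometry
    d <- s1$study@slices[[sax[i]]]$geometry@origin - g0@origin
    # zero out-of-plane component
    expect_lt(abs(sum(d * lvatlas:::sliceNormal(g0))), 1e-9)
    expect_equal(sqrt(sum(d^2)), sqrt(sum(s1$shifts[i, ]^2)),
                 tolerance = 1e-9)
  }
  # LAX untouched
  for (v in c("2CH", "4CH")) {
    k <- laxIndex(r$study, v)
    expect_identical(s1$study@slices[[k]]$geometry@origin,
                     r$study@slices[[k]]$geometry@origin)
  }
})

test_that("population labels, effects and demographics follow the cohort spec", {
  base <- phantomSpec()
  # stratified draw -> exact label count
  p0 <- generatePopulation(cohortSpec(200, effectSize = 0, prevalence = 0.5,
                                      seed = 5L), base)
  labs <- vapply(p0, `[[`, integer(1), "label")
  expect_identical(sum(labs), 100L)
  sc <- vapply(p0, `[[`, numeric(1), "modeScore")
  # effect 0: group means equal within Monte-Carlo error
  expect_gt(t.test(sc[labs == 1], sc[labs == 0])$p.value, 0.01)
  # effect 2: clearly separated
  p2 <- generatePopulation(cohortSpec(200, effectSize = 2, seed = 6L), base)
  labs2 <- vapply(p2, `[[`, integer(1), "label")
  sc2 <- vapply(p2, `[[`, numeric(1), "modeScore")
  expect_lt(t.test(sc2[labs2 == 1], sc2[labs2 == 0])$p.value, 0.01)
  h <- vapply(p0, `[[`, numeric(1), "heightCm")
  expect_true(all(h >= 150 & h <= 190))
  # reproducibility
  p0b <- generatePopulation(cohortSpec(200, effectSize = 0, prevalence = 0.5,
                                       seed = 5L), base)
  expect_identical(vapply(p0b, `[[`, numeric(1), "modeScore"), sc)
  expect_error(cohortSpec(1), "nSubjects")
})

test_that("slices missing the ventricle are flagged, not fatal", {
  # a short LV with a full-length stack: apical slices are empty
  s <- phantomSpec(endoAxes = c(25, 25, 40), noiseSd = 0)
  r <- renderCineStudy(s, imagingParams(nSax = 12))
  expect_gt(length(r$study@meta$emptySlices), 0)
  expect_s4_class(r$study, "CineStudy")
})
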