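# Helpers: ground-truth contour cloud of a rendered phantom in patient mm.
studyCloud <- function(r, lab, frame = 1) {
  lvatlas:::saxContourCloud(r$study, r$truth@contours, frame, lab)
}

gtPose <- function(r) {
  lm <- r$truth@landmarks
  mv <- as.matrix(lm[lm$view %in% c("2CH", "4CH") & lm$frame_id == 1,
                     c("x", "y", "z")])
  rv <- as.matrix(lm[lm$view == "SAX" & lm$frame_id == 1, c("x", "y", "z")])
  spec <- r$truth@spec
  apex <- applyTransform(spec@pose, c(0, 0, -spec@endoAxes[3]))
  initializePose(mv, rv, drop(apex))
}

test_that("pose initialization recovers the phantom long axis and scales", {
  r <- posedStudy()
  pose <- gtPose(r)
  spec <- r$truth@spec
  trueAxis <- -spec@pose[1:3, 3]  # base-to-apex = -z of the model frame
  ang <- acos(abs(sum(pose$R[, 3] * trueAxis))) * 180 / pi
  expect_lt(ang, 2)
  # length = MV centroid to apex distance
  zb <- spec@baseTruncation * spec@endoAxes[3]
  expect_equal(pose$L, zb + spec@endoAxes[3], tolerance = 0.5)
  expect_error(initializePose(matrix(0, 2, 3), matrix(1, 2, 3), c(0, 0, 0)),
               "apex")
})

test_that("pose initialization is equivariant to rigid motion of its inputs", {
  r <- posedStudy()
  lm <- r$truth@landmarks
  mv <- as.matrix(lm[lm$view %in% c("2CH", "4CH") & lm$frame_id == 1,
                     c("x", "y", "z")])
  rv <- as.matrix(lm[lm$view == "SAX" & lm$frame_id == 1, c("x", "y", "z")])
  apex <- c(5, 5, -80)
  p0 <- initializePose(mv, rv, apex)
  Tr <- lvatlas:::rigidTransform(lvatlas:::rotationMatrix(c(0, 1, 2), 0.7),
                                 c(12, -3, 40))
  p1 <- initializePose(applyTransform(Tr, mv), applyTransform(Tr, rv),
                       drop(applyTransform(Tr, apex)))
  expect_equal(p1$R, Tr[1:3, 1:3] %*% p0$R, tolerance = 1e-9)
  expect_equal(p1$t, drop(applyTransform(Tr, p0$t)), tolerance = 1e-9)
  expect_equal(p1$L, p0$L, tolerance = 1e-9)
})

test_that("rotating the RV inserts rotates the septal azimuth equally", {
  r <- noiselessStudy()
  lm <- r$truth@landmarks
  mv <- as.matrix(lm[lm$view %in% c("2CH", "4CH") & lm$frame_id == 1,
                     c("x", "y", "z")])
  rv <- as.matrix(lm[lm$view == "SAX" & lm$frame_id == 1, c("x", "y", "z")])
  apex <- c(0, 0, -60)
  p0 <- initializePose(mv, rv, apex)
  Rz <- lvatlas:::rotationMatrix(c(0, 0, 1), 30 * pi / 180)
  p1 <- initializePose(mv, rv %*% t(Rz), apex)
  cosang <- sum(p0$R[, 1] * p1$R[, 1])
  expect_equal(acos(pmin(1, cosang)) * 180 / pi, 30, tolerance = 1)
})

test_that("surface fitting reaches sub-half-millimetre residuals on clean contours", {
  r <- posedStudy()
  pose <- gtPose(r)
  cl <- studyCloud(r, "endocardium")
  f <- fitSurfaces(cl$points, "endo", pose, lambda = 0.1)
  expect_lt(f$rms, 0.5)
  # objective non-increasing across outer iterations
  expect_true(all(diff(f$rmsTrace) < 1e-6))
  # duplicating every data point leaves the solution unchanged
  f2 <- fitSurfaces(rbind(cl$points, cl$points), "endo", pose, lambda = 0.1)
  expect_equal(f2$theta, f$theta, tolerance = 1e-9)
})

test_that("the infinite-regularization limit is the pose-placed template", {
  r <- noiselessStudy()
  pose <- gtPose(r)
  cl <- studyCloud(r, "endocardium")
  tmpl <- lvTemplate()
  f <- fitSurfaces(cl$points, "endo", pose, tmpl, lambda = 1e8, maxIter = 2)
  expect_lt(max(abs(f$theta - tmpl$endo)), 1e-3)
})

test_that("slice intersections match analytic ellipse sections", {
  r <- noiselessStudy()
  res <- fitLV(r$study, r$truth@contours, r$truth@landmarks, correct = FALSE)
  spec <- r$truth@spec
  # equatorial plane: section of the ED endocardium is a circle of radius 25
  k <- 5  # mid-ventricular slice, model z = -25
  g <- r$study@slices[[k]]$geometry
  sec <- intersectWithSlice(res$fit, g, "ED", "endo")
  expect_false(sec$empty)
  zk <- -25
  rTrue <- 25 * sqrt(1 - (zk / 60)^2)
  px <- sec$polygonPx
  ctr <- lvatlas:::polygonCentroid(px)
  rad <- sqrt(rowSums(sweep(px, 2, ctr)^2)) * g@pixelSpacing[1]
  expect_lt(max(abs(rad - rTrue)), 1)
  # the section centroid lies on the long axis
  axPt <- applyTransform(spec@pose, c(0, 0, zk))
  expect_lt(sqrt(sum((sec$centroidPatient - axPt)^2)), 0.5)
  # a plane beyond the apex yields an empty, flagged result
  gFar <- sliceGeometry(c(-100, -100, -200), c(1, 0, 0), c(0, 1, 0), c(2, 2))
  secFar <- intersectWithSlice(res$fit, gFar, "ED", "endo")
  expect_true(secFar$empty)
})

test_that("breath-hold correction recovers injected shifts and is null-safe", {
  r <- posedStudy()
  # null case: no spurious shifts
  res0 <- fitLV(r$study, r$truth@contours, r$truth@landmarks)
  expect_lt(max(abs(res0$shifts)), 0.5)
  # injected uniform shifts up to 8 mm
  sh <- applyBreathholdShifts(r$study, 8, seed = 77L, truth = r$truth)
  res <- fitLV(sh$study, r$truth@contours, r$truth@landmarks)
  expect_lt(mean(abs(res$shifts - sh$shifts)), 1)
  # final-pass residuals cannot exceed the first-pass residuals
  expect_lte(res$pass2Rms, res$pass1Rms)
})

test_that("surface sampling is deterministic, sized 12N and equivariant", {
  r <- posedStudy()
  res <- fitLV(r$study, r$truth@contours, r$truth@landmarks, correct = FALSE)
  s1 <- sampleSurfacePoints(res$fit, 512)
  s2 <- sampleSurfacePoints(res$fit, 512)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, nrow, integer(1)) == 512L))
  sv <- assembleShapeVector(s1)
  expect_identical(length(sv), 12L * 512L)
  # endo strictly inside epi: positive wall thickness at sampled parameters
  wall <- sqrt(rowSums((s1$epiED - s1$endoED)^2))
  expect_true(all(wall > 0))
})

test_that("fitting is equivariant to a rigid motion of the whole study", {
  r <- noiselessStudy()
  res0 <- fitLV(r$study, r$truth@contours, r$truth@landmarks, correct = FALSE)
  Tr <- lvatlas:::rigidTransform(lvatlas:::rotationMatrix(c(2, 0, 1), 0.6),
                                 c(-15, 25, 10))
  moved <- r$study
  for (k in seq_along(moved@slices)) {
    g <- moved@slices[[k]]$geometry
    g@origin <- drop(applyTransform(Tr, g@origin))
    g@rowDir <- drop(Tr[1:3, 1:3] %*% g@rowDir)
    g@colDir <- drop(Tr[1:3, 1:3] %*% g@colDir)
    moved@slices[[k]]$geometry <- g
  }
  res1 <- fitLV(moved, r$truth@contours, r$truth@landmarks, correct = FALSE)
  expect_equal(res1$fit@residuals$residual_mm, res0$fit@residuals$residual_mm,
               tolerance = 1e-6)
  sp0 <- sampleSurfacePoints(res0$fit, 128)
  sp1 <- sampleSurfacePoints(res1$fit, 128)
  expect_equal(sp1$endoED, applyTransform(Tr, sp0$endoED), tolerance = 1e-6)
})
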