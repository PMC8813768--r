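test_that("pixel-to-patient is the documented affine map", {
  g <- sliceGeometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1))
  expect_equal(drop(pixelToPatient(c(2, 3), g)), c(3, 2, 0))
  g2 <- sliceGeometry(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 2))
  expect_equal(drop(pixelToPatient(c(2, 3), g2)), c(6, 4, 0))
  expect_error(pixelToPatient(c(0, 0),
    sliceGeometry(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(1, 1))), "unit")
})

test_that("patient/pixel round trips are exact on random geometries", {
  withr::local_seed(42)
  for (rep in 1:20) {
    g <- randomGeometry()
    rc <- cbind(runif(50, 0, 200), runif(50, 0, 200))
    p <- pixelToPatient(rc, g)
    back <- patientToPixel(p, g)
    expect_lt(max(abs(back - rc)), 1e-9)
    expect_lt(max(abs(attr(back, "outOfPlane"))), 1e-9)
  }
})

# rasterize a disc: pixel centers within radius r of (cr, cc), 0-based
disc <- function(n, cr, cc, r) {
  rows <- matrix(0:(n - 1), n, n)
  cols <- t(rows)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

test_that("contours extracted from an annulus mask recover the circles", {
  n <- 64
  mask <- matrix(0L, n, n)
  mask[disc(n, 31.5, 31.5, 16)] <- 1L
  mask[disc(n, 31.5, 31.5, 10)] <- 2L
  cc <- maskToContours(mask)
  endo <- lvatlas:::contourPoints(cc, "endocardium")
  epi <- lvatlas:::contourPoints(cc, "epicardium")
  rEndo <- sqrt(rowSums(sweep(endo, 2, c(31.5, 31.5))^2))
  rEpi <- sqrt(rowSums(sweep(epi, 2, c(31.5, 31.5))^2))
  expect_lt(max(abs(rEndo - 10)), 0.7)
  expect_lt(max(abs(rEpi - 16)), 0.7)
  # counter-clockwise ordering
  expect_gt(lvatlas:::polygonArea(endo), 0)
})

test_that("an all-background mask yields no contours, flagged", {
  cc <- maskToContours(matrix(0L, 16, 16))
  expect_identical(nrow(cc), 0L)
  expect_setequal(attr(cc, "missing"), c("endocardium", "epicardium"))
})

test_that("mask -> contours -> mask round trip preserves labels up to the boundary", {
  r <- noiselessStudy()
  m <- r$truth@masks[[5]][[1]]
  cc <- maskToContours(m, 5, 1)
  m2 <- contoursToMask(cc, dim(m))
  perim <- nrow(lvatlas:::contourPoints(cc, "epicardium")) +
    nrow(lvatlas:::contourPoints(cc, "endocardium"))
  expect_lte(sum(m2 != m), perim)
  # partition: counts sum to the pixel count
  expect_identical(sum(m2 == 0) + sum(m2 == 1) + sum(m2 == 2), length(m2))
})

test_that("concentric-circle contours rasterize to the analytic areas", {
  t <- seq(0, 2 * pi, length.out = 73)[-73]
  mk <- function(r, lab) data.frame(slice_id = 1L, frame_id = 1L, label = lab,
                                    point_index = seq_along(t) - 1L,
                                    row = 32 + r * sin(t), col = 32 + r * cos(t))
  cc <- rbind(mk(10, "endocardium"), mk(16, "epicardium"))
  m <- contoursToMask(cc, c(64, 64))
  expect_lt(abs(sum(m == 2) - pi * 100) / (pi * 100), 0.03)
  expect_lt(abs(sum(m == 1) - pi * (256 - 100)) / (pi * 156), 0.03)
  # coincident contours: degenerate, zero myocardium
  ccd <- rbind(mk(10, "endocardium"), mk(10, "epicardium"))
  expect_warning(md <- contoursToMask(ccd, c(64, 64)), "degenerate")
  expect_identical(sum(md == 1), 0L)
  # endo outside epi is an error naming the slice
  ccb <- rbind(mk(16, "endocardium"), mk(10, "epicardium"))
  expect_error(contoursToMask(ccb, c(64, 64)), "slice 1")
})

test_that("cine sorting recovers apex-to-base and temporal order", {
  r <- noiselessStudy()
  sax <- saxIndices(r$study)
  slices <- lapply(r$study@slices[sax], function(s)
    list(geometry = s$geometry, triggerTimes = s$triggerTimes))
  perm <- c(7, 2, 9, 1, 5, 10, 3, 8, 4, 6)
  mvc <- colMeans(as.matrix(
    r$truth@landmarks[r$truth@landmarks$view != "SAX" &
                        r$truth@landmarks$frame_id == 1, c("x", "y", "z")]))
  out <- sortCine(slices[perm], mvCentroid = mvc)
  expect_equal(perm[out$order], 1:10)
  expect_false(out$flagged)
  # already sorted: unchanged
  out2 <- sortCine(slices, mvCentroid = mvc)
  expect_identical(out2$order, 1:10)
  # missing trigger time flags the series as temporally unsortable
  slices[[3]]$triggerTimes[2] <- NA
  expect_true(sortCine(slices, mvCentroid = mvc)$flagged)
  # inconsistent orientations are an error
  bad <- slices
  bad[[2]]$geometry <- sliceGeometry(bad[[2]]$geometry@origin,
                                     c(0, 0, 1), c(0, 1, 0), c(2, 2))
  expect_error(sortCine(bad), "orientation")
})

test_that("geometry-free contour files are matched back to their slices", {
  r <- noiselessStudy()
  sax <- saxIndices(r$study)
  masks <- lapply(sax, function(k) r$truth@masks[[k]][[1]])
  withMask <- which(vapply(masks, function(m) any(m == 2), logical(1)))
  contourList <- lapply(withMask, function(k)
    r$truth@contours[r$truth@contours$slice_id == k &
                       r$truth@contours$frame_id == 1, ])
  m <- matchContoursToSlices(contourList, masks[withMask])
  expect_false(m$excluded)
  expect_identical(m$assignment$slice_index, m$assignment$contour_index)
  # truncated by one apical slice: remaining assigned with offset 1
  m2 <- matchContoursToSlices(contourList[-1], masks[withMask])
  expect_identical(m2$offset, 1L)
  expect_identical(m2$assignment$slice_index, m2$assignment$contour_index + 1L)
  # empty contour file: excluded with a reason
  m3 <- matchContoursToSlices(list(), masks)
  expect_true(m3$excluded)
  expect_match(m3$reason, "empty")
  # count mismatch beyond tolerance: excluded
  m4 <- matchContoursToSlices(contourList[1:3], masks)
  expect_true(m4$excluded)
})
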