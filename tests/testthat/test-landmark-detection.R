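test_that("preprocessing whitens and zero-pads with recoverable offsets", {
  withr::local_seed(1)
  img <- matrix(runif(192 * 160), 192, 160)
  pp <- preprocessImage(img, 256L)
  expect_identical(dim(pp$image), c(256L, 256L))
  expect_identical(pp$offset, c(32, 48))
  content <- pp$image[pp$contentMask]
  expect_lt(abs(mean(content)), 1e-6)
  expect_lt(abs(sd(content) - 1), 1e-6)
  expect_true(all(pp$image[!pp$contentMask] == 0))
  # already at target size: offsets (0, 0)
  pp2 <- preprocessImage(matrix(runif(256 * 256), 256, 256), 256L)
  expect_identical(pp2$offset, c(0, 0))
  # constant image: centered only, no division
  pp3 <- preprocessImage(matrix(5, 64, 64), 64L)
  expect_true(all(pp3$image == 0))
  # landmark remapping is exactly invertible under pure padding
  lm <- c(10.25, 20.5)
  remapped <- lm + pp$offset
  expect_identical(remapped - pp$offset, lm)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  # worked 6 x 3 fixture; oracle computed from aov() mean squares
  m <- matrix(c(9, 2, 5, 8, 6, 7,
                10, 4, 6, 9, 7, 8,
                8, 2, 4, 9, 5, 7), 6, 3)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:6, 3)), rater = factor(rep(1:3, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + 2 * mse + 3 * (msc - mse) / 6)
  expect_equal(iccTwoWay(m), oracle, tolerance = 1e-10)
  # identical columns, non-constant rows -> 1
  r <- matrix(rep(c(1, 3, 7, 2), 3), 4, 3)
  expect_equal(iccTwoWay(r), 1)
  # independent columns -> near zero
  withr::local_seed(7)
  nullm <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(iccTwoWay(nullm)), 0.1)
  # zero between-subject variance: degenerate 0 with warning
  expect_warning(z <- iccTwoWay(matrix(rep(c(1, 2, 3), each = 4), 4, 3)),
                 "zero between-subject")
  expect_identical(z, 0)
})

test_that("landmark distances scale with pixel spacing", {
  p <- matrix(c(0, 0, 10, 10), 1, 4)
  ev <- evaluateLandmarks(p, p)
  expect_true(all(ev$distances == 0))
  off <- matrix(c(3, 4, 3, 4), 1, 4)
  ev1 <- evaluateLandmarks(p + off, p, pixelSpacing = 1)
  expect_equal(unname(ev1$distances), c(5, 5))
  ev2 <- evaluateLandmarks(p + off, p, pixelSpacing = 2)
  expect_equal(unname(ev2$distances), c(10, 10))
  expect_equal(ev2$mean, 10)
  expect_error(evaluateLandmarks(matrix(0, 2, 4), matrix(0, 3, 4)), "differ")
})

test_that("the landmark net overfits a single repeated image", {
  pop <- tinyPopulation()
  lds <- landmarkDatasets(pop, views = "2CH")[["2CH"]]
  imgs <- rep(lds$images[1], 60)
  tg <- lds$targets[rep(1, 60), ]
  cfg <- landmarkNetConfig(epochs = 25, seed = 4L)
  fit <- trainLandmarkNet(cfg, imgs, tg)
  expect_lt(tail(fit$valCurve, 1), 0.5)  # px, on the repeated image
})

test_that("landmark training is deterministic under a fixed seed", {
  pop <- tinyPopulation()
  lds <- landmarkDatasets(pop, views = "4CH")[["4CH"]]
  cfg <- landmarkNetConfig(epochs = 2, seed = 11L)
  f1 <- trainLandmarkNet(cfg, lds$images, lds$targets)
  f2 <- trainLandmarkNet(cfg, lds$images, lds$targets)
  expect_equal(f1$valCurve, f2$valCurve, tolerance = 1e-12)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-12)
})

test_that("a zero-step cycle leaves models at their initialization", {
  pop <- tinyPopulation()
  lds <- landmarkDatasets(pop)
  cfgs <- lapply(c("2CH", "4CH", "SAX"), function(v)
    landmarkNetConfig(epochs = 0, seed = 21L))
  names(cfgs) <- c("2CH", "4CH", "SAX")
  # epochs = 0 means no training steps: all views share the initial weights
  expect_warning(cyc <- cyclicTransferTrain(cfgs, lds, maxCycles = 1),
                 "cycle cap")
  expect_identical(cyc$cycles, 1L)
  init <- lvatlas:::lmnetInit(64L, cfgs[[1]]$channels, cfgs[[1]]$hidden, 21L)
  for (v in names(cfgs))
    expect_equal(cyc$models[[v]]$params, as.numeric(init), tolerance = 1e-12)
})
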