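randomSurfaces <- function(N = 32) {
  lapply(setNames(1:4, c("endoED", "epiED", "endoES", "epiES")),
         function(i) matrix(rnorm(N * 3), N, 3))
}

test_that("shape vectors assemble to 12N and round trip exactly", {
  withr::local_seed(8)
  s <- randomSurfaces(512)
  v <- assembleShapeVector(s)
  expect_identical(length(v), 12L * 512L)
  back <- disassembleShapeVector(v)
  expect_equal(back, unname(s), ignore_attr = TRUE)
  for (b in names(s)) expect_equal(back[[b]], s[[b]])
  # the block order is semantic: permuting it changes the vector
  sPerm <- s[c("epiED", "endoED", "endoES", "epiES")]
  names(sPerm) <- names(s)
  expect_false(isTRUE(all.equal(assembleShapeVector(sPerm), v)))
  s$epiED <- s$epiED[1:10, ]
  expect_error(assembleShapeVector(s), "equal N")
})

test_that("Procrustes removes rigid motion only and keeps size", {
  withr::local_seed(9)
  base <- as.numeric(assembleShapeVector(randomSurfaces(64)))
  copies <- t(vapply(1:6, function(i) {
    R <- lvatlas:::rotationMatrix(rnorm(3), runif(1, -pi, pi))
    p <- lvatlas:::shapeToPoints(base) %*% t(R)
    lvatlas:::pointsToShape(sweep(p, 2, runif(3, -50, 50), "+"))
  }, numeric(length(base))))
  g <- procrustesAlign(copies)
  expect_lt(sum(apply(g$aligned, 2, var)), 1e-12)
  # scaling survives alignment: size is signal
  scaled <- rbind(base, 2 * base)
  g2 <- procrustesAlign(scaled)
  n1 <- sqrt(sum(scale(lvatlas:::shapeToPoints(g2$aligned[1, ]), scale = FALSE)^2))
  n2 <- sqrt(sum(scale(lvatlas:::shapeToPoints(g2$aligned[2, ]), scale = FALSE)^2))
  expect_equal(n2 / n1, 2, tolerance = 1e-9)
  # idempotence
  g3 <- procrustesAlign(g$aligned)
  expect_equal(g3$aligned, g$aligned, tolerance = 1e-7)
  # degenerate collinear shapes are rejected
  line <- cbind(1:10, 0, 0)
  bad <- rbind(lvatlas:::pointsToShape(line), lvatlas:::pointsToShape(2 * line))
  expect_error(procrustesAlign(bad), "degenerate")
})

test_that("PCA conserves variance and reconstructs its training shapes", {
  withr::local_seed(10)
  X <- matrix(rnorm(20 * 120), 20, 120)
  g <- procrustesAlign(X)
  atlas <- atlasPCA(g$aligned)
  Xc <- sweep(g$aligned, 2, atlas@meanShape)
  expect_equal(sum(atlas@eigenvalues), sum(Xc^2) / (nrow(Xc) - 1),
               tolerance = 1e-8)
  # scores have zero mean and projecting training shapes returns them
  expect_lt(max(abs(colMeans(atlas@scores))), 1e-8)
  pr <- projectShape(atlas, g$aligned)
  expect_equal(pr, atlas@scores, tolerance = 1e-8, ignore_attr = TRUE)
  # full reconstruction is the identity
  rec <- reconstructShape(atlas, atlas@scores[3, ])
  expect_equal(rec, g$aligned[3, ], tolerance = 1e-8)
  # projecting the mean gives zero scores
  expect_lt(max(abs(projectShape(atlas, atlas@meanShape))), 1e-8)
  # mean + 2 sqrt(l1) PC1 -> scores (2 sqrt(l1), 0, ...)
  sh <- atlas@meanShape + 2 * sqrt(atlas@eigenvalues[1]) * atlas@directions[, 1]
  sc <- projectShape(atlas, sh)
  expect_equal(sc[1], 2 * sqrt(atlas@eigenvalues[1]), tolerance = 1e-8)
  expect_lt(max(abs(sc[-1])), 1e-8)
  expect_error(atlasPCA(X[1, , drop = FALSE]), "two subjects")
  expect_error(projectShape(atlas, rnorm(10)), "mismatch")
})

test_that("a single-mode cohort is recovered as PC1 along the generative mode", {
  base <- phantomSpec()
  coh <- cohortSpec(80, deformationMode = "sphericalization", effectSize = 0,
                    jitterSd = 0, seed = 13L)
  pop <- generatePopulation(coh, base, randomPose = FALSE)
  shapes <- cohortShapeVectors(pop, N = 128, nCirc = 16)
  g <- procrustesAlign(shapes)
  atlas <- atlasPCA(g$aligned)
  ev <- atlas@eigenvalues
  expect_gt(ev[1] / sum(ev), 0.99)
  md <- modeDirection(base, "sphericalization", N = 128, nCirc = 16)
  # compare in the centered frame the atlas lives in
  mdPts <- lvatlas:::shapeToPoints(md)
  mdC <- lvatlas:::unitv(lvatlas:::pointsToShape(
    sweep(mdPts, 2, colMeans(mdPts))))
  expect_gt(abs(sum(atlas@directions[, 1] * mdC)), 0.99)
  # cumulative explained variance is monotone non-decreasing
  expect_true(all(diff(cumsum(ev) / sum(ev)) >= -1e-12))
})

test_that("atlas scores are invariant to a global rigid motion of the cohort", {
  withr::local_seed(14)
  base <- phantomSpec()
  pop <- generatePopulation(cohortSpec(15, effectSize = 0, jitterSd = 0.05,
                                       seed = 15L), base, randomPose = FALSE)
  shapes <- cohortShapeVectors(pop, N = 64, nCirc = 16)
  R <- lvatlas:::rotationMatrix(c(1, 2, 3), 1.1)
  tr <- c(30, -40, 12)
  moved <- t(apply(shapes, 1, function(s)
    lvatlas:::pointsToShape(sweep(lvatlas:::shapeToPoints(s) %*% t(R), 2, tr, "+"))))
  a1 <- atlasPCA(procrustesAlign(shapes)$aligned)
  a2 <- atlasPCA(procrustesAlign(moved)$aligned)
  expect_equal(abs(a1@scores), abs(a2@scores), tolerance = 1e-6)
  expect_equal(a1@eigenvalues, a2@eigenvalues, tolerance = 1e-8)
})

test_that("atlas files round trip through the delimited format", {
  withr::local_seed(16)
  X <- matrix(rnorm(10 * 48), 10, 48)
  atlas <- atlasPCA(procrustesAlign(X)$aligned)
  d <- withr::local_tempdir()
  writeAtlas(atlas, d)
  back <- readAtlas(d)
  expect_equal(back@meanShape, atlas@meanShape, tolerance = 1e-10)
  expect_equal(abs(back@directions), abs(atlas@directions), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back@eigenvalues, atlas@eigenvalues, tolerance = 1e-10)
})
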