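# Small association cohorts: analytic shape vectors keep these fast.
assocCohort <- function(n, effect, seed, jitter = 0.03) {
  pop <- generatePopulation(cohortSpec(n, effectSize = effect,
                                       jitterSd = jitter, seed = seed),
                            phantomSpec())
  list(shapes = procrustesAlign(cohortShapeVectors(pop, N = 64, nCirc = 16))$aligned,
       labels = vapply(pop, `[[`, integer(1), "label"))
}

fakeResult <- function(labels, prob, ids = seq_along(labels)) {
  structure(list(factor = "sim", foldAUCs = NA, nComponents = NA, folds = NA,
                 pooledAUC = as.numeric(pROC::auc(pROC::roc(
                   labels, prob, quiet = TRUE, direction = "<", levels = c(0, 1)))),
                 predictions = data.frame(id = ids, label = labels,
                                          prob = prob, fold = 1L)),
            class = "lvAssociation")
}

test_that("cross-validated folds partition subjects and key to subject ids", {
  cc <- assocCohort(120, 1, seed = 21L)
  res <- cvAssociation(cc$shapes, cc$labels, kComponents = 10, folds = 5,
                       seed = 3L)
  pr <- res$predictions
  expect_identical(sort(pr$id), 1:120)      # disjoint cover, once each
  expect_identical(length(unique(pr$fold)), 5L)
  # shuffling the subject order leaves the pooled AUC unchanged
  perm <- withSeed(4L, sample(120))
  res2 <- cvAssociation(cc$shapes[perm, ], cc$labels[perm], kComponents = 10,
                        folds = 5, seed = 3L, ids = (1:120)[perm])
  expect_equal(res2$pooledAUC, res$pooledAUC, tolerance = 1e-10)
  expect_error(cvAssociation(cc$shapes[1:4, ], cc$labels[1:4], folds = 10),
               "folds")
})

test_that("association strength is monotone in the generative effect size", {
  aucs <- vapply(c(0, 1, 2), function(es)
    with(assocCohort(200, es, seed = 30L + es),
         cvAssociation(shapes, labels, kComponents = 10, folds = 5,
                       seed = 5L)$pooledAUC), numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(abs(aucs[1] - 0.5), 0.1)
  expect_gt(aucs[3], 0.8)
})

test_that("label-permuted cohorts concentrate at AUC one half", {
  cc <- assocCohort(100, 2, seed = 22L)
  withr::local_seed(6)
  aucs <- vapply(1:40, function(i)
    cvAssociation(cc$shapes, sample(cc$labels), kComponents = 8, folds = 5,
                  seed = i)$pooledAUC, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("comparing a result with itself gives p = 1", {
  cc <- assocCohort(80, 1, seed = 23L)
  res <- cvAssociation(cc$shapes, cc$labels, kComponents = 8, folds = 5,
                       seed = 2L)
  cmp <- compareAuc(res, res)
  expect_gte(cmp$p.value, 0.99)
  expect_equal(cmp$aucA, cmp$aucB)
  res2 <- res
  res2$predictions <- res2$predictions[c(2:nrow(res2$predictions), 1), ]
  expect_error(compareAuc(res, res2), "identical subjects")
})

test_that("the paired AUC test holds its type-I error and has power", {
  withr::local_seed(31)
  n <- 100
  # two independent null pipelines on the same labels
  rej <- vapply(1:200, function(i) {
    labels <- rep(0:1, n / 2)
    a <- fakeResult(labels, rnorm(n))
    b <- fakeResult(labels, rnorm(n))
    compareAuc(a, b)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  # informative vs null pipeline: rejects most of the time
  power <- vapply(1:100, function(i) {
    labels <- rep(0:1, n / 2)
    a <- fakeResult(labels, labels * 1.5 + rnorm(n))
    b <- fakeResult(labels, rnorm(n))
    compareAuc(a, b)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.8)
})

test_that("separation falls back to a ridge-penalized fit with a warning", {
  withr::local_seed(32)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.integer(X[, 1] > 0)  # perfectly separable in one coordinate
  expect_warning(f <- lvatlas:::fitLogistic(as.data.frame(X), y), "ridge")
  p <- f(as.data.frame(X))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
})
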