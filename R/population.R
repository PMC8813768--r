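# Apply a deformation-mode score t (in population SD units) to a base
# phantom. Modes are linearized so that shape vectors vary ~linearly in t.
applyMode <- function(base, mode, t) {
  spec <- base
  if (mode == "wall_thickening") {
    spec@wallThickness <- base@wallThickness * (1 + 0.12 * t)
  } else if (mode == "sphericalization") {
    spec@endoAxes <- base@endoAxes * c(1 + 0.06 * t, 1 + 0.06 * t, 1 - 0.06 * t)
  } else if (mode == "dilation") {
    spec@endoAxes <- base@endoAxes * (1 + 0.06 * t)
  } else stop("unknown deformation mode: ", mode)
  spec
}

# Sampling grid shared by analytic phantom surfaces: nCirc x nLong points,
# circumferential index fastest, apex to base.
phantomSurfacePoints <- function(axes, zBase, nCirc, nLong, pose) {
  u <- 2 * pi * (seq_len(nCirc) - 1) / nCirc
  v <- (seq_len(nLong) - 0.5) / nLong
  z <- -axes[3] + v * (zBase + axes[3])
  pts <- matrix(0, nCirc * nLong, 3)
  for (j in seq_len(nLong)) {
    s <- sqrt(max(0, 1 - (z[j] / axes[3])^2))
    idx <- (j - 1) * nCirc + seq_len(nCirc)
    pts[idx, ] <- cbind(axes[1] * s * cos(u), axes[2] * s * sin(u), z[j])
  }
  applyTransform(pose, pts)
}

#' Analytic 12N shape vector of a phantom
#'
#' Samples the four generative truncated-ellipsoid surfaces (endo/epi at
#' ED/ES) on the package's fixed parameter grid and concatenates them, the
#' same construction the fitted-model sampler uses.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param N points per surface (must be nCirc * nLong; default 512 = 32 x 16).
#' @param nCirc circumferential sample count.
#' @return numeric vector of length 12N.
#' @export
phantomShapeVector <- function(spec, N = 512, nCirc = 32) {
  nLong <- N / nCirc
  if (nLong != round(nLong)) stop("N must be a multiple of nCirc")
  surf <- list()
  for (ph in c("ED", "ES")) {
    g <- phaseGeometry(spec, if (ph == "ED") 0 else 1)
    surf[[paste0("endo", ph)]] <-
      phantomSurfacePoints(g$endoAxes, g$zBase, nCirc, nLong, spec@pose)
    surf[[paste0("epi", ph)]] <-
      phantomSurfacePoints(g$epiAxes, g$zBase, nCirc, nLong, spec@pose)
  }
  assembleShapeVector(surf)
}

#' Unit generative mode direction in shape space
#'
#' Central-difference derivative of the phantom shape vector with respect to
#' the mode score at the base shape, normalized to unit length.
#'
#' @param base A \linkS4class{PhantomSpec} (identity pose recommended).
#' @param mode deformation mode name.
#' @param N,nCirc sampling layout (see \code{\link{phantomShapeVector}}).
#' @return unit 12N vector.
#' @export
modeDirection <- function(base, mode, N = 512, nCirc = 32) {
  h <- 0.05
  d <- phantomShapeVector(applyMode(base, mode, h), N, nCirc) -
    phantomShapeVector(applyMode(base, mode, -h), N, nCirc)
  unitv(d)
}

#' Generate a synthetic phantom population with risk-linked shape variation
#'
#' Per-subject phantoms are drawn around \code{base}: the deformation-mode
#' score is N(0,1) with subjects labelled 1 shifted by \code{effectSize}
#' standard deviations; remaining parameters receive independent relative
#' jitter of SD \code{jitterSd}; each subject gets a random rigid pose.
#' Labels are assigned by stratified draw (exact prevalence). Demographics
#' are sampled uniformly in the stated ranges.
#'
#' @param cohort A \linkS4class{CohortSpec}.
#' @param base A \linkS4class{PhantomSpec} the population varies around.
#' @param render when TRUE, each subject is rendered to a cine study with
#'   ground truth (slow; off by default).
#' @param imaging imaging parameters used when rendering.
#' @param maxShift breath-hold shift magnitude injected when rendering.
#' @param randomPose give each subject a random rigid pose (rotation up to
#'   15 degrees, translation up to 20 mm).
#' @return list of subjects: list(id, spec, modeScore, label, heightCm,
#'   weightKg[, study, truth, shifts]). Attribute \code{mode} carries the
#'   mode name.
#' @export
generatePopulation <- function(cohort, base = phantomSpec(), render = FALSE,
                               imaging = imagingParams(), maxShift = 0,
                               randomPose = TRUE) {
  validObject(cohort)
  n <- cohort@nSubjects
  withSeed(cohort@seed, {
    n1 <- round(cohort@prevalence * n)
    labels <- integer(n)
    labels[sample.int(n, n1)] <- 1L
    t0 <- rnorm(n)
    score <- t0 + cohort@effectSize * labels
    height <- runif(n, cohort@heightRange[1], cohort@heightRange[2])
    weight <- runif(n, cohort@weightRange[1], cohort@weightRange[2])
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- applyMode(base, cohort@deformationMode, score[i])
      if (cohort@jitterSd > 0) {
        spec@endoAxes <- spec@endoAxes * (1 + rnorm(3, 0, cohort@jitterSd))
        spec@wallThickness <- spec@wallThickness * (1 + rnorm(1, 0, cohort@jitterSd))
        spec@esContraction <- min(0.6, max(0.05,
          spec@esContraction * (1 + rnorm(1, 0, cohort@jitterSd))))
      }
      if (randomPose) {
        ax <- unitv(rnorm(3))
        ang <- runif(1, -15, 15) * pi / 180
        spec@pose <- rigidTransform(rotationMatrix(ax, ang), runif(3, -20, 20))
      }
      spec@seed <- as.integer((cohort@seed + 7 * i) %% .Machine$integer.max)
      subjects[[i]] <- list(id = i, spec = spec, modeScore = score[i],
                            label = labels[i], heightCm = height[i],
                            weightKg = weight[i])
    }
    if (render) {
      for (i in seq_len(n)) {
        r <- renderCineStudy(subjects[[i]]$spec, imaging)
        if (maxShift > 0) {
          sh <- applyBreathholdShifts(r$study, maxShift,
                                      seed = subjects[[i]]$spec@seed + 1L,
                                      truth = r$truth)
          r$study <- sh$study; r$truth <- sh$truth
        }
        subjects[[i]]$study <- r$study
        subjects[[i]]$truth <- r$truth
      }
    }
    attr(subjects, "mode") <- cohort@deformationMode
    subjects
  })
}

#' Shape vectors of a generated population
#'
#' @param population output of \code{\link{generatePopulation}}.
#' @param N,nCirc sampling layout.
#' @return n x 12N matrix (rows = subjects, rownames = subject ids).
#' @export
cohortShapeVectors <- function(population, N = 512, nCirc = 32) {
  m <- do.call(rbind, lapply(population, function(s)
    phantomShapeVector(s$spec, N, nCirc)))
  rownames(m) <- vapply(population, function(s) as.character(s$id), character(1))
  m
}
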