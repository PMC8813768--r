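# Closed-form volume of an ellipsoid with semi-axes `axes`, truncated by the
# plane z = zmax (keeping z <= zmax), in mm^3.
truncatedEllipsoidVolume <- function(axes, zmax) {
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  u <- max(-1, min(1, zmax / c))
  pi * a * b * c * ((u + 1) - (u^3 + 1) / 3)
}

# Per-phase geometry: endocardial contraction with systolic wall thickening.
# `w` interpolates 0 (ED) -> 1 (ES); the basal plane height is fixed.
phaseGeometry <- function(spec, w) {
  endo <- spec@endoAxes * (1 - spec@esContraction * w)
  wall <- spec@wallThickness * (1 + 0.35 * w)
  list(endoAxes = endo, epiAxes = endo + wall,
       zBase = spec@baseTruncation * spec@endoAxes[3])
}

#' Generate the analytic LV geometry for one cardiac phase
#'
#' Returns the truncated-ellipsoid endo/epi surfaces in patient space
#' together with the closed-form cavity and myocardial volumes. The
#' myocardial volume is the epicardial truncated-ellipsoid volume minus the
#' cavity volume (both cut by the shared basal plane).
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param phase "ED" or "ES".
#' @return list(endoAxes, epiAxes, zBase, pose, cavityML, myocardiumML).
#' @export
generatePhantom <- function(spec, phase = c("ED", "ES")) {
  validObject(spec)
  phase <- match.arg(phase)
  g <- phaseGeometry(spec, if (phase == "ED") 0 else 1)
  cav <- truncatedEllipsoidVolume(g$endoAxes, g$zBase)
  epi <- truncatedEllipsoidVolume(g$epiAxes, g$zBase)
  list(endoAxes = g$endoAxes, epiAxes = g$epiAxes, zBase = g$zBase,
       pose = spec@pose, cavityML = cav / 1000, myocardiumML = (epi - cav) / 1000)
}

#' Imaging parameters for rendering a phantom study
#'
#' Defaults mirror a legacy fast gradient-echo protocol: 10 short-axis
#' slices of 6 mm thickness with a 4 mm gap (10 mm slab), rendered on a
#' square matrix. \code{centerJitterMm} and \code{inPlaneRotDeg} randomize
#' the in-plane placement of the imaging grids (per view), emulating
#' operator variability in plane prescription; both default to zero.
#'
#' @param nSax number of short-axis slices.
#' @param matrixSize image matrix (square).
#' @param pixelSpacing in-plane pixel spacing, mm.
#' @param thickness,gap slice thickness and inter-slice gap, mm.
#' @param nFrames cardiac frames from ED (first) to ES (last).
#' @param centerJitterMm max in-plane offset of the image center, mm.
#' @param inPlaneRotDeg max in-plane rotation of the image grid, degrees.
#' @return A named list of imaging parameters.
#' @export
imagingParams <- function(nSax = 10, matrixSize = 96, pixelSpacing = 2,
                          thickness = 6, gap = 4, nFrames = 3,
                          centerJitterMm = 0, inPlaneRotDeg = 0) {
  list(nSax = as.integer(nSax), matrixSize = as.integer(matrixSize),
       pixelSpacing = pixelSpacing, thickness = thickness, gap = gap,
       nFrames = as.integer(nFrames), centerJitterMm = centerJitterMm,
       inPlaneRotDeg = inPlaneRotDeg)
}

# Azimuthal extent of the RV half-annulus (septum at 180 degrees) and the
# long-axis plane azimuths of the two LAX views.
RV_ARC <- c(120, 240) * pi / 180
LAX_AZIMUTH <- c("2CH" = 60, "4CH" = 150) * pi / 180

# Tissue intensities on [0, 1].
INTENS <- c(background = 0.15, myocardium = 0.55, cavity = 1.0, rv = 0.8)

# Model-frame slice grid: origin and in-plane direction cosines (model
# coordinates), pixel spacing and matrix size.
modelGrid <- function(center, rowDir, colDir, ps, M) {
  ctrOff <- (M - 1) / 2 * ps
  list(origin = center - ctrOff * rowDir - ctrOff * colDir,
       rowDir = rowDir, colDir = colDir, ps = ps, M = M)
}

# Project a model-frame point onto a model grid -> (row, col) pixel coords.
modelToPixel <- function(pm, gm) {
  d <- pm - gm$origin
  c(row = sum(d * gm$colDir) / gm$ps, col = sum(d * gm$rowDir) / gm$ps)
}

# Rasterize one slice plane for phase weight w; labels 0 bg / 1 myo /
# 2 cavity (the RV half-annulus renders as tissue but labels background).
rasterizeSlice <- function(spec, gm, w, noise) {
  g <- phaseGeometry(spec, w)
  M <- gm$M
  idx <- 0:(M - 1)
  P <- outer(rep(1, M * M), gm$origin) +
    outer(rep(idx, each = M) * gm$ps, gm$rowDir) +  # column index
    outer(rep(idx, times = M) * gm$ps, gm$colDir)   # row index
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  sEndo <- (x / g$endoAxes[1])^2 + (y / g$endoAxes[2])^2 + (z / g$endoAxes[3])^2
  sEpi <- (x / g$epiAxes[1])^2 + (y / g$epiAxes[2])^2 + (z / g$epiAxes[3])^2
  below <- z <= g$zBase
  cavity <- sEndo <= 1 & below
  myo <- sEpi <= 1 & below & !cavity
  az <- atan2(y, x); az <- ifelse(az < 0, az + 2 * pi, az)
  rv <- sEpi > 1 & sqrt(sEpi) <= 1 + spec@rvOffset / g$epiAxes[1] &
    az >= RV_ARC[1] & az <= RV_ARC[2] & below
  img <- rep(INTENS[["background"]], M * M)
  img[rv] <- INTENS[["rv"]]
  img[myo] <- INTENS[["myocardium"]]
  img[cavity] <- INTENS[["cavity"]]
  image <- matrix(img, M, M)   # element (row, col): row index fastest
  if (noise > 0) image <- image + matrix(rnorm(M * M, 0, noise), M, M)
  mask <- matrix(0L, M, M)
  mask[matrix(myo, M, M)] <- 1L
  mask[matrix(cavity, M, M)] <- 2L
  list(image = image, mask = mask)
}

# Analytic elliptical cross-section of a truncated ellipsoid at model
# height z, projected to pixel coordinates of `gm`; NULL if no section.
ellipseContourPixels <- function(axes, zBase, z, gm, npts = 48) {
  if (z > zBase + 1e-9 || abs(z) >= axes[3]) return(NULL)
  s <- sqrt(1 - (z / axes[3])^2)
  a <- axes[1] * s; b <- axes[2] * s
  t <- seq(0, 2 * pi, length.out = npts + 1)[-(npts + 1)]
  pts3 <- cbind(a * cos(t), b * sin(t), z)
  rc <- t(apply(pts3, 1, modelToPixel, gm = gm))
  xy <- cbind(row = rc[, 1], col = rc[, 2])
  if (polygonArea(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  xy
}

#' Render a phantom into a cine study with full slice geometry
#'
#' Builds a short-axis stack (apex to base) plus 2CH and 4CH long-axis
#' views. Every slice carries origin, direction cosines, pixel spacing,
#' thickness, gap and trigger time; images have three intensity bands
#' (bright cavity, mid myocardium, dark background, plus an RV half-annulus)
#' with additive Gaussian noise. Ground truth includes closed-form volumes,
#' per-slice 3-label masks, analytic endo/epi contours (pixel coordinates),
#' and mitral-valve / RV-insertion landmarks in both pixel and patient
#' coordinates. Slices whose plane misses the LV get an empty mask and are
#' flagged in \code{study@meta$emptySlices}.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param imaging see \code{\link{imagingParams}}.
#' @return list(study = \linkS4class{CineStudy}, truth =
#'   \linkS4class{GroundTruth}).
#' @export
renderCineStudy <- function(spec, imaging = imagingParams()) {
  validObject(spec)
  withSeed(spec@seed, {
    M <- imaging$matrixSize; ps <- imaging$pixelSpacing
    nf <- imaging$nFrames
    w <- if (nf == 1) 0 else seq(0, 1, length.out = nf)
    trig <- 40 * (seq_len(nf) - 1)
    slab <- imaging$thickness + imaging$gap
    z0 <- spec@baseTruncation * spec@endoAxes[3]
    zTop <- z0 - slab / 2
    zs <- zTop - (imaging$nSax - seq_len(imaging$nSax)) * slab  # apex first
    R <- spec@pose[1:3, 1:3]
    jit <- function() if (imaging$centerJitterMm > 0)
      runif(2, -imaging$centerJitterMm, imaging$centerJitterMm) else c(0, 0)
    rot <- function() if (imaging$inPlaneRotDeg > 0)
      runif(1, -imaging$inPlaneRotDeg, imaging$inPlaneRotDeg) * pi / 180 else 0

    slices <- list(); masks <- list(); contours <- list(); lms <- list()
    empty <- integer()
    mkGeom <- function(gm, view, tt) {
      sliceGeometry(origin = applyTransform(spec@pose, gm$origin),
                    rowDir = drop(R %*% gm$rowDir), colDir = drop(R %*% gm$colDir),
                    pixelSpacing = c(ps, ps), thickness = imaging$thickness,
                    gap = imaging$gap, triggerTime = tt, view = view)
    }

    # --- SAX stack: one shared in-plane placement for the whole stack ---
    bS <- rot(); oS <- jit()
    rdS <- c(cos(bS), sin(bS), 0); cdS <- c(-sin(bS), cos(bS), 0)
    for (k in seq_len(imaging$nSax)) {
      gm <- modelGrid(c(oS[1], oS[2], zs[k]), rdS, cdS, ps, M)
      frames <- vector("list", nf); fmasks <- vector("list", nf)
      for (t in seq_len(nf)) {
        rs <- rasterizeSlice(spec, gm, w[t], spec@noiseSd)
        frames[[t]] <- rs$image; fmasks[[t]] <- rs$mask
        ph <- phaseGeometry(spec, w[t])
        for (lab in c("endocardium", "epicardium")) {
          axes <- if (lab == "endocardium") ph$endoAxes else ph$epiAxes
          xy <- ellipseContourPixels(axes, ph$zBase, zs[k], gm)
          if (!is.null(xy))
            contours[[length(contours) + 1L]] <- data.frame(
              slice_id = k, frame_id = t, label = lab,
              point_index = seq_len(nrow(xy)) - 1L, row = xy[, 1], col = xy[, 2])
        }
        # RV insertion points on the epicardial section
        if (zs[k] <= ph$zBase && abs(zs[k]) < ph$epiAxes[3]) {
          s <- sqrt(1 - (zs[k] / ph$epiAxes[3])^2)
          A <- ph$epiAxes[1] * s; B <- ph$epiAxes[2] * s
          for (ip in 1:2) {
            psi <- RV_ARC[ip]
            r <- 1 / sqrt((cos(psi) / A)^2 + (sin(psi) / B)^2)
            pm <- c(r * cos(psi), r * sin(psi), zs[k])
            rc <- modelToPixel(pm, gm)
            pp <- applyTransform(spec@pose, pm)
            lms[[length(lms) + 1L]] <- data.frame(
              view = "SAX", slice_id = k, frame_id = t, point_index = ip,
              row = rc[1], col = rc[2], x = pp[1], y = pp[2], z = pp[3])
          }
        }
      }
      if (all(vapply(fmasks, function(m) !any(m > 0), logical(1))))
        empty <- c(empty, k)
      slices[[k]] <- list(geometry = mkGeom(gm, "SAX", trig[1]),
                          frames = frames, triggerTimes = trig)
      masks[[k]] <- fmasks
    }

    # --- LAX views ---
    zc <- (z0 - spec@endoAxes[3]) / 2
    for (view in c("2CH", "4CH")) {
      phiv <- LAX_AZIMUTH[[view]]
      u <- c(cos(phiv), sin(phiv), 0)
      dn <- c(0, 0, -1)  # image "down" = toward the apex
      bL <- rot(); oL <- jit()
      rd <- cos(bL) * u + sin(bL) * dn
      cd <- -sin(bL) * u + cos(bL) * dn
      center <- oL[1] * u + c(0, 0, zc + oL[2])
      gm <- modelGrid(center, rd, cd, ps, M)
      frames <- vector("list", nf)
      sid <- imaging$nSax + match(view, c("2CH", "4CH"))
      for (t in seq_len(nf)) {
        rs <- rasterizeSlice(spec, gm, w[t], spec@noiseSd)
        frames[[t]] <- rs$image
        # MV hinge points: intersection of this plane with the basal rim
        ph <- phaseGeometry(spec, w[t])
        s <- sqrt(max(0, 1 - (ph$zBase / ph$endoAxes[3])^2))
        ar <- ph$endoAxes[1] * s; br <- ph$endoAxes[2] * s
        th <- atan2(ar * u[2], br * u[1])
        for (ip in 1:2) {
          tt2 <- th + (ip - 1) * pi
          pm <- c(ar * cos(tt2), br * sin(tt2), ph$zBase)
          rc <- modelToPixel(pm, gm)
          pp <- applyTransform(spec@pose, pm)
          lms[[length(lms) + 1L]] <- data.frame(
            view = view, slice_id = sid, frame_id = t, point_index = ip,
            row = rc[1], col = rc[2], x = pp[1], y = pp[2], z = pp[3])
        }
      }
      slices[[sid]] <- list(geometry = mkGeom(gm, view, trig[1]),
                            frames = frames, triggerTimes = trig)
    }

    study <- new("CineStudy", slices = slices,
                 meta = list(imaging = imaging, seed = spec@seed,
                             emptySlices = empty))
    vED <- generatePhantom(spec, "ED"); vES <- generatePhantom(spec, "ES")
    truth <- new("GroundTruth",
                 volumes = list(edCavity = vED$cavityML, esCavity = vES$cavityML,
                                edMyocardium = vED$myocardiumML,
                                esMyocardium = vES$myocardiumML),
                 landmarks = do.call(rbind, lms),
                 contours = do.call(rbind, contours),
                 masks = masks,
                 shifts = matrix(0, imaging$nSax, 2,
                                 dimnames = list(NULL, c("dRow", "dCol"))),
                 spec = spec)
    list(study = study, truth = truth)
  })
}

#' Inject in-plane breath-hold misregistration
#'
#' Translates each short-axis slice origin in-plane by an independent
#' uniform random 2-vector in [-maxShift, maxShift]^2 mm (image content is
#' untouched, so the header no longer reflects where the tissue truly was —
#' the misregistration a breath-hold offset produces). Long-axis views and
#' the longitudinal component are untouched.
#'
#' @param study A \linkS4class{CineStudy}.
#' @param maxShift maximum per-component shift, mm.
#' @param seed integer RNG seed.
#' @param truth optional \linkS4class{GroundTruth}; returned with its
#'   \code{shifts} slot filled.
#' @return list(study, shifts, truth). \code{shifts} is n SAX x 2 mm
#'   (dRow along colDir, dCol along rowDir).
#' @export
applyBreathholdShifts <- function(study, maxShift, seed = 1L, truth = NULL) {
  sax <- saxIndices(study)
  shifts <- matrix(0, length(sax), 2, dimnames = list(NULL, c("dRow", "dCol")))
  if (maxShift > 0) {
    withSeed(seed, {
      for (i in seq_along(sax)) {
        d <- runif(2, -maxShift, maxShift)
        shifts[i, ] <- d
        g <- study@slices[[sax[i]]]$geometry
        g@origin <- g@origin + d[1] * g@colDir + d[2] * g@rowDir
        study@slices[[sax[i]]]$geometry <- g
      }
    })
  }
  if (!is.null(truth)) truth@shifts <- shifts
  list(study = study, shifts = shifts, truth = truth)
}
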