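# Study-level model customization: landmarks -> pose, contours -> 3D,
# two-pass breath-hold correction, final low-regularization fit.

# Convert contour pixel coordinates of one slice/frame to patient mm.
contourPatient <- function(contours, lab, slice, frame, g) {
  px <- contourPoints(contours, lab, slice = slice, frame = frame)
  if (is.null(px)) return(NULL)
  pixelToPatient(px, g)
}

# Landmark pixel coordinates -> patient mm through the slice geometry the
# landmark was observed on (the header is the measurement frame).
landmarksPatient <- function(landmarks, study, views, frame) {
  d <- landmarks[landmarks$view %in% views & landmarks$frame_id == frame, ,
                 drop = FALSE]
  if (!nrow(d)) return(matrix(numeric(0), 0, 3))
  out <- matrix(0, nrow(d), 3)
  for (i in seq_len(nrow(d))) {
    g <- study@slices[[d$slice_id[i]]]$geometry
    out[i, ] <- pixelToPatient(c(d$row[i], d$col[i]), g)
  }
  out
}

# ED = earliest trigger frame; ES = frame minimizing summed cavity area.
selectPhases <- function(study, contours) {
  sax <- saxIndices(study)
  tt <- study@slices[[sax[1]]]$triggerTimes
  ed <- which.min(tt)
  frames <- sort(unique(contours$frame_id))
  ps <- study@slices[[sax[1]]]$geometry@pixelSpacing
  tot <- vapply(frames, function(f)
    sum(contourAreas(contours, f, ps)$cavity_mm2), numeric(1))
  es <- frames[which.min(tot)]
  list(ed = ed, es = es)
}

# Collect all endo/epi contour points of the SAX slices of one frame.
saxContourCloud <- function(study, contours, frame, lab) {
  pts <- list()
  for (k in saxIndices(study)) {
    p <- contourPatient(contours, lab, k, frame, study@slices[[k]]$geometry)
    if (!is.null(p)) pts[[length(pts) + 1L]] <- cbind(p, k)
  }
  if (!length(pts)) return(NULL)
  m <- do.call(rbind, pts)
  list(points = m[, 1:3, drop = FALSE], slice = m[, 4])
}

# Pose from landmarks with the apex estimated from the contours: the most
# apical SAX endocardial centroid extended by half a slab along the long
# axis. When the SAX stack normal is within `anchorDeg` of the MV-to-apex
# direction, the long axis is anchored along the stack normal (the
# longitudinal geometry is immune to in-plane breath-hold shifts).
studyPose <- function(study, contours, landmarks, edFrame, anchorDeg = 15) {
  mv <- landmarksPatient(landmarks, study, c("2CH", "4CH"), edFrame)
  rv <- landmarksPatient(landmarks, study, "SAX", edFrame)
  if (nrow(mv) < 2 || nrow(rv) < 2)
    stop("pose initialization needs >= 2 MV points and >= 2 RV inserts")
  mvc <- colMeans(mv)
  sax <- saxIndices(study)
  cents <- list()
  for (k in sax) {
    px <- contourPoints(contours, "endocardium", slice = k, frame = edFrame)
    if (is.null(px)) next
    g <- study@slices[[k]]$geometry
    cents[[length(cents) + 1L]] <-
      c(drop(pixelToPatient(polygonCentroid(px), g)), k)
  }
  if (!length(cents)) stop("no endocardial contours to estimate the apex from")
  cm <- do.call(rbind, cents)
  d <- sqrt(rowSums((cm[, 1:3, drop = FALSE] -
                       matrix(mvc, nrow(cm), 3, byrow = TRUE))^2))
  apicalC <- cm[which.max(d), 1:3]
  g1 <- study@slices[[sax[1]]]$geometry
  slab <- g1@thickness + g1@gap
  dir0 <- unitv(apicalC - mvc)
  apex <- apicalC + 0.5 * slab * dir0
  pose <- initializePose(mv, rv, apex)
  nrm <- sliceNormal(g1)
  if (sum(nrm * pose$R[, 3]) < 0) nrm <- -nrm
  if (acos(pmin(1, sum(nrm * pose$R[, 3]))) * 180 / pi < anchorDeg) {
    e3 <- nrm
    L <- sum((apex - pose$t) * e3)
    dsep <- colMeans(landmarksPatient(landmarks, study, "SAX", edFrame)) - pose$t
    dsep <- dsep - sum(dsep * e3) * e3
    e1 <- unitv(dsep)
    pose <- list(R = cbind(e1, pracma::cross(e3, e1), e3), t = pose$t, L = L)
  }
  pose
}

fitPhase <- function(study, contours, frame, phase, pose, template, lambda,
                     maxIter, tol, thetaInit = list(endo = NULL, epi = NULL)) {
  out <- list()
  for (sf in c("endo", "epi")) {
    lab <- if (sf == "endo") "endocardium" else "epicardium"
    cl <- saxContourCloud(study, contours, frame, lab)
    if (is.null(cl)) stop("no ", lab, " contours in frame ", frame)
    f <- fitSurfaces(cl$points, sf, pose, template, lambda,
                     maxIter = maxIter, tol = tol, thetaInit = thetaInit[[sf]])
    out[[sf]] <- f
    out[[paste0(sf, "Res")]] <- data.frame(
      phase = phase, surface = sf, slice_id = cl$slice, residual_mm = f$residuals)
  }
  out
}

#' Two-pass breath-hold misregistration correction and final model fit
#'
#' Pass 1 fits a highly regularized (shape-preserving) model to the ED
#' contours; every SAX slice is then translated in-plane (two degrees of
#' freedom, none longitudinally) so its endocardial contour centroid lands
#' on the area-weighted centroid of the model-slice intersection; pass 2
#' refits both phases with a low regularization weight on the corrected
#' geometry.
#'
#' @param study A \linkS4class{CineStudy}.
#' @param contours contour table (pixel coordinates).
#' @param landmarks landmark table (pixel coordinates with view/slice/frame).
#' @param config see \code{\link{fitConfig}}.
#' @param template see \code{\link{lvTemplate}}.
#' @return list(fit = \linkS4class{FittedLV}, shifts = n SAX x 2 estimated
#'   displacements (dRow, dCol) mm, correctedStudy, pass1Rms, pass2Rms,
#'   flaggedSlices).
#' @export
correctBreathhold <- function(study, contours, landmarks,
                              config = fitConfig(), template = lvTemplate()) {
  ph <- selectPhases(study, contours)
  pose <- studyPose(study, contours, landmarks, ph$ed)
  p1 <- fitPhase(study, contours, ph$ed, "ED", pose, template,
                 config$lambdaHigh, maxIter = 2, tol = config$tol)
  fit1 <- new("FittedLV", endoED = p1$endo$theta, epiED = p1$epi$theta,
              endoES = p1$endo$theta, epiES = p1$epi$theta, pose = pose,
              template = template,
              residuals = rbind(p1$endoRes, p1$epiRes))
  sax <- saxIndices(study)
  shifts <- matrix(0, length(sax), 2, dimnames = list(NULL, c("dRow", "dCol")))
  flagged <- integer()
  corrected <- study
  for (i in seq_along(sax)) {
    k <- sax[i]
    g <- study@slices[[k]]$geometry
    px <- contourPoints(contours, "endocardium", slice = k, frame = ph$ed)
    if (is.null(px)) { flagged <- c(flagged, k); next }
    sec <- intersectWithSlice(fit1, g, phase = "ED", surface = "endo")
    if (sec$empty) { flagged <- c(flagged, k); next }
    cd <- drop(pixelToPatient(polygonCentroid(px), g))
    s <- sec$centroidPatient - cd
    # keep the correction strictly in-plane
    nrm <- sliceNormal(g)
    s <- s - sum(s * nrm) * nrm
    shifts[i, ] <- c(-sum(s * g@colDir), -sum(s * g@rowDir))
    g@origin <- g@origin + s
    corrected@slices[[k]]$geometry <- g
  }
  p2ed <- fitPhase(corrected, contours, ph$ed, "ED", pose, template,
                   config$lambdaLow, maxIter = config$maxIter, tol = config$tol,
                   thetaInit = list(endo = p1$endo$theta, epi = p1$epi$theta))
  p2es <- fitPhase(corrected, contours, ph$es, "ES", pose, template,
                   config$lambdaLow, maxIter = config$maxIter, tol = config$tol,
                   thetaInit = list(endo = p2ed$endo$theta, epi = p2ed$epi$theta))
  fit <- new("FittedLV", endoED = p2ed$endo$theta, epiED = p2ed$epi$theta,
             endoES = p2es$endo$theta, epiES = p2es$epi$theta, pose = pose,
             template = template,
             residuals = rbind(p2ed$endoRes, p2ed$epiRes,
                               p2es$endoRes, p2es$epiRes))
  list(fit = fit, shifts = shifts, correctedStudy = corrected,
       pass1Rms = sqrt(mean(c(p1$endo$residuals, p1$epi$residuals)^2)),
       pass2Rms = sqrt(mean(c(p2ed$endo$residuals, p2ed$epi$residuals)^2)),
       flaggedSlices = flagged, phases = ph)
}

#' Customize the LV model to one study
#'
#' Convenience wrapper: with \code{correct = TRUE} runs the two-pass
#' breath-hold correction; otherwise a single low-regularization fit.
#'
#' @inheritParams correctBreathhold
#' @param correct run the misregistration correction.
#' @return see \code{\link{correctBreathhold}}; without correction the
#'   shifts are zero.
#' @export
fitLV <- function(study, contours, landmarks, config = fitConfig(),
                  template = lvTemplate(), correct = TRUE) {
  if (correct)
    return(correctBreathhold(study, contours, landmarks, config, template))
  ph <- selectPhases(study, contours)
  pose <- studyPose(study, contours, landmarks, ph$ed)
  p2ed <- fitPhase(study, contours, ph$ed, "ED", pose, template,
                   config$lambdaLow, config$maxIter, config$tol)
  p2es <- fitPhase(study, contours, ph$es, "ES", pose, template,
                   config$lambdaLow, config$maxIter, config$tol,
                   thetaInit = list(endo = p2ed$endo$theta, epi = p2ed$epi$theta))
  fit <- new("FittedLV", endoED = p2ed$endo$theta, epiED = p2ed$epi$theta,
             endoES = p2es$endo$theta, epiES = p2es$epi$theta, pose = pose,
             template = template,
             residuals = rbind(p2ed$endoRes, p2ed$epiRes,
                               p2es$endoRes, p2es$epiRes))
  sax <- saxIndices(study)
  list(fit = fit, shifts = matrix(0, length(sax), 2,
                                  dimnames = list(NULL, c("dRow", "dCol"))),
       correctedStudy = study, pass1Rms = NA_real_,
       pass2Rms = sqrt(mean(c(p2ed$endo$residuals, p2ed$epi$residuals)^2)),
       flaggedSlices = integer(), phases = ph)
}
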