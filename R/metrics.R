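#' Slice-summation (disk) volume
#'
#' Sum of per-slice cavity areas times the slab height (slice thickness plus
#' gap), the standard short-axis disk summation. Slices without contours
#' simply contribute nothing and should be omitted from \code{areas}.
#'
#' @param areas per-slice cavity areas, mm^2 (only slices with contours).
#' @param thickness slice thickness, mm.
#' @param gap inter-slice gap, mm.
#' @return volume in mL.
#' @export
sliceSummationVolume <- function(areas, thickness = 6, gap = 4) {
  if (any(areas < 0)) stop("areas must be non-negative")
  sum(areas) * (thickness + gap) / 1000
}

#' Left-ventricular mass from myocardial volume
#'
#' @param myoVolumeML myocardial volume, mL.
#' @param density myocardial density, g/mL (1.05 by convention).
#' @return mass in g.
#' @export
lvMass <- function(myoVolumeML, density = 1.05) {
  if (any(myoVolumeML < 0)) stop("myocardial volume must be non-negative")
  myoVolumeML * density
}

#' Ejection fraction
#'
#' (EDV - ESV) / EDV * 100; identical for raw and BSA-indexed volumes.
#'
#' @param edv,esv end-diastolic and end-systolic volume (raw or indexed).
#' @return percent.
#' @export
ejectionFraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("end-diastolic volume must be positive")
  (edv - esv) / edv * 100
}

#' Body surface area
#'
#' Du Bois by default: 0.007184 * W^0.425 * H^0.725 (W kg, H cm); the
#' Mosteller alternative sqrt(H*W/3600) is selectable.
#'
#' @param heightCm,weightKg anthropometrics.
#' @param formula "dubois" or "mosteller".
#' @return BSA in m^2.
#' @export
bodySurfaceArea <- function(heightCm, weightKg, formula = c("dubois", "mosteller")) {
  if (any(heightCm <= 0) || any(weightKg <= 0))
    stop("height and weight must be positive")
  formula <- match.arg(formula)
  switch(formula,
         dubois = 0.007184 * weightKg^0.425 * heightCm^0.725,
         mosteller = sqrt(heightCm * weightKg / 3600))
}

#' Clinical measures with BSA indexing
#'
#' Assembles LVEDV/LVESV/mass, indexes them by body surface area and
#' computes the ejection fraction.
#'
#' @param edvML,esvML cavity volumes, mL.
#' @param massG LV mass, g.
#' @param heightCm,weightKg anthropometrics.
#' @param bsaFormula passed to \code{\link{bodySurfaceArea}}.
#' @return list: LVEDV, LVESV, LVMass, BSA, LVEDVi, LVESVi, LVMi, LVEF.
#' @export
clinicalMeasures <- function(edvML, esvML, massG, heightCm, weightKg,
                             bsaFormula = "dubois") {
  bsa <- bodySurfaceArea(heightCm, weightKg, bsaFormula)
  list(LVEDV = edvML, LVESV = esvML, LVMass = massG, BSA = bsa,
       LVEDVi = edvML / bsa, LVESVi = esvML / bsa, LVMi = massG / bsa,
       LVEF = ejectionFraction(edvML, esvML))
}

#' Bland-Altman agreement and Pearson correlation for paired series
#'
#' Differences are y - x; limits of agreement are mean(d) +/- 1.96 sd(d).
#'
#' @param x,y paired measurement series, length >= 3.
#' @return list: meanDiff, sdDiff, limits (length 2), r (NA and
#'   \code{flagged = TRUE} when either series is constant), and \code{table}
#'   with per-pair (mean, difference) for plotting.
#' @export
agreementStats <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- y - x
  m <- mean(d); s <- sd(d)
  flagged <- sd(x) == 0 || sd(y) == 0
  r <- if (flagged) NA_real_ else cor(x, y)
  list(meanDiff = m, sdDiff = s, limits = c(m - 1.96 * s, m + 1.96 * s),
       r = r, flagged = flagged,
       table = data.frame(mean = (x + y) / 2, difference = d))
}

#' Intraclass correlation, two-way random effects, single rater,
#' absolute agreement (ICC(2,1))
#'
#' Computed from the two-way ANOVA mean squares: with n subjects (rows) and
#' k raters (columns),
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#'
#' @param ratings n x k matrix, no missing cells, n >= 2, k >= 2.
#' @return ICC value; 0 with a warning when between-subject variance is zero.
#' @export
iccTwoWay <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2, !anyNA(ratings))
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps) {
    warning("zero between-subject variance; ICC undefined, returning 0")
    return(0)
  }
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Per-slice cavity and myocardial areas from a contour table
#'
#' Shoelace polygon areas in mm^2 for one frame; the myocardial area is the
#' epicardial minus the cavity area.
#'
#' @param contours contour data.frame (pixel coordinates).
#' @param frame frame id.
#' @param pixelSpacing mm pair (row, col spacing).
#' @return data.frame(slice_id, cavity_mm2, myo_mm2).
#' @export
contourAreas <- function(contours, frame, pixelSpacing) {
  pxArea <- pixelSpacing[1] * pixelSpacing[2]
  sids <- sort(unique(contours$slice_id[contours$frame_id == frame]))
  out <- lapply(sids, function(s) {
    endo <- contourPoints(contours, "endocardium", slice = s, frame = frame)
    epi <- contourPoints(contours, "epicardium", slice = s, frame = frame)
    cav <- if (is.null(endo)) 0 else abs(polygonArea(endo)) * pxArea
    epiA <- if (is.null(epi)) 0 else abs(polygonArea(epi)) * pxArea
    data.frame(slice_id = s, cavity_mm2 = cav, myo_mm2 = max(0, epiA - cav))
  })
  do.call(rbind, out)
}
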