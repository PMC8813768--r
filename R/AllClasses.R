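#' Per-slice acquisition geometry
#'
#' Holds the geometric content of an MR image header: the patient-space
#' position of the first pixel's center, the direction cosines of the image
#' rows and columns, pixel spacing, slice thickness and inter-slice gap,
#' trigger time and the view type. \code{rowDir} is the patient-space
#' direction of increasing \emph{column} index and \code{colDir} of
#' increasing \emph{row} index; \code{pixelSpacing} is (row spacing,
#' column spacing) in mm. Pixel indices are 0-based at pixel centers.
#'
#' @slot origin numeric(3), mm.
#' @slot rowDir,colDir unit direction cosines.
#' @slot pixelSpacing numeric(2), mm.
#' @slot thickness,gap slice thickness and gap, mm.
#' @slot triggerTime ms (NA when absent).
#' @slot view one of "SAX", "2CH", "4CH".
#' @export
setClass("SliceGeometry",
  representation(origin = "numeric", rowDir = "numeric", colDir = "numeric",
                 pixelSpacing = "numeric", thickness = "numeric",
                 gap = "numeric", triggerTime = "numeric", view = "character"),
  prototype(thickness = 6, gap = 4, triggerTime = NA_real_, view = "SAX"))

setValidity("SliceGeometry", function(object) {
  msg <- character()
  if (length(object@origin) != 3) msg <- c(msg, "origin must have length 3")
  if (abs(vnorm(object@rowDir) - 1) > 1e-6) msg <- c(msg, "rowDir must be unit length")
  if (abs(vnorm(object@colDir) - 1) > 1e-6) msg <- c(msg, "colDir must be unit length")
  if (abs(sum(object@rowDir * object@colDir)) > 1e-6)
    msg <- c(msg, "rowDir and colDir must be orthogonal")
  if (any(object@pixelSpacing <= 0)) msg <- c(msg, "pixelSpacing must be positive")
  if (!object@view %in% c("SAX", "2CH", "4CH")) msg <- c(msg, "view must be SAX, 2CH or 4CH")
  if (length(msg)) msg else TRUE
})

#' Construct a SliceGeometry
#' @param origin,rowDir,colDir,pixelSpacing,thickness,gap,triggerTime,view see
#'   the class documentation.
#' @return A \linkS4class{SliceGeometry}.
#' @export
sliceGeometry <- function(origin, rowDir, colDir, pixelSpacing,
                          thickness = 6, gap = 4, triggerTime = NA_real_,
                          view = "SAX") {
  new("SliceGeometry", origin = as.numeric(origin), rowDir = as.numeric(rowDir),
      colDir = as.numeric(colDir), pixelSpacing = as.numeric(pixelSpacing),
      thickness = thickness, gap = gap, triggerTime = triggerTime, view = view)
}

# Plane unit normal of a slice.
sliceNormal <- function(g) unitv(pracma::cross(g@rowDir, g@colDir))

#' A single-subject cine study
#'
#' A short-axis stack plus two long-axis views. Each element of \code{slices}
#' is a list with components \code{geometry} (a \linkS4class{SliceGeometry}),
#' \code{frames} (a list of image matrices, one per cardiac frame) and
#' \code{triggerTimes} (numeric, ms, one per frame). Short-axis slices are
#' stored apex to base.
#'
#' @slot slices list as described above.
#' @slot meta list of acquisition / provenance metadata.
#' @export
setClass("CineStudy", representation(slices = "list", meta = "list"))

setValidity("CineStudy", function(object) {
  ok <- vapply(object@slices, function(s)
    is.list(s) && all(c("geometry", "frames", "triggerTimes") %in% names(s)) &&
      is(s$geometry, "SliceGeometry"), logical(1))
  if (!all(ok)) return("each slice needs geometry, frames and triggerTimes")
  TRUE
})

#' @describeIn CineStudy indices of the short-axis slices
#' @param study A CineStudy.
#' @export
saxIndices <- function(study)
  which(vapply(study@slices, function(s) s$geometry@view == "SAX", logical(1)))

#' @describeIn CineStudy index of a long-axis view ("2CH" or "4CH")
#' @param view view label.
#' @export
laxIndex <- function(study, view)
  which(vapply(study@slices, function(s) s$geometry@view == view, logical(1)))

#' @describeIn CineStudy number of frames
#' @export
nFrames <- function(study) length(study@slices[[1]]$frames)

setMethod("show", "CineStudy", function(object) {
  nsax <- length(saxIndices(object))
  cat(sprintf("CineStudy: %d SAX slice(s), %d LAX view(s), %d frame(s)\n",
              nsax, length(object@slices) - nsax, nFrames(object)))
})

#' Analytic left-ventricular phantom specification
#'
#' A truncated-ellipsoid LV: the endocardial surface is an ellipsoid with
#' semi-axes \code{endoAxes} (mm) cut by a basal plane at a fraction
#' \code{baseTruncation} of the long semi-axis above the equator; the
#' epicardial ellipsoid adds \code{wallThickness} to each semi-axis. At
#' end-systole the endocardial semi-axes shrink by the fraction
#' \code{esContraction} and the wall thickens. \code{pose} is a 4x4 rigid
#' transform placing the model frame (long axis = +z, base above apex) in
#' patient space. A half-annulus of right-ventricular tissue abuts the
#' septum (the -x side) with radial extent \code{rvOffset} mm, defining the
#' RV insertion points.
#'
#' @slot endoAxes numeric(3) mm.
#' @slot wallThickness mm.
#' @slot baseTruncation fraction in (0,1).
#' @slot esContraction fraction in [0,1).
#' @slot pose 4x4 rigid transform.
#' @slot rvOffset mm.
#' @slot noiseSd image-intensity noise SD (intensities are on [0,1]).
#' @slot seed integer.
#' @export
setClass("PhantomSpec",
  representation(endoAxes = "numeric", wallThickness = "numeric",
                 baseTruncation = "numeric", esContraction = "numeric",
                 pose = "matrix", rvOffset = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@endoAxes) != 3 || any(object@endoAxes <= 0))
    msg <- c(msg, "endoAxes: all semi-axes must be positive")
  if (object@wallThickness <= 0)
    msg <- c(msg, "wallThickness: must be positive (epi axes must exceed endo axes)")
  if (object@baseTruncation < 0 || object@baseTruncation >= 1)
    msg <- c(msg, "baseTruncation: must lie in [0, 1)")
  if (object@esContraction < 0 || object@esContraction >= 1)
    msg <- c(msg, "esContraction: must lie in [0, 1)")
  if (!all(dim(object@pose) == c(4, 4)))
    msg <- c(msg, "pose: must be a 4x4 matrix")
  if (object@rvOffset <= 0) msg <- c(msg, "rvOffset: must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd: must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe a mid-size adult LV: endocardial semi-axes 25 x 25 x 60
#' mm truncated half-way up the long axis (LV length 90 mm), 8 mm diastolic
#' wall, 30\% end-systolic short-axis contraction.
#'
#' @param endoAxes,wallThickness,baseTruncation,esContraction,pose,rvOffset,noiseSd,seed
#'   see \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(endoAxes = c(25, 25, 60), wallThickness = 8,
                        baseTruncation = 0.5, esContraction = 0.3,
                        pose = diag(4), rvOffset = 12, noiseSd = 0.05,
                        seed = 1L) {
  new("PhantomSpec", endoAxes = as.numeric(endoAxes),
      wallThickness = wallThickness, baseTruncation = baseTruncation,
      esContraction = esContraction, pose = pose, rvOffset = rvOffset,
      noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: endo (%.1f, %.1f, %.1f) mm, wall %.1f mm, truncation %.2f, ES contraction %.2f\n",
    object@endoAxes[1], object@endoAxes[2], object@endoAxes[3],
    object@wallThickness, object@baseTruncation, object@esContraction))
})

#' Ground truth accompanying a rendered phantom study
#'
#' @slot volumes named list: edCavity, esCavity, edMyocardium, esMyocardium (mL),
#'   from the closed-form truncated-ellipsoid volume.
#' @slot landmarks data.frame: view, slice_id, frame_id, point_index, row, col,
#'   x, y, z (pixel and patient coordinates of each landmark).
#' @slot contours data.frame: slice_id, frame_id, label, point_index, row, col.
#' @slot masks list indexed by slice then frame: true 3-label masks
#'   (0 background, 1 myocardium, 2 cavity) for the SAX slices.
#' @slot shifts matrix (n SAX slices x 2): injected in-plane origin shifts, mm.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("GroundTruth",
  representation(volumes = "list", landmarks = "data.frame",
                 contours = "data.frame", masks = "list", shifts = "matrix",
                 spec = "PhantomSpec"))

setMethod("show", "GroundTruth", function(object) {
  v <- object@volumes
  cat(sprintf("GroundTruth: EDV %.1f mL, ESV %.1f mL, ED myocardium %.1f mL\n",
              v$edCavity, v$esCavity, v$edMyocardium))
})

#' Synthetic cohort specification
#'
#' Describes a population of phantoms whose shape varies along one known
#' deformation mode, with a binary risk label shifting the mode score.
#'
#' @slot nSubjects integer >= 2.
#' @slot deformationMode one of "wall_thickening", "sphericalization",
#'   "dilation".
#' @slot effectSize standardized mean shift of the mode score between label
#'   groups (>= 0).
#' @slot prevalence fraction of subjects with label 1, in (0,1).
#' @slot heightRange,weightRange demographic sampling ranges (cm, kg).
#' @slot jitterSd SD of independent relative jitter on the remaining phantom
#'   parameters (0 gives a pure single-mode cohort).
#' @slot seed integer.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", deformationMode = "character",
                 effectSize = "numeric", prevalence = "numeric",
                 heightRange = "numeric", weightRange = "numeric",
                 jitterSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 2) msg <- c(msg, "nSubjects: must be >= 2")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence: must lie strictly in (0, 1)")
  if (object@effectSize < 0) msg <- c(msg, "effectSize: must be >= 0")
  if (!object@deformationMode %in% c("wall_thickening", "sphericalization", "dilation"))
    msg <- c(msg, "deformationMode: unknown mode")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#' @param nSubjects,deformationMode,effectSize,prevalence,heightRange,weightRange,jitterSd,seed
#'   see \linkS4class{CohortSpec}.
#' @return A \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects, deformationMode = "sphericalization",
                       effectSize = 0, prevalence = 0.5,
                       heightRange = c(150, 190), weightRange = c(50, 100),
                       jitterSd = 0.03, seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      deformationMode = deformationMode, effectSize = effectSize,
      prevalence = prevalence, heightRange = as.numeric(heightRange),
      weightRange = as.numeric(weightRange), jitterSd = jitterSd,
      seed = as.integer(seed))
}

#' Fitted two-surface LV model
#'
#' Control grids of the endocardial and epicardial surfaces at ED and ES in
#' the normalized pose-local frame, the pose placing them in patient space,
#' and per-point fit residuals.
#'
#' @slot endoED,epiED,endoES,epiES control-vertex matrices (nCtrl x 3,
#'   reduced grid: shared apex vertex + free rings), normalized local frame.
#' @slot pose list(R, t, L): rotation columns (septal, cross, long-axis
#'   base-to-apex), MV centroid (mm), and length scale (mm).
#' @slot template the \code{lvTemplate} the fit used.
#' @slot residuals data.frame: phase, surface, slice_id, residual_mm.
#' @export
setClass("FittedLV",
  representation(endoED = "matrix", epiED = "matrix", endoES = "matrix",
                 epiES = "matrix", pose = "list", template = "list",
                 residuals = "data.frame"))

setMethod("show", "FittedLV", function(object) {
  cat(sprintf("FittedLV: %dx%d control grid per surface, RMS residual %.3f mm\n",
              object@template$nCirc, object@template$nLong,
              sqrt(mean(object@residuals$residual_mm^2))))
})

#' Statistical shape atlas
#'
#' @slot meanShape numeric 12N vector (mm), Procrustes-aligned frame.
#' @slot directions orthonormal matrix (12N x k) of principal directions.
#' @slot eigenvalues numeric(k), variances (mm^2), non-increasing.
#' @slot scores matrix (n subjects x k) of PC scores, zero column means.
#' @slot alignment list of per-subject rigid transforms used by Procrustes.
#' @slot npoints N, the per-surface sample count.
#' @export
setClass("AtlasModel",
  representation(meanShape = "numeric", directions = "matrix",
                 eigenvalues = "numeric", scores = "matrix",
                 alignment = "list", npoints = "integer"))

setValidity("AtlasModel", function(object) {
  msg <- character()
  if (length(object@meanShape) %% 12 != 0)
    msg <- c(msg, "meanShape length must be divisible by 12")
  k <- ncol(object@directions)
  if (k > 1) {
    g <- crossprod(object@directions)
    if (max(abs(g - diag(k))) > 1e-8) msg <- c(msg, "directions must be orthonormal")
  }
  if (any(diff(object@eigenvalues) > 1e-10)) msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < -1e-10)) msg <- c(msg, "eigenvalues must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AtlasModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("AtlasModel: N = %d points/surface, %d subjects, %d components (PC1 %.1f%% variance)\n",
              object@npoints, nrow(object@scores), length(ev),
              100 * ev[1] / sum(ev)))
})
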