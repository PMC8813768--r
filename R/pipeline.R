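# End-to-end orchestration: synthetic cohort -> (landmarks, contours) ->
# pose + breath-hold correction + surface fit -> clinical measures ->
# shape atlas -> risk association, with per-subject failure isolation.

#' Pipeline configuration
#'
#' @param cohort A \linkS4class{CohortSpec}.
#' @param base base \linkS4class{PhantomSpec}.
#' @param imaging imaging parameters.
#' @param maxShift injected breath-hold shift magnitude, mm.
#' @param useGroundTruthContours,useGroundTruthLandmarks stage toggles:
#'   when FALSE the respective network model must be supplied.
#' @param segModel,landmarkModels trained models (see
#'   \code{\link{trainSegmentation}}, \code{\link{cyclicTransferTrain}}).
#' @param fit see \code{\link{fitConfig}}.
#' @param template see \code{\link{lvTemplate}}.
#' @param nSample surface samples per surface (N).
#' @param kComponents,folds association settings.
#' @param seed master seed, recorded in every output.
#' @return named list.
#' @export
pipelineConfig <- function(cohort = cohortSpec(20, effectSize = 1, seed = 1L),
                           base = phantomSpec(noiseSd = 0.02),
                           imaging = imagingParams(),
                           maxShift = 4,
                           useGroundTruthContours = TRUE,
                           useGroundTruthLandmarks = TRUE,
                           segModel = NULL, landmarkModels = NULL,
                           fit = fitConfig(), template = lvTemplate(),
                           nSample = 512L, kComponents = 10, folds = 5,
                           seed = 1L) {
  if (!useGroundTruthContours && is.null(segModel))
    stop("segmentation model required when ground-truth contours are off")
  if (!useGroundTruthLandmarks && is.null(landmarkModels))
    stop("landmark models required when ground-truth landmarks are off")
  list(cohort = cohort, base = base, imaging = imaging, maxShift = maxShift,
       useGroundTruthContours = useGroundTruthContours,
       useGroundTruthLandmarks = useGroundTruthLandmarks,
       segModel = segModel, landmarkModels = landmarkModels,
       fit = fit, template = template, nSample = as.integer(nSample),
       kComponents = kComponents, folds = folds, seed = as.integer(seed))
}

# Predicted contours for the frames the fit needs, via the U-Net.
predictStudyContours <- function(study, segModel, frames) {
  out <- list()
  for (k in saxIndices(study)) {
    for (t in frames) {
      m <- predictMask(segModel, study@slices[[k]]$frames[[t]])
      cc <- maskToContours(m, slice_id = k, frame_id = t)
      if (nrow(cc)) out[[length(out) + 1L]] <- cc
    }
  }
  do.call(rbind, out)
}

# Predicted landmarks (MV pairs on each LAX view, RV inserts on the mid
# SAX slice) via the trained coordinate-regression networks.
predictStudyLandmarks <- function(study, landmarkModels, frame, midSax) {
  rows <- list()
  for (v in c("2CH", "4CH", "SAX")) {
    sid <- if (v == "SAX") midSax else laxIndex(study, v)
    img <- study@slices[[sid]]$frames[[frame]]
    pr <- predictLandmarks(landmarkModels[[v]], list(img))
    rows[[v]] <- data.frame(view = v, slice_id = sid, frame_id = frame,
                            point_index = 1:2,
                            row = c(pr[1, 1], pr[1, 3]),
                            col = c(pr[1, 2], pr[1, 4]),
                            x = NA_real_, y = NA_real_, z = NA_real_)
  }
  do.call(rbind, rows)
}

processSubject <- function(subj, config) {
  study <- subj$study; truth <- subj$truth
  frames <- sort(unique(truth@contours$frame_id))
  contours <- if (config$useGroundTruthContours) truth@contours else
    predictStudyContours(study, config$segModel, frames)
  landmarks <- if (config$useGroundTruthLandmarks) truth@landmarks else
    predictStudyLandmarks(study, config$landmarkModels, 1L,
                          midSaxSlice(truth@landmarks))
  res <- fitLV(study, contours, landmarks, config$fit, config$template)
  ph <- res$phases
  g1 <- study@slices[[saxIndices(study)[1]]]$geometry
  edA <- contourAreas(contours, ph$ed, g1@pixelSpacing)
  esA <- contourAreas(contours, ph$es, g1@pixelSpacing)
  edv <- sliceSummationVolume(edA$cavity_mm2, g1@thickness, g1@gap)
  esv <- sliceSummationVolume(esA$cavity_mm2, g1@thickness, g1@gap)
  myoVol <- sliceSummationVolume(edA$myo_mm2, g1@thickness, g1@gap)
  measures <- clinicalMeasures(edv, esv, lvMass(myoVol),
                               subj$heightCm, subj$weightKg)
  shape <- assembleShapeVector(sampleSurfacePoints(res$fit, config$nSample))
  list(id = subj$id, label = subj$label, fit = res$fit,
       shifts = res$shifts, trueShifts = truth@shifts,
       measures = measures, shape = shape,
       residualRms = res$pass2Rms, truth = truth)
}

#' Run the full automated analysis pipeline on a synthetic cohort
#'
#' Renders the cohort (with injected breath-hold shifts), obtains contours
#' and landmarks (ground truth or network predictions per the stage
#' toggles), customizes the LV model with misregistration correction,
#' derives clinical measures, builds the Procrustes/PCA shape atlas and
#' quantifies the shape / risk-label association. A subject failing any
#' stage is excluded downstream with a reason code; cohort stages require
#' at least two surviving subjects.
#'
#' @param config see \code{\link{pipelineConfig}}.
#' @return list(subjects, atlas, association, exclusions, manifest).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  population <- generatePopulation(config$cohort, config$base, render = TRUE,
                                   imaging = config$imaging,
                                   maxShift = config$maxShift)
  subjects <- list(); exclusions <- list()
  for (subj in population) {
    out <- tryCatch(processSubject(subj, config), error = function(e)
      structure(list(id = subj$id, reason = conditionMessage(e)),
                class = "subjectFailure"))
    if (inherits(out, "subjectFailure"))
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(id = out$id, reason = out$reason)
    else subjects[[length(subjects) + 1L]] <- out
  }
  if (length(subjects) < 2)
    stop("fewer than two subjects survived; cannot build cohort outputs")
  shapes <- do.call(rbind, lapply(subjects, `[[`, "shape"))
  rownames(shapes) <- vapply(subjects, function(s) as.character(s$id), character(1))
  labels <- vapply(subjects, `[[`, integer(1), "label")
  gpa <- procrustesAlign(shapes)
  atlas <- atlasPCA(gpa$aligned, alignment = gpa$transforms)
  association <- cvAssociation(gpa$aligned, labels,
                               kComponents = config$kComponents,
                               folds = min(config$folds, length(subjects)),
                               seed = config$seed,
                               ids = as.integer(rownames(shapes)))
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(id = integer(), reason = character())
  manifest <- list(
    seed = config$seed,
    nSubjects = config$cohort@nSubjects,
    nAnalyzed = length(subjects),
    nExcluded = nrow(exclusions),
    configDigest = objectDigest(list(config$cohort@seed, config$maxShift,
                                     config$nSample, config$kComponents,
                                     config$folds, config$seed)),
    outputDigest = objectDigest(list(round(shapes, 9),
                                     round(atlas@eigenvalues, 9),
                                     round(association$pooledAUC, 9))),
    packageVersion = as.character(utils::packageVersion("lvatlas")))
  list(subjects = subjects, atlas = atlas, association = association,
       exclusions = exclusions, manifest = manifest)
}
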