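# Desk-scale synthetic benchmarks: one rendered population feeds the
# landmark views (2CH, 4CH MV hinges; SAX RV inserts) and the segmentation
# dataset.

#' Render a benchmark population for network training
#'
#' A jittered phantom cohort rendered at the scaled network resolution with
#' randomized in-plane image placement, so landmark positions vary within
#' the frame.
#'
#' @param n subjects.
#' @param seed integer.
#' @param matrixSize,pixelSpacing imaging grid (defaults 64 px at 3 mm).
#' @param noiseSd image noise.
#' @return rendered population (see \code{\link{generatePopulation}}).
#' @export
benchmarkPopulation <- function(n, seed = 1L, matrixSize = 64,
                                pixelSpacing = 3, noiseSd = 0.08) {
  base <- phantomSpec(noiseSd = noiseSd)
  cohort <- cohortSpec(n, effectSize = 0, jitterSd = 0.08, seed = seed)
  imaging <- imagingParams(nSax = 10, matrixSize = matrixSize,
                           pixelSpacing = pixelSpacing, nFrames = 1,
                           centerJitterMm = 6, inPlaneRotDeg = 10)
  generatePopulation(cohort, base, render = TRUE, imaging = imaging)
}

# Mid-ventricular SAX slice: the slice with RV landmarks closest to the
# middle of the landmarked range.
midSaxSlice <- function(landmarks) {
  sids <- sort(unique(landmarks$slice_id[landmarks$view == "SAX"]))
  sids[ceiling(length(sids) / 2)]
}

#' Landmark training datasets from a rendered population
#'
#' For each view, one image and one landmark pair per subject: the LAX
#' image with its two mitral hinge points, or the mid-ventricular SAX slice
#' with its two RV insertion points. Targets are (row1, col1, row2, col2)
#' pixel coordinates in the image frame.
#'
#' @param population rendered population.
#' @param views subset of c("2CH", "4CH", "SAX").
#' @return named list per view: list(images, targets, pixelSpacing).
#' @export
landmarkDatasets <- function(population, views = c("2CH", "4CH", "SAX")) {
  out <- list()
  for (v in views) {
    imgs <- vector("list", length(population))
    tg <- matrix(0, length(population), 4)
    for (i in seq_along(population)) {
      s <- population[[i]]
      lm <- s$truth@landmarks
      sid <- if (v == "SAX") midSaxSlice(lm) else
        laxIndex(s$study, v)
      d <- lm[lm$view == v & lm$slice_id == sid & lm$frame_id == 1, ]
      d <- d[order(d$point_index), ]
      stopifnot(nrow(d) == 2)
      imgs[[i]] <- s$study@slices[[sid]]$frames[[1]]
      tg[i, ] <- c(d$row[1], d$col[1], d$row[2], d$col[2])
    }
    ps <- population[[1]]$study@slices[[1]]$geometry@pixelSpacing[1]
    out[[v]] <- list(images = imgs, targets = tg, pixelSpacing = ps)
  }
  out
}

#' Segmentation training dataset from a rendered population
#'
#' Takes short-axis slices at roughly one- and two-thirds ventricular depth
#' per subject, paired with their ground-truth 3-label masks.
#'
#' @param population rendered population.
#' @param slicesPerSubject 1 or 2.
#' @return list(images, masks).
#' @export
segmentationDataset <- function(population, slicesPerSubject = 2) {
  images <- list(); masks <- list()
  for (s in population) {
    nonEmpty <- setdiff(saxIndices(s$study), s$study@meta$emptySlices)
    picks <- unique(nonEmpty[pmax(1, round(c(0.35, 0.65) * length(nonEmpty)))])
    picks <- head(picks, slicesPerSubject)
    for (k in picks) {
      images[[length(images) + 1L]] <- s$study@slices[[k]]$frames[[1]]
      masks[[length(masks) + 1L]] <- s$truth@masks[[k]][[1]]
    }
  }
  list(images = images, masks = masks)
}
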