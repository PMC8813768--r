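#' Map pixel coordinates to patient space
#'
#' Pixel indices are 0-based at pixel centers, supplied as (row, col). The
#' patient-space point is
#' \code{origin + col * colSpacing * rowDir + row * rowSpacing * colDir},
#' the standard imaging-header affine.
#'
#' @param rc numeric vector (row, col) or an n x 2 matrix.
#' @param g A \linkS4class{SliceGeometry}.
#' @return An n x 3 matrix of patient-space mm coordinates.
#' @export
pixelToPatient <- function(rc, g) {
  stopifnot(is(g, "SliceGeometry"))
  validObject(g)
  rc <- matrix(rc, ncol = 2)
  out <- matrix(g@origin, nrow(rc), 3, byrow = TRUE) +
    outer(rc[, 2] * g@pixelSpacing[2], g@rowDir) +
    outer(rc[, 1] * g@pixelSpacing[1], g@colDir)
  out
}

#' Map patient-space points to pixel coordinates of a slice
#'
#' The exact inverse of \code{\link{pixelToPatient}} within the slice plane.
#' Out-of-plane distance (mm) is returned as an attribute.
#'
#' @param pts n x 3 matrix of patient-space mm coordinates.
#' @param g A \linkS4class{SliceGeometry}.
#' @return n x 2 matrix of (row, col), attribute \code{outOfPlane}.
#' @export
patientToPixel <- function(pts, g) {
  stopifnot(is(g, "SliceGeometry"))
  pts <- matrix(pts, ncol = 3)
  d <- sweep(pts, 2, g@origin)
  col <- drop(d %*% g@rowDir) / g@pixelSpacing[2]
  row <- drop(d %*% g@colDir) / g@pixelSpacing[1]
  out <- cbind(row = row, col = col)
  attr(out, "outOfPlane") <- drop(d %*% sliceNormal(g))
  out
}

# Largest connected component of a binary matrix (8-connectivity).
largestComponent <- function(bin) {
  if (!any(bin)) return(bin)
  lab <- EBImage::bwlabel(bin)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

contourLabels <- c(endocardium = "endocardium", epicardium = "epicardium")

# Subpixel iso-contour of a binary matrix at level 0.5, closed, ordered CCW
# in (row, col). Returns NULL when the region is empty.
traceBoundary <- function(bin) {
  if (!any(bin)) return(NULL)
  nr <- nrow(bin); nc <- ncol(bin)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- bin
  cl <- grDevices::contourLines(x = -1:nr, y = -1:nc, z = z, levels = 0.5)
  if (!length(cl)) return(NULL)
  lens <- vapply(cl, function(s) length(s$x), numeric(1))
  s <- cl[[which.max(lens)]]
  xy <- cbind(row = s$x, col = s$y)
  if (all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-9)) xy <- xy[-nrow(xy), , drop = FALSE]
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 1e-9)
  xy <- xy[keep, , drop = FALSE]
  if (polygonArea(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

#' Extract endo- and epicardial contours from a 3-label mask
#'
#' Labels are 0 = background, 1 = myocardium, 2 = LV cavity. The endocardial
#' contour is the cavity/myocardium boundary (boundary of the cavity region)
#' and the epicardial contour the outer myocardial boundary (boundary of
#' cavity + myocardium). Only the largest connected component of each region
#' is traced; boundaries are extracted at subpixel precision (marching
#' squares on the label indicator at level 0.5, pixel-center convention) and
#' ordered counter-clockwise.
#'
#' @param mask integer matrix with values in 0:2.
#' @param slice_id,frame_id identifiers stored in the output.
#' @return A contour data.frame (slice_id, frame_id, label, point_index,
#'   row, col); attribute \code{missing} lists labels with empty regions.
#' @export
maskToContours <- function(mask, slice_id = 1L, frame_id = 1L) {
  stopifnot(all(mask %in% 0:2))
  res <- list(); missing <- character()
  regions <- list(endocardium = mask == 2, epicardium = mask >= 1)
  for (lab in names(regions)) {
    xy <- traceBoundary(largestComponent(regions[[lab]]))
    if (is.null(xy)) { missing <- c(missing, lab); next }
    res[[lab]] <- data.frame(slice_id = slice_id, frame_id = frame_id,
                             label = lab, point_index = seq_len(nrow(xy)) - 1L,
                             row = xy[, 1], col = xy[, 2])
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(slice_id = integer(), frame_id = integer(), label = character(),
               point_index = integer(), row = numeric(), col = numeric())
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

# Points of one contour as a matrix, ordered by point_index.
contourPoints <- function(contours, lab, slice = NULL, frame = NULL) {
  d <- contours[contours$label == lab, , drop = FALSE]
  if (!is.null(slice)) d <- d[d$slice_id == slice, , drop = FALSE]
  if (!is.null(frame)) d <- d[d$frame_id == frame, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  d <- d[order(d$point_index), ]
  cbind(row = d$row, col = d$col)
}

#' Rasterize paired endo/epi contours into a 3-label mask
#'
#' Cavity = interior of the endocardial contour; myocardium = interior of the
#' epicardial contour minus the cavity; the three labels partition the image
#' by construction. Pixel centers are tested against the closed polygons.
#'
#' @param contours contour data.frame for one slice/frame with both labels.
#' @param shape integer(2): output (rows, cols).
#' @return Integer matrix with 0 = background, 1 = myocardium, 2 = cavity.
#'   Attribute \code{degenerate} is TRUE when the two contours coincide
#'   (zero myocardium).
#' @export
contoursToMask <- function(contours, shape) {
  endo <- contourPoints(contours, "endocardium")
  epi <- contourPoints(contours, "epicardium")
  if (is.null(endo) || is.null(epi))
    stop("contoursToMask needs paired endocardium and epicardium contours")
  sid <- contours$slice_id[1]
  inEpi <- pracma::inpolygon(endo[, 1], endo[, 2], epi[, 1], epi[, 2],
                             boundary = TRUE)
  if (!all(inEpi))
    stop(sprintf("endocardial contour not inside epicardial contour on slice %s", sid))
  mask <- matrix(0L, shape[1], shape[2])
  # test pixel centers within the epi bounding box only
  r0 <- max(0L, floor(min(epi[, 1]))); r1 <- min(shape[1] - 1L, ceiling(max(epi[, 1])))
  c0 <- max(0L, floor(min(epi[, 2]))); c1 <- min(shape[2] - 1L, ceiling(max(epi[, 2])))
  if (r1 >= r0 && c1 >= c0) {
    gr <- expand.grid(row = r0:r1, col = c0:c1)
    inE <- pracma::inpolygon(gr$row, gr$col, epi[, 1], epi[, 2])
    inI <- pracma::inpolygon(gr$row, gr$col, endo[, 1], endo[, 2])
    lab <- ifelse(inI, 2L, ifelse(inE, 1L, 0L))
    mask[cbind(gr$row + 1L, gr$col + 1L)] <- lab
  }
  degen <- !any(mask == 1L)
  if (degen) warning(sprintf("degenerate contours on slice %s: zero myocardium", sid))
  attr(mask, "degenerate") <- degen
  mask
}

#' Sort cine slices spatially and temporally
#'
#' Short-axis slices are ordered apex to base by the projection of their
#' origins onto the stack normal; frames are ordered by trigger time
#' (stable sort). The apex end is resolved from the mitral-valve side when
#' an MV centroid is supplied, otherwise the end with the smaller cavity
#' area (from \code{areas}) is taken as apex; with neither, increasing
#' normal projection is used as-is.
#'
#' @param slices list of lists with components \code{geometry} and
#'   \code{triggerTimes}.
#' @param mvCentroid optional patient-space MV centroid (mm).
#' @param areas optional per-slice cavity areas used to resolve the apex end.
#' @return list(order, frameOrder, flagged): slice permutation, per-slice
#'   frame permutations, and TRUE when any trigger time is missing (series
#'   unsortable temporally).
#' @export
sortCine <- function(slices, mvCentroid = NULL, areas = NULL) {
  geos <- lapply(slices, `[[`, "geometry")
  normals <- t(vapply(geos, sliceNormal, numeric(3)))
  nref <- normals[1, ]
  flip <- drop(normals %*% nref) < 0
  normals[flip, ] <- -normals[flip, ]
  ang <- acos(pmin(1, drop(normals %*% nref))) * 180 / pi
  if (max(ang) > 5)
    stop(sprintf("inconsistent slice orientations: %.1f degree spread", max(ang)))
  n <- unitv(colMeans(normals))
  proj <- vapply(geos, function(g) sum(g@origin * n), numeric(1))
  ord <- order(proj)
  if (!is.null(mvCentroid)) {
    # base (MV) end last
    if (sum(mvCentroid * n) < mean(range(proj))) ord <- rev(ord)
  } else if (!is.null(areas)) {
    if (areas[ord[1]] > areas[ord[length(ord)]]) ord <- rev(ord)
  }
  flagged <- FALSE
  frameOrder <- lapply(slices, function(s) {
    tt <- s$triggerTimes
    if (anyNA(tt)) { flagged <<- TRUE; return(seq_along(tt)) }
    order(tt)
  })
  list(order = ord, frameOrder = frameOrder, flagged = flagged)
}

#' Match a geometry-free contour file to image slices
#'
#' Legacy contour files carry ordered per-slice contours without 3D position
#' information. Both sequences are ordered apex to base and aligned by an
#' integer offset chosen to maximize mean contour/image-mask Dice overlap
#' (when reference masks are available) or slice-count agreement otherwise.
#'
#' @param contourList list (apex to base) of contour data.frames, one per
#'   contoured slice.
#' @param masks list (apex to base) of reference 3-label masks, one per image
#'   slice; entries may be NULL when no mask is available.
#' @param maxOffsetTol maximum |slice count mismatch| accepted (default 2).
#' @return list(assignment, offset, excluded, reason, unmatched):
#'   \code{assignment} maps contour index to slice index.
#' @export
matchContoursToSlices <- function(contourList, masks, maxOffsetTol = 2L) {
  nc <- length(contourList); ns <- length(masks)
  if (nc == 0)
    return(list(assignment = NULL, offset = NA_integer_, excluded = TRUE,
                reason = "empty contour file", unmatched = integer()))
  if (abs(ns - nc) > maxOffsetTol)
    return(list(assignment = NULL, offset = NA_integer_, excluded = TRUE,
                reason = sprintf("slice-count mismatch %d vs %d beyond tolerance", nc, ns),
                unmatched = seq_len(nc)))
  offsets <- (-maxOffsetTol):maxOffsetTol
  score <- function(off) {
    s <- 0; npair <- 0
    for (i in seq_len(nc)) {
      j <- i + off
      if (j < 1 || j > ns || is.null(masks[[j]])) next
      m <- masks[[j]]
      pred <- tryCatch(contoursToMask(contourList[[i]], dim(m)),
                       error = function(e) NULL, warning = function(w) NULL)
      if (is.null(pred)) next
      s <- s + diceScore(pred, m, class = 2L)
      npair <- npair + 1
    }
    if (npair == 0) -Inf else s / npair
  }
  sc <- vapply(offsets, score, numeric(1))
  if (all(!is.finite(sc))) {
    # no masks usable: align by count agreement, centered
    best <- offsets[which.min(abs(offsets - (ns - nc) %/% 2))]
  } else best <- offsets[which.max(sc)]
  idx <- seq_len(nc)
  slice <- idx + best
  ok <- slice >= 1 & slice <= ns
  list(assignment = data.frame(contour_index = idx[ok], slice_index = slice[ok]),
       offset = best, excluded = FALSE, reason = NA_character_,
       unmatched = idx[!ok])
}
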