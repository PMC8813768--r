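# External interfaces: an image + JSON-geometry sidecar dialect for cine
# studies (PNG images, one file per slice/frame), contour tables as CSV,
# and a delimited atlas format (JSON header + matrix files).

geometryToList <- function(g)
  list(origin = g@origin, rowDir = g@rowDir, colDir = g@colDir,
       pixelSpacing = g@pixelSpacing, thickness = g@thickness, gap = g@gap,
       triggerTime = g@triggerTime, view = g@view)

listToGeometry <- function(l)
  sliceGeometry(l$origin, l$rowDir, l$colDir, l$pixelSpacing, l$thickness,
                l$gap, if (is.null(l$triggerTime)) NA_real_ else l$triggerTime,
                l$view)

#' Write a cine study as PNG images plus a JSON geometry sidecar
#'
#' Images are intensity-scaled to 16-bit PNG (scaling recorded in the
#' sidecar); per-slice geometry and trigger times go to geometry.json.
#'
#' @param study A \linkS4class{CineStudy}.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
writeCineStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list(nSlices = length(study@slices), slices = list())
  for (k in seq_along(study@slices)) {
    sl <- study@slices[[k]]
    lo <- min(vapply(sl$frames, min, numeric(1)))
    hi <- max(vapply(sl$frames, max, numeric(1)))
    rng <- if (hi > lo) hi - lo else 1
    files <- character(length(sl$frames))
    for (t in seq_along(sl$frames)) {
      files[t] <- sprintf("slice%02d_frame%02d.png", k, t)
      png::writePNG((sl$frames[[t]] - lo) / rng, file.path(dir, files[t]))
    }
    sidecar$slices[[k]] <- c(geometryToList(sl$geometry),
                             list(triggerTimes = sl$triggerTimes,
                                  files = files, intensityMin = lo,
                                  intensityRange = rng))
  }
  sidecar$meta <- study@meta[c("seed")]
  jsonlite::write_json(sidecar, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cine study written by \code{\link{writeCineStudy}}
#' @param dir study directory.
#' @return A \linkS4class{CineStudy}.
#' @export
readCineStudy <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "geometry.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  slices <- lapply(sc$slices, function(l) {
    frames <- lapply(l$files, function(f)
      png::readPNG(file.path(dir, f)) * l$intensityRange + l$intensityMin)
    list(geometry = listToGeometry(l), frames = frames,
         triggerTimes = as.numeric(l$triggerTimes))
  })
  new("CineStudy", slices = slices,
      meta = list(seed = sc$meta$seed))
}

#' Write / read contour tables
#'
#' CSV columns: slice_id, frame_id, label, point_index, row, col.
#'
#' @param contours contour data.frame.
#' @param path CSV path.
#' @export
writeContoursCsv <- function(contours, path) {
  write.csv(contours[, c("slice_id", "frame_id", "label", "point_index",
                         "row", "col")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContoursCsv
#' @export
readContoursCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read an atlas model
#'
#' JSON header (N, block order, eigenvalues) plus whitespace-delimited
#' matrix files for the mean shape, principal directions and scores.
#'
#' @param atlas An \linkS4class{AtlasModel}.
#' @param dir output directory.
#' @export
writeAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(npoints = atlas@npoints,
                            blockOrder = SURFACE_BLOCKS,
                            eigenvalues = atlas@eigenvalues),
                       file.path(dir, "atlas.json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(atlas@meanShape, file.path(dir, "mean.dat"),
              row.names = FALSE, col.names = FALSE)
  write.table(atlas@directions, file.path(dir, "directions.dat"),
              row.names = FALSE, col.names = FALSE)
  write.table(atlas@scores, file.path(dir, "scores.dat"),
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(dir) {
  hd <- jsonlite::read_json(file.path(dir, "atlas.json"), simplifyVector = TRUE)
  new("AtlasModel",
      meanShape = scan(file.path(dir, "mean.dat"), quiet = TRUE),
      directions = as.matrix(read.table(file.path(dir, "directions.dat"))),
      eigenvalues = as.numeric(hd$eigenvalues),
      scores = as.matrix(read.table(file.path(dir, "scores.dat"))),
      alignment = list(), npoints = as.integer(hd$npoints))
}

#' Write / read a fitted LV model
#'
#' JSON header (grid dimensions, pose, residual summary) plus CSV control
#' vertices (one row per control vertex per surface/phase) and a CSV
#' residual report.
#'
#' @param fit A \linkS4class{FittedLV}.
#' @param dir output directory.
#' @export
writeFittedLV <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- fit@template
  jsonlite::write_json(list(nCirc = tm$nCirc, nLong = tm$nLong,
                            knots = tm$knots,
                            pose = list(R = as.vector(fit@pose$R),  # column-major
                                        t = fit@pose$t, L = fit@pose$L),
                            rmsResidual = sqrt(mean(fit@residuals$residual_mm^2))),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  ctrl <- do.call(rbind, lapply(c("endoED", "epiED", "endoES", "epiES"),
    function(b) {
      th <- slot(fit, b)
      data.frame(block = b, vertex = seq_len(nrow(th)) - 1L,
                 x = th[, 1], y = th[, 2], z = th[, 3])
    }))
  write.csv(ctrl, file.path(dir, "control_vertices.csv"), row.names = FALSE)
  write.csv(fit@residuals, file.path(dir, "residuals.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeFittedLV
#' @export
readFittedLV <- function(dir) {
  hd <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  ctrl <- read.csv(file.path(dir, "control_vertices.csv"))
  res <- read.csv(file.path(dir, "residuals.csv"))
  tm <- lvTemplate(hd$nCirc, hd$nLong)
  grab <- function(b) {
    d <- ctrl[ctrl$block == b, ]
    as.matrix(d[order(d$vertex), c("x", "y", "z")])
  }
  new("FittedLV", endoED = grab("endoED"), epiED = grab("epiED"),
      endoES = grab("endoES"), epiES = grab("epiES"),
      pose = list(R = matrix(unlist(hd$pose$R), 3, 3), t = unlist(hd$pose$t),
                  L = hd$pose$L),
      template = tm, residuals = res)
}

#' Write / read a trained network checkpoint
#'
#' Parameters in R's standard serialization plus a JSON configuration
#' sidecar.
#'
#' @param model a landmark or segmentation model (list(params, config)).
#' @param path checkpoint path (an .rds file; the sidecar gets .json).
#' @export
writeModelCheckpoint <- function(model, path) {
  saveRDS(model$params, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelCheckpoint
#' @export
readModelCheckpoint <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg$channels <- as.integer(cfg$channels)
  list(params = readRDS(path), config = cfg)
}

#' Write / read a label mask as palette-coded PNG
#'
#' Labels 0..2 are stored as gray levels 0, 128, 255.
#'
#' @param mask integer matrix with values in 0:2.
#' @param path PNG path.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(mask / 2, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 2)), nrow(m), ncol(m))
}

#' Write an agreement-metrics table
#'
#' One row per clinical measure: Pearson correlation and mean difference
#' (SD), the standard validation-table layout.
#'
#' @param stats named list of \code{\link{agreementStats}} results.
#' @param path CSV path.
#' @export
writeAgreementCsv <- function(stats, path) {
  d <- do.call(rbind, lapply(names(stats), function(nm) {
    s <- stats[[nm]]
    data.frame(measure = nm, correlation = s$r, mean_difference = s$meanDiff,
               sd_difference = s$sdDiff, loa_lower = s$limits[1],
               loa_upper = s$limits[2])
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Bland-Altman plot
#'
#' Mean-vs-difference scatter with the mean difference (solid) and the
#' mean +/- 1.96 SD limits of agreement (dashed).
#'
#' @param stats an \code{\link{agreementStats}} result.
#' @param main plot title.
#' @param file optional PNG path; when given the plot is written there.
#' @export
plotBlandAltman <- function(stats, main = "Bland-Altman", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(stats$table$mean, stats$table$difference, pch = 16,
                 cex = 0.6, xlab = "Mean of methods",
                 ylab = "Difference (B - A)", main = main)
  graphics::abline(h = stats$meanDiff, lwd = 2)
  graphics::abline(h = stats$limits, lty = 2)
  invisible(stats)
}

#' Write association comparison results
#'
#' One row per risk factor: the two pipelines' pooled AUCs and the paired
#' DeLong p-value.
#'
#' @param comparisons named list of \code{\link{compareAuc}} results (names
#'   are factor labels).
#' @param path CSV path.
#' @export
writeAssociationCsv <- function(comparisons, path) {
  d <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    data.frame(factor = nm, auc_a = cmp$aucA, auc_b = cmp$aucB,
               p_value = cmp$p.value)
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Per-fold association diagnostics as JSON
#'
#' @param result an \code{lvAssociation} object.
#' @param path JSON path.
#' @export
writeFoldDiagnostics <- function(result, path) {
  jsonlite::write_json(list(factor = result$factor, folds = result$folds,
                            nComponents = result$nComponents,
                            foldAUCs = result$foldAUCs,
                            pooledAUC = result$pooledAUC,
                            meanFoldAUC = result$meanFoldAUC),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
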