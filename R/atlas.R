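# Surface block order of a shape vector; fixed and semantic.
SURFACE_BLOCKS <- c("endoED", "epiED", "endoES", "epiES")

#' Assemble a 12N shape vector from four sampled surfaces
#'
#' Concatenates the endocardial and epicardial surface samples at ED and ES
#' (block order endoED, epiED, endoES, epiES), each N x 3 point set
#' flattened as [x1, y1, z1, ..., xN, yN, zN], giving 12N coordinates.
#'
#' @param surfaces named list of four N x 3 matrices (names as above).
#' @return numeric vector of length 12N.
#' @export
assembleShapeVector <- function(surfaces) {
  stopifnot(all(SURFACE_BLOCKS %in% names(surfaces)))
  ns <- vapply(surfaces[SURFACE_BLOCKS], nrow, integer(1))
  if (length(unique(ns)) != 1) stop("all four surfaces must have equal N")
  unlist(lapply(surfaces[SURFACE_BLOCKS], function(p) as.vector(t(p))),
         use.names = FALSE)
}

#' Split a 12N shape vector back into its four surfaces
#' @param s numeric vector of length 12N.
#' @return named list of four N x 3 matrices.
#' @export
disassembleShapeVector <- function(s) {
  stopifnot(length(s) %% 12 == 0)
  N <- length(s) / 12
  out <- lapply(0:3, function(b)
    matrix(s[(b * 3 * N + 1):((b + 1) * 3 * N)], ncol = 3, byrow = TRUE))
  names(out) <- SURFACE_BLOCKS
  out
}

shapeToPoints <- function(s) matrix(s, ncol = 3, byrow = TRUE)
pointsToShape <- function(p) as.vector(t(p))

# Optimal rotation (no scaling) aligning centered X onto centered Y (Kabsch).
kabschRotation <- function(Xc, Yc) {
  M <- crossprod(Xc, Yc)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes alignment (position and orientation only)
#'
#' Iteratively aligns every shape to the evolving mean by the optimal rigid
#' rotation and translation. Scale is deliberately retained: ventricular
#' size is signal, not nuisance. All 4N points of a subject (ED and ES
#' blocks together) share a single transform, so phase-to-phase motion is
#' preserved in shape space.
#'
#' @param shapes n x 12N matrix (rows = subjects) or list of 12N vectors.
#' @param tol convergence tolerance on the mean-shape change.
#' @param maxIter iteration cap.
#' @return list(aligned = n x 12N matrix, transforms = per-subject
#'   list(R, t), meanShape, iterations).
#' @export
procrustesAlign <- function(shapes, tol = 1e-8, maxIter = 100) {
  if (is.list(shapes)) shapes <- do.call(rbind, shapes)
  stopifnot(nrow(shapes) >= 2)
  n <- nrow(shapes)
  pts <- lapply(seq_len(n), function(i) shapeToPoints(shapes[i, ]))
  cents <- lapply(pts, colMeans)
  ptsC <- mapply(function(p, c) sweep(p, 2, c), pts, cents, SIMPLIFY = FALSE)
  for (p in ptsC)
    if (qr(p)$rank < 2) stop("degenerate (collinear) shape cannot be aligned")
  Rs <- replicate(n, diag(3), simplify = FALSE)
  mean_ <- ptsC[[1]]
  for (it in seq_len(maxIter)) {
    aligned <- vector("list", n)
    for (i in seq_len(n)) {
      Rs[[i]] <- kabschRotation(ptsC[[i]], mean_)
      aligned[[i]] <- ptsC[[i]] %*% Rs[[i]]
    }
    newMean <- Reduce(`+`, aligned) / n
    newMean <- sweep(newMean, 2, colMeans(newMean))
    delta <- sqrt(mean((newMean - mean_)^2))
    mean_ <- newMean
    if (delta < tol) break
  }
  alignedMat <- do.call(rbind, lapply(seq_len(n), function(i)
    pointsToShape(ptsC[[i]] %*% Rs[[i]])))
  transforms <- lapply(seq_len(n), function(i) list(R = Rs[[i]], t = -cents[[i]]))
  list(aligned = alignedMat, transforms = transforms,
       meanShape = pointsToShape(mean_), iterations = it)
}

#' Rigidly align one shape vector onto a reference shape
#'
#' @param shape,reference 12N vectors of corresponding points.
#' @return the aligned 12N vector.
#' @export
alignShape <- function(shape, reference) {
  X <- shapeToPoints(shape); Y <- shapeToPoints(reference)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  R <- kabschRotation(Xc, Yc)
  pointsToShape(sweep(Xc %*% R, 2, colMeans(Y), "+"))
}

#' Principal component analysis of aligned shape vectors
#'
#' Mean-centered PCA computed through the singular value decomposition of
#' the n x 12N data matrix (the dual, subject-space route when n << 12N);
#' eigenvalues are variances (denominator n - 1) and sum to the total
#' centered variance. Component signs follow a fixed convention: the
#' largest-magnitude loading of each direction is positive.
#'
#' @param aligned n x 12N matrix of Procrustes-aligned shape vectors.
#' @param alignment optional transforms list stored in the model.
#' @return An \linkS4class{AtlasModel}.
#' @export
atlasPCA <- function(aligned, alignment = list()) {
  if (is.list(aligned) && !is.matrix(aligned)) aligned <- do.call(rbind, aligned)
  n <- nrow(aligned)
  if (n < 2) stop("PCA needs at least two subjects")
  mu <- colMeans(aligned)
  Xc <- sweep(aligned, 2, mu)
  sv <- svd(Xc, nu = 0)
  k <- min(sum(sv$d > max(sv$d) * 1e-12), n - 1)
  k <- max(k, 1L)
  V <- sv$v[, seq_len(k), drop = FALSE]
  ev <- sv$d[seq_len(k)]^2 / (n - 1)
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  new("AtlasModel", meanShape = mu, directions = V, eigenvalues = ev,
      scores = scores, alignment = alignment,
      npoints = as.integer(length(mu) / 12))
}

#' Project a shape onto the atlas principal directions
#'
#' Scores are directions' (shape - mean). The shape must already be in the
#' atlas mean frame (see \code{\link{alignShape}}).
#'
#' @param atlas An \linkS4class{AtlasModel}.
#' @param shape 12N vector (or n x 12N matrix).
#' @param k number of leading components (default all).
#' @return score vector (or matrix).
#' @export
projectShape <- function(atlas, shape, k = NULL) {
  V <- atlas@directions
  if (!is.null(k)) V <- V[, seq_len(min(k, ncol(V))), drop = FALSE]
  if (is.matrix(shape)) {
    if (ncol(shape) != length(atlas@meanShape)) stop("shape length mismatch")
    sweep(shape, 2, atlas@meanShape) %*% V
  } else {
    if (length(shape) != length(atlas@meanShape)) stop("shape length mismatch")
    drop(crossprod(V, shape - atlas@meanShape))
  }
}

#' Reconstruct a shape from scores
#' @param atlas An \linkS4class{AtlasModel}.
#' @param scores score vector.
#' @return 12N shape vector.
#' @export
reconstructShape <- function(atlas, scores) {
  V <- atlas@directions[, seq_along(scores), drop = FALSE]
  atlas@meanShape + drop(V %*% scores)
}
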