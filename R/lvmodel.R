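# Parametric two-surface LV model: for each surface a tensor-product cubic
# B-spline over a periodic circumferential parameter u in [0, 2pi) and an
# open longitudinal parameter v in [0, 1] (apex -> base), with the apex row
# of control vertices collapsed to a single shared vertex so the surface
# closes at the apex. Control grids live in a normalized pose-local frame
# (MV centroid at the origin, +z toward the apex, unit length = MV-to-apex
# distance).

# Centered uniform cubic B-spline kernel, support [-2, 2].
cubicBspline <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Periodic cubic B-spline basis: n x nCirc, partition of unity.
basisCirc <- function(u, nCirc) {
  x <- u * nCirc / (2 * pi)
  B <- matrix(0, length(u), nCirc)
  for (i in seq_len(nCirc)) {
    t <- x - (i - 1)
    t <- ((t + nCirc / 2) %% nCirc) - nCirc / 2
    B[, i] <- cubicBspline(t)
  }
  B
}

# Clamped cubic B-spline basis on [0, 1] with nLong control vertices.
basisLong <- function(v, nLong, knots) {
  v <- pmin(pmax(v, 0), 1 - 1e-12)
  splines::splineDesign(knots, v, ord = 4)
}

# Reduced control indexing: row 1 = shared apex vertex, then rings for
# longitudinal rows 2..nLong (circumferential index wraps).
ridx <- function(j, i, nCirc) {
  if (j == 1) return(1L)
  1L + (j - 2L) * nCirc + ((i - 1L) %% nCirc) + 1L
}

#' Construct the LV surface template
#'
#' Builds the control grids (endo and epi) of a canonical truncated
#' half-ellipsoid in the normalized local frame, plus the second-difference
#' smoothing operator used as the fitting penalty.
#'
#' @param nCirc,nLong circumferential / longitudinal control counts
#'   (default 8 x 6 per surface).
#' @param endoRadius,epiRadius canonical base radii in units of LV length.
#' @return list with control grids, knots and penalty operator.
#' @export
lvTemplate <- function(nCirc = 8, nLong = 6, endoRadius = 0.33, epiRadius = 0.44) {
  stopifnot(nLong >= 4, nCirc >= 4)
  knots <- c(rep(0, 4), seq(0, 1, length.out = nLong - 2)[-c(1, nLong - 2)], rep(1, 4))
  nRed <- 1L + (nLong - 1L) * nCirc
  mkTheta <- function(r0) {
    th <- matrix(0, nRed, 3)
    th[1, ] <- c(0, 0, 1)                       # apex (z = 1, apexward)
    for (j in 2:nLong) {
      zeta <- 1 - (j - 1) / (nLong - 1)          # 1 apex -> 0 base
      r <- r0 * sqrt(max(0, 1 - zeta^2))
      for (i in seq_len(nCirc)) {
        phi <- 2 * pi * (i - 1) / nCirc
        th[ridx(j, i, nCirc), ] <- c(r * cos(phi), r * sin(phi), zeta)
      }
    }
    th
  }
  # second differences of the control displacement field (circ wraps; long
  # runs through the shared apex vertex)
  rows <- list()
  for (j in 2:nLong) for (i in seq_len(nCirc)) {
    r <- numeric(nRed)
    r[ridx(j, i - 1, nCirc)] <- r[ridx(j, i - 1, nCirc)] + 1
    r[ridx(j, i, nCirc)] <- r[ridx(j, i, nCirc)] - 2
    r[ridx(j, i + 1, nCirc)] <- r[ridx(j, i + 1, nCirc)] + 1
    rows[[length(rows) + 1L]] <- r
  }
  for (j in 2:(nLong - 1)) for (i in seq_len(nCirc)) {
    r <- numeric(nRed)
    r[ridx(j - 1, i, nCirc)] <- r[ridx(j - 1, i, nCirc)] + 1
    r[ridx(j, i, nCirc)] <- r[ridx(j, i, nCirc)] - 2
    r[ridx(j + 1, i, nCirc)] <- r[ridx(j + 1, i, nCirc)] + 1
    rows[[length(rows) + 1L]] <- r
  }
  D <- do.call(rbind, rows)
  K <- crossprod(D) / nrow(D)
  list(nCirc = as.integer(nCirc), nLong = as.integer(nLong), knots = knots,
       nRed = nRed, endo = mkTheta(endoRadius), epi = mkTheta(epiRadius),
       K = K)
}

# Reduced design matrix for parameter locations (u, v): n x nRed.
designMatrix <- function(u, v, template) {
  Bc <- basisCirc(u, template$nCirc)
  Bl <- basisLong(v, template$nLong, template$knots)
  A <- matrix(0, length(u), template$nRed)
  A[, 1] <- Bl[, 1]
  for (j in 2:template$nLong)
    for (i in seq_len(template$nCirc))
      A[, ridx(j, i, template$nCirc)] <- Bl[, j] * Bc[, i]
  A
}

evalSurfaceLocal <- function(theta, template, u, v)
  designMatrix(u, v, template) %*% theta

# Pose helpers -------------------------------------------------------------

toLocal <- function(pts, pose)
  sweep(matrix(pts, ncol = 3), 2, pose$t) %*% pose$R / pose$L

fromLocal <- function(q, pose)
  sweep(matrix(q, ncol = 3) %*% t(pose$R) * pose$L, 2, pose$t, "+")

#' Initialize the model pose from landmarks
#'
#' The long axis runs from the mitral-valve centroid to the apex; the basal
#' plane passes through the MV centroid normal to it; the zero azimuth
#' (septal direction) is set by the projection of the RV-insertion midpoint.
#' The template length is scaled to the MV-centroid-to-apex distance.
#'
#' @param mvPoints >= 2 mitral hinge points, patient mm (n x 3).
#' @param rvInserts >= 2 RV insertion points, patient mm (n x 3).
#' @param apex apex estimate, patient mm (length 3).
#' @return pose: list(R = cbind(septal, cross, long axis base-to-apex),
#'   t = MV centroid, L = length scale mm).
#' @export
initializePose <- function(mvPoints, rvInserts, apex) {
  mvPoints <- matrix(mvPoints, ncol = 3); rvInserts <- matrix(rvInserts, ncol = 3)
  stopifnot(nrow(mvPoints) >= 2, nrow(rvInserts) >= 2)
  t0 <- colMeans(mvPoints)
  ax <- apex - t0
  L <- vnorm(ax)
  if (L < 1e-6) stop("apex coincides with the mitral-valve centroid")
  e3 <- ax / L
  rvMid <- colMeans(rvInserts)
  d <- rvMid - t0
  d <- d - sum(d * e3) * e3
  if (vnorm(d) < 1e-9) stop("RV inserts give no septal direction")
  e1 <- unitv(d)
  e2 <- pracma::cross(e3, e1)
  list(R = cbind(e1, e2, e3), t = t0, L = L)
}

# Assign surface parameters to local points: nearest vertex on a dense
# parameter grid, then local 3x3 refinement with halved steps.
projectParams <- function(q, theta, template, nu = 64, nv = 17, refine = 5) {
  uu <- 2 * pi * (seq_len(nu) - 1) / nu
  vv <- (seq_len(nv) - 0.5) / nv
  grid <- expand.grid(u = uu, v = vv)
  S <- evalSurfaceLocal(theta, template, grid$u, grid$v)
  # nearest dense sample (n x m distance in blocks to bound memory)
  n <- nrow(q)
  best <- integer(n)
  bs <- 2000L
  for (s in seq(1, n, by = bs)) {
    e <- min(n, s + bs - 1L)
    d2 <- outer(rowSums(q[s:e, , drop = FALSE]^2), rowSums(S^2), "+") -
      2 * q[s:e, , drop = FALSE] %*% t(S)
    best[s:e] <- max.col(-d2, ties.method = "first")
  }
  u <- grid$u[best]; v <- grid$v[best]
  du <- 2 * pi / nu; dv <- 1 / nv
  off <- expand.grid(a = -1:1, b = -1:1)
  for (lev in seq_len(refine)) {
    du <- du / 2; dv <- dv / 2
    cand <- vector("list", nrow(off))
    for (kk in seq_len(nrow(off))) {
      uc <- (u + off$a[kk] * du) %% (2 * pi)
      vc <- pmin(pmax(v + off$b[kk] * dv, 1e-6), 1)
      Sc <- evalSurfaceLocal(theta, template, uc, vc)
      cand[[kk]] <- list(u = uc, v = vc, d2 = rowSums((q - Sc)^2))
    }
    d2m <- do.call(cbind, lapply(cand, `[[`, "d2"))
    pick <- max.col(-d2m, ties.method = "first")
    um <- do.call(cbind, lapply(cand, `[[`, "u"))
    vm <- do.call(cbind, lapply(cand, `[[`, "v"))
    sel <- cbind(seq_len(n), pick)
    u <- um[sel]
    v <- vm[sel]
  }
  list(u = u, v = v)
}

#' Fit one model surface to 3D contour points
#'
#' Outer loop: each data point is assigned the parameter location of its
#' closest surface point; inner solve: linear ridge least squares over the
#' control vertices minimizing the mean squared point-to-surface distance
#' plus lambda times a second-difference smoothing penalty on the control
#' displacements from the template (so the lambda -> infinity limit is the
#' pose-placed template itself). Iterates until the RMS distance changes by
#' less than \code{tol} mm.
#'
#' @param points3d n x 3 patient-space contour points (mm).
#' @param surface "endo" or "epi".
#' @param pose from \code{\link{initializePose}}.
#' @param template from \code{\link{lvTemplate}}.
#' @param lambda smoothing weight (normalized coordinates).
#' @param maxIter outer iteration cap.
#' @param tol convergence tolerance, mm.
#' @param thetaInit optional starting control grid.
#' @return list(theta, residuals (mm per point), rms (mm), rmsTrace).
#' @export
fitSurfaces <- function(points3d, surface = c("endo", "epi"), pose,
                        template = lvTemplate(), lambda = 0.1,
                        maxIter = 8, tol = 0.01, thetaInit = NULL) {
  surface <- match.arg(surface)
  q <- toLocal(points3d, pose)
  theta0 <- template[[surface]]
  theta <- if (is.null(thetaInit)) theta0 else thetaInit
  Kreg <- template$K + 1e-3 * diag(template$nRed)
  rmsTrace <- numeric()
  prevRms <- Inf
  for (it in seq_len(maxIter)) {
    pp <- projectParams(q, theta, template)
    A <- designMatrix(pp$u, pp$v, template)
    n <- nrow(A)
    lhs <- crossprod(A) / n + lambda * Kreg
    rhs <- crossprod(A, q) / n + lambda * Kreg %*% theta0
    theta <- tryCatch(solve(lhs, rhs), error = function(e)
      stop("rank-deficient fitting system; increase lambda"))
    res <- sqrt(rowSums((q - designMatrix(pp$u, pp$v, template) %*% theta)^2)) * pose$L
    rms <- sqrt(mean(res^2))
    rmsTrace <- c(rmsTrace, rms)
    if (abs(prevRms - rms) < tol) break
    prevRms <- rms
  }
  pp <- projectParams(q, theta, template)
  res <- sqrt(rowSums((q - designMatrix(pp$u, pp$v, template) %*% theta)^2)) * pose$L
  list(theta = theta, residuals = res, rms = sqrt(mean(res^2)), rmsTrace = rmsTrace)
}

#' Intersect a fitted surface with an image slice plane
#'
#' The surface is sampled on a dense parameter grid; along each
#' circumferential column the longitudinal crossing of the plane is located
#' by sign change and linear interpolation, giving an ordered intersection
#' polygon. The centroid is the area-weighted centroid of that polygon.
#'
#' @param fit A \linkS4class{FittedLV}.
#' @param g A \linkS4class{SliceGeometry}.
#' @param phase "ED" or "ES"; @param surface "endo" or "epi".
#' @param nu circumferential sampling density.
#' @return list(polygonPx (m x 2 row/col), centroidPatient (mm),
#'   empty flag).
#' @export
intersectWithSlice <- function(fit, g, phase = "ED", surface = "endo", nu = 96) {
  theta <- slot(fit, paste0(surface, phase))
  template <- fit@template; pose <- fit@pose
  n0 <- sliceNormal(g); p0 <- g@origin
  nv <- 65
  uu <- 2 * pi * (seq_len(nu) - 1) / nu
  vv <- seq(0, 1, length.out = nv)
  pts <- numeric(0)
  poly <- matrix(NA_real_, nu, 3)
  grid <- expand.grid(v = vv, u = uu)  # v fastest within each u column
  S <- fromLocal(evalSurfaceLocal(theta, template, grid$u, grid$v), pose)
  sd_ <- drop(sweep(S, 2, p0) %*% n0)
  for (ic in seq_len(nu)) {
    idx <- ((ic - 1) * nv + 1):(ic * nv)
    dcol <- sd_[idx]
    sgn <- which(dcol[-nv] * dcol[-1] <= 0 & is.finite(dcol[-nv]))
    if (!length(sgn)) next
    j <- sgn[1]
    w <- dcol[j] / (dcol[j] - dcol[j + 1])
    poly[ic, ] <- S[idx[j], ] * (1 - w) + S[idx[j + 1], ] * w
  }
  ok <- !is.na(poly[, 1])
  if (sum(ok) < 3)
    return(list(polygonPx = NULL, centroidPatient = NULL, empty = TRUE))
  px <- patientToPixel(poly[ok, , drop = FALSE], g)
  ctr <- polygonCentroid(px)
  list(polygonPx = px, centroidPatient = drop(pixelToPatient(ctr, g)),
      empty = FALSE)
}

#' Fit configuration
#' @param lambdaHigh first-pass (rigid-ish) smoothing weight.
#' @param lambdaLow final-pass weight.
#' @param maxIter outer iterations per fit.
#' @param tol convergence tolerance, mm.
#' @param nSample default N for surface sampling.
#' @return named list.
#' @export
fitConfig <- function(lambdaHigh = 1000, lambdaLow = 0.1, maxIter = 8,
                      tol = 0.01, nSample = 512L) {
  stopifnot(lambdaHigh > lambdaLow, lambdaLow > 0)
  list(lambdaHigh = lambdaHigh, lambdaLow = lambdaLow, maxIter = maxIter,
       tol = tol, nSample = as.integer(nSample))
}

#' Sample corresponding surface points from a fitted model
#'
#' Deterministic parameter-grid sampling (circumferential index fastest,
#' apex to base), identical parameter locations for every subject and
#' phase, so samples correspond across a cohort by parameterization.
#'
#' @param fit A \linkS4class{FittedLV}.
#' @param N points per surface; must be expressible as nCirc x nLong with
#'   nCirc = 32 (otherwise the nearest valid layout is used with a warning).
#' @return named list of four N x 3 matrices (endoED, epiED, endoES, epiES),
#'   patient mm.
#' @export
sampleSurfacePoints <- function(fit, N = 512) {
  nCirc <- 32L
  nLong <- N / nCirc
  if (nLong != round(nLong)) {
    nLong <- max(1, round(N / nCirc))
    warning(sprintf("N not expressible on the grid; using %d", nCirc * nLong))
  }
  u <- rep(2 * pi * (seq_len(nCirc) - 1) / nCirc, times = nLong)
  v <- rep((seq_len(nLong) - 0.5) / nLong, each = nCirc)
  out <- list()
  for (blk in SURFACE_BLOCKS) {
    theta <- slot(fit, blk)
    # surface parameter v = 0 at the apex, matching the apex->base ordering
    out[[blk]] <- fromLocal(evalSurfaceLocal(theta, fit@template, u, v), fit@pose)
  }
  out
}
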