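#' @useDynLib lvatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(x) sqrt(sum(x^2))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

# Rotation about a unit axis by `theta` radians (Rodrigues).
rotationMatrix <- function(axis, theta) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# 4x4 homogeneous rigid transform from rotation R and translation t.
rigidTransform <- function(R = diag(3), t = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  m
}

applyTransform <- function(m, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
}

invertTransform <- function(m) {
  R <- m[1:3, 1:3]
  rigidTransform(t(R), -t(R) %*% m[1:3, 4])
}

# Signed area of a closed 2D polygon (shoelace); positive = counter-clockwise
# in a right-handed (x up, y right) sense of the supplied columns.
polygonArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

polygonCentroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

# Deterministic digest of an R object: md5 of its canonical text serialization.
objectDigest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = c("exact")), f)
  unname(tools::md5sum(f))
}

#' @importFrom stats rnorm runif sd var aov coef glm binomial predict qnorm cor
#'   plogis setNames
#' @importFrom utils head tail read.csv write.csv
#' @importFrom graphics plot abline
#' @importFrom grDevices contourLines png dev.off
NULL
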