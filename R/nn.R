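#' Landmark network configuration
#'
#' A VGG-style coordinate-regression CNN: stacked 3x3 conv + ReLU + 2x2
#' max-pool blocks, a dense feature head and a 4-unit linear output
#' [row1, col1, row2, col2] (normalized by the input size). The full preset
#' mirrors the 16-layer / 2048-feature / 256x256 design; the scaled preset
#' (the test-suite default) uses 64x64 inputs, three conv blocks and a
#' 64-unit head so it trains on a desktop CPU.
#'
#' @param preset "scaled" or "full".
#' @param inputSize square input size in pixels.
#' @param channels conv channels per block.
#' @param hidden dense head width.
#' @param epochs,batchSize,lr optimizer settings (Adam).
#' @param seed integer.
#' @return named list of class \code{landmarkNetConfig}.
#' @export
landmarkNetConfig <- function(preset = c("scaled", "full"), inputSize = NULL,
                              channels = NULL, hidden = NULL, epochs = 20,
                              batchSize = 8, lr = 3e-3, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "scaled") {
    if (is.null(inputSize)) inputSize <- 64L
    if (is.null(channels)) channels <- c(8L, 16L, 32L)
    if (is.null(hidden)) hidden <- 64L
  } else {
    if (is.null(inputSize)) inputSize <- 256L
    if (is.null(channels)) channels <- c(32L, 64L, 128L, 256L, 512L, 512L)
    if (is.null(hidden)) hidden <- 2048L
  }
  stopifnot(inputSize %% 2^length(channels) == 0)
  structure(list(preset = preset, inputSize = as.integer(inputSize),
                 channels = as.integer(channels), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lr = lr, seed = as.integer(seed)),
            class = "landmarkNetConfig")
}

#' Whiten and pad/crop an image to the network input size
#'
#' The image is whitened per image (mean 0, SD 1 over the original-content
#' pixels), then zero-padded (or center-cropped) to a square target.
#' Landmark coordinates move by the returned offsets: new = old + offset.
#' A constant image (SD zero) is only centered.
#'
#' @param image numeric matrix.
#' @param targetSize square output size.
#' @return list(image, offset = c(rowOff, colOff), contentMask).
#' @export
preprocessImage <- function(image, targetSize = 256L) {
  s <- sd(as.vector(image))
  img <- if (s > 0) (image - mean(image)) / s else image - mean(image)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, targetSize, targetSize)
  rOff <- floor((targetSize - nr) / 2)
  cOff <- floor((targetSize - nc) / 2)
  srcR <- max(1, 1 - rOff):min(nr, targetSize - rOff)
  srcC <- max(1, 1 - cOff):min(nc, targetSize - cOff)
  out[srcR + rOff, srcC + cOff] <- img[srcR, srcC]
  cm <- matrix(FALSE, targetSize, targetSize)
  cm[srcR + rOff, srcC + cOff] <- TRUE
  list(image = out, offset = c(rOff, cOff), contentMask = cm)
}

# Build the (S,S,N) image array + 4 x N normalized target matrix from a
# list of images and an n x 4 pixel-coordinate target matrix, preprocessing
# each image and remapping its targets.
buildLandmarkArrays <- function(images, targets, S) {
  n <- length(images)
  arr <- array(0, c(S, S, n))
  tg <- matrix(0, 4, n)
  for (i in seq_len(n)) {
    pp <- preprocessImage(images[[i]], S)
    arr[, , i] <- pp$image
    tg[, i] <- (targets[i, ] + c(pp$offset, pp$offset)) / S
  }
  list(images = arr, targets = tg)
}

#' Train a landmark detection network (single view)
#'
#' Minimizes the mean squared error of the normalized landmark coordinates;
#' reports the validation mean Euclidean distance (pixels) per epoch.
#'
#' @param config see \code{\link{landmarkNetConfig}}.
#' @param images list of grayscale matrices.
#' @param targets n x 4 matrix of pixel coordinates (row1, col1, row2, col2)
#'   in each image's own frame.
#' @param valFraction held-out fraction (deterministic split under the
#'   config seed).
#' @param initParams optional warm-start parameter vector (transfer
#'   learning); random initialization otherwise.
#' @return list(model = list(params, config), valCurve, trainLoss,
#'   valIndex).
#' @export
trainLandmarkNet <- function(config, images, targets, valFraction = 0.2,
                             initParams = NULL) {
  n <- length(images)
  if (n < 50) stop("landmark training needs at least 50 images")
  S <- config$inputSize
  ba <- buildLandmarkArrays(images, targets, S)
  nVal <- max(1, round(valFraction * n))
  split <- withSeed(config$seed, sample.int(n))
  valIdx <- sort(split[seq_len(nVal)])
  trainIdx <- sort(split[-seq_len(nVal)])
  params <- if (is.null(initParams))
    lmnetInit(S, config$channels, config$hidden, config$seed)
  else initParams
  fit <- lmnetTrain(params, S, config$channels, config$hidden,
                    ba$images, ba$targets,
                    trainIdx - 1L, valIdx - 1L,
                    config$epochs, config$batchSize, config$lr, config$seed)
  valCurve <- as.numeric(fit$valCurve)
  if (!length(valCurve)) {  # zero-epoch run: evaluate the initial weights
    pr <- lmnetPredict(fit$params, S, config$channels, config$hidden,
                       ba$images[, , valIdx, drop = FALSE]) * S
    tg <- ba$targets[, valIdx, drop = FALSE] * S
    d <- sqrt(colSums(matrix((pr - tg)^2, nrow = 2)))
    valCurve <- mean(d)
  }
  list(model = list(params = as.numeric(fit$params), config = config),
       valCurve = valCurve,
       trainLoss = as.numeric(fit$trainLoss), valIndex = valIdx)
}

#' Predict landmark pairs
#'
#' @param model from \code{\link{trainLandmarkNet}}.
#' @param images list of grayscale matrices.
#' @return n x 4 matrix of pixel coordinates (row1, col1, row2, col2) in
#'   each image's original frame (preprocessing offsets undone).
#' @export
predictLandmarks <- function(model, images) {
  cfg <- model$config
  S <- cfg$inputSize
  n <- length(images)
  arr <- array(0, c(S, S, n))
  offs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    pp <- preprocessImage(images[[i]], S)
    arr[, , i] <- pp$image
    offs[i, ] <- pp$offset
  }
  out <- t(lmnetPredict(model$params, S, cfg$channels, cfg$hidden, arr)) * S
  out - cbind(offs, offs)
}

#' Cyclic cross-view transfer training
#'
#' Trains one view from scratch, then initializes each subsequent view from
#' the previously trained weights, cycling through the views in a seeded
#' random order until no view improves its validation mean distance by more
#' than \code{tolPx} over a full cycle (or \code{maxCycles} is reached).
#' The best weights per view are kept, so a later cycle can never degrade a
#' view's final model.
#'
#' @param configs named list of \code{landmarkNetConfig}, one per view.
#' @param datasets named list (same names) of list(images, targets).
#' @param maxCycles cycle cap.
#' @param tolPx convergence tolerance on validation mean distance, pixels.
#' @return list(models, history (per-cycle per-view validation distance),
#'   cycles, converged).
#' @export
cyclicTransferTrain <- function(configs, datasets, maxCycles = 10, tolPx = 0.05) {
  views <- names(configs)
  stopifnot(length(views) >= 2, setequal(views, names(datasets)))
  order_ <- withSeed(configs[[1]]$seed, sample(views))
  best <- setNames(vector("list", length(views)), views)
  bestVal <- setNames(rep(Inf, length(views)), views)
  params <- NULL
  history <- list()
  converged <- FALSE
  cyc <- 0
  for (cyc in seq_len(maxCycles)) {
    improved <- FALSE
    for (v in order_) {
      fit <- trainLandmarkNet(configs[[v]], datasets[[v]]$images,
                              datasets[[v]]$targets, initParams = params)
      params <- fit$model$params
      val <- tail(fit$valCurve, 1)
      if (val < bestVal[[v]] - tolPx) improved <- TRUE
      if (val < bestVal[[v]]) { bestVal[[v]] <- val; best[[v]] <- fit$model }
      history[[length(history) + 1L]] <-
        data.frame(cycle = cyc, view = v, valDistancePx = val)
    }
    if (!improved) { converged <- TRUE; break }
  }
  if (!converged && cyc == maxCycles)
    warning("cyclic transfer reached the cycle cap; returning best-so-far models")
  list(models = best, history = do.call(rbind, history),
       finalVal = bestVal, cycles = cyc, converged = converged)
}

#' Euclidean landmark error in millimetres
#'
#' @param predicted,reference n x 4 pixel-coordinate matrices (matched
#'   ordering) or n x 2 per-point matrices.
#' @param pixelSpacing mm per pixel (scalar or per-row vector).
#' @return list(distances (mm, one per point), mean, sd, max).
#' @export
evaluateLandmarks <- function(predicted, reference, pixelSpacing = 1) {
  predicted <- as.matrix(predicted); reference <- as.matrix(reference)
  if (!all(dim(predicted) == dim(reference)))
    stop("predicted and reference landmark counts differ")
  if (ncol(predicted) == 4) {
    predicted <- rbind(predicted[, 1:2, drop = FALSE], predicted[, 3:4, drop = FALSE])
    reference <- rbind(reference[, 1:2, drop = FALSE], reference[, 3:4, drop = FALSE])
    pixelSpacing <- rep(pixelSpacing, length.out = nrow(predicted))
  }
  d <- sqrt(rowSums((predicted - reference)^2)) * pixelSpacing
  list(distances = d, mean = mean(d), sd = sd(d), max = max(d))
}

# ------------------------------------------------------------ segmentation

#' Segmentation network configuration
#'
#' A U-Net with two encoder levels, a bottleneck and skip connections,
#' predicting 3 classes (background / myocardium / LV cavity) per pixel.
#'
#' @param inputSize square input size (scaled preset 64).
#' @param baseChannels first-level channel width.
#' @param epochs,batchSize,lr Adam settings.
#' @param augmentation list(flip, zoom, brightness, contrast): flip is
#'   logical; zoom and contrast are multiplicative ranges; brightness an
#'   additive half-range. NULL entries disable an augmentation.
#' @param seed integer.
#' @return named list of class \code{segNetConfig}.
#' @export
segNetConfig <- function(inputSize = 64L, baseChannels = 8L, epochs = 4,
                         batchSize = 16, lr = 3e-3,
                         augmentation = list(flip = TRUE, zoom = c(0.9, 1.1),
                                             brightness = 0.1,
                                             contrast = c(0.9, 1.1)),
                         seed = 1L) {
  stopifnot(inputSize %% 4 == 0)
  structure(list(inputSize = as.integer(inputSize),
                 baseChannels = as.integer(baseChannels),
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lr = lr, augmentation = augmentation, seed = as.integer(seed)),
            class = "segNetConfig")
}

flipImage <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

# Zoom about the image center; bilinear for images, nearest for masks.
zoomImage <- function(m, factor, nearest = FALSE) {
  n <- nrow(m); ctr <- (n - 1) / 2
  idx <- ((0:(n - 1)) - ctr) / factor + ctr
  if (nearest) {
    ii <- pmin(pmax(round(idx), 0), n - 1) + 1
    return(m[ii, ii, drop = FALSE])
  }
  i0 <- pmin(pmax(floor(idx), 0), n - 1)
  i1 <- pmin(i0 + 1, n - 1)
  w <- idx - i0
  w <- pmin(pmax(w, 0), 1)
  a <- m[i0 + 1, i0 + 1] * outer(1 - w, 1 - w) +
    m[i1 + 1, i0 + 1] * outer(w, 1 - w) +
    m[i0 + 1, i1 + 1] * outer(1 - w, w) +
    m[i1 + 1, i1 + 1] * outer(w, w)
  a
}

# One random augmentation of an (image, mask) pair: spatial ops applied
# jointly, intensity ops to the image only.
augmentPair <- function(image, mask, aug) {
  if (isTRUE(aug$flip) && runif(1) < 0.5) {
    image <- flipImage(image); mask <- flipImage(mask)
  }
  if (!is.null(aug$zoom)) {
    z <- runif(1, aug$zoom[1], aug$zoom[2])
    image <- zoomImage(image, z)
    mask <- zoomImage(mask, z, nearest = TRUE)
  }
  if (!is.null(aug$brightness)) image <- image + runif(1, -aug$brightness, aug$brightness)
  if (!is.null(aug$contrast)) {
    f <- runif(1, aug$contrast[1], aug$contrast[2])
    image <- (image - mean(image)) * f + mean(image)
  }
  list(image = image, mask = mask)
}

#' Train the 3-class U-Net on short-axis images
#'
#' Each image is segmented independently (no temporal or multi-slice
#' context). Augmentation (flip, zoom, brightness, contrast) doubles the
#' training set with randomized copies; spatial transforms are applied
#' identically to image and mask. Reports per-class validation Dice per
#' epoch.
#'
#' @param config see \code{\link{segNetConfig}}.
#' @param images list of grayscale matrices.
#' @param masks list of integer matrices (0 background, 1 myocardium,
#'   2 cavity).
#' @param valFraction held-out fraction.
#' @return list(model = list(params, config), valDice (epochs x 3),
#'   trainLoss, valIndex).
#' @export
trainSegmentation <- function(config, images, masks, valFraction = 0.2) {
  n <- length(images)
  stopifnot(n == length(masks), n >= 5)
  present <- sort(unique(unlist(lapply(masks, unique))))
  if (!all(0:2 %in% present))
    stop("training masks must contain all three classes (0, 1, 2)")
  S <- config$inputSize
  nVal <- max(1, round(valFraction * n))
  split <- withSeed(config$seed, sample.int(n))
  valIdx <- sort(split[seq_len(nVal)])
  trainIdx <- sort(split[-seq_len(nVal)])
  imgs <- images; msks <- masks
  if (!is.null(config$augmentation)) {
    withSeed(config$seed + 1L, {
      for (i in trainIdx) {
        ap <- augmentPair(images[[i]], masks[[i]], config$augmentation)
        imgs[[length(imgs) + 1L]] <- ap$image
        msks[[length(msks) + 1L]] <- ap$mask
      }
    })
    trainIdx <- c(trainIdx, seq(n + 1L, length(imgs)))
  }
  N <- length(imgs)
  arr <- array(0, c(S, S, N))
  marr <- array(0L, c(S, S, N))
  for (i in seq_len(N)) {
    arr[, , i] <- preprocessImage(imgs[[i]], S)$image
    # pad the mask with background, no whitening
    mm <- matrix(0L, S, S)
    nr <- nrow(msks[[i]]); nc <- ncol(msks[[i]])
    rOff <- floor((S - nr) / 2); cOff <- floor((S - nc) / 2)
    srcR <- max(1, 1 - rOff):min(nr, S - rOff)
    srcC <- max(1, 1 - cOff):min(nc, S - cOff)
    mm[srcR + rOff, srcC + cOff] <- as.integer(round(msks[[i]][srcR, srcC]))
    marr[, , i] <- mm
  }
  fit <- segnetTrain(segnetInit(S, config$baseChannels, config$seed),
                     S, config$baseChannels, arr, marr,
                     trainIdx - 1L, valIdx - 1L,
                     config$epochs, config$batchSize, config$lr, config$seed)
  list(model = list(params = as.numeric(fit$params), config = config),
       valDice = matrix(fit$valDice, ncol = 3,
                        dimnames = list(NULL, c("background", "myocardium", "cavity"))),
       trainLoss = as.numeric(fit$trainLoss), valIndex = valIdx)
}

#' Predict a 3-label mask
#'
#' Argmax class per pixel; the prediction is un-padded back to the original
#' image frame. Labels: 0 background, 1 myocardium, 2 LV cavity.
#'
#' @param model from \code{\link{trainSegmentation}}.
#' @param image grayscale matrix.
#' @return integer matrix with the input's dimensions.
#' @export
predictMask <- function(model, image) {
  cfg <- model$config
  S <- cfg$inputSize
  pp <- preprocessImage(image, S)
  lab <- segnetPredictOne(model$params, S, cfg$baseChannels, pp$image)
  nr <- nrow(image); nc <- ncol(image)
  rOff <- pp$offset[1]; cOff <- pp$offset[2]
  out <- matrix(0L, nr, nc)
  srcR <- max(1, 1 - rOff):min(nr, S - rOff)
  srcC <- max(1, 1 - cOff):min(nc, S - cOff)
  out[srcR, srcC] <- lab[srcR + rOff, srcC + cOff]
  out
}

#' Dice overlap for one class
#'
#' 2|A∩B| / (|A|+|B|). When the class is absent from both masks the score
#' is defined as 1 and flagged.
#'
#' @param pred,ref same-shape label matrices.
#' @param class class value compared.
#' @return Dice in [0,1]; attribute \code{bothEmpty}.
#' @export
diceScore <- function(pred, ref, class) {
  if (!all(dim(pred) == dim(ref))) stop("mask shapes differ")
  a <- pred == class; b <- ref == class
  denom <- sum(a) + sum(b)
  if (denom == 0) return(structure(1, bothEmpty = TRUE))
  structure(2 * sum(a & b) / denom, bothEmpty = FALSE)
}
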