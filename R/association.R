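# Stratified k-fold assignment keyed to stable subject ids: permuting the
# row order of the inputs never changes a subject's fold.
stratifiedFolds <- function(ids, labels, folds, seed) {
  fold <- integer(length(ids))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[order(ids[idx])]
      f <- rep(seq_len(folds), length.out = length(idx))
      fold[idx] <- sample(f)
    }
  })
  fold
}

# Logistic regression with a ridge-penalized IRLS fallback when quasi-perfect
# separation is detected. Returns a function(newX) -> probability.
fitLogistic <- function(X, y) {
  df <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep) {
    warning("separation detected; refitting with a ridge penalty")
    fit <- ridgeLogistic(as.matrix(X), y, lambda = 1e-2)
    return(function(newX) plogis(drop(cbind(1, as.matrix(newX)) %*% fit)))
  }
  function(newX) predict(fit, newdata = data.frame(newX), type = "response")
}

# Ridge-penalized logistic regression via IRLS (intercept unpenalized).
ridgeLogistic <- function(X, y, lambda = 1e-2, maxIter = 50) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (i in seq_len(maxIter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    betaNew <- solve(H, crossprod(Xd, w * z))
    if (max(abs(betaNew - beta)) < 1e-8) { beta <- betaNew; break }
    beta <- betaNew
  }
  drop(beta)
}

aucOf <- function(labels, prob) {
  as.numeric(pROC::auc(pROC::roc(labels, prob, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Cross-validated shape/risk-factor association
#'
#' For each of \code{folds} stratified folds the PCA atlas is rebuilt from
#' scratch on the training shapes only; a logistic regression of the binary
#' factor on the first \code{kComponents} training scores is fitted; the
#' held-out shapes are projected onto the training atlas and their predicted
#' probabilities retained. The headline statistic is the AUC of the pooled
#' out-of-fold probabilities (the fold-averaged AUC is also reported).
#'
#' @param shapes n x 12N matrix of Procrustes-aligned shape vectors.
#' @param labels binary 0/1 vector.
#' @param kComponents leading principal components used (default 20).
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param ids stable subject identifiers (default row order); fold
#'   assignment is keyed to these, not to row order.
#' @param factorName stored in the result.
#' @return An object of class \code{lvAssociation}: factor, foldAUCs,
#'   pooledAUC, meanFoldAUC, nComponents, predictions (data.frame id,
#'   label, prob, fold).
#' @export
cvAssociation <- function(shapes, labels, kComponents = 20, folds = 10,
                          seed = 1L, ids = NULL, factorName = "factor") {
  if (is.list(shapes) && !is.matrix(shapes)) shapes <- do.call(rbind, shapes)
  n <- nrow(shapes)
  stopifnot(length(labels) == n, all(labels %in% 0:1))
  if (n < folds) stop("need at least as many subjects as folds")
  if (is.null(ids)) ids <- seq_len(n)
  fold <- stratifiedFolds(ids, labels, folds, seed)
  # a fold must contain both classes to score; stratification guarantees it
  # unless a class has fewer members than folds
  for (f in seq_len(folds)) {
    if (length(unique(labels[fold == f])) < 2) {
      warning("fold with a single class; re-assigning folds with fewer splits")
      return(cvAssociation(shapes, labels, kComponents, max(2, folds - 1),
                           seed, ids, factorName))
    }
  }
  preds <- vector("list", folds)
  foldAUC <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    stopifnot(length(intersect(tr, te)) == 0)
    atlas <- atlasPCA(shapes[tr, , drop = FALSE])
    k <- min(kComponents, ncol(atlas@directions))
    Ztr <- atlas@scores[, seq_len(k), drop = FALSE]
    Zte <- projectShape(atlas, shapes[te, , drop = FALSE], k = k)
    colnames(Ztr) <- colnames(Zte) <- paste0("PC", seq_len(k))
    model <- fitLogistic(Ztr, labels[tr])
    p <- as.numeric(model(Zte))
    foldAUC[f] <- aucOf(labels[te], p)
    preds[[f]] <- data.frame(id = ids[te], label = labels[te], prob = p, fold = f)
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$id), ]
  structure(list(factor = factorName, foldAUCs = foldAUC,
                 pooledAUC = aucOf(predictions$label, predictions$prob),
                 meanFoldAUC = mean(foldAUC),
                 nComponents = kComponents, folds = folds,
                 predictions = predictions),
            class = "lvAssociation")
}

#' @export
print.lvAssociation <- function(x, ...) {
  cat(sprintf("Association '%s': pooled AUC %.3f (fold mean %.3f) over %d folds, %d PCs\n",
              x$factor, x$pooledAUC, x$meanFoldAUC, x$folds, x$nComponents))
  invisible(x)
}

#' Paired comparison of two cross-validated AUCs
#'
#' DeLong's paired test on the pooled out-of-fold predicted probabilities of
#' two pipelines evaluated on the same subjects and labels.
#'
#' @param resultA,resultB \code{lvAssociation} objects from
#'   \code{\link{cvAssociation}} on identical subjects.
#' @return list(aucA, aucB, p.value).
#' @export
compareAuc <- function(resultA, resultB) {
  pa <- resultA$predictions; pb <- resultB$predictions
  if (!identical(pa$id, pb$id) || !identical(pa$label, pb$label))
    stop("the two results must cover identical subjects and labels")
  if (isTRUE(all.equal(pa$prob, pb$prob)))
    return(list(aucA = resultA$pooledAUC, aucB = resultB$pooledAUC, p.value = 1))
  ra <- pROC::roc(pa$label, pa$prob, quiet = TRUE, direction = "<", levels = c(0, 1))
  rb <- pROC::roc(pb$label, pb$prob, quiet = TRUE, direction = "<", levels = c(0, 1))
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- tt$p.value
  if (is.nan(p)) p <- 1
  list(aucA = as.numeric(ra$auc), aucB = as.numeric(rb$auc), p.value = p)
}
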