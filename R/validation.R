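#' @include pls.R
NULL

#' Build a fixed-structure PLS modeler for permutation testing
#'
#' Returns a function(X, y) -> list(r2, q2) that refits a PLS model with a
#' frozen variable subset and component count, as required by
#' [yRandomization()]: the permutation test must refit the same model family,
#' not re-run the variable selection.
#'
#' @param mask Logical vector over descriptor columns (default: all).
#' @param ncomp Component count to use in every refit.
#' @return A modeler function.
#' @export
plsModeler <- function(ncomp, mask = NULL) {
  force(ncomp); force(mask)
  function(X, y) {
    X <- as.matrix(X)
    if (!is.null(mask)) X <- X[, as.logical(mask), drop = FALSE]
    cv <- looQ2(X, y, ncomp)
    list(r2 = cv$r2, q2 = cv$q2)
  }
}

#' Y-randomization (response permutation) test
#'
#' Refits the model on randomly permuted activities and regresses the
#' resulting R2 and Q2 against the absolute Pearson correlation between each
#' permuted response and the original one. The unpermuted model enters the
#' regression at r = 1 (default; can be excluded). A model free of chance
#' correlation has intercepts below the conventional limits R2 < 0.300 and
#' Q2 < 0.050.
#'
#' @param X Descriptor matrix.
#' @param y Activity vector.
#' @param modeler Function(X, y) returning list(r2, q2); see [plsModeler()].
#' @param nPerm Number of permutations (>= 10; default 50).
#' @param seed Integer seed; required for a reproducible report.
#' @param includeUnpermuted Include the real model at r = 1 (default TRUE).
#' @param limits Intercept pass limits for (R2, Q2).
#' @return List with the per-permutation `records` data frame (r, r2, q2;
#'   first row is the unpermuted model when included), fitted `interceptR2`
#'   and `interceptQ2`, slopes, logical `pass` flags, nPerm and seed.
#' @export
yRandomization <- function(X, y, modeler, nPerm = 50L, seed,
                           includeUnpermuted = TRUE,
                           limits = c(r2 = 0.300, q2 = 0.050)) {
  if (missing(seed)) stop("a seed is required for a reproducible report")
  nPerm <- as.integer(nPerm)
  if (nPerm < 10L) stop("nPerm must be >= 10")
  X <- as.matrix(X); y <- as.numeric(y)
  set.seed(seed)
  rows <- vector("list", nPerm + 1L)
  if (includeUnpermuted) {
    real <- modeler(X, y)
    rows[[1L]] <- data.frame(r = 1, r2 = real$r2, q2 = real$q2)
  }
  nFail <- 0L
  for (k in seq_len(nPerm)) {
    yp <- sample(y)
    rec <- tryCatch(modeler(X, yp), error = function(e) NULL)
    if (is.null(rec)) { nFail <- nFail + 1L; next }
    rows[[k + 1L]] <- data.frame(r = abs(stats::cor(yp, y)),
                                 r2 = rec$r2, q2 = rec$q2)
  }
  if (nFail > 0L)
    warning(nFail, " permutation refit(s) failed and were excluded")
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(records) <- NULL
  fitR2 <- stats::lm(r2 ~ r, data = records)
  fitQ2 <- stats::lm(q2 ~ r, data = records)
  iR2 <- unname(stats::coef(fitR2)[1])
  iQ2 <- unname(stats::coef(fitQ2)[1])
  list(records = records,
       interceptR2 = iR2, interceptQ2 = iQ2,
       slopeR2 = unname(stats::coef(fitR2)[2]),
       slopeQ2 = unname(stats::coef(fitQ2)[2]),
       pass = c(r2 = iR2 < limits[["r2"]], q2 = iQ2 < limits[["q2"]]),
       limits = limits, nPerm = nPerm, seed = seed)
}

#' Rational train/test division: k-means clusters, odd/even activity ranks
#'
#' Clusters the samples in autoscaled descriptor space with k-means (k = 2,
#' seeded, 10 restarts, best inertia kept), sorts each cluster by ascending
#' activity, and assigns odd ranks (1st, 3rd, ...) to the training set and
#' even ranks to the test set. Ties in activity are ordered by sample ID so
#' the split is reproducible.
#'
#' @param X Descriptor matrix (rownames used as sample IDs when present).
#' @param y Activity vector.
#' @param seed Integer seed for the k-means restarts.
#' @param centers Number of clusters (default 2).
#' @return List with `train` and `test` index vectors, `clusters`, and the
#'   within-cluster activity `ranks`.
#' @export
kmeansOddEvenSplit <- function(X, y, seed, centers = 2L) {
  if (missing(seed)) stop("a seed is required for a reproducible split")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples to split")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  Z <- scale(X)
  Z <- Z[, apply(X, 2L, stats::sd) > 0, drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(Z, centers = centers, nstart = 10L)
  if (any(km$size == 0L)) stop("k-means produced an empty cluster")
  ranks <- integer(n)
  train <- logical(n)
  for (cl in seq_len(centers)) {
    idx <- which(km$cluster == cl)
    ord <- idx[order(y[idx], ids[idx])]   # ascending activity, ties by ID
    ranks[ord] <- seq_along(ord)
    train[ord[seq_along(ord) %% 2L == 1L]] <- TRUE
  }
  list(train = which(train), test = which(!train),
       clusters = km$cluster, ranks = ranks, ids = ids)
}

#' External-set validation statistics
#'
#' Predicts a disjoint test set and reports the external Q2 computed against
#' the training-set mean activity (the stricter convention), plus the RMS of
#' the test residuals.
#'
#' @param model A fitted [PLSModel-class].
#' @param Xtest,ytest Test descriptors and activities.
#' @return List with q2ext, rms, press and n.
#' @export
externalValidate <- function(model, Xtest, ytest) {
  ytest <- as.numeric(ytest)
  pred <- predict(model, Xtest)
  press <- sum((ytest - pred)^2)
  ybarTrain <- model@yCenter
  ss <- sum((ytest - ybarTrain)^2)
  list(q2ext = 1 - press / ss, rms = sqrt(press / length(ytest)),
       press = press, n = length(ytest))
}
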