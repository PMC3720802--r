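#' @include AllClasses.R
NULL

.checkXy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (nrow(X) < 3L) stop("need at least 3 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(y) == 0) stop("constant response: nothing to model")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  list(X = X, y = y)
}

# autoscale columns; zero-variance columns are reported for the caller to drop
.autoscale <- function(X) {
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep], "-"),
             2L, sds[keep], "/")
  list(Z = Z, center = ctr, scale = sds, keep = keep)
}

# NIPALS PLS1 on autoscaled blocks. Extracts up to A components, fewer if the
# X-block or y-residual is exhausted. The inner iteration is kept for
# generality; with a single response it converges in one pass.
.nipals <- function(Z, f, A, tol = 1e-12, maxit = 500L) {
  n <- nrow(Z); p <- ncol(Z)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  TT <- matrix(0, n, A); U <- matrix(0, n, A)
  cvec <- numeric(A)
  E <- Z; fr <- f
  a <- 0L
  while (a < A) {
    u <- fr
    w <- crossprod(E, u)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    it <- 0L
    repeat {
      t <- E %*% w
      cc <- sum(fr * t) / sum(t * t)
      unew <- fr * cc                      # y-block score (single response)
      wnew <- crossprod(E, unew)
      nw <- sqrt(sum(wnew^2))
      if (nw < tol) break
      wnew <- wnew / nw
      it <- it + 1L
      if (sum((wnew - w)^2) < tol || it >= maxit) { w <- wnew; break }
      w <- wnew
    }
    t <- E %*% w
    tt <- sum(t * t)
    if (tt < tol) break
    pvec <- crossprod(E, t) / tt
    cc <- sum(fr * t) / tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- pvec; TT[, a] <- t; U[, a] <- u; cvec[a] <- cc
    E <- E - tcrossprod(t, pvec)
    fr <- fr - cc * t
    if (sqrt(sum(fr^2)) < tol) break
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       T = TT[, seq_len(a), drop = FALSE], U = U[, seq_len(a), drop = FALSE],
       c = cvec[seq_len(a)], ncomp = a)
}

# regression vector on the autoscaled data for each component count 1..A
.plsCoefPath <- function(fit) {
  A <- fit$ncomp
  p <- nrow(fit$W)
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- fit$W[, seq_len(a), drop = FALSE]
    Pa <- fit$P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))
    B[, a] <- R %*% fit$c[seq_len(a)]
  }
  B
}

#' Fit a NIPALS partial least squares regression
#'
#' Both the descriptor columns and the response are autoscaled (centered,
#' unit variance) before extraction; each component deflates the X block and
#' the response. The returned regression vector is expressed back on the
#' original variable scale.
#'
#' @param X Numeric descriptor matrix, samples x variables.
#' @param y Numeric response (e.g. pT or pIC50).
#' @param ncomp Number of latent components A; must not exceed the rank of
#'   the centered X.
#' @return A [PLSModel-class]; `fitStats(model)` holds the calibration R2 and
#'   RMS (Q2 fields are NA until [looQ2()] is run).
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X[, 1] - 2 * X[, 2] + rnorm(20, sd = .1)
#' fitStats(fitPLS(X, y, 2))$r2
#' @export
fitPLS <- function(X, y, ncomp) {
  d <- .checkXy(X, y)
  X <- d$X; y <- d$y
  A <- as.integer(ncomp)
  if (A < 1L) stop("ncomp must be >= 1")
  sc <- .autoscale(X)
  if (!all(sc$keep))
    stop("zero-variance descriptor column(s): ",
         paste(colnames(X)[!sc$keep], collapse = ", "))
  rk <- qr(sweep(X, 2L, colMeans(X)))$rank
  if (A > rk)
    stop(sprintf("ncomp = %d exceeds the rank of centered X (%d)", A, rk))
  yc <- mean(y); ys <- stats::sd(y)
  f <- (y - yc) / ys
  fit <- .nipals(sc$Z, f, A)
  if (fit$ncomp < A)
    stop(sprintf("NIPALS could only extract %d component(s)", fit$ncomp))
  Bz <- .plsCoefPath(fit)[, A]
  beta <- ys * Bz / sc$scale
  intercept <- yc - sum(beta * sc$center)
  fitted <- as.numeric(X %*% beta + intercept)
  ssres <- sum((y - fitted)^2)
  sstot <- sum((y - yc)^2)
  new("PLSModel",
      ncomp = A, weights = fit$W, xLoadings = fit$P, scores = fit$T,
      yScores = fit$U, innerCoef = fit$c,
      xCenter = sc$center, xScale = sc$scale, yCenter = yc, yScale = ys,
      coefficients = c("(Intercept)" = intercept,
                       stats::setNames(beta, colnames(X))),
      fitted = fitted, y = y, varNames = colnames(X),
      fitStats = list(r2 = 1 - ssres / sstot, q2 = NA_real_,
                      rms = sqrt(ssres / length(y)), press = NA_real_,
                      n = length(y)))
}

#' Predict activities for new peptides from a fitted PLS model
#'
#' @param object A [PLSModel-class].
#' @param newdata Descriptor matrix with the training columns (matched by
#'   name when names are present).
#' @return Numeric vector of predictions on the original response scale.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    miss <- setdiff(object@varNames, colnames(X))
    if (length(miss))
      stop("newdata is missing descriptor column(s): ",
           paste(miss, collapse = ", "))
    X <- X[, object@varNames, drop = FALSE]
  } else if (ncol(X) != length(object@varNames)) {
    stop(sprintf("newdata has %d columns, model expects %d",
                 ncol(X), length(object@varNames)))
  }
  b <- object@coefficients
  as.numeric(X %*% b[-1] + b[1])
})

# one full LOO pass; returns the n x Amax matrix of held-out predictions on
# the original response scale (autoscaling refit inside every fold).
.looPredictions <- function(X, y, aMax) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, aMax)
  droppedAny <- FALSE
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    sc <- .autoscale(Xi)
    if (!all(sc$keep)) droppedAny <- TRUE
    yc <- mean(yi); ys <- stats::sd(yi)
    if (ys == 0) stop("constant response inside a leave-one-out fold")
    fit <- .nipals(sc$Z, (yi - yc) / ys, aMax)
    if (fit$ncomp == 0L) { pred[i, ] <- yc; next }
    B <- .plsCoefPath(fit)
    znew <- (X[i, sc$keep] - sc$center[sc$keep]) / sc$scale[sc$keep]
    ph <- yc + ys * as.numeric(znew %*% B)
    if (fit$ncomp < aMax)                 # exhausted: carry the last model
      ph <- c(ph, rep(ph[fit$ncomp], aMax - fit$ncomp))
    pred[i, ] <- ph
  }
  if (droppedAny)
    warning("zero-variance descriptor column(s) dropped inside LOO fold(s)")
  pred
}

#' Leave-one-out cross-validation statistics for a PLS model
#'
#' Every fold refits the autoscaling and the NIPALS decomposition on the
#' remaining n - 1 samples and predicts the held-out one. Q2 is
#' 1 - PRESS / total sum of squares about the full-sample mean; the reported
#' RMS is the root mean square of the cross-validated residuals
#' (sqrt(PRESS / n)).
#'
#' @inheritParams fitPLS
#' @param ncomp Number of components used in every fold.
#' @return List with r2 (calibration, from the full-data fit), q2, rms,
#'   press and n.
#' @export
looQ2 <- function(X, y, ncomp) {
  d <- .checkXy(X, y)
  X <- d$X; y <- d$y
  full <- fitPLS(X, y, ncomp)
  pred <- .looPredictions(X, y, as.integer(ncomp))[, as.integer(ncomp)]
  press <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  list(r2 = fitStats(full)$r2, q2 = 1 - press / sstot,
       rms = sqrt(press / length(y)), press = press, n = length(y))
}

#' Choose the PLS component count by minimum LOO PRESS
#'
#' Evaluates 1..`aMax` components in a single leave-one-out pass and returns
#' the count with the smallest predictive residual sum of squares, breaking
#' ties toward the smaller model.
#'
#' @inheritParams fitPLS
#' @param aMax Largest component count to consider.
#' @return Integer, the selected component count.
#' @export
selectComponents <- function(X, y, aMax) {
  d <- .checkXy(X, y)
  X <- d$X; y <- d$y
  aMax <- min(as.integer(aMax), ncol(X), nrow(X) - 2L)
  if (aMax < 1L) stop("aMax must be >= 1")
  pred <- .looPredictions(X, y, aMax)
  press <- colSums((y - pred)^2)
  which.min(press)                         # first minimum = smallest A
}
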