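#' @include AllClasses.R
NULL

.checkTwoClass <- function(labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L) stop("exactly two classes are required")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  labels
}

.positiveClass <- function(labels, positive = NULL) {
  cls <- unique(as.character(labels))
  if (!is.null(positive)) {
    if (!positive %in% cls) stop("positive class '", positive, "' not present")
    return(c(positive, setdiff(cls, positive)))
  }
  if ("strong" %in% cls) c("strong", setdiff(cls, "strong")) else cls
}

# Wilks' lambda det(W)/det(T) on a column subset
.wilksLambda <- function(X, labels, cols) {
  if (length(cols) == 0L) return(1)
  Xs <- X[, cols, drop = FALSE]
  Tm <- crossprod(sweep(Xs, 2L, colMeans(Xs)))
  Wm <- matrix(0, length(cols), length(cols))
  for (cl in unique(labels)) {
    Xc <- Xs[labels == cl, , drop = FALSE]
    Wm <- Wm + crossprod(sweep(Xc, 2L, colMeans(Xc)))
  }
  dT <- det(Tm)
  if (dT <= 0) return(NA_real_)
  det(Wm) / dT
}

#' Stepwise variable selection by partial-F tests on Wilks' lambda
#'
#' Forward selection with backward checks: at each step the candidate with
#' the largest partial F enters if F exceeds `fEnter` (default 3.84), and any
#' included variable whose F-to-remove drops below `fRemove` (default 2.71)
#' leaves again. Ties break toward the lower column index, so the procedure
#' is deterministic. The partial F for moving between a q-variable model with
#' lambda L_q and a (q+1)-variable model with lambda L_{q+1} is
#' (n - g - q) / (g - 1) * (L_q / L_{q+1} - 1) with g = 2 classes.
#'
#' @param X Descriptor matrix, samples x variables.
#' @param labels Two-class vector.
#' @param fEnter,fRemove Entry and removal thresholds.
#' @return Integer vector of selected column indices, in entry order.
#' @export
stepwiseSelect <- function(X, labels, fEnter = 3.84, fRemove = 2.71) {
  X <- as.matrix(X)
  labels <- .checkTwoClass(labels)
  n <- nrow(X); g <- 2L
  selected <- integer(0)
  lambdaCur <- 1
  repeat {
    # backward: drop the weakest included variable if it fails fRemove
    if (length(selected) > 1L) {
      q <- length(selected)
      fRem <- vapply(seq_along(selected), function(k) {
        lam <- .wilksLambda(X, labels, selected[-k])
        (n - g - (q - 1L)) / (g - 1L) * (lam / lambdaCur - 1)
      }, numeric(1))
      k <- which.min(fRem)
      if (is.finite(fRem[k]) && fRem[k] < fRemove) {
        selected <- selected[-k]
        lambdaCur <- .wilksLambda(X, labels, selected)
        next
      }
    }
    # forward: enter the strongest remaining candidate if it passes fEnter
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (length(cand) == 0L) break
    q <- length(selected)
    fEnt <- vapply(cand, function(j) {
      lam <- .wilksLambda(X, labels, c(selected, j))
      if (!is.finite(lam) || lam <= 0) return(-Inf)
      (n - g - q) / (g - 1L) * (lambdaCur / lam - 1)
    }, numeric(1))
    j <- cand[which.max(fEnt)]
    if (max(fEnt) > fEnter) {
      selected <- c(selected, j)
      lambdaCur <- .wilksLambda(X, labels, selected)
    } else break
  }
  if (length(selected) == 0L)
    stop("no variable reached the entry threshold F > ", fEnter,
         "; review the thresholds or the descriptors")
  selected
}

#' Fit a two-class linear discriminant on selected descriptors
#'
#' Fisher discriminant with pooled within-class covariance: the discriminant
#' function is Y = a0 + a'x with a = S^-1 (mu_pos - mu_neg) and the intercept
#' placing the boundary midway between the projected class means, shifted by
#' the log prior ratio. Y > 0 classifies to the positive class, and the
#' Gaussian equal-covariance posterior for the positive class is plogis(Y).
#'
#' @param X Descriptor matrix (already restricted to the selected variables,
#'   or use `selected` to subset).
#' @param labels Two-class vector.
#' @param selected Column indices to use (default: all columns of X).
#' @param priors "equal" (default) or "proportional", or a named numeric.
#' @param positive Positive class label; defaults to "strong" when present.
#' @return An [LDAModel-class].
#' @export
fitLDA <- function(X, labels, selected = seq_len(ncol(as.matrix(X))),
                   priors = c("equal", "proportional"), positive = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  labels <- .checkTwoClass(labels)
  selected <- as.integer(selected)
  cls <- .positiveClass(labels, positive)
  Xs <- X[, selected, drop = FALSE]
  k <- ncol(Xs); n <- nrow(Xs)
  if (is.character(priors)) {
    priors <- match.arg(priors)
    pr <- if (priors == "equal") c(0.5, 0.5)
          else as.numeric(table(factor(labels, cls)) / n)
  } else pr <- as.numeric(priors[cls])
  mu <- rbind(colMeans(Xs[labels == cls[1], , drop = FALSE]),
              colMeans(Xs[labels == cls[2], , drop = FALSE]))
  rownames(mu) <- cls
  Sp <- matrix(0, k, k)
  for (i in 1:2) {
    Xc <- Xs[labels == cls[i], , drop = FALSE]
    Sp <- Sp + crossprod(sweep(Xc, 2L, colMeans(Xc)))
  }
  Sp <- Sp / (n - 2L)
  a <- tryCatch(solve(Sp, mu[1, ] - mu[2, ]),
                error = function(e)
                  stop("pooled covariance is singular; use fewer variables"))
  a0 <- -sum(a * (mu[1, ] + mu[2, ])) / 2 + log(pr[1] / pr[2])
  new("LDAModel",
      selected = selected, classes = cls, priors = stats::setNames(pr, cls),
      coefficients = c("(Intercept)" = a0,
                       stats::setNames(a, colnames(Xs))),
      standardized = stats::setNames(a * sqrt(diag(Sp)), colnames(Xs)),
      means = mu, pooledCov = Sp, varNames = colnames(Xs))
}

#' Predict classes from a fitted discriminant
#'
#' @param object An [LDAModel-class].
#' @param newdata Descriptor matrix with all original columns (the model
#'   subsets its selected variables) or exactly the selected columns.
#' @return List with `class`, discriminant `score` and positive-class
#'   `posterior`.
#' @export
setMethod("predict", "LDAModel", function(object, newdata) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@selected)) {
    if (max(object@selected) > ncol(X))
      stop("newdata has too few columns for the model's selected variables")
    X <- X[, object@selected, drop = FALSE]
  }
  b <- object@coefficients
  score <- as.numeric(X %*% b[-1] + b[1])
  list(class = ifelse(score > 0, object@classes[1], object@classes[2]),
       score = score, posterior = stats::plogis(score))
})

#' Confusion-matrix statistics for a two-class prediction
#'
#' @param obs,pred Observed and predicted class vectors, or pass explicit
#'   counts via `tp`, `fn`, `tn`, `fp`.
#' @param positive Positive class label (default "strong" when present).
#' @param tp,fn,tn,fp Explicit counts (used when `obs` is missing).
#' @return List with counts, accuracy, sensitivity, specificity and the
#'   Matthews correlation coefficient (0/0 convention: MCC = 0).
#' @examples
#' confusionStats(tp = 6, fn = 2, tn = 9, fp = 3)$mcc
#' @export
confusionStats <- function(obs, pred, positive = NULL,
                           tp = NULL, fn = NULL, tn = NULL, fp = NULL) {
  if (missing(obs)) {
    stopifnot(!is.null(tp), !is.null(fn), !is.null(tn), !is.null(fp))
  } else {
    obs <- as.character(obs); pred <- as.character(pred)
    cls <- .positiveClass(obs, positive)
    tp <- sum(obs == cls[1] & pred == cls[1])
    fn <- sum(obs == cls[1] & pred != cls[1])
    tn <- sum(obs != cls[1] & pred != cls[1])
    fp <- sum(obs != cls[1] & pred == cls[1])
  }
  n <- tp + fn + tn + fp
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(tp = tp, fn = fn, tn = tn, fp = fp, n = n,
       accuracy = (tp + tn) / n,
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       mcc = mcc)
}

#' Leave-one-out classification with stepwise LDA
#'
#' By default ("paper" mode) the stepwise selection is performed once on the
#' full dataset and only the discriminant is refit in each leave-one-out
#' fold; "strict" mode repeats the selection inside every fold as well.
#'
#' @inheritParams stepwiseSelect
#' @param priors,positive Passed to [fitLDA()].
#' @param mode "paper" (selection outside the loop, default) or "strict".
#' @return [confusionStats()] list for the cross-validated predictions, with
#'   the selected variable indices attached as `selected`.
#' @export
looClassify <- function(X, labels, fEnter = 3.84, fRemove = 2.71,
                        priors = "equal", positive = NULL,
                        mode = c("paper", "strict")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  labels <- .checkTwoClass(labels)
  n <- nrow(X)
  selectedFull <- stepwiseSelect(X, labels, fEnter, fRemove)
  pred <- character(n)
  for (i in seq_len(n)) {
    li <- labels[-i]
    if (length(unique(li)) < 2L)
      stop("a leave-one-out fold has a single-class training set")
    sel <- if (mode == "paper") selectedFull
           else stepwiseSelect(X[-i, , drop = FALSE], li, fEnter, fRemove)
    m <- fitLDA(X[-i, , drop = FALSE], li, selected = sel,
                priors = priors, positive = positive)
    pred[i] <- predict(m, X[i, , drop = FALSE])$class
  }
  out <- confusionStats(labels, pred, positive = positive)
  out$selected <- selectedFull
  out
}
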