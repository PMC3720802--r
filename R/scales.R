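#' @include AllClasses.R
NULL

.asPropertyTable <- function(table) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("property table needs at least 2 rows and 2 columns")
  if (anyNA(x)) stop("property table must not contain missing cells")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("P", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("residue IDs (rownames) must be unique")
  if (anyDuplicated(colnames(x))) stop("property names (colnames) must be unique")
  x
}

#' Standardize a residue-by-property table
#'
#' Centers every property to mean zero and scales to unit standard deviation
#' (n - 1 denominator), returning the parameters so that new residues can be
#' placed on the same scale later.
#'
#' @param table Numeric matrix or data frame, residues x properties.
#' @return List with `values` (standardized matrix), `center` and `scale`.
#' @examples
#' standardizeProperties(cbind(a = 1:3, b = c(2, 4, 9)))$values
#' @export
standardizeProperties <- function(table) {
  x <- .asPropertyTable(table)
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop("zero-variance property column(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, sds, "/")
  list(values = z, center = ctr, scale = sds)
}

#' Eigenvalues of the property correlation matrix
#'
#' Reports the eigenvalue spectrum so the number of factors to retain can be
#' chosen by the usual scree / eigenvalue-greater-than-one reasoning; the
#' package never picks the number automatically.
#'
#' @inheritParams standardizeProperties
#' @return Numeric vector of eigenvalues, descending.
#' @export
propertyEigenvalues <- function(table) {
  z <- standardizeProperties(table)$values
  R <- stats::cor(z)
  eigen(R, symmetric = TRUE, only.values = TRUE)$values
}

# flip each factor so its maximum-|loading| entry is positive; propagate the
# flip into phi and score coefficients so the solution stays self-consistent
.applySignConvention <- function(L, phi = NULL, W = NULL) {
  flip <- vapply(seq_len(ncol(L)), function(j) {
    v <- L[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  s <- ifelse(flip, -1, 1)
  L <- sweep(L, 2L, s, "*")
  if (!is.null(phi)) phi <- diag(s, length(s)) %*% phi %*% diag(s, length(s))
  if (!is.null(W)) W <- sweep(W, 2L, s, "*")
  list(L = L, phi = phi, W = W)
}

#' Fit a rotated factor model to a residue-by-property table
#'
#' Extraction is the principal-component method: eigendecomposition of the
#' property correlation matrix, the top `nFactors` components scaled to
#' loadings (eigenvector times the square root of its eigenvalue). Rotation is
#' varimax with Kaiser row-normalization followed by an oblique promax step of
#' the given power; `promaxPower = 1` leaves the varimax solution (factor
#' correlations collapse to the identity). Factor score coefficients are
#' computed by the regression (Thurstone) method by default, from the factor
#' structure matrix and the inverse property correlation matrix; the Bartlett
#' weighted-least-squares estimator is available as an alternative.
#'
#' Rotational indeterminacy is resolved deterministically: factors keep the
#' order produced from the descending-eigenvalue extraction and every rotated
#' factor is flipped so its maximum-absolute-loading entry is positive.
#'
#' @inheritParams standardizeProperties
#' @param nFactors Number of factors m to retain (<= min(p, n - 1)).
#' @param promaxPower Promax power; 1 reduces to varimax. Default 4.
#' @param scoreMethod "regression" (default) or "bartlett".
#' @param factorNames Optional names for the factors; defaults to the six
#'   canonical pattern names when m = 6, F1..Fm otherwise.
#' @return A [FactorModel-class].
#' @examples
#' fix <- syntheticPropertyTable(nEntities = 60, nProperties = 8,
#'                               nFactors = 2, seed = 1)
#' fm <- fitFactorModel(fix$table, nFactors = 2)
#' explainedVariance(fm)
#' @export
fitFactorModel <- function(table, nFactors, promaxPower = 4L,
                           scoreMethod = c("regression", "bartlett"),
                           factorNames = NULL) {
  scoreMethod <- match.arg(scoreMethod)
  std <- standardizeProperties(table)
  z <- std$values
  p <- ncol(z)
  m <- as.integer(nFactors)
  if (m < 1L) stop("nFactors must be >= 1")
  if (m > min(p, nrow(z) - 1L))
    stop(sprintf("nFactors = %d exceeds min(p, n - 1) = %d",
                 m, min(p, nrow(z) - 1L)))
  R <- stats::cor(z)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  L <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(m)]), m)
  # deterministic sign for the unrotated solution too
  L <- .applySignConvention(L)$L
  dimnames(L) <- list(colnames(z), NULL)

  if (m == 1L) {
    pat <- L
    phi <- matrix(1, 1, 1)
  } else if (promaxPower == 1L) {
    vm <- stats::varimax(L, normalize = TRUE)
    pat <- L %*% vm$rotmat
    phi <- diag(m)
  } else {
    pm <- stats::promax(L, m = promaxPower)
    pat <- unclass(pm$loadings)
    U <- pm$rotmat
    phi <- solve(crossprod(U))
    phi <- (phi + t(phi)) / 2
  }

  h2 <- rowSums(L^2)
  S <- pat %*% phi                      # structure matrix
  W <- switch(scoreMethod,
    regression = solve(R, S),
    bartlett = {
      u <- pmax(1 - h2, 1e-8)
      Uinv <- diag(1 / u, p)
      Uinv %*% pat %*% solve(t(pat) %*% Uinv %*% pat)
    })

  fixed <- .applySignConvention(pat, phi, W)
  pat <- fixed$L; phi <- fixed$phi; W <- fixed$W

  fn <- if (is.null(factorNames)) .factorNamesFor(m) else factorNames
  if (length(fn) != m) stop("factorNames must have length nFactors")
  dimnames(pat) <- list(colnames(z), fn)
  dimnames(W) <- list(colnames(z), fn)
  dimnames(phi) <- list(fn, fn)
  colnames(L) <- fn

  new("FactorModel",
      nFactors = m, center = std$center, scale = std$scale,
      eigenvalues = ev, unrotated = L, pattern = pat, phi = phi,
      communalities = stats::setNames(h2, colnames(z)),
      scoreCoefficients = W,
      explainedVariance = sum(ev[seq_len(m)]) / p,
      promaxPower = as.integer(promaxPower), scoreMethod = scoreMethod)
}

#' Compute factor scores for residues
#'
#' Places each residue of a property table on the model's factor scales:
#' scores are the standardized property values multiplied by the model's
#' score-coefficient matrix. Columns are matched by property name
#' (order-insensitive); any missing or extra property is an error.
#'
#' @param model A [FactorModel-class].
#' @inheritParams standardizeProperties
#' @return A [ScaleTable-class] with one row per residue.
#' @export
factorScores <- function(model, table) {
  x <- .asPropertyTable(table)
  want <- names(model@center)
  missing <- setdiff(want, colnames(x))
  extra <- setdiff(colnames(x), want)
  if (length(missing) || length(extra))
    stop("property columns do not match the model",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  x <- x[, want, drop = FALSE]
  z <- sweep(sweep(x, 2L, model@center, "-"), 2L, model@scale, "/")
  ScaleTable(z %*% model@scoreCoefficients)
}

#' Tucker congruence between two loading matrices
#'
#' Matches columns of `estimated` to columns of `truth` greedily by absolute
#' Tucker congruence (sign- and permutation-invariant) and returns the
#' per-matched-factor congruence coefficients. Used to judge parameter
#' recovery on synthetic fixtures with known loadings.
#'
#' @param estimated,truth Numeric matrices with equal row counts.
#' @return Numeric vector, one absolute congruence per column of `truth`.
#' @export
tuckerCongruence <- function(estimated, truth) {
  cong <- abs(crossprod(
    sweep(estimated, 2L, sqrt(colSums(estimated^2)), "/"),
    sweep(truth, 2L, sqrt(colSums(truth^2)), "/")))
  k <- ncol(truth)
  out <- numeric(k)
  for (step in seq_len(k)) {
    idx <- which(cong == max(cong), arr.ind = TRUE)[1, ]
    out[idx[2]] <- cong[idx[1], idx[2]]
    cong[idx[1], ] <- -Inf
    cong[, idx[2]] <- -Inf
  }
  out
}
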