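#' @import methods
NULL

#' Default factor names for six-factor amino-acid scales
#'
#' The six property patterns commonly recovered from large residue-by-property
#' matrices: geometric characteristics, hydrogen bonding, connectivity,
#' accessible surface area, integy moments and volume/shape. Used as default
#' column names whenever a model with six factors is built; names carry no
#' computation and can be overridden everywhere they appear.
#'
#' @return Character vector of length six.
#' @export
defaultFactorNames <- function() {
  c("geometric", "h_bond", "connectivity", "asa", "integy_moment",
    "volume_shape")
}

.factorNamesFor <- function(m) {
  if (m == 6L) defaultFactorNames() else paste0("F", seq_len(m))
}

#' FactorModel: a rotated factor-analysis solution for residue properties
#'
#' Holds everything needed to score new residues on a low-dimensional scale
#' set derived from a residue-by-property matrix: standardization parameters,
#' unrotated (principal-component) loadings, oblique pattern loadings, the
#' factor correlation matrix, communalities, factor score coefficients and the
#' fraction of total variance retained.
#'
#' @slot nFactors Number of retained factors (m).
#' @slot center,scale Per-property column means and standard deviations
#'   (n - 1 denominator) of the training table.
#' @slot eigenvalues All eigenvalues of the property correlation matrix.
#' @slot unrotated p x m principal-component loadings (eigvec * sqrt(eigval)).
#' @slot pattern p x m oblique pattern loadings after Kaiser-normalized
#'   varimax followed by promax.
#' @slot phi m x m factor correlation matrix (identity for orthogonal fits).
#' @slot communalities Length-p vector, row sums of squared unrotated
#'   loadings; invariant under rotation.
#' @slot scoreCoefficients p x m weights mapping standardized properties to
#'   factor scores.
#' @slot explainedVariance Fraction of total variance carried by the retained
#'   factors: sum of retained eigenvalues divided by p.
#' @slot promaxPower Integer power used in the promax step (1 = varimax).
#' @slot scoreMethod "regression" (Thurstone) or "bartlett".
#' @export
setClass("FactorModel",
  representation(
    nFactors = "integer",
    center = "numeric",
    scale = "numeric",
    eigenvalues = "numeric",
    unrotated = "matrix",
    pattern = "matrix",
    phi = "matrix",
    communalities = "numeric",
    scoreCoefficients = "matrix",
    explainedVariance = "numeric",
    promaxPower = "integer",
    scoreMethod = "character"
  )
)

setValidity("FactorModel", function(object) {
  msg <- character()
  m <- object@nFactors
  p <- length(object@center)
  if (m < 1L) msg <- c(msg, "nFactors must be >= 1")
  if (!all(dim(object@pattern) == c(p, m)))
    msg <- c(msg, "pattern loadings must be p x m")
  if (!all(dim(object@phi) == c(m, m)))
    msg <- c(msg, "phi must be m x m")
  if (max(abs(object@phi - t(object@phi))) > 1e-8)
    msg <- c(msg, "phi must be symmetric")
  if (max(abs(diag(object@phi) - 1)) > 1e-8)
    msg <- c(msg, "phi must have unit diagonal")
  h2 <- rowSums(object@unrotated^2)
  if (max(abs(h2 - object@communalities)) > 1e-10)
    msg <- c(msg, "communalities must equal row sums of squared unrotated loadings")
  ev <- object@explainedVariance
  if (ev <= 0 || ev > 1 + 1e-12)
    msg <- c(msg, "explainedVariance must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ScaleTable: residue identifiers mapped to factor scores
#'
#' The central descriptor object: one row per residue (one-letter natural
#' codes or opaque numeric identifiers for non-natural residues), one column
#' per factor. Row order is irrelevant to all downstream computation.
#'
#' @slot scores Numeric matrix, residues x factors; rownames are residue IDs,
#'   colnames the factor names.
#' @export
setClass("ScaleTable", representation(scores = "matrix"))

setValidity("ScaleTable", function(object) {
  s <- object@scores
  msg <- character()
  if (!is.numeric(s)) msg <- c(msg, "scores must be numeric")
  if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
    msg <- c(msg, "residue IDs (rownames) must be present and unique")
  if (is.null(colnames(s)) || anyDuplicated(colnames(s)))
    msg <- c(msg, "factor names (colnames) must be present and unique")
  if (ncol(s) < 1L) msg <- c(msg, "at least one factor column required")
  if (anyNA(s)) msg <- c(msg, "scores must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a ScaleTable
#'
#' @param scores Numeric matrix or data frame of factor scores with residue
#'   IDs as rownames (or in `ids`).
#' @param ids Optional residue IDs overriding rownames.
#' @param factorNames Optional factor names overriding colnames.
#' @return A [ScaleTable-class] object.
#' @examples
#' st <- ScaleTable(matrix(rnorm(12), 2, 6, dimnames = list(c("A", "G"), NULL)))
#' factorNames(st)
#' @export
ScaleTable <- function(scores, ids = NULL, factorNames = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (!is.null(ids)) rownames(scores) <- as.character(ids)
  if (!is.null(factorNames)) colnames(scores) <- factorNames
  if (is.null(colnames(scores)))
    colnames(scores) <- .factorNamesFor(ncol(scores))
  new("ScaleTable", scores = scores)
}

#' PLSModel: a fitted NIPALS partial least squares regression
#'
#' @slot ncomp Number of latent components A.
#' @slot weights p x A X-weights W (unit norm, on autoscaled data).
#' @slot xLoadings p x A X-loadings P.
#' @slot scores n x A X-score vectors t (mutually orthogonal).
#' @slot yScores n x A Y-score vectors u.
#' @slot innerCoef Length-A inner-relation coefficients b linking u to t.
#' @slot xCenter,xScale,yCenter,yScale Autoscaling parameters.
#' @slot coefficients Regression vector on the original variable scale,
#'   first element the intercept.
#' @slot fitted Fitted values for the training samples.
#' @slot y Observed training response.
#' @slot varNames Training variable names.
#' @slot fitStats List with r2, q2, rms, press, n (q2 fields NA until a
#'   leave-one-out run is attached).
#' @export
setClass("PLSModel",
  representation(
    ncomp = "integer",
    weights = "matrix",
    xLoadings = "matrix",
    scores = "matrix",
    yScores = "matrix",
    innerCoef = "numeric",
    xCenter = "numeric",
    xScale = "numeric",
    yCenter = "numeric",
    yScale = "numeric",
    coefficients = "numeric",
    fitted = "numeric",
    y = "numeric",
    varNames = "character",
    fitStats = "list"
  )
)

setValidity("PLSModel", function(object) {
  msg <- character()
  if (object@ncomp < 1L) msg <- c(msg, "ncomp must be >= 1")
  TT <- crossprod(object@scores)
  off <- TT - diag(diag(TT), ncol(TT))
  if (max(abs(off)) > 1e-6 * max(diag(TT)))
    msg <- c(msg, "X-score vectors must be mutually orthogonal")
  if (length(msg)) msg else TRUE
})

#' LDAModel: a two-class linear discriminant on selected descriptors
#'
#' @slot selected Integer indices of the descriptor columns in the model.
#' @slot classes The two class labels; the first is the positive class.
#' @slot priors Class prior probabilities.
#' @slot coefficients Discriminant function a0 + a1 x1 + ... (raw scale);
#'   positive values classify to the positive class.
#' @slot standardized Coefficients rescaled by pooled within-class standard
#'   deviations (no intercept).
#' @slot means 2 x k class mean matrix on the selected variables.
#' @slot pooledCov Pooled within-class covariance on the selected variables.
#' @slot varNames Names of the selected descriptor columns.
#' @export
setClass("LDAModel",
  representation(
    selected = "integer",
    classes = "character",
    priors = "numeric",
    coefficients = "numeric",
    standardized = "numeric",
    means = "matrix",
    pooledCov = "matrix",
    varNames = "character"
  )
)

setValidity("LDAModel", function(object) {
  msg <- character()
  if (length(object@selected) < 1L || anyDuplicated(object@selected))
    msg <- c(msg, "selected variables must be non-empty and duplicate-free")
  if (length(object@classes) != 2L)
    msg <- c(msg, "exactly two classes required")
  if (length(msg)) msg else TRUE
})

#' GAPLSResult: outcome of genetic-algorithm variable selection
#'
#' @slot bestMask Logical vector over descriptor columns; TRUE = selected.
#' @slot bestFitness Leave-one-out Q2 of the best chromosome.
#' @slot history Data frame with one row per generation: generation, best,
#'   mean fitness. Best fitness is non-decreasing (elitism).
#' @slot finalModel PLSModel refit on the selected variables.
#' @slot config The resolved GA configuration.
#' @export
setClass("GAPLSResult",
  representation(
    bestMask = "logical",
    bestFitness = "numeric",
    history = "data.frame",
    finalModel = "PLSModel",
    config = "list"
  )
)

setValidity("GAPLSResult", function(object) {
  msg <- character()
  if (!any(object@bestMask))
    msg <- c(msg, "bestMask must select at least one variable")
  if (nrow(object@history) > 1L &&
      any(diff(object@history$best) < -1e-12))
    msg <- c(msg, "best fitness must be non-decreasing across generations")
  if (length(msg)) msg else TRUE
})
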