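#' @include AllClasses.R
NULL

#' Generate a residue-by-property table with planted factor structure
#'
#' Draws factor scores (optionally correlated via the Cholesky factor of a
#' compound-symmetric target correlation), builds sparse loadings with
#' non-zero entries of magnitude 0.9, and returns X = scores %*% t(loadings)
#' plus Gaussian noise. Ground truth is returned so recovery can be tested.
#' The default sizes (300 entities x 40 properties, 4 factors) emulate a
#' property matrix large enough for stable factor recovery while staying
#' quick to analyse.
#'
#' @param nEntities,nProperties,nFactors Table dimensions and rank.
#' @param loadingSparsity Probability that a loading is zero (each property
#'   always keeps one dominant factor).
#' @param factorCorrelation Common correlation planted between factor pairs
#'   (0 = orthogonal).
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `table` (matrix with residue rownames), `loadings`
#'   (nProperties x nFactors) and `scores` (nEntities x nFactors).
#' @export
syntheticPropertyTable <- function(nEntities = 300L, nProperties = 40L,
                                   nFactors = 4L, loadingSparsity = 0.9,
                                   factorCorrelation = 0, noiseSd = 0.05,
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  if (nEntities <= nFactors) stop("need more entities than factors")
  set.seed(seed)
  m <- as.integer(nFactors); p <- as.integer(nProperties)
  n <- as.integer(nEntities)
  Phi <- matrix(factorCorrelation, m, m); diag(Phi) <- 1
  F <- matrix(stats::rnorm(n * m), n, m) %*% chol(Phi)
  # each property loads 0.9 on one dominant factor, others sparse
  L <- matrix(0, p, m)
  dominant <- rep_len(seq_len(m), p)
  for (j in seq_len(p)) {
    L[j, dominant[j]] <- 0.9
    others <- setdiff(seq_len(m), dominant[j])
    on <- stats::runif(length(others)) > loadingSparsity
    L[j, others[on]] <- 0.9
  }
  X <- F %*% t(L) + matrix(stats::rnorm(n * p, sd = noiseSd), n, p)
  dimnames(X) <- list(paste0("R", seq_len(n)), paste0("P", seq_len(p)))
  # the model factors the correlation matrix, so the recoverable ground truth
  # is the loading matrix rescaled by each property's standard deviation
  sds <- apply(X, 2L, stats::sd)
  list(table = X, loadings = L,
       loadingsStandardized = sweep(L, 1L, sds, "/"), scores = F)
}

#' Generate a synthetic scale table
#'
#' Standard-normal factor scores for a residue alphabet of natural one-letter
#' codes plus numeric non-natural IDs; a synthetic stand-in used by the
#' examples and the pipeline tests, with no relation to any real residue.
#'
#' @param nNatural Number of natural one-letter residues (<= 20).
#' @param nNonNatural Number of numeric non-natural residue IDs.
#' @param nFactors Number of factors (default 6).
#' @param seed Integer seed.
#' @return A [ScaleTable-class].
#' @export
syntheticScaleTable <- function(nNatural = 20L, nNonNatural = 0L,
                                nFactors = 6L, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  ids <- c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")][seq_len(nNatural)],
           if (nNonNatural > 0L) as.character(100L + seq_len(nNonNatural)))
  ScaleTable(matrix(stats::rnorm(length(ids) * nFactors),
                    nrow = length(ids),
                    dimnames = list(ids, .factorNamesFor(as.integer(nFactors)))))
}

#' Generate a peptide QSAR dataset with known linear structure
#'
#' Samples random token sequences of fixed length from a scale table and sets
#' activity = encoded descriptors %*% trueCoefficients + Gaussian noise. With
#' sparse coefficients this plants a known set of informative descriptor
#' positions for selection methods to recover.
#'
#' @param scales A [ScaleTable-class] to draw residues from.
#' @param nPeptides Number of peptides.
#' @param length Peptide length L (descriptors = L x nFactors).
#' @param trueCoefficients Numeric vector of length L x nFactors (default:
#'   3 non-zero entries of +/-1 at the first, fifth and last descriptor).
#' @param noiseSd Activity noise standard deviation.
#' @param seed Integer seed.
#' @return List with `sequences`, `y`, encoded `X`, `trueCoefficients` and
#'   the data frame `dataset` (id, sequence, activity).
#' @export
syntheticQSARDataset <- function(scales, nPeptides = 50L, length = 2L,
                                 trueCoefficients = NULL, noiseSd = 0.1,
                                 seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  ids <- residueIds(scales)
  m <- base::length(factorNames(scales))
  nv <- m * length
  if (is.null(trueCoefficients)) {
    trueCoefficients <- numeric(nv)
    trueCoefficients[unique(c(1L, min(5L, nv), nv))] <- c(1, -1, 1)[
      seq_along(unique(c(1L, min(5L, nv), nv)))]
  }
  if (base::length(trueCoefficients) != nv)
    stop("trueCoefficients must have length ", nv)
  tokenMat <- matrix(sample(ids, nPeptides * length, replace = TRUE),
                     nPeptides, length)
  sequences <- apply(tokenMat, 1L, formatSequence)
  X <- encodeDataset(sequences, scales,
                     ids = paste0("S", seq_len(nPeptides)))
  y <- as.numeric(X %*% trueCoefficients) +
    stats::rnorm(nPeptides, sd = noiseSd)
  list(sequences = sequences, y = y, X = X,
       trueCoefficients = stats::setNames(trueCoefficients, colnames(X)),
       dataset = data.frame(id = rownames(X), sequence = sequences,
                            activity = y, stringsAsFactors = FALSE))
}

#' One-call QSAR fixture: synthetic scales plus a planted-signal dataset
#'
#' Convenience wrapper building a 20-residue synthetic scale table and a
#' QSAR dataset on it with the same seed; used throughout the examples and
#' tests. The default 50 peptides of length 2 give the 12-descriptor,
#' 3-informative-variable selection problem.
#'
#' @inheritParams syntheticQSARDataset
#' @param nFactors Number of factors in the synthetic scales (default 6).
#' @return As [syntheticQSARDataset()], plus `scales`.
#' @export
syntheticQSARFixture <- function(nPeptides = 50L, length = 2L, nFactors = 6L,
                                 trueCoefficients = NULL, noiseSd = 0.1,
                                 seed) {
  if (missing(seed)) stop("a seed is required")
  scales <- syntheticScaleTable(nNatural = 20L, nFactors = nFactors,
                                seed = seed)
  out <- syntheticQSARDataset(scales, nPeptides = nPeptides, length = length,
                              trueCoefficients = trueCoefficients,
                              noiseSd = noiseSd, seed = seed + 1L)
  out$scales <- scales
  out
}

#' Two-class dataset by thresholding a planted linear activity
#'
#' Generates a continuous QSAR fixture and labels samples "strong" when the
#' noiseless linear signal exceeds its median, "moderate" otherwise, giving a
#' discriminant problem whose separating variables are known.
#'
#' @inheritParams syntheticQSARFixture
#' @return The fixture list plus `labels`.
#' @export
syntheticClassificationFixture <- function(nPeptides = 40L, length = 7L,
                                           nFactors = 6L,
                                           trueCoefficients = NULL,
                                           noiseSd = 0.1, seed) {
  if (missing(seed)) stop("a seed is required")
  fix <- syntheticQSARFixture(nPeptides = nPeptides, length = length,
                              nFactors = nFactors,
                              trueCoefficients = trueCoefficients,
                              noiseSd = noiseSd, seed = seed)
  signal <- as.numeric(fix$X %*% fix$trueCoefficients)
  fix$labels <- ifelse(signal > stats::median(signal), "strong", "moderate")
  fix
}
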