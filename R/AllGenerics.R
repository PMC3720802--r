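#' @include AllClasses.R
NULL

#' Accessors for factor-analysis and QSAR model objects
#'
#' Small accessor generics so slot layout stays private: `patternLoadings`
#' and `unrotatedLoadings` return the p x m loading matrices,
#' `factorCorrelations` the factor correlation matrix, `communalities` the
#' per-property communalities, `explainedVariance` the retained-variance
#' fraction, `scoreCoefficients` the property-to-score weights,
#' `scoreMatrix` / `residueIds` / `factorNames` the content of a
#' [ScaleTable-class], and `fitStats` the fit-statistics list of a model.
#'
#' @param object A FactorModel, ScaleTable, PLSModel or GAPLSResult.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patternLoadings", function(object) standardGeneric("patternLoadings"))
#' @rdname accessors
#' @export
setGeneric("unrotatedLoadings", function(object) standardGeneric("unrotatedLoadings"))
#' @rdname accessors
#' @export
setGeneric("factorCorrelations", function(object) standardGeneric("factorCorrelations"))
#' @rdname accessors
#' @export
setGeneric("communalities", function(object) standardGeneric("communalities"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("scoreCoefficients", function(object) standardGeneric("scoreCoefficients"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("residueIds", function(object) standardGeneric("residueIds"))
#' @rdname accessors
#' @export
setGeneric("factorNames", function(object) standardGeneric("factorNames"))
#' @rdname accessors
#' @export
setGeneric("fitStats", function(object) standardGeneric("fitStats"))

#' @rdname accessors
#' @export
setMethod("patternLoadings", "FactorModel", function(object) object@pattern)
#' @rdname accessors
#' @export
setMethod("unrotatedLoadings", "FactorModel", function(object) object@unrotated)
#' @rdname accessors
#' @export
setMethod("factorCorrelations", "FactorModel", function(object) object@phi)
#' @rdname accessors
#' @export
setMethod("communalities", "FactorModel", function(object) object@communalities)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "FactorModel", function(object) object@explainedVariance)
#' @rdname accessors
#' @export
setMethod("scoreCoefficients", "FactorModel", function(object) object@scoreCoefficients)

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "ScaleTable", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("residueIds", "ScaleTable", function(object) rownames(object@scores))
#' @rdname accessors
#' @export
setMethod("factorNames", "ScaleTable", function(object) colnames(object@scores))
#' @rdname accessors
#' @export
setMethod("factorNames", "FactorModel", function(object) colnames(object@pattern))

#' @rdname accessors
#' @export
setMethod("fitStats", "PLSModel", function(object) object@fitStats)
#' @rdname accessors
#' @export
setMethod("fitStats", "GAPLSResult", function(object) object@finalModel@fitStats)

#' @describeIn ScaleTable Number of residues.
#' @param x A ScaleTable.
#' @export
setMethod("nrow", "ScaleTable", function(x) nrow(x@scores))

#' @describeIn ScaleTable Subset residues by ID or index; returns a ScaleTable.
#' @param i Residue selector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "ScaleTable", function(x, i, j, ..., drop = FALSE) {
  ScaleTable(x@scores[i, , drop = FALSE])
})

setMethod("show", "ScaleTable", function(object) {
  cat(sprintf("ScaleTable: %d residues x %d factors\n",
              nrow(object@scores), ncol(object@scores)))
  cat("factors:", paste(colnames(object@scores), collapse = ", "), "\n")
  n <- min(4L, nrow(object@scores))
  print(round(object@scores[seq_len(n), , drop = FALSE], 3))
  if (nrow(object@scores) > n) cat("...\n")
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf("FactorModel: %d properties -> %d factors (promax power %d, %s scores)\n",
              length(object@center), object@nFactors, object@promaxPower,
              object@scoreMethod))
  cat(sprintf("explained variance fraction: %.4f\n", object@explainedVariance))
})

setMethod("show", "PLSModel", function(object) {
  fs <- object@fitStats
  cat(sprintf("PLSModel: %d components, %d variables, n = %d\n",
              object@ncomp, length(object@varNames), length(object@y)))
  cat(sprintf("R2 = %.3f", fs$r2))
  if (!is.na(fs$q2)) cat(sprintf(", Q2(LOO) = %.3f, RMS = %.3f", fs$q2, fs$rms))
  cat("\n")
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d selected variable(s): %s\n",
              length(object@selected), paste(object@varNames, collapse = ", ")))
  cat(sprintf("classes: %s (positive) vs %s\n",
              object@classes[1], object@classes[2]))
})

setMethod("show", "GAPLSResult", function(object) {
  cat(sprintf("GAPLSResult: %d/%d variables selected, best Q2 = %.3f (%d generations)\n",
              sum(object@bestMask), length(object@bestMask),
              object@bestFitness, nrow(object@history)))
})
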