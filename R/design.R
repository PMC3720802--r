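#' @include encoding.R
NULL

#' A positional design rule
#'
#' Constrains which residues may occupy one template position: every
#' constraint is a (factor, comparator, threshold) triple and a residue
#' qualifies only if it satisfies all of them. Positions without a rule keep
#' the template residue.
#'
#' @param position 1-based position in the template.
#' @param ... Constraints given as `factor = c(">", 2)` pairs, e.g.
#'   `integy_moment = c(">", 2), h_bond = c("<", -0.5)`.
#' @return A design-rule list.
#' @export
designRule <- function(position, ...) {
  cons <- list(...)
  if (length(cons) == 0L) stop("a rule needs at least one constraint")
  parsed <- lapply(names(cons), function(fn) {
    v <- cons[[fn]]
    cmp <- as.character(v[1])
    if (!cmp %in% c(">", "<"))
      stop("comparator must be '>' or '<', got '", cmp, "'")
    list(factor = fn, comparator = cmp, threshold = as.numeric(v[2]))
  })
  list(position = as.integer(position), constraints = parsed)
}

#' The worked bitter-taste dipeptide design rule set
#'
#' First position: integy-moment and volume/shape scores both above 2.0.
#' Second position: geometric and integy-moment scores above 2.0 and H-bond
#' score below -0.5. Supplied as a worked example of the rule format; other
#' systems require explicit rules.
#'
#' @return List of two [designRule()]s.
#' @export
btdDesignRules <- function() {
  list(designRule(1L, integy_moment = c(">", 2), volume_shape = c(">", 2)),
       designRule(2L, geometric = c(">", 2), integy_moment = c(">", 2),
                  h_bond = c("<", -0.5)))
}

.qualifyingResidues <- function(rule, scales) {
  s <- scoreMatrix(scales)
  ok <- rep(TRUE, nrow(s))
  for (con in rule$constraints) {
    if (!con$factor %in% colnames(s))
      stop("unknown factor '", con$factor, "' in design rule")
    v <- s[, con$factor]
    ok <- ok & if (con$comparator == ">") v > con$threshold
               else v < con$threshold
  }
  rownames(s)[ok]
}

#' Enumerate candidate peptidomimetics under positional score rules
#'
#' Takes the Cartesian product over, for each constrained position, every
#' residue in the scale table satisfying that position's constraints;
#' unconstrained positions keep the template residue. Duplicate sequences
#' are removed and candidates are returned in lexicographic token order.
#'
#' @param template Sequence string or token vector.
#' @param rules List of [designRule()]s.
#' @param scales A [ScaleTable-class].
#' @return Character vector of canonical candidate sequences (possibly empty,
#'   with a warning when a position admits no residue).
#' @export
enumerateCandidates <- function(template, rules, scales) {
  tokens <- if (length(template) == 1L) parseSequence(template)
            else as.character(template)
  L <- length(tokens)
  pos <- vapply(rules, `[[`, integer(1), "position")
  if (anyDuplicated(pos)) stop("multiple rules for the same position")
  if (any(pos < 1L | pos > L))
    stop("rule position outside template length ", L)
  choices <- as.list(tokens)
  for (r in rules) {
    q <- .qualifyingResidues(r, scales)
    if (length(q) == 0L) {
      warning("no residue satisfies the rule at position ", r$position)
      return(character(0))
    }
    choices[[r$position]] <- sort(q)
  }
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE)[, L:1, drop = FALSE]
  seqs <- unique(apply(grid, 1L, formatSequence))
  sort(seqs)
}

#' Score candidates with a fitted model and rank them
#'
#' Encodes every candidate with the scale table, predicts with the supplied
#' regression ([PLSModel-class]) or discriminant ([LDAModel-class]) model,
#' and ranks by descending predicted activity (discriminant: positive-class
#' posterior), ties broken lexicographically by sequence. Ranks are dense
#' with 1 = best.
#'
#' @param candidates Character vector of candidate sequences.
#' @param model A fitted PLSModel or LDAModel.
#' @param scales A [ScaleTable-class].
#' @return Data frame: sequence, prediction, rank (and class for
#'   discriminant models), ordered best first.
#' @export
scoreAndRank <- function(candidates, model, scales) {
  if (length(candidates) == 0L)
    return(data.frame(sequence = character(0), prediction = numeric(0),
                      rank = integer(0)))
  X <- encodeDataset(candidates, scales, ids = candidates)
  if (is(model, "LDAModel")) {
    pr <- predict(model, X)
    out <- data.frame(sequence = candidates, prediction = pr$posterior,
                      class = pr$class, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(sequence = candidates,
                      prediction = predict(model, X),
                      stringsAsFactors = FALSE)
  }
  ord <- order(-out$prediction, out$sequence)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Keep candidates predicted above the best training activity
#'
#' @param ranked Data frame from [scoreAndRank()].
#' @param yTrain Observed training activities; candidates must exceed
#'   `max(yTrain)` strictly.
#' @return The qualifying subset of `ranked`.
#' @export
aboveTrainingMax <- function(ranked, yTrain) {
  ranked[ranked$prediction > max(as.numeric(yTrain)), , drop = FALSE]
}
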