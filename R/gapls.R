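#' @include pls.R
NULL

#' Genetic-algorithm configuration for variable selection
#'
#' Defaults follow the standard GA-PLS settings for this methodology:
#' population 200, at most 200 generations, generation gap 0.8 (fraction of
#' the population replaced each generation), crossover probability 0.5 and
#' per-bit mutation rate 0.005. Selection is linear-rank; crossover is
#' uniform by default with single-point available; the best chromosome is
#' always preserved (elitism). A run stops early after `stagnationLimit`
#' generations without improvement.
#'
#' @param populationSize,maxGenerations,generationGap,crossoverRate,mutationRate
#'   Core GA parameters (see above).
#' @param seed Integer seed; required so every run is reproducible.
#' @param aMax Largest PLS component count tried inside each fitness
#'   evaluation.
#' @param stagnationLimit Generations without improvement before stopping.
#' @param crossoverType "uniform" or "single".
#' @return Named list of settings.
#' @export
gaConfig <- function(populationSize = 200L, maxGenerations = 200L,
                     generationGap = 0.8, crossoverRate = 0.5,
                     mutationRate = 0.005, seed, aMax = 5L,
                     stagnationLimit = 30L,
                     crossoverType = c("uniform", "single")) {
  if (missing(seed)) stop("a seed is required for a reproducible GA run")
  stopifnot(generationGap > 0 || generationGap == 0,
            generationGap <= 1, crossoverRate >= 0, crossoverRate <= 1,
            mutationRate >= 0, mutationRate <= 1, populationSize >= 2)
  list(populationSize = as.integer(populationSize),
       maxGenerations = as.integer(maxGenerations),
       generationGap = generationGap, crossoverRate = crossoverRate,
       mutationRate = mutationRate, seed = as.integer(seed),
       aMax = as.integer(aMax), stagnationLimit = as.integer(stagnationLimit),
       crossoverType = match.arg(crossoverType))
}

#' Memoization cache for GA-PLS fitness evaluations
#'
#' Fitness depends only on the variable mask, so evaluations are memoized by
#' mask. A cache can be shared across repeated runs on the same data to avoid
#' recomputing identical subsets.
#'
#' @return An environment usable as the `cache` argument of [gaplsFitness()]
#'   and [runGAPLS()].
#' @export
makeFitnessCache <- function() new.env(parent = emptyenv())

#' GA-PLS fitness: LOO Q2 of the PLS model on a variable subset
#'
#' The PLS component count is chosen per subset by minimum LOO PRESS up to
#' `aMax`; the fitness is the corresponding Q2. An empty mask returns -Inf
#' (never selectable as best).
#'
#' @param mask Logical (or 0/1) vector over descriptor columns.
#' @inheritParams fitPLS
#' @param aMax Largest component count tried.
#' @param cache Optional environment from [makeFitnessCache()].
#' @return Leave-one-out Q2 of the masked model.
#' @export
gaplsFitness <- function(mask, X, y, aMax = 5L, cache = NULL) {
  mask <- as.logical(mask)
  if (!any(mask)) return(-Inf)
  key <- paste(as.integer(mask), collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  Xm <- as.matrix(X)[, mask, drop = FALSE]
  aTry <- min(aMax, ncol(Xm), nrow(Xm) - 2L)
  pred <- .looPredictions(Xm, as.numeric(y), aTry)
  press <- colSums((as.numeric(y) - pred)^2)
  q2 <- 1 - min(press) / sum((y - mean(y))^2)
  if (!is.null(cache)) cache[[key]] <- q2
  q2
}

.repairEmpty <- function(pop) {
  empty <- which(rowSums(pop) == 0L)
  for (i in empty) pop[i, sample.int(ncol(pop), 1L)] <- 1L
  pop
}

# linear-rank selection probabilities: worst gets weight 1, best weight N
.rankSelect <- function(fitness, k) {
  r <- rank(fitness, ties.method = "first")
  sample.int(length(fitness), k, replace = TRUE, prob = r)
}

#' Run genetic-algorithm variable selection for a PLS model
#'
#' Chromosomes are binary masks over descriptor columns, initialized
#' Bernoulli(0.5). Each generation, `generationGap` of the population is
#' replaced by offspring of rank-selected parents (uniform crossover with
#' probability `crossoverRate`, per-bit mutation at `mutationRate`); the
#' worst individuals are replaced so the best chromosome always survives.
#' The run is a pure function of the data and the seed.
#'
#' @inheritParams fitPLS
#' @param config A [gaConfig()] list.
#' @param cache Optional shared fitness cache from [makeFitnessCache()].
#' @return A [GAPLSResult-class]: best mask, its Q2, the per-generation
#'   history, and the PLS model refit on the selected variables (with LOO
#'   statistics attached).
#' @examples
#' fix <- syntheticQSARFixture(nPeptides = 30, length = 2, seed = 1)
#' res <- runGAPLS(fix$X, fix$y, gaConfig(populationSize = 20,
#'   maxGenerations = 10, seed = 1, aMax = 2))
#' sum(res@bestMask)
#' @export
runGAPLS <- function(X, y, config, cache = NULL) {
  d <- .checkXy(X, y)
  X <- d$X; y <- d$y
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 variables to select from")
  if (is.null(cache)) cache <- makeFitnessCache()
  set.seed(config$seed)
  N <- config$populationSize
  pop <- matrix(as.integer(stats::runif(N * p) < 0.5), N, p)
  pop <- .repairEmpty(pop)
  evalPop <- function(rows)
    vapply(seq_len(nrow(rows)), function(i)
      gaplsFitness(rows[i, ], X, y, aMax = config$aMax, cache = cache),
      numeric(1))
  fit <- evalPop(pop)
  history <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0))
  bestFit <- max(fit)
  stagnant <- 0L
  nRepl <- min(round(config$generationGap * N), N - 1L)  # elitism: best survives
  for (gen in seq_len(config$maxGenerations)) {
    if (nRepl > 0L) {
      parents <- .rankSelect(fit, 2L * nRepl)
      kids <- matrix(0L, nRepl, p)
      for (k in seq_len(nRepl)) {
        p1 <- pop[parents[2L * k - 1L], ]
        p2 <- pop[parents[2L * k], ]
        child <- p1
        if (stats::runif(1) < config$crossoverRate) {
          if (config$crossoverType == "uniform") {
            take2 <- stats::runif(p) < 0.5
            child[take2] <- p2[take2]
          } else {
            cut <- sample.int(p - 1L, 1L)
            child[(cut + 1L):p] <- p2[(cut + 1L):p]
          }
        }
        mut <- stats::runif(p) < config$mutationRate
        child[mut] <- 1L - child[mut]
        kids[k, ] <- child
      }
      kids <- .repairEmpty(kids)
      kidFit <- evalPop(kids)
      worst <- order(fit)[seq_len(nRepl)]   # replace worst: elitism for free
      pop[worst, ] <- kids
      fit[worst] <- kidFit
    }
    newBest <- max(fit)
    if (newBest > bestFit + 1e-12) {
      bestFit <- newBest; stagnant <- 0L
    } else stagnant <- stagnant + 1L
    history <- rbind(history,
                     data.frame(generation = gen, best = bestFit,
                                mean = mean(fit[is.finite(fit)])))
    if (stagnant >= config$stagnationLimit) break
  }
  bestIdx <- which.max(fit)
  bestMask <- as.logical(pop[bestIdx, ])
  Xm <- X[, bestMask, drop = FALSE]
  aStar <- selectComponents(Xm, y, config$aMax)
  final <- fitPLS(Xm, y, aStar)
  cv <- looQ2(Xm, y, aStar)
  final@fitStats$q2 <- cv$q2
  final@fitStats$press <- cv$press
  new("GAPLSResult", bestMask = stats::setNames(bestMask, colnames(X)),
      bestFitness = fit[bestIdx],
      history = history, finalModel = final, config = config)
}
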