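# pepQSAR

Scale-based QSAR modelling for peptides and peptidomimetics built from
natural **and non-natural** amino acids.

Peptide QSAR needs numeric descriptors per residue. For the 20 coded amino
acids many descriptor scales exist, but peptidomimetic design draws on
hundreds of non-natural residues for which no curated scales are available.
The workflow this package implements derives such scales itself: start from
a large residue-by-property matrix (hundreds of computed physicochemical
properties per residue), compress it by factor analysis into a handful of
interpretable property patterns, score every residue on those factors, and
use the positional factor scores as QSAR descriptors for any peptide built
from those residues — natural or not. Models fitted on the descriptors then
drive rule-based enumeration of candidate peptidomimetics.

It is aimed at cheminformatics / peptide-engineering groups who have (or can
compute) a property table for their residue alphabet and want a reproducible
scale-derivation + modelling + design pipeline in R.

## The method

**Scales.** For a standardized residue-by-property matrix with correlation
matrix *R*, the principal-component method retains the top *m* eigenvectors
scaled to loadings, `L = V diag(sqrt(lambda))`. The loadings are rotated by
Kaiser-normalized varimax followed by an oblique promax step (default power
4), giving pattern loadings *P* and a factor correlation matrix *Phi*.
Communalities are the row sums of squared unrotated loadings (rotation
invariant); the retained-variance fraction is `sum(lambda_1..m) / p`.
Factor scores use the regression (Thurstone) estimator
`W = R^-1 P Phi`, applied to each residue's standardized property profile.
With six factors the columns default to the canonical pattern names
*geometric, h_bond, connectivity, asa, integy_moment, volume_shape*.

**Encoding.** A peptide of length *L* becomes the position-major
concatenation of its residues' *m* factor scores (`pos1.f1 ... posL.fm`,
*m·L* descriptors). Sequences mix one-letter codes and numeric non-natural
IDs: `TLTRV108W` or hyphen-separated `512-439`.

**Models.**

* NIPALS PLS1 on autoscaled blocks, with leave-one-out
  `Q2 = 1 - PRESS / sum((y - mean(y))^2)` (autoscaling refit inside every
  fold) and component count chosen by minimum LOO PRESS.
* Genetic-algorithm variable selection (population 200, 200 generations,
  generation gap 0.8, crossover 0.5, mutation 0.005, rank selection,
  elitism) with LOO Q2 as fitness.
* Stepwise two-class linear discriminant analysis using partial-F tests on
  Wilks' lambda (enter at F > 3.84, remove at F < 2.71), with LOO confusion
  statistics (accuracy, sensitivity, specificity, MCC).

**Validation & design.** Y-randomization (intercepts of the R2/Q2 versus
permutation-correlation lines, pass limits 0.300 / 0.050), k-means odd/even
train-test splitting, external-set Q2, and Cartesian enumeration of
candidate sequences under per-position factor-score threshold rules, ranked
by predicted activity.

## Worked example

Everything below is generated: no external data are needed.

```r
library(pepQSAR)

## 1. derive scales from a property matrix with planted factor structure
fix <- syntheticPropertyTable(seed = 42)        # 300 residues x 40 properties
fm  <- fitFactorModel(fix$table, nFactors = 4)
fm
#> FactorModel: 40 properties -> 4 factors (promax power 4, regression scores)
#> explained variance fraction: 0.9977
scales <- factorScores(fm, fix$table)

## 2. encode dipeptides and fit PLS / GA-PLS QSAR models
qsar <- syntheticQSARFixture(seed = 10)         # 50 dipeptides, 12 descriptors
cv <- looQ2(qsar$X, qsar$y, 2)
#> PLS (A=2): R2 = 0.964, Q2 = 0.930, RMS = 0.351
ga <- runGAPLS(qsar$X, qsar$y,
               gaConfig(populationSize = 60, maxGenerations = 60,
                        seed = 1, aMax = 3, stagnationLimit = 15))
ga
#> GAPLSResult: 5/12 variables selected, best Q2 = 0.995 (21 generations)

## 3. guard against chance correlation
yr <- yRandomization(qsar$X, qsar$y,
                     plsModeler(ga@finalModel@ncomp, ga@bestMask),
                     nPerm = 50, seed = 2)
#> Y-randomization intercepts: R2 0.024, Q2 -0.262 (limits 0.300 / 0.050)

## 4. enumerate and rank peptidomimetic candidates
rules <- list(designRule(1, geometric = c(">", 0.5),
                         integy_moment = c("<", 0)),
              designRule(2, volume_shape = c(">", 0.5)))
cand <- enumerateCandidates("WW", rules, qsar$scales)
rk   <- scoreAndRank(cand, ga@finalModel, qsar$scales)
head(rk, 3)
#>   sequence prediction rank
#> 1       MW   2.753179    1
#> 2       ML   2.626752    2
#> 3       MN   2.625907    3
nrow(aboveTrainingMax(rk, qsar$y))
#> 7        # of 22 candidates beat the best training activity (2.40)
```

The R2/Q2 values say how much activity variance the model explains in
calibration and under leave-one-out prediction; the Y-randomization
intercepts sitting far below 0.300 / 0.050 say the fit is not a chance
correlation; the design table ranks enumerated sequences by predicted
activity so the top rows are the synthesis candidates.

A thin command-line interface (`exec/pepqsar`) wraps the same functions:
`pepqsar synth-scales`, `fit-pls`, `fit-gapls`, `fit-lda`, `validate`,
`split`, `design`; run `pepqsar --help` for flags.

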