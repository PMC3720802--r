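---
title: "Deriving amino-acid scales and QSAR models for peptidomimetic design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving amino-acid scales and QSAR models for peptidomimetic design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery behind pepQSAR, the choices
made where the methodology leaves room, and what the synthetic fixtures do
and do not establish.

## 1. The factor model behind the scales

The starting object is a residue-by-property matrix: one row per amino acid
(natural one-letter codes or opaque numeric IDs for non-natural residues),
one column per computed physicochemical property. Properties of this kind
are strongly inter-correlated, so the matrix is compressed into a handful of
interpretable factors and each residue is scored on those factors once; the
scores then serve as transferable descriptors for any peptide over that
residue alphabet.

`fitFactorModel()` proceeds in three steps:

1. **Extraction** is the principal-component method. Every property is
   standardized (mean 0, unit variance with the $n-1$ denominator), the
   eigendecomposition of the property correlation matrix $R$ is taken, and
   the top $m$ components are rescaled to loadings
   $L = V_m\,\mathrm{diag}(\sqrt{\lambda_{1..m}})$. Communalities are the
   row sums of $L^2$ and are invariant under any subsequent rotation — the
   package enforces this to $10^{-10}$ in the class validity check. The
   retained-variance fraction is $\sum_{j\le m}\lambda_j / p$.
2. **Rotation** is varimax with Kaiser row-normalization followed by an
   oblique promax step. Promax powers the varimax loadings element-wise and
   Procrustes-fits the original loadings to that target, yielding pattern
   loadings $P$ and a factor correlation matrix
   $\Phi = (U^\top U)^{-1}$. With power 1 the target is the varimax
   solution itself, so the rotation collapses to varimax and $\Phi = I$;
   the test suite asserts this identity.
3. **Scoring** uses the regression (Thurstone) estimator
   $W = R^{-1} S$ with $S = P\Phi$ the structure matrix; residue scores are
   the standardized property profile times $W$. A Bartlett
   weighted-least-squares estimator is available via
   `scoreMethod = "bartlett"`; it is undefined for a complete decomposition
   (all uniquenesses zero), which is why regression scoring is the default.

Two indeterminacies are resolved deterministically so repeated runs agree
bit-for-bit: factors keep the descending-eigenvalue order of the
extraction, and each factor (unrotated and rotated alike) is flipped so its
largest-magnitude loading is positive. $\Phi$ and $W$ are flipped
consistently.

**Number of factors.** There is no automatic selection.
`propertyEigenvalues()` reports the spectrum so the user can apply scree or
eigenvalue-greater-than-one reasoning; six factors is the convention for
amino-acid property panels and supplies the default factor names
(`geometric`, `h_bond`, `connectivity`, `asa`, `integy_moment`,
`volume_shape`). The names carry no computation and can be overridden.

**Promax power.** The methodology literature rarely states the power; 4 is
the long-standing default of the major statistical packages and is exposed
as `promaxPower`. Power 1 gives an orthogonal analysis.

**Pattern versus structure.** Oblique pattern coefficients can exceed 1;
the model stores the pattern matrix and $\Phi$, from which the structure
matrix is $P\Phi$ — both interpretations are recoverable.

## 2. Positional encoding

A peptide of length $L$ maps to the concatenation of its residues' $m$
factor scores, position-major: `pos1.f1 ... posL.fm`. Two sequence dialects
are accepted — compact (`TLTRV108W`, maximal digit runs are one numeric
token) and hyphen-separated (`512-439`) — and the canonical form is
hyphen-separated whenever a numeric token is present. Encoding is a pure
lookup: permuting scale-table rows never changes an encoding, and all
peptides in one descriptor matrix must share a length.

## 3. PLS with leave-one-out validation

`fitPLS()` is NIPALS PLS1. Both blocks are autoscaled; each component
extracts a unit-norm weight vector $w \propto E^\top f$, scores $t = Ew$,
and deflates $E$ and $f$; the inner relation links the blocks through
$u \approx b\,t$. The regression vector is accumulated as
$W(P^\top W)^{-1}c$ and reported on the original variable scale. Successive
score vectors are orthogonal (enforced in the validity check), and at full
rank the fit coincides with ordinary least squares — the suite checks both,
plus per-component agreement with an independent PLS implementation
(`mixOmics::pls`) to $10^{-6}$.

Cross-validation is leave-one-out with **no leakage**: the autoscaling and
the whole NIPALS decomposition are refit on every fold.
$Q^2 = 1 - \mathrm{PRESS}/\sum_i (y_i - \bar y)^2$ with $\bar y$ the
full-sample mean. RMS is reported as $\sqrt{SS/n}$, with the $SS$ taken
from calibration residuals alongside $R^2$ and from cross-validated
residuals alongside $Q^2$, matching the statistic each accompanies.
`selectComponents()` minimizes LOO PRESS over $1..A_{max}$, ties toward the
smaller model; one LOO pass yields the predictions for every component
count simultaneously. Zero-variance columns inside a fold are dropped for
that fold with a warning.

A practical note on minimum-PRESS selection: when irrelevant autoscaled
columns accompany a single informative one, their chance correlations
contaminate the first weight vector, and later components genuinely reduce
LOO error by undoing that contamination. Minimum PRESS therefore often
selects more components than the rank of the underlying signal; on
noise-free data of known rank it selects exactly that rank.

## 4. Genetic-algorithm variable selection

`runGAPLS()` searches binary masks over descriptor columns; the fitness of
a mask is the LOO $Q^2$ of the PLS model on the masked columns, with the
component count chosen per subset up to `aMax`. The canonical GA settings
are the defaults: population 200, at most 200 generations, generation gap
0.8, crossover probability 0.5, per-bit mutation 0.005. The methodology
leaves the operators unstated, so the package documents its choices:
generation gap is read as the fraction of the population replaced each
generation (its standard GA meaning); selection is linear-rank (robust to
fitness scale); crossover is uniform (single-point available); replacement
targets the worst individuals, which preserves the best chromosome —
elitism — and makes the best-fitness trace non-decreasing; an
all-zero chromosome is repaired by switching one random bit on; runs stop
after 30 stagnant generations (configurable). Every run is a pure function
of the data and the seed, and fitness values are memoized by mask
(`makeFitnessCache()` shares the memo across repeated runs on the same
data).

## 5. Stepwise linear discriminant analysis

For two classes, variables enter and leave by partial-$F$ tests on Wilks'
$\Lambda = \det(W)/\det(T)$: moving between a $q$- and a $(q{+}1)$-variable
model, $F = (n - g - q)\,(\Lambda_q/\Lambda_{q+1} - 1)$ with $g = 2$.
The conventional thresholds — enter at $F > 3.84$, remove at $F < 2.71$ —
are defaults, not constants. Ties resolve to the lower column index. The
discriminant itself is Fisher's: $a = S_p^{-1}(\mu_+ - \mu_-)$ with pooled
within-class covariance, intercept midway between projected class means
plus the log prior ratio. Priors are equal by default (proportional via
config); the "strong" class is the positive class for sensitivity. The
equal-covariance Gaussian posterior for the positive class is
$\mathrm{plogis}(Y)$, and "strong predicted binding" means posterior
$> 0.5$.

Leave-one-out classification defaults to selecting variables **once on the
full data** and refitting only the discriminant per fold. Re-selection on
each $n-1$ subset ("strict" mode, also provided) produces unstable variable
sets at the dataset sizes this method targets (tens of peptides) and cannot
yield a single reportable model; the default mirrors how such models are
reported. Matthews correlation uses the 0/0 → 0 convention.

## 6. Validation procedures

**Y-randomization** refits a frozen model family (fixed variable subset and
component count — `plsModeler()`) on permuted activities, then regresses
$R^2$ and $Q^2$ on the absolute correlation between permuted and original
response. The abscissa is not standardized anywhere in the methodology
literature; the package uses $|r(y_{perm}, y)|$ with the unpermuted model
included at $r = 1$ (excludable via flag), which is the construction the
conventional intercept limits $R^2 < 0.300$, $Q^2 < 0.050$ refer to.
Failed refits are excluded with a warning.

**k-means odd/even splitting** clusters samples in autoscaled descriptor
space ($k = 2$, 10 seeded restarts, best inertia), sorts each cluster by
ascending activity with ties broken by sample ID, and alternates ranks into
train (odd) and test (even) — a rational division that balances both
clusters and the activity range across the two sets.

**External validation** reports
$Q^2_{ext} = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y_{train})^2$ against
the training mean — the stricter of the two conventions in use, chosen
because the test set must be predicted from training-set information only.

## 7. Design enumeration

A design rule constrains one template position with factor-score
thresholds; `enumerateCandidates()` takes the Cartesian product of the
qualifying residue sets over constrained positions, keeping template
residues elsewhere, removes duplicates and orders candidates
lexicographically. The enumeration count equals the product of per-position
qualifying counts. Candidates are ranked by predicted activity (or
positive-class posterior) with lexicographic tie-breaks; the
`aboveTrainingMax()` filter compares against **observed** training
activities (comparison against fitted values is available), the stricter
reading of "better than the training set". The bitter-taste rule set ships
as `btdDesignRules()` as a worked example of the format; no silent default
rules exist for other systems.

## 8. The synthetic fixtures: what they show and what they cannot

`syntheticPropertyTable()` builds $X = F\,L^\top + \varepsilon$: factor
scores optionally correlated through the Cholesky factor of a
compound-symmetric $\Phi$, sparse loadings with non-zero magnitude 0.9
(each property keeps one dominant factor; cross-loadings appear with
probability `1 - loadingSparsity`, default 0.1, keeping near-simple
structure — the regime factor rotation is designed for), Gaussian noise
(default sd 0.05). Because the model factors the *correlation* matrix, the
recoverable ground truth is the loading matrix rescaled by each property's
standard deviation; the generator returns it as `loadingsStandardized`, and
recovery is judged by Tucker congruence under greedy sign/permutation
matching. The default 300 × 40, 4-factor table recovers congruence
> 0.95 and score correlations > 0.9.

`syntheticQSARDataset()` draws random sequences over a synthetic scale
table and sets activity to a known linear form of the encoded descriptors
plus Gaussian noise (default sd 0.1, three informative descriptors of
effect ±1). The default 50 dipeptides over 6-factor scales give the
12-descriptor selection problem; thresholding the noiseless signal at its
median yields the two-class fixture for the discriminant pipeline
(40 heptapeptides, 42 descriptors).

These fixtures validate *recovery*: that the estimators find structure that
is truly there, under Gaussian noise and a linear activity model. They do
not emulate real residue chemistry — property distributions are Gaussian,
descriptors are independent across positions, activities are exactly
linear, and class labels derive from a sharp threshold. Passing tests
therefore demonstrate correctness of the machinery, not predictive validity
on any laboratory dataset. The published benchmark statistics (the
dipeptide taste and enzyme-inhibition tables and the mica-binding panel)
were distributed only as word-processor supplements; the reproduction test
in `test-acceptance.R` states the file layout it expects
(`inst/extdata/nnaa_scales.csv` etc.) and fails — deliberately, rather
than skipping — until converted CSVs are supplied. Likewise the full-scale
six-factor solution over 615 residues × 155 properties (≈ 83 % variance
retained) cannot be rebuilt without the unpublished raw property matrix;
its checkable content — the variance-accounting identity, communality
bounds, $\Phi$ symmetry — is asserted on synthetic tables instead.

## 9. Problem sizes and numerical settings

The test suite and `scripts/acceptance.R` run the study conditions at
these sizes, chosen to make every stochastic claim testable in about a
minute apiece: factor recovery at 300 × 40 with 4 factors; GA-PLS recovery
on the 50 × 12 fixture over 20 seeded runs with population 60, at most 60
generations, stagnation limit 15 and a shared fitness cache (the mask space
has only 4095 elements, so the cache converts repeated runs into lookups);
LDA at 40 × 42. NIPALS uses tolerance $10^{-12}$ with a 500-iteration
ceiling (univariate responses converge in one pass); stepwise LDA guards
singular scatter matrices by refusing non-positive determinant ratios;
k-means uses 10 restarts.

## 10. Known limitations

* PLS1 only — one response at a time; no kernel or multi-block variants.
* Two-class LDA only; no quadratic discriminant.
* Min-PRESS component selection can overselect in noisy, many-descriptor
  settings (see §3); inspect the PRESS path when in doubt.
* The GA is single-objective and serial; its defaults (200 × 200) are
  sized for dozens of descriptors, not thousands.
* Scales derived from a property table standardize by that table's means
  and variances; scoring residues far outside the training property range
  extrapolates.
* Residue IDs are opaque: the package knows nothing of the underlying
  chemistry, stereochemistry, or synthesizability of enumerated candidates.
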