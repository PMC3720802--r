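test_that("standardization centers and scales with the n-1 denominator", {
  out <- standardizeProperties(cbind(a = c(1, 2, 3), b = c(2, 4, 6, 8)[1:3]))
  expect_equal(unname(out$values[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(out$values), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(out$values, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)

  # hand oracle on [2,4,6,8]: mean 5, sd sqrt(20/3)
  z <- standardizeProperties(cbind(x = c(2, 4, 6, 8), y = 1:4))
  expect_equal(unname(z$values[, "x"]),
               (c(2, 4, 6, 8) - 5) / sqrt(20 / 3), tolerance = 1e-12)

  # idempotence
  again <- standardizeProperties(z$values)
  expect_equal(again$values, z$values, tolerance = 1e-12)

  expect_error(standardizeProperties(cbind(ok = 1:3, flat = c(2, 2, 2))),
               "flat")
})

test_that("factor extraction recovers planted structure on synthetic tables", {
  fix <- syntheticPropertyTable(seed = 42L)   # 300 x 40, 4 factors
  fm <- fitFactorModel(fix$table, nFactors = 4)
  cong <- tuckerCongruence(patternLoadings(fm), fix$loadingsStandardized)
  expect_true(all(cong > 0.95))

  st <- factorScores(fm, fix$table)
  scoreCong <- tuckerCongruence(scale(scoreMatrix(st), scale = FALSE),
                                scale(fix$scores, scale = FALSE))
  expect_true(all(scoreCong > 0.9))
})

test_that("communalities are rotation-invariant and complete at full rank", {
  fix <- smallPropertyFixture()
  fm <- fitFactorModel(fix$table, nFactors = 3)
  expect_lt(max(abs(rowSums(unrotatedLoadings(fm)^2) - communalities(fm))),
            1e-10)

  # full decomposition: m = p
  full <- fitFactorModel(fix$table, nFactors = ncol(fix$table))
  expect_equal(unname(communalities(full)), rep(1, ncol(fix$table)),
               tolerance = 1e-8)
  expect_equal(explainedVariance(full), 1, tolerance = 1e-12)
})

test_that("loading reconstruction of the correlation matrix improves with m", {
  fix <- smallPropertyFixture()
  R <- cor(standardizeProperties(fix$table)$values)
  errs <- vapply(1:5, function(m) {
    L <- unrotatedLoadings(fitFactorModel(fix$table, nFactors = m))
    max(abs(R - tcrossprod(L)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("promax with power 1 reduces to the varimax solution", {
  fix <- smallPropertyFixture()
  fm <- fitFactorModel(fix$table, nFactors = 3, promaxPower = 1)
  expect_equal(factorCorrelations(fm), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("oblique rotation recovers a planted factor correlation", {
  fix <- syntheticPropertyTable(nEntities = 300L, nProperties = 20L,
                                nFactors = 2L, factorCorrelation = 0.4,
                                seed = 5L)
  fm <- fitFactorModel(fix$table, nFactors = 2)
  expect_lt(abs(factorCorrelations(fm)[1, 2] - 0.4), 0.1)
  phi <- factorCorrelations(fm)
  expect_equal(phi, t(phi))
  expect_equal(unname(diag(phi)), c(1, 1), tolerance = 1e-12)
})

test_that("regression factor scores behave like regression scores", {
  fix <- smallPropertyFixture()
  fm <- fitFactorModel(fix$table, nFactors = 3)
  st <- factorScores(fm, fix$table)
  expect_lt(max(abs(colMeans(scoreMatrix(st)))), 1e-8)

  # residue sitting at the column means scores zero on every factor
  meanRow <- matrix(fm@center, nrow = 1,
                    dimnames = list("mu", names(fm@center)))
  # .asPropertyTable requires >= 2 rows, so pair it with a real residue
  two <- rbind(meanRow, fix$table[1, , drop = FALSE])
  expect_equal(unname(scoreMatrix(factorScores(fm, two))[1, ]),
               rep(0, 3), tolerance = 1e-10)

  # column matching is by name, order-insensitive; mismatches are errors
  shuffled <- fix$table[, rev(colnames(fix$table))]
  expect_equal(scoreMatrix(factorScores(fm, shuffled)), scoreMatrix(st))
  expect_error(factorScores(fm, fix$table[, -1]), "missing")
})

test_that("factor model guards its preconditions", {
  fix <- smallPropertyFixture()
  expect_error(fitFactorModel(fix$table, nFactors = 50), "exceeds")
  expect_error(fitFactorModel(fix$table[1:2, ], nFactors = 3), "exceeds")
  ev <- propertyEigenvalues(fix$table)
  expect_equal(sum(ev), ncol(fix$table), tolerance = 1e-8)
  expect_true(all(diff(ev) <= 1e-10))
})

test_that("factor model serializes losslessly to JSON", {
  fix <- smallPropertyFixture()
  fm <- fitFactorModel(fix$table, nFactors = 3)
  path <- withr::local_tempfile(fileext = ".json")
  writeFactorModel(fm, path)
  fm2 <- readFactorModel(path)
  expect_equal(patternLoadings(fm), patternLoadings(fm2))
  expect_equal(factorCorrelations(fm), factorCorrelations(fm2))
  expect_equal(scoreCoefficients(fm), scoreCoefficients(fm2))
  expect_equal(explainedVariance(fm), explainedVariance(fm2))
})
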