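test_that("Y-randomization is reproducible and structured as documented", {
  fix <- syntheticQSARFixture(nPeptides = 30L, seed = 6L)
  r1 <- yRandomization(fix$X, fix$y, plsModeler(2), nPerm = 12L, seed = 3L)
  r2 <- yRandomization(fix$X, fix$y, plsModeler(2), nPerm = 12L, seed = 3L)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records), 13L)        # permutations + unpermuted
  expect_equal(r1$records$r[1], 1)
  expect_error(yRandomization(fix$X, fix$y, plsModeler(2), nPerm = 5L,
                              seed = 1L), "nPerm")
  expect_error(yRandomization(fix$X, fix$y, plsModeler(2), nPerm = 12L),
               "seed")
})

test_that("a modeler that ignores y produces zero-slope lines", {
  fix <- syntheticQSARFixture(nPeptides = 20L, seed = 8L)
  constant <- function(X, y) list(r2 = 0.4, q2 = 0.2)
  rep <- yRandomization(fix$X, fix$y, constant, nPerm = 10L, seed = 2L)
  expect_equal(rep$slopeR2, 0, tolerance = 1e-10)
  expect_equal(rep$slopeQ2, 0, tolerance = 1e-10)
  expect_equal(rep$interceptR2, 0.4, tolerance = 1e-10)
})

test_that("a predictive model passes the intercept limits; scrambled data do not", {
  fix <- syntheticQSARFixture(seed = 12L)
  mask <- fix$trueCoefficients != 0
  rep <- yRandomization(fix$X, fix$y, plsModeler(2, mask = mask),
                        nPerm = 15L, seed = 5L)
  expect_true(rep$pass[["r2"]] && rep$pass[["q2"]])
  expect_lt(rep$interceptR2, 0.300)
  expect_lt(rep$interceptQ2, 0.050)

  # with no real relationship both intercepts sit near the permuted cloud
  set.seed(13)
  yNull <- rnorm(nrow(fix$X))
  repNull <- yRandomization(fix$X, yNull, plsModeler(2, mask = mask),
                            nPerm = 15L, seed = 5L)
  expect_lt(repNull$interceptR2, 0.300)
  # and the unpermuted model itself shows no predictivity to validate
  expect_lt(repNull$records$q2[1], 0.3)
})

test_that("the k-means odd/even split partitions and is reproducible", {
  fix <- syntheticQSARFixture(nPeptides = 48L, seed = 14L)
  sp <- kmeansOddEvenSplit(fix$X, fix$y, seed = 2L)
  expect_equal(sort(c(sp$train, sp$test)), seq_len(48L))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_equal(length(sp$train), 24L)        # 48 samples -> 24/24
  sp2 <- kmeansOddEvenSplit(fix$X, fix$y, seed = 2L)
  expect_identical(sp, sp2)
})

test_that("two obvious clusters of two each contribute one train, one test", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.1))
  rownames(X) <- paste0("s", 1:4)
  y <- c(1, 2, 3, 4)
  sp <- kmeansOddEvenSplit(X, y, seed = 1L)
  for (cl in 1:2) {
    idx <- which(sp$clusters == cl)
    expect_equal(sum(idx %in% sp$train), 1L)
    expect_equal(sum(idx %in% sp$test), 1L)
  }
  # within a cluster the lower activity gets rank 1 (train)
  low <- which.min(y[1:2])
  expect_true(low %in% sp$train)
})

test_that("tied activities are ordered by sample ID", {
  X <- matrix(rnorm(12, sd = 0.01), 6, 2,
              dimnames = list(c("b", "a", "d", "c", "f", "e"), NULL))
  y <- rep(1, 6)
  sp1 <- kmeansOddEvenSplit(X, y, seed = 3L, centers = 1L)
  # all activities tie, so rank order is ID order: a,b,c,d,e,f
  ord <- order(sp1$ranks)
  expect_equal(sp1$ids[ord], sort(rownames(X)))
})

test_that("external validation uses the training mean and its edge cases", {
  fix <- syntheticQSARFixture(nPeptides = 30L, seed = 16L)
  m <- fitPLS(fix$X, fix$y, 2)
  # test set identical to training: Q2ext equals calibration R2
  ext <- externalValidate(m, fix$X, fix$y)
  expect_equal(ext$q2ext, fitStats(m)$r2, tolerance = 1e-10)

  # split fit: statistics are finite and bounded by 1
  sp <- kmeansOddEvenSplit(fix$X, fix$y, seed = 4L)
  mt <- fitPLS(fix$X[sp$train, ], fix$y[sp$train], 2)
  ev <- externalValidate(mt, fix$X[sp$test, ], fix$y[sp$test])
  expect_lte(ev$q2ext, 1)
  expect_equal(ev$rms, sqrt(ev$press / ev$n))
})
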