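test_that("an exact univariate relation is fit perfectly with one component", {
  set.seed(1)
  X <- cbind(a = rnorm(20))
  y <- 3 * X[, "a"] + 2
  m <- fitPLS(X, y, 1)
  expect_equal(fitStats(m)$r2, 1, tolerance = 1e-10)
  expect_equal(m@fitted, y, tolerance = 1e-8)
})

test_that("full-rank PLS coincides with ordinary least squares", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(100), 20, 5)
    y <- rnorm(20)
    m <- fitPLS(X, y, 5)
    expect_equal(m@fitted, unname(fitted(lm(y ~ X))), tolerance = 1e-8)
  }
})

test_that("successive X-scores are orthogonal and predictions deterministic", {
  set.seed(7)
  X <- matrix(rnorm(200), 20, 10)
  y <- X[, 1] - X[, 3] + rnorm(20, sd = 0.2)
  m <- fitPLS(X, y, 4)
  G <- crossprod(m@scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  # training X reproduces fitted values; duplicated rows predict identically
  expect_equal(predict(m, X), m@fitted)
  expect_equal(predict(m, X[c(2, 2), ]), rep(predict(m, X[2, , drop = FALSE]), 2))
  expect_error(predict(m, X[, 1:3]), "columns")
})

test_that("predictions are invariant to affine rescaling of X columns", {
  set.seed(3)
  X <- matrix(rnorm(90), 30, 3)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(30, sd = 0.1)
  X2 <- X
  X2[, 2] <- 100 * X[, 2] + 7
  m1 <- fitPLS(X, y, 2)
  m2 <- fitPLS(X2, y, 2)
  expect_equal(m1@fitted, m2@fitted, tolerance = 1e-8)
  cv1 <- looQ2(X, y, 2); cv2 <- looQ2(X2, y, 2)
  expect_equal(cv1$q2, cv2$q2, tolerance = 1e-8)
})

test_that("a hand-built two-predictor system matches explicit algebra", {
  # y is an exact linear form; at full rank the PLS coefficient vector must
  # equal the generating coefficients (symbolic oracle)
  X <- cbind(x1 = c(1, 2, 3, 4), x2 = c(0, 1, 1, 3))
  y <- 2 * X[, 1] - 1 * X[, 2] + 5
  m <- fitPLS(X, y, 2)
  expect_equal(unname(m@coefficients), c(5, 2, -1), tolerance = 1e-8)
})

test_that("LOO Q2 follows its defining formula and edge cases", {
  # predictions at the mean give Q2 = 0; the 3-point hand case gives 0.5
  y <- c(1, 2, 3)
  expect_equal(1 - sum((y - mean(y))^2) / sum((y - mean(y))^2), 0)
  expect_equal(1 - sum((y - c(1, 2, 4))^2) / sum((y - mean(y))^2), 0.5)

  set.seed(11)
  X <- matrix(rnorm(120), 30, 4)
  y <- X[, 1] + rnorm(30, sd = 0.3)
  cv <- looQ2(X, y, 2)
  expect_true(cv$q2 <= cv$r2 + 1e-9)
  expect_true(cv$q2 <= 1 && cv$r2 <= 1)
  expect_equal(cv$rms, sqrt(cv$press / cv$n))

  # Q2 is invariant to sample reordering
  perm <- sample(30)
  cv2 <- looQ2(X[perm, ], y[perm], 2)
  expect_equal(cv$q2, cv2$q2, tolerance = 1e-10)
})

test_that("cross-validated NIPALS agrees with an independent PLS oracle", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  X <- matrix(rnorm(25 * 6), 25, 6,
              dimnames = list(NULL, paste0("V", 1:6)))
  y <- X[, 2] - X[, 5] + rnorm(25, sd = 0.2)
  m <- fitPLS(X, y, 3)
  or <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                      scale = TRUE)
  pr <- predict(or, X)$predict[, 1, 3]
  expect_equal(m@fitted, unname(pr), tolerance = 1e-6)
})

test_that("component selection minimizes LOO PRESS with small-A ties", {
  # noise-free rank-2 relationship: PRESS flat at ~0 from A = 2 on,
  # so the tie must resolve to 2
  set.seed(21)
  S <- matrix(rnorm(60), 30, 2)
  X <- S %*% matrix(rnorm(10), 2, 5)         # rank-2 X
  y <- S %*% c(1, -2)
  expect_equal(selectComponents(X, y, 4), 2L)

  # single informative column plus noise columns: min-PRESS selection is
  # deterministic per dataset, never predicts worse than the one-component
  # model, and recovers the strong planted signal at high Q2
  for (s in 1:5) {
    set.seed(s)
    sig <- rnorm(40)
    yn <- sig + rnorm(40, sd = 0.1)
    Xn <- cbind(sig, matrix(rnorm(40 * 5), 40, 5))
    aStar <- selectComponents(Xn, yn, 4)
    expect_identical(selectComponents(Xn, yn, 4), aStar)
    q2Star <- looQ2(Xn, yn, aStar)$q2
    expect_gte(q2Star, looQ2(Xn, yn, 1)$q2 - 1e-10)
    expect_gt(q2Star, 0.9)
  }
})

test_that("degenerate inputs are rejected with clear messages", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fitPLS(X, rep(1, 10), 1), "constant")
  expect_error(fitPLS(X, rnorm(10), 5), "rank")
  Xz <- cbind(X, flat = 1)
  expect_error(fitPLS(Xz, rnorm(10), 1), "flat")
})
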