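test_that("a perfectly separating column is selected first", {
  set.seed(1)
  lab <- rep(c("strong", "moderate"), each = 10)
  X <- cbind(noise1 = rnorm(20),
             sep = ifelse(lab == "strong", 5, -5) + rnorm(20, sd = 0.1),
             noise2 = rnorm(20))
  sel <- stepwiseSelect(X, lab)
  expect_equal(sel[1], 2L)
})

test_that("noise-only descriptors enter near the nominal F rate", {
  # with all columns pure noise the per-variable entry rate should sit near
  # the 5% level implied by F > 3.84 at (1, n-2) df
  entered <- 0L; total <- 0L
  for (s in 1:50) {
    set.seed(s)
    X <- matrix(rnorm(40 * 8), 40, 8)
    lab <- rep(c("strong", "moderate"), each = 20)
    sel <- tryCatch(stepwiseSelect(X, lab), error = function(e) integer(0))
    entered <- entered + length(sel)
    total <- total + 8L
  }
  rate <- entered / total
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})

test_that("two symmetric 1-D classes give a zero threshold", {
  x <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1)
  lab <- rep(c("moderate", "strong"), each = 3)
  m <- fitLDA(x, lab)
  b <- m@coefficients
  expect_equal(unname(-b[1] / b[2]), 0, tolerance = 1e-10)
  expect_equal(m@classes[1], "strong")
})

test_that("the discriminant matches explicit matrix algebra and MASS", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40), 20, 2) + 2, matrix(rnorm(40), 20, 2))
  lab <- rep(c("strong", "moderate"), each = 20)
  m <- fitLDA(X, lab)

  # explicit algebra: a = Sp^-1 (mu1 - mu2)
  mu1 <- colMeans(X[1:20, ]); mu2 <- colMeans(X[21:40, ])
  Sp <- (cov(X[1:20, ]) * 19 + cov(X[21:40, ]) * 19) / 38
  a <- solve(Sp, mu1 - mu2)
  expect_equal(unname(m@coefficients[-1]), unname(a), tolerance = 1e-10)
  expect_equal(unname(m@coefficients[1]),
               unname(-sum(a * (mu1 + mu2)) / 2), tolerance = 1e-10)

  # class assignments agree with MASS::lda at equal priors
  mm <- MASS::lda(X, grouping = lab, prior = c(0.5, 0.5))
  expect_equal(predict(m, X)$class,
               as.character(predict(mm, X)$class))
})

test_that("equal class means classify at the prior rate", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  lab <- rep(c("strong", "moderate"), 15)
  m <- fitLDA(X, lab)
  pred <- predict(m, X)$class
  expect_gt(mean(pred == lab), 0.2)  # chance-level, not degenerate
  expect_lt(mean(pred == lab), 0.8)
})

test_that("confusion statistics reproduce hand values and conventions", {
  cs <- confusionStats(tp = 6, fn = 2, tn = 9, fp = 3)
  expect_equal(cs$accuracy, 0.75)
  expect_equal(cs$sensitivity, 0.75)
  expect_equal(cs$specificity, 0.75)
  expect_equal(cs$mcc, (6 * 9 - 3 * 2) / sqrt(9 * 8 * 12 * 11))
  expect_equal(round(cs$mcc, 3), 0.492)

  # constant predictions give MCC 0 by the 0/0 convention
  expect_equal(confusionStats(tp = 8, fn = 0, tn = 0, fp = 12)$mcc, 0)

  # MCC is symmetric under simultaneous label/prediction swap
  obs <- c(rep("strong", 8), rep("moderate", 12))
  prd <- c(rep("strong", 6), rep("moderate", 2),
           rep("strong", 3), rep("moderate", 9))
  swap <- function(v) ifelse(v == "strong", "moderate", "strong")
  expect_equal(confusionStats(obs, prd)$mcc,
               confusionStats(swap(obs), swap(prd), positive = "moderate")$mcc)
})

test_that("LOO classification is perfect on cleanly separated data", {
  set.seed(4)
  lab <- rep(c("strong", "moderate"), each = 10)
  X <- cbind(sep = ifelse(lab == "strong", 4, -4) + rnorm(20, sd = 0.2),
             n1 = rnorm(20), n2 = rnorm(20))
  cs <- looClassify(X, lab)
  expect_equal(cs$accuracy, 1)
  expect_equal(cs$mcc, 1)
})

test_that("stepwise LDA pipeline recovers planted class structure", {
  fix <- syntheticClassificationFixture(seed = 11L)
  cs <- looClassify(fix$X, fix$labels)
  expect_gt(cs$accuracy, 0.7)
  expect_gt(cs$mcc, 0.4)
  expect_true(all(cs$tp + cs$fn + cs$tn + cs$fp == length(fix$labels)))
})

test_that("strict LOO mode reselects variables inside each fold", {
  set.seed(4)
  lab <- rep(c("strong", "moderate"), each = 10)
  X <- cbind(sep = ifelse(lab == "strong", 4, -4) + rnorm(20, sd = 0.2),
             n1 = rnorm(20), n2 = rnorm(20))
  strict <- looClassify(X, lab, mode = "strict")
  expect_equal(strict$accuracy, 1)
  expect_equal(strict$n, 20)
})
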