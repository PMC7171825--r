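test_that("RBF kernel follows its closed form and symmetry", {
  expect_equal(rbfKernel(c(1, 2), c(1, 2), sigma = 0.7), 1.0)
  expect_equal(rbfKernel(0, 2, sigma = 1), exp(-2))
  set.seed(1)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(rbfKernel(a, b, 1.3), rbfKernel(b, a, 1.3))
  expect_true(rbfKernel(a, b, 1.3) > 0 && rbfKernel(a, b, 1.3) <= 1)
  expect_error(rbfKernel(a, b, 0), "sigma")
  expect_error(rbfKernel(a, b[1:3], 1), "equal length")
})

test_that("confusion metrics reproduce the printed-class-size arithmetic", {
  mk <- function(tp, fn, tn, fp) {
    truth <- rep(c("pMCI", "sMCI"), c(tp + fn, tn + fp))
    pred <- c(rep("pMCI", tp), rep("sMCI", fn),
              rep("sMCI", tn), rep("pMCI", fp))
    confusionMetrics(pred, truth)
  }
  expect_equal(round(mk(2, 31, 45, 1), 2),
               c(acc = 59.49, sen = 6.06, spe = 97.83))
  expect_equal(round(mk(27, 6, 43, 3), 2),
               c(acc = 88.61, sen = 81.82, spe = 93.48))
  expect_equal(unname(mk(33, 0, 46, 0)), c(100, 100, 100))
  expect_error(confusionMetrics(rep("pMCI", 4), rep("pMCI", 4)),
               "both classes")
})

test_that("threshold-sweep AUC equals pairwise concordance", {
  r <- rocAuc(c(0.1, 0.4, 0.35, 0.8), c("sMCI", "sMCI", "pMCI", "pMCI"))
  expect_equal(r$auc, 0.75)  # 3 concordant pairs of 4
  expect_equal(r$roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))

  expect_equal(rocAuc(c(1, 2, 3, 4), rep(c("sMCI", "pMCI"), each = 2))$auc, 1)
  expect_equal(rocAuc(c(4, 3, 2, 1), rep(c("sMCI", "pMCI"), each = 2))$auc, 0)
  expect_warning(r0 <- rocAuc(rep(1, 4), rep(c("sMCI", "pMCI"), each = 2)),
                 "constant")
  expect_equal(r0$auc, 0.5)

  set.seed(2)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    y <- sample(rep(c("pMCI", "sMCI"), c(ceiling(n / 2), floor(n / 2))))
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(rocAuc(s, y)$auc, concordanceAuc(s, y), tolerance = 1e-12)
  }
})

test_that("LOO evaluation holds one subject out per fold and is deterministic", {
  set.seed(3)
  n <- 14
  y <- rep(c("pMCI", "sMCI"), each = 7)
  x <- matrix(rnorm(n * 10), n, 10)
  r <- looEvaluate(x, y, k = 4)
  expect_equal(nrow(r@perSubject), n)
  expect_equal(r@perSubject$fold, 1:n)
  expect_equal(r@perSubject$truth, y)
  r2 <- looEvaluate(x, y, k = 4)
  expect_identical(r@perSubject, r2@perSubject)

  # large-margin separable data: perfect LOO accuracy
  xs <- matrix(rnorm(n * 5), n, 5)
  xs[y == "pMCI", 1] <- xs[y == "pMCI", 1] + 20
  rs <- looEvaluate(xs, y, k = 3)
  expect_equal(rs@acc, 100)
  expect_equal(rs@auc, 1)

  expect_error(looEvaluate(x, c("pMCI", rep("sMCI", n - 1)), k = 2),
               "at least 2")
  expect_error(looEvaluate(x, y, k = 11), "exceeds")
})

test_that("feature-count sweep reports the curve and a deterministic argmax", {
  set.seed(4)
  n <- 12
  y <- rep(c("pMCI", "sMCI"), each = 6)
  x <- matrix(rnorm(n * 8), n, 8)
  x[y == "pMCI", 1:2] <- x[y == "pMCI", 1:2] + 3

  # degenerate sweep equals a single evaluation
  sw1 <- sweepFeatureCount(x, y, kRange = 8)
  expect_equal(sw1$curve$acc, looEvaluate(x, y, k = 8)@acc)
  expect_equal(sw1$bestK, 8L)

  sw <- sweepFeatureCount(x, y, kRange = c(1, 2, 4, 8))
  expect_equal(sw$curve$k, c(1L, 2L, 4L, 8L))
  expect_equal(sw$best@acc, max(sw$curve$acc))
  expect_equal(sw$bestK, sw$curve$k[which.max(sw$curve$acc)])
  sw2 <- sweepFeatureCount(x, y, kRange = c(1, 2, 4, 8))
  expect_identical(sw$curve, sw2$curve)
  expect_error(sweepFeatureCount(x, y, kRange = integer(0)), "empty")

  # constant features: flat curve at the majority-class rate
  xc <- matrix(1, n + 2, 5)
  yc <- rep(c("pMCI", "sMCI"), c(6, 8))
  swc <- suppressWarnings(sweepFeatureCount(xc, yc, kRange = c(1, 5)))
  expect_equal(unique(swc$curve$acc), 100 * 8 / 14)
})

test_that("nested-k selection never sees the held-out subject", {
  set.seed(5)
  n <- 10
  y <- rep(c("pMCI", "sMCI"), each = 5)
  x <- matrix(rnorm(n * 6), n, 6)
  x[y == "pMCI", 1] <- x[y == "pMCI", 1] + 6
  nk <- looEvaluateNestedK(x, y, kRange = c(1, 3, 6))
  expect_length(nk$kPerFold, n)
  expect_true(all(nk$kPerFold %in% c(1, 3, 6)))
  expect_equal(nk$result@acc, 100)  # strong planted signal survives nesting
})

test_that("svm configuration maps sigma to gamma and validates", {
  expect_equal(svmConfig(sigma = 2)@gamma, 1 / 8)
  expect_true(is.na(svmConfig()@gamma))
  expect_error(svmConfig(sigma = 1, gamma = 1), "not both")
  expect_error(svmConfig(cost = -1), "cost")
  expect_error(svmConfig(sigma = -1), "sigma")
})
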