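test_that("separable classes classify perfectly and constants fall back to majority", {
  set.seed(61)
  X <- rbind(matrix(rnorm(10 * 4), 10, 4),
             matrix(rnorm(10 * 4, mean = 8), 10, 4))
  y <- factor(rep(c("hc", "sz"), each = 10))
  cv <- loocvSVM(X, y, screen = TRUE)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_length(cv$perFold$predicted, 20)

  Xc <- matrix(1, 30, 4)
  yc <- factor(rep(c("a", "b"), c(17, 13)))
  cvc <- suppressMessages(loocvSVM(Xc, yc, screen = FALSE))
  expect_equal(cvc$accuracy, 17 / 30)
})

test_that("structureless features stay at chance under per-fold screening", {
  set.seed(62)
  acc <- vapply(1:10, function(i) {
    X <- matrix(rnorm(40 * 120), 40, 120)
    y <- factor(rep(c("a", "b"), each = 20))
    suppressMessages(loocvSVM(X, y, screen = TRUE)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})

test_that("screening helps when noise features swamp one informative feature", {
  set.seed(63)
  diff <- vapply(1:8, function(i) {
    X <- cbind(rep(c(0, 1.5), each = 15) + rnorm(30, 0, 0.5),
               matrix(rnorm(30 * 300), 30, 300))
    y <- factor(rep(c("a", "b"), each = 15))
    on <- suppressMessages(loocvSVM(X, y, screen = TRUE)$accuracy)
    off <- loocvSVM(X, y, screen = FALSE)$accuracy
    on - off
  }, numeric(1))
  expect_gt(mean(diff), 0)
})

test_that("per-fold standardisation makes predictions scale-invariant", {
  set.seed(64)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 1] <- X[, 1] + rep(c(0, 1), c(15, 15))
  y <- factor(rep(c("a", "b"), each = 15))
  p1 <- loocvSVM(X, y, screen = FALSE)$perFold$predicted
  X2 <- sweep(X, 2, c(10, 0.01, 1, 5, 100, 2), "*")
  p2 <- loocvSVM(X2, y, screen = FALSE)$perFold$predicted
  expect_identical(p1, p2)
})

test_that("label-aligned features cannot leak through held-out standardisation", {
  # canary: a feature identical to the label is informative, but LOOCV must
  # estimate everything on training folds; a pure-noise companion set must
  # not let accuracy exceed what the informative feature alone supports
  set.seed(65)
  y <- factor(rep(c("a", "b"), each = 12))
  X <- cbind(as.numeric(y) + rnorm(24, 0, 0.05),
             matrix(rnorm(24 * 50), 24, 50))
  cv <- loocvSVM(X, y, screen = TRUE)
  expect_equal(cv$accuracy, 1) # genuinely separable, fine
  # now remove the signal: chance performance proves no other leak path
  Xnull <- X[, -1, drop = FALSE]
  accs <- vapply(1:5, function(i)
    suppressMessages(loocvSVM(Xnull[sample(24), ], y, screen = TRUE)$accuracy),
    numeric(1))
  expect_lt(mean(accs), 0.8)
})

test_that("permutation p-values obey the add-one rule", {
  set.seed(66)
  X <- rbind(matrix(rnorm(8 * 3), 8, 3), matrix(rnorm(8 * 3, 6), 8, 3))
  y <- factor(rep(c("a", "b"), each = 8))
  pt <- permutationTest(X, y, R = 30, seed = 2)
  expect_equal(pt$observed, 1)
  expect_gt(pt$p.value, 0)
  expect_lte(pt$p.value, 1)
  expect_equal(pt$p.value, (1 + sum(pt$null >= pt$observed)) / 31)
  # deterministic given the seed
  pt2 <- permutationTest(X, y, R = 30, seed = 2)
  expect_identical(pt$null, pt2$null)
})

test_that("window validation selects the most discriminative width", {
  P1 <- matrix(c(.97, .015, .015, .02, .96, .02, .02, .02, .96), 3, 3, byrow = TRUE)
  P2 <- matrix(c(.90, .05, .05, .02, .96, .02, .02, .02, .96), 3, 3, byrow = TRUE)
  spec <- CohortSpec(list(GroupSpec("A", 6, P1), GroupSpec("B", 6, P2)),
                     connectivityStateTemplates(6, strength = 0.7),
                     C = 6, T = 150, observationNoiseSd = 0.2, spikeRate = 0,
                     seed = 8)
  co <- simulateCohort(spec)
  filt <- lapply(co, postprocessSubject)
  wv <- suppressMessages(windowValidation(filt, c("A", "B"), widths = c(30, 44)))
  best <- c(30, 44)[wv$accuracies == max(wv$accuracies)]
  expected <- if (44 %in% best) 44 else min(best)  # ties favour 44 s
  expect_identical(wv$selectedWidth, expected)
  expect_named(wv$accuracies, c("30", "44"))
  expect_true(all(wv$accuracies >= 0 & wv$accuracies <= 1))
})

test_that("combined classification runs static, dynamic and joint feature sets", {
  set.seed(68)
  y <- factor(rep(c("a", "b"), each = 12))
  stat <- cbind(as.numeric(y) + rnorm(24, 0, 0.3),
                matrix(rnorm(24 * 6), 24, 6))
  dyn <- matrix(rnorm(24 * 6), 24, 6)
  dyn[3, 2] <- NA # a subject that never visited a state
  expect_message(res <- combinedClassification(stat, dyn, y), "imputed")
  expect_named(res, c("static", "dynamic", "combined"))
  # static carries all the signal; combined should not fall to chance
  expect_gt(res$static$accuracy, res$dynamic$accuracy - 0.2)
  expect_gt(res$combined$accuracy, 0.6)
})
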