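# Stacking: meta-features, RBF kernel, BER, grid search, prediction.

trainTwoBases <- function(seed = 1) {
  list(trainBaseForest(makeSeparableDataset(nPos = 40, nNeg = 160,
                                            seed = seed, tissue = "tA"),
                       forestConfig(seed = seed)),
       trainBaseForest(makeSeparableDataset(nPos = 40, nNeg = 160,
                                            seed = seed + 1, tissue = "tB"),
                       forestConfig(seed = seed + 1)))
}

test_that("meta-features are confidence times held-out F-score, elementwise", {
  models <- trainTwoBases(3)
  pooled <- pooledHeldout(models)
  meta <- buildMetaFeatures(models, pooled$features, pooled$labels)
  expect_equal(dim(meta@metaFeatures),
               c(nrow(pooled$features), 2L))
  expect_equal(meta@baseNames, c("tA", "tB"))
  # elementwise oracle from stored confidences and F-scores
  for (j in 1:2) {
    expect_equal(meta@metaFeatures[, j],
                 confidenceScores(models[[j]], pooled$features) *
                   heldoutFscore(models[[j]]))
    expect_true(all(meta@metaFeatures[, j] <= heldoutFscore(models[[j]]) + 1e-12))
  }
  # spot-check the arithmetic: confidences (0.8, 0.5) x F (0.9, 0.5)
  expect_equal(c(0.8, 0.5) * c(0.9, 0.5), c(0.72, 0.25))
  # a base with F-score 0 contributes an all-zero column
  zeroF <- models[[2]]
  zeroF@heldoutFscore <- 0
  metaZ <- buildMetaFeatures(list(models[[1]], zeroF), pooled$features,
                             pooled$labels)
  expect_true(all(metaZ@metaFeatures[, 2] == 0))
  expect_error(buildMetaFeatures(models[1], pooled$features, pooled$labels),
               "at least 2")
})

test_that("the RBF kernel evaluates, is symmetric, and rejects bad input", {
  expect_equal(rbfKernel(c(1, 2), c(1, 2), gamma = 3), 1)
  expect_equal(rbfKernel(0, 1, gamma = 1), exp(-1))
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4); g <- runif(1, 0.1, 10)
    expect_equal(rbfKernel(x, y, g), rbfKernel(y, x, g))
    expect_true(rbfKernel(x, y, g) > 0 && rbfKernel(x, y, g) <= 1)
  }
  expect_error(rbfKernel(c(1, 2), 1, gamma = 1), "dimension")
  expect_error(rbfKernel(1, 2, gamma = 0))
})

test_that("kernel is invariant to scaling x by c and gamma by 1/c^2", {
  set.seed(5)
  x <- runif(3); y <- runif(3)
  for (cc in c(0.1, 2, 50)) {
    expect_equal(rbfKernel(x, y, gamma = 4),
                 rbfKernel(cc * x, cc * y, gamma = 4 / cc^2))
  }
})

test_that("balanced error rate matches its confusion-count definition", {
  expect_equal(balancedErrorRate(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(balancedErrorRate(c(1, 1, 0, 0), c(1, 1, 1, 1)), 0.5)
  # TP=3 FN=1 TN=2 FP=2 -> 1 - (0.75 + 0.5)/2
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 1, 0, 0)
  expect_equal(balancedErrorRate(labels, pred), 0.375)
  expect_error(balancedErrorRate(rep(1, 4), rep(1, 4)), "both classes")
})

test_that("grid search solves a separable stack and stays on the grid", {
  set.seed(6)
  labels <- rep(c(1L, 0L), each = 50)
  meta <- new("MetaDataset",
              metaFeatures = matrix(
                c(runif(50, 0.7, 0.9), runif(50, 0.1, 0.3),
                  runif(100, 0, 1)), ncol = 2,
                dimnames = list(NULL, c("b1", "b2"))),
              labels = labels, baseNames = c("b1", "b2"))
  cfg <- testSvmConfig()
  model <- gridSearchSvm(meta, cfg)
  expect_equal(model@cvBalancedError, 0)
  expect_true(model@chosenC %in% cfg$cGrid)
  expect_true(model@chosenGamma %in% cfg$gammaGrid)
  expect_equal(nrow(model@cvSurface), 9L)
  # perfect training accuracy on the separable example
  pred <- predictMeta(model, meta)
  expect_equal(pred$labels, labels)
  expect_equal(pred$labels, as.integer(pred$scores > 0))
})

test_that("grid selection matches an exhaustive independent recomputation", {
  set.seed(7)
  n <- 200
  labels <- rep(c(1L, 0L), c(60, 140))
  x <- cbind(b1 = 0.5 * labels + runif(n, 0, 0.5),
             b2 = 0.3 * labels + runif(n, 0, 0.6))
  meta <- new("MetaDataset", metaFeatures = x, labels = labels,
              baseNames = c("b1", "b2"))
  cfg <- svmConfig(cGrid = c(2, 10, 40), gammaGrid = c(2, 20, 100),
                   nFolds = 5, seed = 17)
  model <- gridSearchSvm(meta, cfg)
  # oracle: same folds, every pair, every fold, straight e1071 calls
  folds <- stratifiedFolds(labels, 5, seed = cfg$seed)
  surface <- expand.grid(gamma = cfg$gammaGrid, C = cfg$cGrid)
  surface <- surface[order(surface$C, surface$gamma), ]
  oracleBer <- apply(surface, 1, function(p) {
    mean(vapply(1:5, function(f) {
      fit <- e1071::svm(x = x[folds != f, ], y = factor(labels[folds != f],
                                                        levels = c("0", "1")),
                        kernel = "radial", cost = p["C"], gamma = p["gamma"],
                        scale = FALSE)
      pr <- as.integer(as.character(predict(fit, x[folds == f, ])))
      truth <- labels[folds == f]
      sens <- sum(pr == 1 & truth == 1) / sum(truth == 1)
      spec <- sum(pr == 0 & truth == 0) / sum(truth == 0)
      1 - (sens + spec) / 2
    }, numeric(1)))
  })
  best <- which.min(oracleBer)
  expect_equal(model@chosenC, unname(surface$C[best]))
  expect_equal(model@chosenGamma, unname(surface$gamma[best]))
  expect_equal(model@cvBalancedError, unname(oracleBer[best]))
  expect_equal(model@cvSurface$ber, unname(oracleBer))
})

test_that("CV folds partition the samples with both classes in each fold", {
  labels <- rep(c(1L, 0L), c(30, 300))
  folds <- stratifiedFolds(labels, 10, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 330L)
  for (f in 1:10) {
    expect_equal(sum(folds == f & labels == 1L), 3L)
  }
  expect_error(stratifiedFolds(rep(c(1L, 0L), c(5, 100)), 10), "at least")
})

test_that("decision values match the dual-form kernel expansion", {
  set.seed(8)
  labels <- rep(c(1L, 0L), each = 10)
  x <- cbind(b1 = 0.6 * labels + runif(20, 0, 0.4),
             b2 = runif(20))
  meta <- new("MetaDataset", metaFeatures = x, labels = labels,
              baseNames = c("b1", "b2"))
  model <- gridSearchSvm(meta, svmConfig(cGrid = 4, gammaGrid = 8,
                                         nFolds = 5, seed = 2))
  got <- predictMeta(model, x)$scores
  # oracle: f(x) = sum_i coef_i k(sv_i, x) - rho from the stored dual
  svm <- model@model
  K <- apply(x, 1, function(row) {
    vapply(seq_len(nrow(svm$SV)), function(i) {
      rbfKernel(svm$SV[i, ], row, gamma = svm$gamma)
    }, numeric(1))
  })
  d <- as.numeric(t(svm$coefs) %*% K) - svm$rho
  # libsvm orients positive decision values toward its first stored class
  firstClass <- svm$levels[svm$labels[1]]
  oracle <- if (firstClass == "1") d else -d
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(predictMeta(model, x)$labels, as.integer(got > 0))
})

test_that("prediction refuses mismatched meta columns", {
  models <- trainTwoBases(9)
  pooled <- pooledHeldout(models)
  meta <- buildMetaFeatures(models, pooled$features, pooled$labels)
  model <- gridSearchSvm(meta, svmConfig(cGrid = 2, gammaGrid = 2, nFolds = 5))
  bad <- meta@metaFeatures
  colnames(bad) <- c("tA", "tX")
  expect_error(predictMeta(model, bad), "do not match")
})
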