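# four well-separated Gaussian clusters in a (L+1)-dim feature space
separableData <- function(nPerClass = 30, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(1, 1, 1, 0.25), c(1, 0.8, 0.3, 0.5),
                   c(1, 0.4, 0.1, 0.8), c(0.3, 0.3, 0.3, 2.0))
  x <- do.call(rbind, lapply(1:4, function(i)
    matrix(rep(centers[i, ], each = nPerClass), nPerClass) +
      matrix(rnorm(nPerClass * 4, 0, 0.02), nPerClass)))
  list(x = x, labels = rep(actionClasses(), each = nPerClass))
}

test_that("both classifiers separate well-separated clusters perfectly", {
  d <- separableData(30)
  train <- stratifiedSplit(d$labels, 0.7, seed = 2)
  for (m in c("ann", "svm")) {
    model <- trainActionModel(d$x[train, ], d$labels[train], method = m,
                              seed = 5)
    rep <- evaluateModel(model, d$x[!train, ], d$labels[!train])
    expect_equal(averagePrecision(rep), 100,
                 label = paste("held-out precision for", m))
    expect_false(any(rep@undefined))
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- separableData(20, seed = 3)
  for (m in c("ann", "svm")) {
    m1 <- trainActionModel(d$x, d$labels, method = m, seed = 11)
    m2 <- trainActionModel(d$x, d$labels, method = m, seed = 11)
    expect_identical(predict(m1, d$x), predict(m2, d$x))
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- separableData(10)
  oneClass <- d$labels == "sitting"
  expect_error(trainActionModel(d$x[oneClass, ], d$labels[oneClass]),
               "two classes")
  expect_error(trainActionModel(list(c(1, 2, 3), c(1, 2)), c("a", "b")),
               "mixed lengths")
})

test_that("precision report: counts, conservation, and the undefined rule", {
  truth <- rep(actionClasses(), each = 10)
  # perfect predictions: diagonal confusion, all precisions 100
  perfect <- precisionReport(truth, truth)
  expect_true(all(diag(confusionMatrix(perfect)) == 10))
  expect_equal(sum(confusionMatrix(perfect)) , 40)
  expect_equal(precisionByClass(perfect), rep(100, 4))
  expect_equal(averagePrecision(perfect), 100)

  # everything predicted as one class on balanced data
  allOne <- precisionReport(truth, rep("sitting", 40))
  expect_equal(precisionByClass(allOne)[2], 25)
  expect_equal(precisionByClass(allOne)[-2], rep(0, 3))
  expect_equal(unname(allOne@undefined), c(TRUE, FALSE, TRUE, TRUE))

  # row sums equal per-class sample counts
  scrambled <- precisionReport(truth, sample(truth))
  expect_equal(unname(rowSums(confusionMatrix(scrambled))), rep(10L, 4))
})

test_that("parameter sweep covers the grid and ignores sample order", {
  cfg <- sceneConfig(backgroundFrames = 40L)
  corpus <- generateCorpus(cfg, samplesPerClass = 12L, seed = 31L)
  sset <- processCorpus(corpus)

  tab <- sweepParameters(sset, layerList = c(3L, 5L), alphaList = c(0, 0.9),
                         methods = "svm", seed = 2L)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$layers, c(3, 5))
  expect_setequal(tab$alpha, c(0, 0.9))
  expect_true(all(tab$averagePrecision >= 0 & tab$averagePrecision <= 100))

  one <- sweepParameters(sset, layerList = 3L, alphaList = 0.9,
                         methods = "svm", seed = 2L)
  expect_equal(nrow(one), 1)

  # permuting sample order leaves the (deterministic) features unchanged
  perm <- sample(length(sset@samples))
  ssetPerm <- new("ActionSampleSet", samples = sset@samples[perm],
                  labels = sset@labels[perm])
  f1 <- extractFeatures(sset, layers = 3L, alpha = 0.9)
  f2 <- extractFeatures(ssetPerm, layers = 3L, alpha = 0.9)
  ord1 <- order(apply(f1$x, 1, paste, collapse = ","))
  ord2 <- order(apply(f2$x, 1, paste, collapse = ","))
  expect_equal(f1$x[ord1, ], f2$x[ord2, ], ignore_attr = TRUE)
  expect_equal(f1$labels[ord1], f2$labels[ord2])
})
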