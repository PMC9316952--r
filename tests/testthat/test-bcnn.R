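# Bifocal classifier: construction, forward-pass contracts, training
# behaviour and evaluation metrics.

randomPairs <- function(n, seed = 1, labels = NULL) {
  set.seed(seed)
  if (is.null(labels))
    labels <- rep(c("negative", "positive"), length.out = n)
  new("BifocalPatchSet",
      narrow = array(runif(32 * 32 * 3 * n), dim = c(32, 32, 3, n)),
      wide = array(runif(64 * 64 * 3 * n), dim = c(64, 64, 3, n)),
      labels = factor(labels, levels = c("negative", "positive")),
      centres = cbind(x = rep(32L, n), y = rep(32L, n)),
      caseIds = rep("c", n), tileIds = rep("t", n))
}

test_that("builds are seed-deterministic and configs are validated", {
  m1 <- buildModel(tinyBcnnConfig(seed = 7L))
  m2 <- buildModel(tinyBcnnConfig(seed = 7L))
  m3 <- buildModel(tinyBcnnConfig(seed = 8L))
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params, m3@params))
  expect_error(bcnnConfig(channels = c(4, 8)), "three")
  expect_error(bcnnConfig(narrowSize = 32, wideSize = 48), "twice")
  expect_error(bcnnConfig(narrowSize = 20, wideSize = 40), "divisible by 8")
})

test_that("forward pass yields normalized, finite, order-stable scores", {
  m <- buildModel(tinyBcnnConfig())
  ps <- randomPairs(32)
  probs <- bifocal:::bcnn_forward_cpp(m@params, ps@narrow, ps@wide)
  expect_equal(rowSums(probs), rep(1, 32), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))

  zero <- ps
  zero@narrow[] <- 0; zero@wide[] <- 0
  expect_true(all(is.finite(predictPairs(m, zero))))

  # functional purity and batching invariance
  sc <- predictPairs(m, ps, batchSize = 256)
  sc1 <- predictPairs(m, ps, batchSize = 1)
  expect_equal(sc, sc1, tolerance = 1e-6)
  dup <- ps[c(3, 3)]
  sdup <- predictPairs(m, dup)
  expect_identical(sdup[1], sdup[2])
})

test_that("training reduces the loss on learnable data, deterministically", {
  cfg <- syntheticConfig(tileWidth = 256L, tileHeight = 256L, nCells = 8L,
                         nNegatives = 8L, nucleiDensity = 40L, seed = 21L)
  cs <- generateCase(cfg, nTiles = 2, caseId = "tr")
  pairs <- buildTrainingSet(cs$tiles, cs$marks, seed = 2)
  m <- buildModel(tinyBcnnConfig())
  tr <- trainModel(m, pairs, epochs = 5)
  expect_lt(tail(tr@history$loss, 1), tr@history$loss[1])
  expect_true(tr@trained)

  tr2 <- trainModel(m, pairs, epochs = 5)
  expect_identical(tr@params, tr2@params)

  onlyPos <- pairs[which(pairLabels(pairs) == "positive")]
  expect_error(trainModel(m, onlyPos), "both classes")
})

test_that("evaluation reproduces closed-form metrics", {
  scores <- c(rep(0.9, 8), 0.1, 0.9, rep(0.1, 10))
  labels <- c(rep("positive", 9), rep("negative", 11))
  rep <- evaluateScores(scores, labels)
  expect_equal(rep@confusion["positive", "positive"], 8)
  expect_equal(rep@confusion["negative", "positive"], 1)
  expect_equal(rep@confusion["positive", "negative"], 1)
  expect_equal(rep@confusion["negative", "negative"], 10)
  expect_equal(rep@precision, 8 / 9)
  expect_equal(rep@recall, 8 / 9)
  expect_equal(rep@f1, 8 / 9)
  expect_equal(sum(rep@confusion), 20)

  perfect <- evaluateScores(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect@accuracy, 1)
  expect_equal(perfect@auc, 1)

  expect_error(evaluateScores(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("label-independent scores give AUC 0.5 and metrics are permutation invariant", {
  set.seed(99)
  n <- 10000
  scores <- runif(n)
  labels <- sample(c(0, 1), n, replace = TRUE)
  rep <- evaluateScores(scores, labels)
  expect_lt(abs(rep@auc - 0.5), 0.02)

  perm <- sample(n)
  rep2 <- evaluateScores(scores[perm], labels[perm])
  expect_equal(rep@auc, rep2@auc)
  expect_equal(rep@accuracy, rep2@accuracy)
  expect_equal(rep@confusion, rep2@confusion)
})

test_that("model checkpoints round-trip with a JSON config sidecar", {
  m <- buildModel(tinyBcnnConfig())
  p <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, p)
  expect_true(file.exists(sub("\\.rds$", ".json", p)))
  back <- loadModel(p)
  expect_identical(back@params, m@params)

  rep <- evaluateScores(c(0.9, 0.8, 0.2, 0.4), c(1, 1, 0, 0))
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  writeEvalReport(rep, js, cs)
  out <- jsonlite::read_json(js)
  expect_equal(out$auc, 1)
  expect_equal(out$accuracy, 1)
  expect_true(file.exists(cs))
})
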