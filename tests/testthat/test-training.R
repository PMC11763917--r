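test_that("reverseTime reverses rows and is an involution", {
  X <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  expect_identical(reverseTime(X), matrix(c(3, 2, 1, 30, 20, 10), 3, 2))
  expect_identical(reverseTime(reverseTime(X)), X)
  one <- matrix(1:4, 1, 4)
  expect_identical(reverseTime(one), one)
  set.seed(1)
  for (i in 1:10) {
    M <- matrix(rnorm(40), 8, 5)
    expect_identical(reverseTime(reverseTime(M)), M)
  }
})

test_that("the pretext dataset is balanced with reversed siblings", {
  coh <- makeToyCohort(n = 10L)
  d <- buildTRDataset(coh)
  expect_length(d, 20L)
  y <- vapply(d, function(e) e@y, integer(1))
  expect_identical(sum(y), 10L)
  for (i in seq_len(10L))
    expect_identical(d[[2L * i]]@values, reverseTime(d[[2L * i - 1L]]@values))
  expect_error(buildTRDataset(Cohort("e", list(), 5L, 2L)), "empty")
})

test_that("binary cross-entropy matches hand evaluation", {
  expect_equal(bceLoss(c(0, 1, 1), rep(0.5, 3)), log(2))
  expect_lt(bceLoss(c(0, 1), c(1e-9, 1 - 1e-9)), 1e-6)
  expect_equal(bceLoss(c(0, 1), c(0.1, 0.9)), -log(0.9), tolerance = 1e-12)
  # clamping keeps exact 0/1 probabilities finite
  expect_true(is.finite(bceLoss(c(0, 1), c(1, 0))))
})

test_that("AUC is the Mann-Whitney statistic with mid-rank ties", {
  expect_equal(aucScore(c(1, 1, 0, 0), c(.9, .8, .3, .2)), 1)
  expect_equal(aucScore(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(rnorm(n), 1)  # coarse scores force ties
    # brute-force pairwise oracle
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(aucScore(y, s), mean(cmp))
    expect_equal(aucScore(y, -s), 1 - aucScore(y, s))
  }
  # independent package cross-check
  set.seed(4)
  y <- sample(0:1, 30, replace = TRUE, prob = c(.4, .6))
  y[1:2] <- 0:1
  s <- rnorm(30)
  expect_equal(aucScore(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))))
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("training is seed-deterministic and rejects degenerate data", {
  coh <- makeToyCohort(n = 8L, tp = 16L, nc = 2L)
  d <- buildTRDataset(coh)
  m <- initModel(tinyModelConfig(2L))
  f1 <- trainModel(m, d, fastTrainConfig(maxEpochs = 4L))
  f2 <- trainModel(m, d, fastTrainConfig(maxEpochs = 4L))
  expect_identical(f1$history, f2$history)
  expect_identical(modelParameters(f1$model), modelParameters(f2$model))
  f3 <- trainModel(m, d, fastTrainConfig(maxEpochs = 4L, seed = 2L))
  expect_false(identical(f1$history$trainLoss, f3$history$trainLoss))

  ones <- lapply(d[c(2, 4, 6)], identity)
  expect_error(trainModel(m, ones, fastTrainConfig()), "both classes")
})

test_that("zero early-stop patience halts at the first non-improvement", {
  coh <- makeToyCohort(n = 8L, tp = 16L, nc = 2L)
  d <- buildTRDataset(coh)
  m <- initModel(tinyModelConfig(2L))
  cfg <- fastTrainConfig(maxEpochs = 100L, earlyStopPatience = 0L)
  fit <- trainModel(m, d, cfg)
  h <- fit$history
  expect_lt(nrow(h), 100L)
  # every epoch but the last improved on the best by more than minDelta
  best <- Inf
  for (e in seq_len(nrow(h) - 1L)) {
    expect_lt(h$valLoss[e], best - cfg@minDelta)
    best <- h$valLoss[e]
  }
  expect_gte(h$valLoss[nrow(h)], best - cfg@minDelta)
})

test_that("the time-reversal pretext task is learned on clean chirps", {
  p <- ChirpParams(nComponents = 8L, nTimepoints = 128L, noiseSd = 0,
                   seed = 6L)
  coh <- generateChirpCohort(64L, p)
  d <- buildTRDataset(coh)
  fit <- trainModel(initModel(ModelConfig(inputSize = 8L, seed = 1L)), d,
                    TrainConfig(maxEpochs = 200L, seed = 1L))
  expect_lte(min(which(fit$history$trainAcc == 1)), 200L)
  probs <- vapply(d, function(e) forwardPass(fit$model, e@values)@probability,
                  numeric(1))
  y <- vapply(d, function(e) e@y, integer(1))
  expect_equal(mean((probs > 0.5) == (y == 1L)), 1)
})

test_that("stratified folds partition subjects exactly", {
  coh <- makeToyCohort(n = 20L, labeled = TRUE)
  y <- cohortLabels(coh)
  set.seed(1)
  fold <- timeArrow:::.stratifiedFolds(y, 10L)
  expect_identical(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 2L))
  for (f in 1:10) expect_identical(sum(fold == f & y == 1L), 1L)
  expect_identical(sort(unlist(lapply(1:10, function(f) which(fold == f)))),
                   1:20)
})

test_that("cross-validation scores a separable labeled cohort highly", {
  # class 1 carries a large constant offset: trivially separable
  set.seed(10)
  subjects <- lapply(1:12, function(i) {
    lab <- as.integer(i > 6)
    SubjectTimeSeries(sprintf("s%02d", i),
                      matrix(rnorm(20 * 2), 20, 2) + 4 * lab, label = lab)
  })
  coh <- Cohort("sep", subjects)
  cv <- crossValidate(coh, tinyModelConfig(2L),
                      fastTrainConfig(maxEpochs = 40L, nFolds = 3L,
                                      earlyStopPatience = 10L))
  expect_identical(nrow(cv), 3L)
  expect_gte(median(cv$auc), 0.9)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_error(
    crossValidate(coh, tinyModelConfig(2L), fastTrainConfig(nFolds = 7L)),
    "minority")
})

test_that("weight transfer copies parameters and honours head re-init", {
  cfg <- tinyModelConfig(3L, seed = 1L)
  donor <- initModel(cfg)
  donor@provenance <- "tr"
  same <- transferWeights(donor, cfg, reinitHead = FALSE)
  expect_identical(modelParameters(same), modelParameters(donor))
  expect_identical(provenance(same), "pretrained:tr")

  reinit <- transferWeights(donor, tinyModelConfig(3L, seed = 9L),
                            reinitHead = TRUE)
  p0 <- modelParameters(donor)
  p1 <- modelParameters(reinit)
  for (nm in c("Wi1", "Wh1", "b1", "Wa1", "wa2"))
    expect_identical(p1[[nm]], p0[[nm]])
  expect_false(identical(p1$Wd1, p0$Wd1))
  expect_false(identical(p1$wd2, p0$wd2))

  expect_error(transferWeights(donor, tinyModelConfig(3L, lstmHidden = 16L)),
               "lstmHidden")
})

test_that("OCP pairs are non-overlapping with an exact half split", {
  coh <- makeToyCohort(n = 3L, tp = 20L, nc = 2L)
  pairs <- buildOCPPairs(coh, segmentLen = 5L, pairsPerSubject = 4L,
                         seed = 2L)
  expect_length(pairs, 12L)
  y <- vapply(pairs, function(p) p@y, integer(1))
  expect_identical(as.vector(table(y[1:4])), c(2L, 2L))
  for (p in pairs) {
    expect_identical(dim(p@segmentA), c(5L, 2L))
    # recover positions from the source subject and check disjointness
    src <- Filter(function(s) subjectId(s) == p@originId,
                  subjects(coh))[[1]]
    find <- function(seg) {
      for (o in 1:16) if (identical(tsValues(src)[o:(o + 4L), ], seg))
        return(o)
      NA_integer_
    }
    oa <- find(p@segmentA); ob <- find(p@segmentB)
    expect_true(abs(oa - ob) >= 5L)  # no overlap
    if (p@y == 1L) expect_lt(oa, ob) else expect_gt(oa, ob)
  }
  expect_identical(
    lapply(buildOCPPairs(coh, 5L, 4L, seed = 2L), function(p) p@segmentA),
    lapply(pairs, function(p) p@segmentA))
  expect_error(buildOCPPairs(coh, 11L, 2L), "too large")
})

test_that("PCL positives are adjacent and negatives unconstrained", {
  coh <- makeToyCohort(n = 4L, tp = 24L, nc = 2L)
  pairs <- buildPCLPairs(coh, windowLen = 6L, pairsPerSubject = 4L,
                         seed = 3L)
  expect_length(pairs, 16L)
  for (p in pairs) {
    src <- Filter(function(s) subjectId(s) == p@originId,
                  subjects(coh))[[1]]
    find <- function(seg) {
      for (o in 1:19) if (identical(tsValues(src)[o:(o + 5L), ], seg))
        return(o)
      NA_integer_
    }
    oa <- find(p@segmentA); ob <- find(p@segmentB)
    if (p@y == 1L) expect_identical(ob, oa + 6L) else expect_true(oa != ob)
  }
  expect_identical(
    vapply(buildPCLPairs(coh, 6L, 4L, seed = 3L), function(p) p@y, integer(1)),
    vapply(pairs, function(p) p@y, integer(1)))
  expect_error(buildPCLPairs(coh, 13L, 2L), "too large")
})

test_that("pretraining baselines beat chance on ordered chirps", {
  # a single global sweep makes window position frequency-coded, the
  # regime where segment order is recoverable from content
  p <- ChirpParams(nComponents = 4L, nTimepoints = 96L, nSegments = 1L,
                   seed = 12L)
  coh <- generateChirpCohort(60L, p)
  mc <- ModelConfig(inputSize = 4L, lstmHidden = 32L,
                    attentionHidden = 32L, decoderHidden = 16L)
  tc <- TrainConfig(maxEpochs = 150L, batchSize = 16L, seed = 2L)
  ocp <- pretrain("ocp", coh, mc, tc, pairsPerSubject = 6L)
  expect_gt(ocp$testAccuracy, 0.5)
  expect_error(pretrain("bogus", coh, mc, tc), "arg")
})
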