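# Pretext-task construction (time reversal and the OCP/PCL baselines),
# the Adam training loop with plateau scheduling and early stopping,
# stratified cross-validation, metrics, and weight transfer.

#' Reverse the time axis of a matrix
#'
#' Row t of the output is row T - t + 1 of the input (an involution); the
#' elementary transform behind the time-reversal pretext task.
#'
#' @param X T x N matrix.
#' @return the row-reversed matrix, same shape.
#' @examples
#' reverseTime(matrix(1:6, 3, 2))
#' @export
reverseTime <- function(X) {
  X <- as.matrix(X)
  X[rev(seq_len(nrow(X))), , drop = FALSE]
}

#' Build the balanced forward/reversed pretext dataset
#'
#' Every subject contributes its original matrix with label 0 and its
#' time-reversed matrix with label 1, so labels are exactly balanced.
#'
#' @param cohort a nonempty [Cohort-class].
#' @return list of [LabeledSequence-class], two per subject.
#' @export
buildTRDataset <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  if (nSubjects(cohort) == 0L) stop("cohort is empty")
  out <- vector("list", 2L * nSubjects(cohort))
  for (i in seq_len(nSubjects(cohort))) {
    s <- cohort@subjects[[i]]
    out[[2L * i - 1L]] <- LabeledSequence(s@values, 0L, s@subjectId)
    out[[2L * i]] <- LabeledSequence(reverseTime(s@values), 1L, s@subjectId)
  }
  out
}

#' Mean binary cross-entropy
#'
#' Probabilities are clamped to [1e-7, 1 - 1e-7] before the logarithm.
#'
#' @param y 0/1 vector.
#' @param yHat probability vector of the same length.
#' @return mean of -(y log yHat + (1 - y) log(1 - yHat)).
#' @export
bceLoss <- function(y, yHat) {
  stopifnot(length(y) == length(yHat))
  p <- pmin(pmax(yHat, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with mid-rank tie handling:
#' equals the fraction of (positive, negative) pairs ranked correctly,
#' counting ties as one half.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores real score vector.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified index split: returns validation indices, at least one and at
# most (class size - 1) per class.
.stratifiedVal <- function(y, fraction) {
  val <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    nv <- min(max(1L, round(fraction * length(idx))), length(idx) - 1L)
    val <- c(val, sample(idx)[seq_len(nv)])
  }
  sort(val)
}

#' Train a model with Adam, plateau scheduling, and early stopping
#'
#' A stratified validation split of size `valFraction` is carved from
#' `data`; minibatch Adam minimizes mean binary cross-entropy with decoder
#' dropout active; after every epoch the validation loss drives a
#' reduce-on-plateau learning-rate schedule and early stopping, and the
#' parameters with the best validation loss are kept. The whole run
#' (splits, shuffling, dropout) is a deterministic function of
#' `config@seed`.
#'
#' @param model a [TrainedModel-class] providing the initial parameters.
#' @param data nonempty list of [LabeledSequence-class] with equal-length
#'   sequences and both classes present.
#' @param config a [TrainConfig-class].
#' @return list with `model` (best-validation [TrainedModel-class]) and
#'   `history` (data.frame: epoch, trainLoss, trainAcc, valLoss, lr).
#' @export
trainModel <- function(model, data, config) {
  stopifnot(is(model, "TrainedModel"), is(config, "TrainConfig"),
            length(data) > 0L)
  y <- vapply(data, function(d) d@y, integer(1))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  Ts <- vapply(data, function(d) nrow(d@values), integer(1))
  if (length(unique(Ts)) != 1L)
    stop("all sequences must have the same length")
  cfg <- .cppConfig(model@config)
  if (ncol(data[[1L]]@values) != model@config@inputSize)
    stop("sequence width does not match model input size")

  arr <- .packBatch(lapply(data, function(d) d@values))
  D <- model@config@decoderHidden
  drop <- model@config@dropoutRate

  .localSeed(config@seed, {
    val <- .stratifiedVal(y, config@valFraction)
    trainIdx <- setdiff(seq_along(data), val)
    valArr <- arr[, val, , drop = FALSE]
    yVal <- y[val]

    params <- model@parameters
    mAdam <- vAdam <- lapply(params, function(p) p * 0)
    lr <- config@learningRate
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    bestVal <- Inf
    bestParams <- params
    badEs <- 0L; badSched <- 0L
    hist <- vector("list", config@maxEpochs)

    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(trainIdx)
      batchLoss <- numeric(0)
      correct <- 0L
      for (start in seq(1L, length(ord), by = config@batchSize)) {
        bidx <- ord[start:min(start + config@batchSize - 1L, length(ord))]
        dm <- if (drop > 0)
          matrix(stats::rbinom(D * length(bidx), 1L, 1 - drop), D,
                 length(bidx))
        else NULL
        r <- ta_loss_grad_cpp(params, cfg, arr[, bidx, , drop = FALSE],
                              y[bidx], dm)
        step <- step + 1L
        for (nm in names(r$grads)) {
          g <- r$grads[[nm]]
          mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g
          vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g * g
          mh <- mAdam[[nm]] / (1 - beta1^step)
          vh <- vAdam[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
        batchLoss <- c(batchLoss, r$loss)
        correct <- correct + sum((r$prob > 0.5) == (y[bidx] == 1L))
      }
      pVal <- ta_forward_cpp(params, cfg, valArr)$prob
      valLoss <- bceLoss(yVal, pVal)
      hist[[epoch]] <- data.frame(
        epoch = epoch, trainLoss = mean(batchLoss),
        trainAcc = correct / length(ord), valLoss = valLoss, lr = lr)
      if (valLoss < bestVal - config@minDelta) {
        bestVal <- valLoss
        bestParams <- params
        badEs <- 0L
        badSched <- 0L
      } else {
        badEs <- badEs + 1L
        badSched <- badSched + 1L
        if (badSched > config@schedulerPatience) {
          lr <- lr * config@schedulerFactor
          badSched <- 0L
        }
        if (badEs > config@earlyStopPatience) break
      }
    }
    trained <- new("TrainedModel", config = model@config,
                   parameters = bestParams, provenance = model@provenance)
    list(model = trained, history = do.call(rbind, hist[!vapply(
      hist, is.null, logical(1))]))
  })
}

#' Copy weights from a pretrained donor model
#'
#' Encoder and attention parameters are copied into a model with
#' `targetConfig`; the donor and target must agree on every
#' size-determining field. By default the decoder layers are re-drawn
#' Xavier-normal under `targetConfig@seed` (`reinitHead = TRUE`): the
#' pretext head is task-specific, and carrying its converged, saturated
#' logits into a new task starts fine-tuning from confidently wrong
#' predictions it recovers from poorly. Set `reinitHead = FALSE` to copy
#' the decoder too.
#'
#' @param donor a [TrainedModel-class].
#' @param targetConfig a structurally identical [ModelConfig-class].
#' @param reinitHead re-draw the decoder head (default) or copy it?
#' @return a [TrainedModel-class] with provenance `"pretrained:<donor>"`.
#' @export
transferWeights <- function(donor, targetConfig, reinitHead = TRUE) {
  stopifnot(is(donor, "TrainedModel"), is(targetConfig, "ModelConfig"))
  dc <- donor@config
  for (f in c("inputSize", "lstmHidden", "lstmLayers", "attentionHidden",
              "decoderHidden", "encoderKind"))
    if (!identical(slot(dc, f), slot(targetConfig, f)))
      stop("donor and target configs differ in '", f, "'")
  params <- donor@parameters
  if (reinitHead) {
    head <- .localSeed(targetConfig@seed, .drawDecoder(targetConfig))
    params[names(head)] <- head
  }
  new("TrainedModel", config = targetConfig, parameters = params,
      provenance = paste0("pretrained:", donor@provenance))
}

# Stratified fold assignment: a permutation within each class is dealt
# round-robin over folds, so every fold holds at least one subject of each
# class whenever nFolds <= class size.
.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[sample(idx)] <- rep(seq_len(nFolds), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Subjects are partitioned into `nFolds` label-stratified folds; for each
#' fold a model is initialized (fresh Xavier draw, or from `initFrom`
#' weights for transfer-learning evaluation), trained on the remaining
#' folds, and scored on the held-out fold.
#'
#' @param cohort a fully labeled [Cohort-class] with both classes present.
#' @param modelConfig a [ModelConfig-class] (input size must match).
#' @param trainConfig a [TrainConfig-class]; `nFolds` must not exceed the
#'   minority class size.
#' @param initFrom optional donor [TrainedModel-class]; per-fold training
#'   then starts from its weights via [transferWeights()].
#' @param reinitHead passed to [transferWeights()] when `initFrom` is used.
#' @return data.frame with one row per fold (fold, auc, accuracy,
#'   balancedAccuracy) carrying the per-fold training histories in
#'   `attr(, "histories")`.
#' @export
crossValidate <- function(cohort, modelConfig, trainConfig,
                          initFrom = NULL, reinitHead = TRUE) {
  y <- cohortLabels(cohort)
  if (anyNA(y)) stop("every subject must be labeled")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (trainConfig@nFolds > min(table(y)))
    stop("nFolds exceeds the minority class size")
  fold <- .localSeed(.deriveSeed(trainConfig@seed, 101L),
                     .stratifiedFolds(y, trainConfig@nFolds))
  rows <- vector("list", trainConfig@nFolds)
  histories <- vector("list", trainConfig@nFolds)
  for (f in seq_len(trainConfig@nFolds)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    dataTrain <- lapply(cohort@subjects[trainIdx], function(s)
      LabeledSequence(s@values, s@label, s@subjectId))
    foldSeed <- .deriveSeed(trainConfig@seed, f)
    model0 <- if (is.null(initFrom)) {
      cfgF <- modelConfig
      cfgF@seed <- foldSeed
      initModel(cfgF)
    } else {
      transferWeights(initFrom, modelConfig, reinitHead = reinitHead)
    }
    cfgT <- trainConfig
    cfgT@seed <- foldSeed
    fit <- trainModel(model0, dataTrain, cfgT)
    probs <- .predictBatch(fit$model,
                           lapply(cohort@subjects[testIdx],
                                  function(s) s@values))
    yTest <- y[testIdx]
    pred <- as.integer(probs > 0.5)
    rec <- vapply(c(0L, 1L), function(cls)
      mean(pred[yTest == cls] == cls), numeric(1))
    rows[[f]] <- data.frame(
      fold = f, auc = aucScore(yTest, probs),
      accuracy = mean(pred == yTest), balancedAccuracy = mean(rec))
    histories[[f]] <- fit$history
  }
  out <- do.call(rbind, rows)
  attr(out, "histories") <- histories
  out
}

#' Order-contrastive pretraining pairs
#'
#' Per subject, `pairsPerSubject` pairs of non-overlapping equal-length
#' segments are drawn with the first segment strictly preceding the second
#' in time; `floor(pairsPerSubject / 2)` of them are presented
#' order-switched with label 0, the rest in correct order with label 1.
#'
#' @param cohort a [Cohort-class].
#' @param segmentLen segment length L with 2L <= T.
#' @param pairsPerSubject pairs drawn per subject.
#' @param seed RNG seed.
#' @return list of [PairExample-class].
#' @export
buildOCPPairs <- function(cohort, segmentLen, pairsPerSubject, seed = 0L) {
  Tn <- nTimepoints(cohort)
  L <- as.integer(segmentLen)
  if (2L * L > Tn) stop("segmentLen too large: need 2 * segmentLen <= T")
  .localSeed(seed, {
    out <- list()
    for (s in cohort@subjects) {
      nNeg <- pairsPerSubject %/% 2L
      for (j in seq_len(pairsPerSubject)) {
        sa <- sample.int(Tn - 2L * L + 1L, 1L)
        cand <- seq(sa + L, Tn - L + 1L)
        sb <- cand[sample.int(length(cand), 1L)]
        early <- s@values[sa:(sa + L - 1L), , drop = FALSE]
        late <- s@values[sb:(sb + L - 1L), , drop = FALSE]
        out[[length(out) + 1L]] <- if (j <= nNeg)
          new("PairExample", segmentA = late, segmentB = early, y = 0L,
              originId = s@subjectId)
        else
          new("PairExample", segmentA = early, segmentB = late, y = 1L,
              originId = s@subjectId)
      }
    }
    out
  })
}

#' Permutation-contrastive learning pairs
#'
#' Positives are consecutive windows in correct order (the second window
#' starts exactly `windowLen` after the first); negatives are two windows
#' drawn uniformly at random from the same trajectory with distinct starts
#' and no order constraint, so a negative may still be correctly ordered
#' (the deliberate contrast with OCP).
#'
#' @inheritParams buildOCPPairs
#' @param windowLen window length L with 2L <= T.
#' @return list of [PairExample-class].
#' @export
buildPCLPairs <- function(cohort, windowLen, pairsPerSubject, seed = 0L) {
  Tn <- nTimepoints(cohort)
  L <- as.integer(windowLen)
  if (2L * L > Tn) stop("windowLen too large: need 2 * windowLen <= T")
  .localSeed(seed, {
    out <- list()
    for (s in cohort@subjects) {
      nPos <- pairsPerSubject - pairsPerSubject %/% 2L
      for (j in seq_len(pairsPerSubject)) {
        if (j <= nPos) {
          sa <- sample.int(Tn - 2L * L + 1L, 1L)
          sb <- sa + L
          yj <- 1L
        } else {
          repeat {
            sa <- sample.int(Tn - L + 1L, 1L)
            sb <- sample.int(Tn - L + 1L, 1L)
            if (sa != sb) break
          }
          yj <- 0L
        }
        out[[length(out) + 1L]] <- new("PairExample",
          segmentA = s@values[sa:(sa + L - 1L), , drop = FALSE],
          segmentB = s@values[sb:(sb + L - 1L), , drop = FALSE],
          y = yj, originId = s@subjectId)
      }
    }
    out
  })
}

.pairsToSequences <- function(pairs) {
  lapply(pairs, function(p)
    LabeledSequence(rbind(p@segmentA, p@segmentB), p@y, p@originId))
}

#' Self-supervised pretraining with a held-out evaluation split
#'
#' Splits the cohort at subject level (so a subject's forward and reversed
#' copies, or its segment pairs, never straddle the split), builds the
#' pretext dataset of the chosen method, trains the model, and reports
#' accuracy on the held-out pretext examples.
#'
#' Methods: `"tr"` classifies forward versus time-reversed whole sequences;
#' `"ocp"` and `"pcl"` classify the order of segment pairs presented to the
#' same architecture as the time-axis concatenation of the two segments.
#'
#' @param method one of "tr", "ocp", "pcl".
#' @param cohort a [Cohort-class].
#' @param modelConfig a [ModelConfig-class] matching the cohort width.
#' @param trainConfig a [TrainConfig-class]; its seed also fixes the
#'   subject split.
#' @param testFraction held-out subject fraction.
#' @param segmentLen segment/window length for ocp/pcl; default
#'   `floor(T / 4)`.
#' @param pairsPerSubject pairs per subject for ocp/pcl.
#' @return list with `model` (provenance set to the method name),
#'   `testAccuracy`, `history`, and `testSubjects` (ids of the held-out
#'   subjects).
#' @export
pretrain <- function(method = c("tr", "ocp", "pcl"), cohort, modelConfig,
                     trainConfig = TrainConfig(), testFraction = 0.2,
                     segmentLen = NULL, pairsPerSubject = 2L) {
  method <- match.arg(method)
  stopifnot(is(cohort, "Cohort"))
  if (modelConfig@inputSize != nComponents(cohort))
    stop("modelConfig input size does not match the cohort")
  n <- nSubjects(cohort)
  testIdx <- .localSeed(.deriveSeed(trainConfig@seed, 977L),
                        sort(sample.int(n, max(1L, floor(testFraction * n)))))
  testCoh <- Cohort(cohort@name, cohort@subjects[testIdx])
  trainCoh <- Cohort(cohort@name, cohort@subjects[-testIdx])
  makeData <- function(coh) {
    if (method == "tr") return(buildTRDataset(coh))
    L <- if (is.null(segmentLen)) nTimepoints(coh) %/% 4L
         else as.integer(segmentLen)
    pairSeed <- .deriveSeed(trainConfig@seed, 431L)
    pairs <- if (method == "ocp")
      buildOCPPairs(coh, L, pairsPerSubject, pairSeed)
    else buildPCLPairs(coh, L, pairsPerSubject, pairSeed)
    .pairsToSequences(pairs)
  }
  fit <- trainModel(initModel(modelConfig), makeData(trainCoh), trainConfig)
  testData <- makeData(testCoh)
  probs <- .predictBatch(fit$model, lapply(testData, function(d) d@values))
  yTest <- vapply(testData, function(d) d@y, integer(1))
  model <- fit$model
  model@provenance <- method
  list(model = model, testAccuracy = mean((probs > 0.5) == (yTest == 1L)),
       history = fit$history,
       testSubjects = vapply(testCoh@subjects, subjectId, character(1)))
}
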