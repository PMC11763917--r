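#' @import methods
NULL

#' One subject's multivariate time course
#'
#' A single subject's T x N real matrix of time courses (rows are time
#' points, columns are components, e.g. ICA time courses from resting-state
#' fMRI), together with a subject identifier and an optional binary label
#' (1 = patient, 0 = control in downstream tasks).
#'
#' @slot subjectId single non-empty character identifier.
#' @slot values numeric matrix, T x N, all entries finite, T >= 2, N >= 1.
#' @slot label integer of length 0 (unlabeled) or 1 with value 0 or 1.
#'
#' @seealso [SubjectTimeSeries()] for the constructor, [Cohort-class]
#' @export
setClass("SubjectTimeSeries",
  slots = c(subjectId = "character", values = "matrix", label = "integer"))

setValidity("SubjectTimeSeries", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "'subjectId' must be a single non-empty string")
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  else if (!all(is.finite(v)))
    msg <- c(msg, "'values' must contain only finite entries")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 time points (rows)")
  if (ncol(v) < 1L) msg <- c(msg, "need at least 1 component (column)")
  if (length(object@label) > 1L || (length(object@label) == 1L &&
      !object@label %in% c(0L, 1L)))
    msg <- c(msg, "'label' must be absent or a single 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectTimeSeries
#'
#' @param subjectId single character identifier.
#' @param values T x N numeric matrix, rows = time points.
#' @param label optional 0/1 label; `NULL` for unlabeled subjects.
#' @return a [SubjectTimeSeries-class] object.
#' @examples
#' sts <- SubjectTimeSeries("s1", matrix(rnorm(20), 10, 2), label = 1)
#' @export
SubjectTimeSeries <- function(subjectId, values, label = NULL) {
  new("SubjectTimeSeries", subjectId = as.character(subjectId),
      values = as.matrix(values),
      label = if (is.null(label) || length(label) == 0L) integer(0)
              else as.integer(label))
}

#' A cohort of subjects with common dimensions
#'
#' An ordered collection of [SubjectTimeSeries-class] objects sharing the
#' same number of time points and components, with unique subject
#' identifiers. The `metadata` slot carries free-form generator provenance
#' (for synthetic cohorts, e.g. injected event positions).
#'
#' @slot name cohort name.
#' @slot subjects list of [SubjectTimeSeries-class].
#' @slot nComponents,nTimepoints common matrix dimensions.
#' @slot metadata free-form list.
#' @export
setClass("Cohort",
  slots = c(name = "character", subjects = "list",
            nComponents = "integer", nTimepoints = "integer",
            metadata = "list"))

setValidity("Cohort", function(object) {
  msg <- character()
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  ok <- vapply(object@subjects, is, logical(1), "SubjectTimeSeries")
  if (!all(ok)) {
    msg <- c(msg, "all subjects must be SubjectTimeSeries objects")
  } else if (length(object@subjects)) {
    dims <- vapply(object@subjects, function(s) dim(s@values), integer(2))
    if (any(dims[1L, ] != object@nTimepoints) ||
        any(dims[2L, ] != object@nComponents))
      msg <- c(msg, "all subject matrices must be nTimepoints x nComponents")
    ids <- vapply(object@subjects, function(s) s@subjectId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate subject ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Cohort
#'
#' Dimensions are taken from the first subject and validated against the
#' rest; an empty subject list requires explicit dimensions.
#'
#' @param name cohort name.
#' @param subjects list of [SubjectTimeSeries-class].
#' @param nTimepoints,nComponents required only when `subjects` is empty.
#' @param metadata optional provenance list.
#' @return a [Cohort-class] object.
#' @export
Cohort <- function(name, subjects, nTimepoints = NULL, nComponents = NULL,
                   metadata = list()) {
  if (length(subjects)) {
    nTimepoints <- nrow(subjects[[1L]]@values)
    nComponents <- ncol(subjects[[1L]]@values)
  } else if (is.null(nTimepoints) || is.null(nComponents)) {
    stop("an empty cohort needs explicit nTimepoints and nComponents")
  }
  new("Cohort", name = as.character(name), subjects = unname(subjects),
      nComponents = as.integer(nComponents),
      nTimepoints = as.integer(nTimepoints), metadata = metadata)
}

#' A (sequence, binary label) training example
#'
#' @slot values T x N numeric matrix.
#' @slot y integer 0/1 label (1 = time-reversed in the pretext task,
#'   1 = patient downstream).
#' @slot originId identifier of the subject the sequence came from.
#' @export
setClass("LabeledSequence",
  slots = c(values = "matrix", y = "integer", originId = "character"))

setValidity("LabeledSequence", function(object) {
  if (!object@y %in% c(0L, 1L)) "y must be 0 or 1" else TRUE
})

#' @rdname LabeledSequence-class
#' @param values,y,originId see slots.
#' @export
LabeledSequence <- function(values, y, originId = "") {
  new("LabeledSequence", values = as.matrix(values), y = as.integer(y),
      originId = as.character(originId))
}

#' A pair of same-length segments with an order label
#'
#' Used by the order-contrastive (OCP) and permutation-contrastive (PCL)
#' pretraining baselines: `y = 1` when the presented order of the two
#' segments is a positive example for the pretext task, `y = 0` otherwise.
#'
#' @slot segmentA,segmentB L x N numeric matrices from the same subject.
#' @slot y integer 0/1.
#' @slot originId source subject id.
#' @export
setClass("PairExample",
  slots = c(segmentA = "matrix", segmentB = "matrix", y = "integer",
            originId = "character"))

setValidity("PairExample", function(object) {
  msg <- character()
  if (!identical(dim(object@segmentA), dim(object@segmentB)))
    msg <- c(msg, "segments must have identical dimensions")
  if (!object@y %in% c(0L, 1L)) msg <- c(msg, "y must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic chirp cohort generator
#'
#' Each component of each subject is a concatenation of `nSegments` linear
#' up-chirp segments: within a segment of length L the signal is
#' sin(2*pi*phi(u) * L/T) with phase phi(u) = f0*u + (f1 - f0)*u^2/2 over
#' normalized segment time u in [0, 1), so the instantaneous frequency
#' rises linearly from f0 to f1, both expressed in cycles per full
#' sequence. f0 and f1 are drawn uniformly per segment from `f0Range` and
#' `f1Range`, redrawing until f1 > f0. Additive white Gaussian noise of
#' standard deviation `noiseSd` is applied. Concatenating several chirps
#' plants frequency-reset landmarks throughout the sequence instead of a
#' single low-frequency region at one end, which is what makes the
#' forward and reverse saliency of an arrow-of-time model comparable
#' position by position.
#'
#' @slot nComponents,nTimepoints cohort dimensions (53 x 1200 mirrors the
#'   ICA time-course dimensions the generator is scaled after).
#' @slot nSegments chirps concatenated per component.
#' @slot f0Range,f1Range start/end frequency ranges, cycles per sequence.
#' @slot noiseSd Gaussian noise standard deviation.
#' @slot seed base seed; per-subject seeds are derived deterministically.
#' @export
setClass("ChirpParams",
  slots = c(nComponents = "integer", nTimepoints = "integer",
            nSegments = "integer", f0Range = "numeric", f1Range = "numeric",
            noiseSd = "numeric", seed = "integer"))

setValidity("ChirpParams", function(object) {
  msg <- character()
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  if (object@nSegments < 1L) msg <- c(msg, "nSegments must be >= 1")
  if (length(object@f0Range) != 2L || length(object@f1Range) != 2L)
    msg <- c(msg, "frequency ranges must have length 2")
  else {
    if (object@f0Range[1L] < 0) msg <- c(msg, "f0Range low must be >= 0")
    if (diff(object@f0Range) < 0 || diff(object@f1Range) < 0)
      msg <- c(msg, "frequency ranges must be (low, high)")
    if (object@f1Range[2L] <= object@f0Range[1L])
      msg <- c(msg, "f1Range high must exceed f0Range low (up-chirp)")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @rdname ChirpParams-class
#' @param nComponents,nTimepoints,nSegments,f0Range,f1Range,noiseSd,seed
#'   see slots.
#' @export
ChirpParams <- function(nComponents = 53L, nTimepoints = 1200L,
                        nSegments = 4L, f0Range = c(1, 5),
                        f1Range = c(20, 60), noiseSd = 0.1, seed = 0L) {
  new("ChirpParams", nComponents = as.integer(nComponents),
      nTimepoints = as.integer(nTimepoints), nSegments = as.integer(nSegments),
      f0Range = as.numeric(f0Range), f1Range = as.numeric(f1Range),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Parameters of the two-class episodic synthetic cohort
#'
#' Controls are AR(1) noise per component; patients share that baseline but
#' carry `nEvents` transient boxcar events of length `eventLength` and
#' height `eventAmplitude`, added to the first `affectedComponents`
#' components at patient-specific, non-overlapping random onsets. This
#' emulates a disorder whose class-discriminative activity is episodic and
#' temporally localized.
#'
#' @slot nPatients,nControls class sizes.
#' @slot nComponents,nTimepoints matrix dimensions.
#' @slot arCoefficient AR(1) coefficient in [0, 1).
#' @slot baseNoiseSd innovation standard deviation (> 0).
#' @slot nEvents,eventLength,eventAmplitude event structure.
#' @slot affectedComponents how many leading components carry events.
#' @slot seed generator seed.
#' @export
setClass("EpisodicCohortParams",
  slots = c(nPatients = "integer", nControls = "integer",
            nComponents = "integer", nTimepoints = "integer",
            arCoefficient = "numeric", baseNoiseSd = "numeric",
            nEvents = "integer", eventLength = "integer",
            eventAmplitude = "numeric", affectedComponents = "integer",
            seed = "integer"))

setValidity("EpisodicCohortParams", function(object) {
  msg <- character()
  if (object@nPatients < 0L || object@nControls < 0L)
    msg <- c(msg, "class sizes must be nonnegative")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msg <- c(msg, "arCoefficient must be in [0, 1)")
  if (object@baseNoiseSd <= 0) msg <- c(msg, "baseNoiseSd must be positive")
  if (object@nEvents * object@eventLength > object@nTimepoints)
    msg <- c(msg, "nEvents * eventLength must not exceed nTimepoints")
  if (object@affectedComponents > object@nComponents)
    msg <- c(msg, "affectedComponents must not exceed nComponents")
  if (length(msg)) msg else TRUE
})

#' @rdname EpisodicCohortParams-class
#' @param nPatients,nControls,nComponents,nTimepoints,arCoefficient,
#'   baseNoiseSd,nEvents,eventLength,eventAmplitude,affectedComponents,seed
#'   see slots.
#' @export
EpisodicCohortParams <- function(nPatients = 20L, nControls = 20L,
                                 nComponents = 8L, nTimepoints = 120L,
                                 arCoefficient = 0.5, baseNoiseSd = 1,
                                 nEvents = 3L, eventLength = 10L,
                                 eventAmplitude = 2,
                                 affectedComponents = 3L, seed = 0L) {
  new("EpisodicCohortParams", nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), nComponents = as.integer(nComponents),
      nTimepoints = as.integer(nTimepoints),
      arCoefficient = as.numeric(arCoefficient),
      baseNoiseSd = as.numeric(baseNoiseSd), nEvents = as.integer(nEvents),
      eventLength = as.integer(eventLength),
      eventAmplitude = as.numeric(eventAmplitude),
      affectedComponents = as.integer(affectedComponents),
      seed = as.integer(seed))
}

#' Architecture configuration of the recurrent attention classifier
#'
#' @slot inputSize number of input components N.
#' @slot lstmHidden,lstmLayers encoder hidden width and depth.
#' @slot attentionHidden width of the additive attention hidden layer.
#' @slot decoderHidden width of the decoder hidden layer.
#' @slot dropoutRate decoder dropout probability in [0, 1).
#' @slot useAttention if `FALSE` the context vector is the last hidden
#'   state (ablation path).
#' @slot encoderKind "lstm" (default) or "gru" (ablation path).
#' @slot seed initialization seed.
#' @export
setClass("ModelConfig",
  slots = c(inputSize = "integer", lstmHidden = "integer",
            lstmLayers = "integer", attentionHidden = "integer",
            decoderHidden = "integer", dropoutRate = "numeric",
            useAttention = "logical", encoderKind = "character",
            seed = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  sizes <- c(object@inputSize, object@lstmHidden, object@lstmLayers,
             object@attentionHidden, object@decoderHidden)
  if (any(sizes < 1L)) msg <- c(msg, "all sizes must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!object@encoderKind %in% c("lstm", "gru"))
    msg <- c(msg, "encoderKind must be 'lstm' or 'gru'")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelConfig-class
#' @param inputSize,lstmHidden,lstmLayers,attentionHidden,decoderHidden,
#'   dropoutRate,useAttention,encoderKind,seed see slots.
#' @export
ModelConfig <- function(inputSize, lstmHidden = 64L, lstmLayers = 1L,
                        attentionHidden = 64L, decoderHidden = 32L,
                        dropoutRate = 0.3, useAttention = TRUE,
                        encoderKind = c("lstm", "gru"), seed = 1L) {
  new("ModelConfig", inputSize = as.integer(inputSize),
      lstmHidden = as.integer(lstmHidden), lstmLayers = as.integer(lstmLayers),
      attentionHidden = as.integer(attentionHidden),
      decoderHidden = as.integer(decoderHidden),
      dropoutRate = as.numeric(dropoutRate),
      useAttention = isTRUE(useAttention),
      encoderKind = match.arg(encoderKind), seed = as.integer(seed))
}

#' Optimization configuration
#'
#' Defaults follow the training protocol of the method: Adam at learning
#' rate 7e-4, batch size 32, at most 1000 epochs with early stopping on
#' validation loss, a reduce-on-plateau learning-rate scheduler, and
#' 10-fold cross-validation for downstream evaluation.
#'
#' @slot learningRate Adam learning rate (> 0).
#' @slot batchSize minibatch size.
#' @slot maxEpochs epoch cap.
#' @slot earlyStopPatience epochs without validation improvement tolerated
#'   before stopping.
#' @slot minDelta smallest validation-loss decrease that counts as an
#'   improvement for early stopping and the scheduler.
#' @slot schedulerFactor,schedulerPatience reduce-on-plateau settings.
#' @slot nFolds number of cross-validation folds (>= 2).
#' @slot valFraction fraction of training data held out for validation.
#' @slot seed seed governing splits, shuffling, and dropout.
#' @export
setClass("TrainConfig",
  slots = c(learningRate = "numeric", batchSize = "integer",
            maxEpochs = "integer", earlyStopPatience = "integer",
            minDelta = "numeric", schedulerFactor = "numeric",
            schedulerPatience = "integer", nFolds = "integer",
            valFraction = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param learningRate,batchSize,maxEpochs,earlyStopPatience,minDelta,
#'   schedulerFactor,schedulerPatience,nFolds,valFraction,seed see slots.
#' @export
TrainConfig <- function(learningRate = 7e-4, batchSize = 32L,
                        maxEpochs = 1000L, earlyStopPatience = 50L,
                        minDelta = 1e-4, schedulerFactor = 0.5,
                        schedulerPatience = 20L,
                        nFolds = 10L, valFraction = 0.2, seed = 1L) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      minDelta = as.numeric(minDelta),
      schedulerFactor = as.numeric(schedulerFactor),
      schedulerPatience = as.integer(schedulerPatience),
      nFolds = as.integer(nFolds), valFraction = as.numeric(valFraction),
      seed = as.integer(seed))
}

#' A trained (or freshly initialized) model
#'
#' @slot config the [ModelConfig-class] the parameters realize.
#' @slot parameters named list of weight matrices and bias vectors.
#' @slot provenance "scratch", a pretext-task tag (e.g. "tr"), or
#'   "pretrained:<tag>" after weight transfer.
#' @export
setClass("TrainedModel",
  slots = c(config = "ModelConfig", parameters = "list",
            provenance = "character"))

#' Output of a single forward pass
#'
#' @slot probability predicted probability of the positive class, in (0, 1).
#' @slot attentionWeights length-T softmax weights over time points.
#' @slot context attention-weighted context vector.
#' @export
setClass("ForwardOutput",
  slots = c(probability = "numeric", attentionWeights = "numeric",
            context = "numeric"))

#' An attribution (saliency) map for one subject
#'
#' @slot subjectId source subject.
#' @slot attributions T x N integrated-gradients attribution matrix.
#' @slot direction "forward" or "reverse": the temporal order of the input
#'   the map was computed on.
#' @slot aligned `TRUE` once the map is in forward time order (forward maps
#'   are born aligned; reverse maps become aligned via
#'   [flipTimeSaliency()]).
#' @export
setClass("SaliencyMap",
  slots = c(subjectId = "character", attributions = "matrix",
            direction = "character", aligned = "logical"))

setValidity("SaliencyMap", function(object) {
  msg <- character()
  if (!all(is.finite(object@attributions)))
    msg <- c(msg, "attributions must be finite")
  if (!object@direction %in% c("forward", "reverse"))
    msg <- c(msg, "direction must be 'forward' or 'reverse'")
  if (length(msg)) msg else TRUE
})

#' A probability distribution over time points
#'
#' The time marginal of masked absolute saliency, normalized to unit mass;
#' the object fed to the Earth Mover's Distance. A degenerate (all-zero
#' before normalization) marginal is flagged rather than normalized.
#'
#' @slot mass length-T nonnegative vector summing to 1 (unless degenerate).
#' @slot degenerate flag for the all-zero case.
#' @export
setClass("TimeDistribution",
  slots = c(mass = "numeric", degenerate = "logical"))

setValidity("TimeDistribution", function(object) {
  if (any(object@mass < 0)) return("mass must be nonnegative")
  if (!object@degenerate && abs(sum(object@mass) - 1) > 1e-9)
    return("mass must sum to 1")
  TRUE
})

#' @rdname TimeDistribution-class
#' @param mass nonnegative vector; normalized to unit mass unless all zero.
#' @export
TimeDistribution <- function(mass) {
  mass <- as.numeric(mass)
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("mass must be finite and nonnegative")
  s <- sum(mass)
  if (s == 0) return(new("TimeDistribution", mass = mass, degenerate = TRUE))
  new("TimeDistribution", mass = mass / s, degenerate = FALSE)
}
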