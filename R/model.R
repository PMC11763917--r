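# Model construction and single-pass inference. The parameter container is
# a named list understood by the C++ routines: per encoder layer l,
# Wi<l> (gates x input), Wh<l> (gates x hidden), b<l>; attention Wa1, ba1,
# wa2, ba2; decoder Wd1, bd1, wd2, bd2. Gate blocks are stacked i,f,g,o for
# the LSTM and r,z,n for the GRU.

.cppConfig <- function(config) {
  list(input_size = config@inputSize, hidden = config@lstmHidden,
       layers = config@lstmLayers, att_hidden = config@attentionHidden,
       dec_hidden = config@decoderHidden, dropout = config@dropoutRate,
       use_attention = config@useAttention, encoder = config@encoderKind)
}

# Pack a list of T x N matrices into the (N, B, T) cube the C++ side expects.
.packBatch <- function(xlist) {
  Tn <- nrow(xlist[[1L]])
  N <- ncol(xlist[[1L]])
  arr <- array(0, c(N, length(xlist), Tn))
  for (b in seq_along(xlist)) arr[, b, ] <- t(xlist[[b]])
  arr
}

.xavierNormal <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / (nrow + ncol))), nrow, ncol)
}

.drawDecoder <- function(config) {
  H <- config@lstmHidden
  D <- config@decoderHidden
  list(Wd1 = .xavierNormal(D, H), bd1 = numeric(D),
       wd2 = drop(.xavierNormal(1L, D)), bd2 = 0)
}

.drawParameters <- function(config) {
  H <- config@lstmHidden
  A <- config@attentionHidden
  gmul <- if (config@encoderKind == "gru") 3L else 4L
  p <- list()
  for (l in seq_len(config@lstmLayers)) {
    inp <- if (l == 1L) config@inputSize else H
    p[[paste0("Wi", l)]] <- .xavierNormal(gmul * H, inp)
    p[[paste0("Wh", l)]] <- .xavierNormal(gmul * H, H)
    p[[paste0("b", l)]] <- numeric(gmul * H)
  }
  p$Wa1 <- .xavierNormal(A, 2L * H)
  p$ba1 <- numeric(A)
  p$wa2 <- drop(.xavierNormal(1L, A))
  p$ba2 <- 0
  c(p, .drawDecoder(config))
}

#' Initialize a model with Xavier-normal weights
#'
#' All weight matrices are drawn from N(0, 2 / (fan_in + fan_out)) under
#' `config@seed`; all biases start at zero. The draw is deterministic given
#' the seed.
#'
#' @param config a [ModelConfig-class].
#' @return a [TrainedModel-class] with provenance `"scratch"`.
#' @examples
#' m <- initModel(ModelConfig(inputSize = 8, lstmHidden = 16))
#' @export
initModel <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  params <- .localSeed(config@seed, .drawParameters(config))
  new("TrainedModel", config = config, parameters = params,
      provenance = "scratch")
}

#' Concatenation attention over hidden states
#'
#' The last hidden state is concatenated with every hidden state; two
#' linear layers with a tanh in between score each time point, a softmax
#' yields the attention weights, and the context vector is the
#' weight-averaged hidden state:
#' `score_t = w2' tanh(W1 [h_t; h_T] + b1) + b2`.
#'
#' @param model a [TrainedModel-class] providing the attention parameters.
#' @param hiddenStates T x d matrix of encoder hidden states (rows = time).
#' @param lastState length-d vector; defaults to the last row.
#' @return a list with `weights` (length T, on the simplex) and `context`
#'   (length d).
#' @export
attend <- function(model, hiddenStates, lastState = NULL) {
  hiddenStates <- as.matrix(hiddenStates)
  stopifnot(nrow(hiddenStates) >= 1L)
  if (is.null(lastState)) lastState <- hiddenStates[nrow(hiddenStates), ]
  p <- model@parameters
  Z <- cbind(hiddenStates,
             matrix(lastState, nrow(hiddenStates), length(lastState),
                    byrow = TRUE))
  U <- tanh(tcrossprod(Z, p$Wa1) + matrix(p$ba1, nrow(Z), length(p$ba1),
                                          byrow = TRUE))
  scores <- drop(U %*% p$wa2) + p$ba2
  e <- exp(scores - max(scores))
  w <- e / sum(e)
  list(weights = w, context = drop(crossprod(hiddenStates, w)))
}

#' Single-subject forward pass (evaluation mode)
#'
#' Runs encoder, attention and decoder on one T x N matrix with dropout
#' disabled, so the output is a deterministic function of the parameters
#' and the input.
#'
#' @param model a [TrainedModel-class].
#' @param X T x N numeric matrix with `N == inputSize`.
#' @return a [ForwardOutput-class].
#' @export
forwardPass <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model@config@inputSize)
    stop(sprintf("input has %d columns, model expects %d", ncol(X),
                 model@config@inputSize))
  out <- ta_forward_cpp(model@parameters, .cppConfig(model@config),
                        .packBatch(list(X)))
  new("ForwardOutput", probability = out$prob[1L],
      attentionWeights = drop(out$attention),
      context = drop(out$context))
}

# Batched evaluation-mode probabilities for a list of equal-shape matrices,
# chunked to bound cache memory.
.predictBatch <- function(model, xlist, chunk = 64L) {
  cfg <- .cppConfig(model@config)
  probs <- numeric(length(xlist))
  for (start in seq(1L, length(xlist), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(xlist))
    out <- ta_forward_cpp(model@parameters, cfg, .packBatch(xlist[idx]))
    probs[idx] <- out$prob
  }
  probs
}
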