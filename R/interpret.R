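# Post hoc explainability: integrated-gradients saliency, forward/reverse
# flip alignment, top-fraction masking, time marginals, EMD spikiness, and
# submodular pick of representative subjects.

# Midpoint-rule path integral: gradFn takes a list of T x N interpolants
# and returns the corresponding list of T x N gradient matrices of the
# scalar output of interest.
.igCore <- function(gradFn, X, baseline, steps, chunk = 64L) {
  diffX <- X - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  gsum <- matrix(0, nrow(X), ncol(X))
  for (start in seq(1L, steps, by = chunk)) {
    ak <- alphas[start:min(start + chunk - 1L, steps)]
    grads <- gradFn(lapply(ak, function(a) baseline + a * diffX))
    gsum <- gsum + Reduce(`+`, grads)
  }
  diffX * (gsum / steps)
}

#' Integrated-gradients saliency map
#'
#' Path-integral attribution along the straight line from `baseline` to
#' `X`, with the midpoint Riemann rule:
#' `IG[t, n] = (X - baseline)[t, n] * mean_k dF/dx[t, n]` evaluated at
#' `baseline + (k - 0.5) / steps * (X - baseline)`, where F is the model's
#' sigmoid output probability. By the completeness axiom the attributions
#' sum to F(X) - F(baseline) as `steps` grows.
#'
#' @param model a [TrainedModel-class].
#' @param X T x N input matrix.
#' @param baseline T x N baseline matrix; default all zeros (a neutral
#'   reference for roughly centered ICA time courses).
#' @param steps number of Riemann steps (>= 1); 64 keeps the completeness
#'   gap small at this model scale.
#' @param direction tag recording whether `X` was in forward or reverse
#'   temporal order (reverse maps start unaligned; see
#'   [flipTimeSaliency()]).
#' @param subjectId identifier stored on the map.
#' @return a [SaliencyMap-class].
#' @export
integratedGradients <- function(model, X, baseline = NULL, steps = 64L,
                                direction = c("forward", "reverse"),
                                subjectId = "") {
  direction <- match.arg(direction)
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  X <- as.matrix(X)
  if (is.null(baseline)) baseline <- matrix(0, nrow(X), ncol(X))
  baseline <- as.matrix(baseline)
  stopifnot(identical(dim(X), dim(baseline)))
  if (ncol(X) != model@config@inputSize)
    stop("input width does not match the model")
  cfg <- .cppConfig(model@config)
  gradFn <- function(xs) {
    g <- ta_input_grad_cpp(model@parameters, cfg, .packBatch(xs))$grad
    lapply(seq_along(xs), function(b)
      t(matrix(g[, b, ], nrow = dim(g)[1L])))
  }
  new("SaliencyMap", subjectId = as.character(subjectId),
      attributions = .igCore(gradFn, X, baseline, steps),
      direction = direction, aligned = direction == "forward")
}

#' Align a reverse-input saliency map with forward time
#'
#' Reverses the time axis of a map computed on reverse-ordered input, so
#' salient features can be compared positionally with the forward map.
#' Refuses forward maps and maps that are already aligned.
#'
#' @param S a [SaliencyMap-class] with `direction == "reverse"`, not yet
#'   aligned.
#' @return the row-reversed map with `aligned = TRUE`.
#' @export
flipTimeSaliency <- function(S) {
  stopifnot(is(S, "SaliencyMap"))
  if (S@direction != "reverse")
    stop("only reverse-direction maps can be flipped")
  if (S@aligned) stop("map is already aligned")
  new("SaliencyMap", subjectId = S@subjectId,
      attributions = reverseTime(S@attributions), direction = "reverse",
      aligned = TRUE)
}

#' Forward/reverse alignment correlation
#'
#' Pearson correlation between the flattened absolute attributions of a
#' forward map and an aligned (flipped) reverse map of the same subject; a
#' high value indicates that the features driving the arrow-of-time
#' decision occupy the same time points in both input orientations.
#'
#' @param Sf forward [SaliencyMap-class].
#' @param Sr aligned reverse [SaliencyMap-class] of the same subject.
#' @param signed correlate signed instead of absolute attributions.
#' @return correlation in [-1, 1].
#' @export
alignmentCorrelation <- function(Sf, Sr, signed = FALSE) {
  stopifnot(is(Sf, "SaliencyMap"), is(Sr, "SaliencyMap"))
  if (Sf@direction != "forward") stop("Sf must be a forward map")
  if (Sr@direction != "reverse" || !Sr@aligned)
    stop("Sr must be an aligned reverse map")
  if (!identical(Sf@subjectId, Sr@subjectId))
    stop("maps belong to different subjects")
  if (!identical(dim(Sf@attributions), dim(Sr@attributions)))
    stop("maps have different shapes")
  a <- as.vector(Sf@attributions)
  b <- as.vector(Sr@attributions)
  if (!signed) {
    a <- abs(a)
    b <- abs(b)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero-variance attribution map")
  stats::cor(a, b)
}

#' Mask of the top fraction of salient entries
#'
#' Selects the `k = ceiling(fraction * T * N)` entries of largest absolute
#' attribution; ties at the cutoff are broken by earlier time index, then
#' lower component index, so exactly k entries are kept.
#'
#' @param S a [SaliencyMap-class].
#' @param fraction in (0, 1]; 0.05 reproduces the top-5% convention.
#' @return logical T x N matrix with exactly k `TRUE` entries.
#' @export
topFractionMask <- function(S, fraction = 0.05) {
  stopifnot(is(S, "SaliencyMap"), fraction > 0, fraction <= 1)
  v <- abs(S@attributions)
  k <- ceiling(fraction * length(v))
  ord <- order(-as.vector(v), as.vector(row(v)), as.vector(col(v)))
  mask <- matrix(FALSE, nrow(v), ncol(v))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Time marginal of masked saliency
#'
#' Sums the masked absolute attributions over components at each time
#' point and normalizes to a unit-mass [TimeDistribution-class]; an
#' all-zero masked sum yields a degenerate (flagged, unnormalized)
#' distribution.
#'
#' @param S a [SaliencyMap-class].
#' @param mask logical matrix of the same shape (e.g. from
#'   [topFractionMask()]).
#' @return a [TimeDistribution-class] of length T.
#' @export
timeMarginal <- function(S, mask) {
  stopifnot(is(S, "SaliencyMap"),
            identical(dim(mask), dim(S@attributions)))
  TimeDistribution(rowSums(abs(S@attributions) * mask))
}

#' 1-Wasserstein distance between time distributions
#'
#' Earth Mover's Distance with ground distance |i - j| in time-index
#' units, via the closed form `sum_t |CDF1(t) - CDF2(t)|`.
#'
#' @param d1,d2 [TimeDistribution-class] objects of equal length.
#' @return nonnegative distance.
#' @export
emd1d <- function(d1, d2) {
  stopifnot(is(d1, "TimeDistribution"), is(d2, "TimeDistribution"))
  if (length(d1@mass) != length(d2@mass))
    stop("distributions have different lengths")
  if (d1@degenerate || d2@degenerate)
    stop("EMD is undefined for a degenerate distribution")
  sum(abs(cumsum(d1@mass - d2@mass)))
}

#' EMD spikiness of a saliency map
#'
#' Distance between the top-fraction time marginal of the map and the
#' uniform distribution over time points: 0 for perfectly scattered
#' saliency, (T - 1) / 2 for a single spike at an endpoint. Higher values
#' mean the salient mass is concentrated in fewer, more focused time
#' intervals.
#'
#' @param S a [SaliencyMap-class].
#' @param fraction top fraction kept before flattening (default 5%).
#' @param normalize divide by (T - 1) for cross-length comparisons.
#' @return nonnegative spikiness, or `NA` (with a warning) when the masked
#'   marginal is degenerate.
#' @export
emdSpikiness <- function(S, fraction = 0.05, normalize = FALSE) {
  marg <- timeMarginal(S, topFractionMask(S, fraction))
  if (marg@degenerate) {
    warning("degenerate saliency marginal; spikiness undefined")
    return(NA_real_)
  }
  Tn <- length(marg@mass)
  v <- emd1d(marg, TimeDistribution(rep(1, Tn)))
  if (normalize) v / (Tn - 1) else v
}

#' Submodular pick of representative saliency maps
#'
#' Greedy maximization of the coverage objective over flattened absolute
#' attributions: with W the (subjects x features) matrix of |attributions|
#' and feature importance `I_j = sqrt(sum_i W[i, j])`, each step picks the
#' map adding the largest total importance of newly covered features
#' (features j with W[i, j] > 0), ties broken by lower subject index.
#'
#' @param maps nonempty list of equal-shape [SaliencyMap-class] objects.
#' @param budget number of picks (>= 1).
#' @return integer vector of `min(budget, length(maps))` indices in pick
#'   order.
#' @export
submodularPick <- function(maps, budget) {
  if (length(maps) == 0L) stop("no saliency maps supplied")
  stopifnot(budget >= 1L)
  W <- t(vapply(maps, function(m) abs(as.vector(m@attributions)),
                numeric(length(maps[[1L]]@attributions))))
  Imp <- sqrt(colSums(W))
  nz <- lapply(seq_len(nrow(W)), function(i) which(W[i, ] > 0))
  covered <- logical(ncol(W))
  picked <- integer(0)
  for (step in seq_len(min(budget, length(maps)))) {
    remaining <- setdiff(seq_len(length(maps)), picked)
    gains <- vapply(remaining, function(i) {
      new <- nz[[i]][!covered[nz[[i]]]]
      sum(Imp[new])
    }, numeric(1))
    best <- remaining[which.max(gains)]
    picked <- c(picked, best)
    covered[nz[[best]]] <- TRUE
  }
  picked
}
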