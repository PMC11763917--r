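test_that("the path integral is exact for linear scorers at any step count", {
  set.seed(2)
  W <- matrix(rnorm(24), 8, 3)
  gradFn <- function(xs) lapply(xs, function(x) W)  # d(sum(W*x))/dx = W
  X <- matrix(rnorm(24), 8, 3)
  zero <- matrix(0, 8, 3)
  for (steps in c(1L, 3L, 64L)) {
    attr <- timeArrow:::.igCore(gradFn, X, zero, steps)
    expect_equal(attr, W * X, tolerance = 1e-12)
  }
  base <- matrix(rnorm(24), 8, 3)
  expect_equal(timeArrow:::.igCore(gradFn, X, base, 5L), W * (X - base),
               tolerance = 1e-12)
})

test_that("attributions satisfy completeness and vanish at the baseline", {
  # lightly trained model so F is nontrivial
  coh <- makeToyCohort(n = 8L, tp = 16L, nc = 2L, seed = 3L)
  fit <- trainModel(initModel(tinyModelConfig(2L)), buildTRDataset(coh),
                    fastTrainConfig(maxEpochs = 10L))
  m <- fit$model
  X <- tsValues(subjects(coh)[[1L]])
  S <- integratedGradients(m, X, steps = 256L)
  gap <- abs(sum(attributions(S)) -
             (forwardPass(m, X)@probability -
              forwardPass(m, matrix(0, 16, 2))@probability))
  expect_lt(gap, 1e-3)
  # the gap shrinks as steps grow
  gapAt <- function(k) abs(sum(attributions(
    integratedGradients(m, X, steps = k))) -
    (forwardPass(m, X)@probability -
     forwardPass(m, matrix(0, 16, 2))@probability))
  expect_lt(gapAt(64L), gapAt(2L) + 1e-12)

  S0 <- integratedGradients(m, matrix(0, 16, 2), steps = 8L)
  expect_equal(attributions(S0), matrix(0, 16, 2))
  expect_error(integratedGradients(m, X, steps = 0L), "steps")
})

test_that("flip alignment reverses rows once and guards its state", {
  S <- randomSaliencyMap(direction = "reverse")
  Sa <- flipTimeSaliency(S)
  expect_identical(attributions(Sa), reverseTime(attributions(S)))
  expect_true(Sa@aligned)
  expect_identical(dim(attributions(Sa)), dim(attributions(S)))
  expect_error(flipTimeSaliency(Sa), "already aligned")
  expect_error(flipTimeSaliency(randomSaliencyMap(direction = "forward")),
               "reverse")
})

test_that("alignment correlation is scale-invariant and alignment-sensitive", {
  Sf <- randomSaliencyMap(seed = 5L)
  Sr <- new("SaliencyMap", subjectId = "s",
            attributions = attributions(Sf), direction = "reverse",
            aligned = TRUE)
  expect_equal(alignmentCorrelation(Sf, Sr), 1)
  Sr2 <- Sr
  Sr2@attributions <- 2 * attributions(Sf)
  expect_equal(alignmentCorrelation(Sf, Sr2), 1)
  # shuffling rows of a non-constant map breaks alignment
  set.seed(8)
  worse <- replicate(10, {
    Srp <- Sr
    Srp@attributions <- attributions(Sf)[sample(nrow(attributions(Sf))), ]
    alignmentCorrelation(Sf, Srp)
  })
  expect_true(all(worse < 1))

  Sc <- Sr
  Sc@attributions <- matrix(1, 10, 4)
  expect_error(alignmentCorrelation(Sf, Sc), "zero-variance")
  Sother <- randomSaliencyMap(direction = "reverse", id = "other")
  expect_error(alignmentCorrelation(Sf, flipTimeSaliency(Sother)),
               "different subjects")
})

test_that("top-fraction masks keep exactly ceiling(fraction * T * N)", {
  S <- new("SaliencyMap", subjectId = "big",
           attributions = matrix(rnorm(140 * 53), 140, 53),
           direction = "forward", aligned = TRUE)
  mask <- topFractionMask(S, 0.05)
  expect_identical(sum(mask), 371L)  # ceiling(0.05 * 7420)
  v <- abs(attributions(S))
  expect_gte(min(v[mask]), max(v[!mask]))
  expect_identical(sum(topFractionMask(S, 1)), 7420L)

  # heavy ties at the cutoff: the time-then-component rule keeps exactly k
  Stie <- new("SaliencyMap", subjectId = "tie",
              attributions = matrix(1, 6, 5), direction = "forward",
              aligned = TRUE)
  mtie <- topFractionMask(Stie, 0.1)  # k = 3 of 30 equal entries
  expect_identical(sum(mtie), 3L)
  expect_true(all(mtie[1L, 1:3]))  # earlier time first, then lower component
})

test_that("time marginals normalize masked salience", {
  S <- randomSaliencyMap(tp = 6L, nc = 3L, seed = 9L)
  one <- matrix(FALSE, 6, 3)
  one[4L, 2L] <- TRUE
  d <- timeMarginal(S, one)
  expect_equal(massVector(d), c(0, 0, 0, 1, 0, 0))

  Su <- new("SaliencyMap", subjectId = "u", attributions = matrix(2, 6, 3),
            direction = "forward", aligned = TRUE)
  expect_equal(massVector(timeMarginal(Su, matrix(TRUE, 6, 3))), rep(1/6, 6))
  expect_equal(sum(massVector(timeMarginal(S, matrix(TRUE, 6, 3)))), 1)

  none <- timeMarginal(S, matrix(FALSE, 6, 3))
  expect_true(none@degenerate)
})

test_that("1-D EMD matches the CDF closed form and the LP oracle", {
  u4 <- TimeDistribution(rep(1, 4))
  expect_equal(emd1d(u4, u4), 0)
  expect_equal(emd1d(TimeDistribution(c(1, 0, 0, 0)), u4), 1.5)
  expect_error(emd1d(u4, TimeDistribution(rep(1, 5))), "length")

  set.seed(14)
  n <- 200L
  tp <- 12L
  d1 <- matrix(stats::rexp(n * tp), n, tp)
  d2 <- matrix(stats::rexp(n * tp), n, tp)
  d1 <- d1 / rowSums(d1)
  d2 <- d2 / rowSums(d2)
  mine <- vapply(seq_len(n), function(i)
    emd1d(TimeDistribution(d1[i, ]), TimeDistribution(d2[i, ])), numeric(1))
  lp <- lpTransportOracle(d1, d2)
  expect_lt(max(abs(mine - lp)), 1e-9)
})

test_that("emd1d is a metric on fixed-length distributions", {
  set.seed(15)
  for (i in 1:30) {
    tp <- sample(3:15, 1)
    a <- TimeDistribution(stats::rexp(tp))
    b <- TimeDistribution(stats::rexp(tp))
    cc <- TimeDistribution(stats::rexp(tp))
    expect_equal(emd1d(a, b), emd1d(b, a))
    expect_equal(emd1d(a, a), 0)
    expect_lte(emd1d(a, cc), emd1d(a, b) + emd1d(b, cc) + 1e-12)
    expect_gte(emd1d(a, b), 0)
  }
})

test_that("spikiness is extremal for uniform and endpoint-delta marginals", {
  tp <- 10L
  Su <- new("SaliencyMap", subjectId = "u",
            attributions = matrix(1, tp, 3), direction = "forward",
            aligned = TRUE)
  expect_equal(emdSpikiness(Su, fraction = 1), 0)

  att <- matrix(0, tp, 1)
  att[1L, 1L] <- 5
  Sd <- new("SaliencyMap", subjectId = "d", attributions = att,
            direction = "forward", aligned = TRUE)
  expect_equal(emdSpikiness(Sd, fraction = 0.1), (tp - 1) / 2)
  expect_equal(emdSpikiness(Sd, fraction = 0.1, normalize = TRUE), 0.5)

  # endpoint delta dominates every random distribution (brute force)
  set.seed(16)
  unif <- TimeDistribution(rep(1, 8))
  best <- max(vapply(1:200, function(i)
    emd1d(TimeDistribution(stats::rexp(8)), unif), numeric(1)))
  expect_lte(best, emd1d(TimeDistribution(c(1, rep(0, 7))), unif))

  # one spike beats the same mass split into two symmetric spikes
  oneSpike <- TimeDistribution(c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  twoSpike <- TimeDistribution(c(0, 0.5, 0, 0, 0, 0, 0, 0.5, 0) )
  u9 <- TimeDistribution(rep(1, 9))
  expect_gt(emd1d(oneSpike, u9), emd1d(twoSpike, u9))

  Sz <- new("SaliencyMap", subjectId = "z",
            attributions = matrix(0, 6, 2), direction = "forward",
            aligned = TRUE)
  expect_warning(vz <- emdSpikiness(Sz), "degenerate")
  expect_true(is.na(vz))
})

test_that("mean spikiness decreases as salient mass splits into more spikes", {
  set.seed(17)
  tp <- 40L
  meanSpik <- vapply(c(1L, 3L, 8L, 20L), function(k) {
    mean(vapply(1:40, function(i) {
      pos <- sample.int(tp, k)
      m <- numeric(tp)
      m[pos] <- stats::rexp(k)
      emd1d(TimeDistribution(m), TimeDistribution(rep(1, tp)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanSpik) < 0))
})

test_that("spikiness has no hidden state under time permutation", {
  set.seed(18)
  m <- stats::rexp(12)
  perm <- sample(12)
  a <- emd1d(TimeDistribution(m[perm]), TimeDistribution(rep(1, 12)))
  b <- sum(abs(cumsum(m[perm] / sum(m) - 1 / 12)))
  expect_equal(a, b)
})

test_that("submodular pick reproduces an exhaustive greedy oracle", {
  greedyOracle <- function(W, budget) {
    Imp <- sqrt(colSums(W))
    covered <- logical(ncol(W))
    picked <- integer(0)
    for (s in seq_len(min(budget, nrow(W)))) {
      gains <- rep(-1, nrow(W))
      for (i in setdiff(seq_len(nrow(W)), picked))
        gains[i] <- sum(Imp[W[i, ] > 0 & !covered])
      best <- which(gains == max(gains))[1L]
      picked <- c(picked, best)
      covered <- covered | W[best, ] > 0
    }
    picked
  }
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    f <- sample(4:10, 1)
    maps <- lapply(seq_len(n), function(i) {
      a <- matrix(stats::rnorm(f), f, 1) * stats::rbinom(f, 1, 0.5)
      new("SaliencyMap", subjectId = sprintf("m%d", i), attributions = a,
          direction = "forward", aligned = TRUE)
    })
    W <- t(vapply(maps, function(m) abs(as.vector(attributions(m))),
                  numeric(f)))
    budget <- sample.int(n, 1)
    expect_identical(submodularPick(maps, budget), greedyOracle(W, budget))
  }
})

test_that("pick order has non-decreasing coverage with diminishing gains", {
  set.seed(20)
  maps <- lapply(1:7, function(i) {
    a <- matrix(stats::rexp(12) * stats::rbinom(12, 1, 0.6), 12, 1)
    new("SaliencyMap", subjectId = sprintf("m%d", i), attributions = a,
        direction = "forward", aligned = TRUE)
  })
  picks <- submodularPick(maps, budget = 7L)
  expect_identical(sort(picks), 1:7)
  W <- t(vapply(maps, function(m) abs(as.vector(attributions(m))),
                numeric(12)))
  Imp <- sqrt(colSums(W))
  covered <- logical(12)
  gains <- numeric(0)
  for (i in picks) {
    gains <- c(gains, sum(Imp[W[i, ] > 0 & !covered]))
    covered <- covered | W[i, ] > 0
  }
  expect_true(all(diff(gains) <= 1e-12))

  # an all-zero map adds no coverage, so it is never the first pick
  zmaps <- c(list(new("SaliencyMap", subjectId = "z",
                      attributions = matrix(0, 12, 1),
                      direction = "forward", aligned = TRUE)), maps)
  expect_gt(submodularPick(zmaps, budget = 1L), 1L)
  expect_error(submodularPick(list(), 1L), "no saliency maps")
})
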