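# Shared fixtures: all data are generated in code at test time.

makeToyCohort <- function(n = 4L, tp = 12L, nc = 3L, labeled = FALSE,
                          seed = 42L, name = "toy") {
  set.seed(seed)
  subjects <- lapply(seq_len(n), function(i)
    SubjectTimeSeries(sprintf("s%02d", i), matrix(rnorm(tp * nc), tp, nc),
                      label = if (labeled) i %% 2L else NULL))
  Cohort(name, subjects)
}

tinyModelConfig <- function(nc, seed = 1L, ...) {
  ModelConfig(inputSize = nc, lstmHidden = 8L, attentionHidden = 8L,
              decoderHidden = 6L, seed = seed, ...)
}

fastTrainConfig <- function(maxEpochs = 5L, seed = 1L, ...) {
  TrainConfig(maxEpochs = maxEpochs, batchSize = 8L, valFraction = 0.25,
              seed = seed, ...)
}

randomSaliencyMap <- function(tp = 10L, nc = 4L, seed = 1L,
                              direction = "forward", id = "s") {
  set.seed(seed)
  new("SaliencyMap", subjectId = id,
      attributions = matrix(rnorm(tp * nc), tp, nc),
      direction = direction, aligned = direction == "forward")
}

# Independent LP transport oracle: solves min sum c_ij f_ij subject to
# marginal constraints with scipy.optimize.linprog (HiGHS), reading pairs
# of distributions from a CSV and writing one optimal cost per pair.
lpTransportOracle <- function(d1mat, d2mat) {
  stopifnot(identical(dim(d1mat), dim(d2mat)))
  inFile <- tempfile(fileext = ".csv")
  outFile <- tempfile(fileext = ".csv")
  utils::write.table(cbind(d1mat, d2mat), inFile, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.optimize import linprog",
    "X = np.loadtxt(sys.argv[1], delimiter=',')",
    "X = np.atleast_2d(X)",
    "T = X.shape[1] // 2",
    "cost = np.abs(np.subtract.outer(np.arange(T), np.arange(T))).ravel()",
    "Aeq = np.zeros((2 * T, T * T))",
    "for i in range(T):",
    "    Aeq[i, i * T:(i + 1) * T] = 1",
    "    Aeq[T + i, i::T] = 1",
    "out = []",
    "for row in X:",
    "    beq = np.concatenate([row[:T], row[T:]])",
    "    r = linprog(cost, A_eq=Aeq[:-1], b_eq=beq[:-1], method='highs')",
    "    out.append(r.fun)",
    "np.savetxt(sys.argv[2], np.array(out))"), script)
  status <- system2("python", c(script, inFile, outFile),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  as.numeric(readLines(outFile))
}
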