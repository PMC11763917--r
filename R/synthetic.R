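# Synthetic cohorts: (a) up-chirp signals for the time-reversal pretext
# task, (b) a two-class "episodic disease" cohort for downstream
# classification. Everything is deterministic given the parameter seeds.

# Derive a 31-bit child seed; keeps all seeds valid R integers.
.deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) %% 65536 * 30269 + as.double(k) * 7919 + 1) %%
             2147483647)
}

.localSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Segment lengths that partition nTimepoints into nSegments near-equal parts.
.segmentLengths <- function(nTimepoints, nSegments) {
  cuts <- floor(seq(0, nTimepoints, length.out = nSegments + 1L))
  diff(cuts)
}

#' Generate one synthetic chirp subject
#'
#' Each component is a concatenation of linear up-chirp segments with the
#' instantaneous frequency rising from f0 to f1 cycles per sequence within
#' every segment, f0 and f1 drawn per segment from the parameter ranges
#' (redrawn until f1 > f0), plus additive Gaussian noise. Deterministic
#' given (`params@seed`, `subjectSeed`).
#'
#' @param params a [ChirpParams-class].
#' @param subjectSeed integer distinguishing subjects under a common
#'   `params@seed`.
#' @return a [SubjectTimeSeries-class] (unlabeled).
#' @examples
#' s <- generateChirpSubject(ChirpParams(nComponents = 4, nTimepoints = 100), 1)
#' @export
generateChirpSubject <- function(params, subjectSeed) {
  stopifnot(is(params, "ChirpParams"))
  validObject(params)
  Tn <- params@nTimepoints
  N <- params@nComponents
  lens <- .segmentLengths(Tn, params@nSegments)
  values <- .localSeed(.deriveSeed(params@seed, subjectSeed), {
    m <- matrix(0, Tn, N)
    for (n in seq_len(N)) {
      col <- numeric(0)
      for (L in lens) {
        f0 <- stats::runif(1, params@f0Range[1L], params@f0Range[2L])
        repeat {
          f1 <- stats::runif(1, params@f1Range[1L], params@f1Range[2L])
          if (f1 > f0) break
        }
        u <- (seq_len(L) - 1) / L
        col <- c(col, sin(2 * pi * (f0 * u + (f1 - f0) * u^2 / 2) * L / Tn))
      }
      m[, n] <- col
    }
    m + matrix(stats::rnorm(Tn * N, sd = params@noiseSd), Tn, N)
  })
  SubjectTimeSeries(sprintf("chirp_%05d", subjectSeed), values)
}

#' Generate a cohort of chirp subjects
#'
#' @param nSubjects number of subjects (>= 1).
#' @param params a [ChirpParams-class]; per-subject seeds are derived from
#'   `params@seed`.
#' @return an unlabeled [Cohort-class].
#' @export
generateChirpCohort <- function(nSubjects, params = ChirpParams()) {
  stopifnot(nSubjects >= 1L)
  subjects <- lapply(seq_len(nSubjects), function(i)
    generateChirpSubject(params, i))
  Cohort("chirp", subjects,
         metadata = list(generator = "chirp", seed = params@seed))
}

#' Generate a labeled two-class episodic cohort
#'
#' Controls are AR(1) noise; patients additionally carry transient boxcar
#' events (see [EpisodicCohortParams-class]). Patients are labeled 1,
#' controls 0. Injected event onsets are recorded in the cohort metadata
#' (`metadata(cohort)$events`), so detector-style checks can score
#' localization against ground truth.
#'
#' @param params an [EpisodicCohortParams-class].
#' @return a labeled [Cohort-class]; controls first, then patients.
#' @export
generateEpisodicCohort <- function(params) {
  stopifnot(is(params, "EpisodicCohortParams"))
  validObject(params)
  Tn <- params@nTimepoints
  N <- params@nComponents
  L <- params@eventLength
  k <- params@nEvents

  ar1 <- function() {
    vapply(seq_len(N), function(n)
      as.numeric(stats::filter(stats::rnorm(Tn, sd = params@baseNoiseSd),
                               params@arCoefficient, method = "recursive")),
      numeric(Tn))
  }
  # k non-overlapping length-L windows, uniform over feasible placements
  drawOnsets <- function() {
    if (k == 0L) return(integer(0))
    pool <- Tn - k * L + k
    p <- sort(sample.int(pool, k))
    p + (seq_len(k) - 1L) * (L - 1L)
  }

  .localSeed(params@seed, {
    subjects <- vector("list", params@nControls + params@nPatients)
    events <- list()
    for (i in seq_len(params@nControls)) {
      subjects[[i]] <- SubjectTimeSeries(sprintf("ctrl_%04d", i), ar1(),
                                         label = 0L)
    }
    for (j in seq_len(params@nPatients)) {
      m <- ar1()
      onsets <- drawOnsets()
      id <- sprintf("pat_%04d", j)
      for (o in onsets) {
        idx <- o:(o + L - 1L)
        m[idx, seq_len(params@affectedComponents)] <-
          m[idx, seq_len(params@affectedComponents)] + params@eventAmplitude
      }
      if (length(onsets))
        events[[id]] <- data.frame(subject = id, onset = onsets, length = L)
      subjects[[params@nControls + j]] <- SubjectTimeSeries(id, m, label = 1L)
    }
    Cohort("episodic", subjects,
           nTimepoints = Tn, nComponents = N,
           metadata = list(generator = "episodic", seed = params@seed,
                           events = do.call(rbind, unname(events)),
                           affectedComponents = params@affectedComponents))
  })
}

#' Cohort metadata
#'
#' @param cohort a [Cohort-class].
#' @return the metadata list (generator provenance, injected events, ...).
#' @export
cohortMetadata <- function(cohort) cohort@metadata
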