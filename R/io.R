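# Cohort exchange format: one delimited-text matrix per subject (one row per
# time point, comma separated, no header, full double precision) plus a JSON
# manifest declaring dimensions and per-subject files/labels.

#' Read a cohort from a JSON manifest
#'
#' The manifest declares `{name, n_timepoints, n_components,
#' subjects: [{id, file, label?}]}`; matrix files are comma-separated
#' numeric text, one row per time point, no header, resolved relative to
#' the manifest's directory. Shapes are validated against the declaration,
#' subject ids must be unique, and non-finite entries are rejected.
#'
#' @param manifestPath path to the manifest JSON.
#' @return a [Cohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  man <- jsonlite::read_json(manifestPath, simplifyVector = FALSE)
  for (f in c("name", "n_timepoints", "n_components", "subjects"))
    if (is.null(man[[f]])) stop("manifest lacks field '", f, "'")
  base <- dirname(normalizePath(manifestPath))
  subjects <- lapply(man$subjects, function(s) {
    path <- file.path(base, s$file)
    if (!file.exists(path))
      stop("matrix file missing for subject '", s$id, "': ", path)
    raw <- utils::read.csv(path, header = FALSE, colClasses = "numeric")
    m <- as.matrix(raw)
    dimnames(m) <- NULL
    if (!all(is.finite(m)))
      stop("non-finite entries in matrix of subject '", s$id, "'")
    if (nrow(m) != man$n_timepoints || ncol(m) != man$n_components)
      stop(sprintf("subject '%s' has shape %dx%d, manifest declares %dx%d",
                   s$id, nrow(m), ncol(m), man$n_timepoints,
                   man$n_components))
    SubjectTimeSeries(s$id, m, label = s$label)
  })
  Cohort(man$name, subjects,
         nTimepoints = man$n_timepoints, nComponents = man$n_components)
}

#' Write a cohort to a directory
#'
#' Inverse of [readCohort()]: writes one CSV matrix per subject at full
#' double precision (`%.17g`, so values round-trip exactly) and a
#' `manifest.json`.
#'
#' @param cohort a [Cohort-class].
#' @param dir target directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  entries <- vector("list", length(cohort@subjects))
  for (i in seq_along(cohort@subjects)) {
    s <- cohort@subjects[[i]]
    fname <- sprintf("%s.csv", gsub("[^A-Za-z0-9._-]", "_", s@subjectId))
    txt <- matrix(sprintf("%.17g", s@values), nrow = nrow(s@values))
    writeLines(apply(txt, 1L, paste, collapse = ","), file.path(dir, fname))
    e <- list(id = s@subjectId, file = fname)
    if (length(s@label)) e$label <- s@label
    entries[[i]] <- e
  }
  man <- list(name = cohort@name, n_timepoints = cohort@nTimepoints,
              n_components = cohort@nComponents, subjects = entries)
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifestPath)
}
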