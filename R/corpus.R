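#' Coordinate corpora: experiments, foci, and their ingestion
#'
#' A corpus is the unit of analysis: one `experiment` per included study,
#' each carrying the study label, the number of scanned subjects, the
#' stereotaxic space the peaks were reported in (MNI or TAL), and the
#' reported activation peaks ("foci") as an n x 3 matrix of mm coordinates.
#'
#' @param study_id non-empty character scalar.
#' @param n_subjects positive integer, subjects scanned in the experiment.
#' @param foci numeric matrix with 3 columns (x, y, z in mm); may have zero
#'   rows only when constructed in metadata-tolerant mode.
#' @param space `"MNI"` or `"TAL"`.
#' @param paradigm optional task label (`"DF"`, `"TNT"`, or `NA`).
#' @param contrast optional free-text contrast description.
#' @return An object of class `cbma_experiment`.
#' @export
experiment <- function(study_id, n_subjects, foci, space = "MNI",
                       paradigm = NA_character_, contrast = NA_character_) {
  if (!is.character(study_id) || length(study_id) != 1L || !nzchar(study_id))
    stop_cbma("study_id must be a non-empty string")
  if (!is_count(n_subjects) || n_subjects < 1)
    stop_cbma("n_subjects must be a positive integer (study '%s')", study_id)
  if (!space %in% c("MNI", "TAL"))
    stop_cbma("unknown space tag '%s' (study '%s')", space, study_id)
  foci <- matrix(as.numeric(foci), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(foci) > 0) {
    if (any(!is.finite(foci)))
      stop_cbma("non-finite focus coordinate in study '%s'", study_id)
    if (any(abs(foci) >= 200))
      stop_cbma("focus coordinate beyond 200 mm sanity bound in study '%s'",
                study_id)
  }
  structure(
    list(study_id = study_id, n_subjects = as.integer(n_subjects),
         space = space, foci = foci,
         paradigm = if (is.na(paradigm)) NA_character_ else
           match.arg(paradigm, c("DF", "TNT")),
         contrast = as.character(contrast)),
    class = "cbma_experiment")
}

#' @param experiments list of [experiment()] objects with unique study ids.
#' @param provenance free-text description of the corpus source.
#' @param require_foci if `TRUE` (analysis mode), every experiment must have
#'   at least one focus; metadata-tolerant mode (`FALSE`) exists for
#'   metadata-only study tables.
#' @rdname experiment
#' @export
corpus <- function(experiments, provenance = "", require_foci = TRUE) {
  if (!length(experiments)) {
    return(structure(list(experiments = list(), provenance = provenance),
                     class = "cbma_corpus"))
  }
  stopifnot(all(vapply(experiments, inherits, TRUE, "cbma_experiment")))
  ids <- vapply(experiments, `[[`, "", "study_id")
  if (anyDuplicated(ids))
    stop_cbma("duplicate study_id: %s", ids[duplicated(ids)][1])
  if (require_foci) {
    n_foci <- vapply(experiments, function(e) nrow(e$foci), 0L)
    if (any(n_foci == 0))
      stop_cbma("experiment '%s' has no foci", ids[n_foci == 0][1])
  }
  structure(list(experiments = experiments, provenance = provenance),
            class = "cbma_corpus")
}

#' @export
print.cbma_corpus <- function(x, ...) {
  s <- summarize_corpus(x)
  cat(sprintf("cbma_corpus: %d studies, %d subjects, %d foci\n",
              s$n_studies, s$n_subjects_total, s$n_foci_total))
  invisible(x)
}

#' Summarize a corpus
#'
#' @param corp a corpus.
#' @return A one-row data frame with `n_studies`, `n_subjects_total`,
#'   `n_foci_total`.
#' @export
summarize_corpus <- function(corp) {
  stopifnot(inherits(corp, "cbma_corpus"))
  exps <- corp$experiments
  data.frame(
    n_studies = length(exps),
    n_subjects_total = if (length(exps))
      sum(vapply(exps, `[[`, 0L, "n_subjects")) else 0L,
    n_foci_total = if (length(exps))
      sum(vapply(exps, function(e) nrow(e$foci), 0L)) else 0L)
}

normalize_paradigm <- function(p) {
  p <- toupper(trimws(as.character(p)))
  p[p %in% c("", "NA")] <- NA
  p[p %in% c("T/NT", "TNT", "T-NT")] <- "TNT"
  p
}

#' Read a coordinate corpus from disk
#'
#' Two dialects are supported. `"sleuth"` is the whitespace text format of
#' coordinate meta-analysis tools: blank-line separated study blocks, each
#' opened by a `// study; contrast` comment, a `// Subjects = N` comment,
#' and one `x y z` coordinate line per focus; a `// Reference = MNI|TAL`
#' line (anywhere before the blocks it covers) declares the reported space.
#' `"csv"` expects columns `study_id, n, space, x, y, z, paradigm,
#' contrast` with one row per focus, grouped by `study_id`.
#'
#' Spaces are recorded as declared; no conversion happens here (see
#' [convert_tal_to_mni()]).
#'
#' @param path file to read.
#' @param dialect `"sleuth"` or `"csv"`.
#' @param require_foci set `FALSE` to accept metadata-only tables (rows
#'   with empty coordinates), e.g. a transcribed study table.
#' @return A [corpus()].
#' @export
read_corpus_table <- function(path, dialect = c("sleuth", "csv"),
                              require_foci = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_cbma("corpus file not found: %s", path)
  corp <- switch(dialect,
                 sleuth = read_sleuth(path, require_foci),
                 csv = read_corpus_csv(path, require_foci))
  corp
}

read_sleuth <- function(path, require_foci) {
  lines <- readLines(path, warn = FALSE)
  space <- "MNI"
  exps <- list()
  block <- list(study = NULL, contrast = NA_character_, n = NULL,
                foci = NULL, space = space)
  flush_block <- function() {
    if (is.null(block$study) && is.null(block$foci)) return()
    if (is.null(block$study))
      stop_cbma("foci block without a '// study; contrast' header")
    if (is.null(block$n))
      stop_cbma("study '%s' is missing a '// Subjects = N' line", block$study)
    foci <- if (is.null(block$foci)) matrix(numeric(), ncol = 3) else
      do.call(rbind, block$foci)
    exps[[length(exps) + 1L]] <<- experiment(
      block$study, block$n, foci, space = block$space,
      contrast = block$contrast)
  }
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nzchar(ln)) { flush_block(); block <- list(study = NULL,
      contrast = NA_character_, n = NULL, foci = NULL, space = space)
      next }
    if (startsWith(ln, "//")) {
      body <- trimws(sub("^//", "", ln))
      if (grepl("^Reference\\s*=", body, ignore.case = TRUE)) {
        ref <- toupper(trimws(sub("^Reference\\s*=", "", body,
                                  ignore.case = TRUE)))
        space <- if (grepl("TAL", ref)) "TAL" else "MNI"
        block$space <- space
      } else if (grepl("^Subjects\\s*=", body, ignore.case = TRUE)) {
        n <- suppressWarnings(as.integer(trimws(
          sub("^Subjects\\s*=", "", body, ignore.case = TRUE))))
        if (is.na(n)) stop_cbma("line %d: unreadable Subjects count", li)
        block$n <- n
      } else if (is.null(block$study)) {
        parts <- strsplit(body, ";", fixed = TRUE)[[1]]
        block$study <- trimws(parts[1])
        if (length(parts) > 1)
          block$contrast <- trimws(paste(parts[-1], collapse = ";"))
      }
      next
    }
    xyz <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:],]+")[[1]]))
    if (length(xyz) != 3L || any(is.na(xyz)))
      stop_cbma("line %d: malformed coordinate line '%s' (need 3 numeric fields)",
                li, lines[li])
    block$foci <- c(block$foci, list(xyz))
  }
  flush_block()
  corpus(exps, provenance = path, require_foci = require_foci)
}

read_corpus_csv <- function(path, require_foci) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "n", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_cbma("corpus CSV is missing columns: %s", paste(miss, collapse = ", "))
  if (any(is.na(df$n))) stop_cbma("missing n (subjects) in corpus CSV")
  ids <- unique(df$study_id)
  exps <- lapply(ids, function(id) {
    rows <- df[df$study_id == id, , drop = FALSE]
    has_xyz <- stats::complete.cases(rows[, c("x", "y", "z")])
    if (any(has_xyz != all(has_xyz)) && any(!has_xyz))
      stop_cbma("study '%s' mixes coordinate and empty-coordinate rows", id)
    foci <- as.matrix(rows[has_xyz, c("x", "y", "z")])
    experiment(
      as.character(id), rows$n[1], foci,
      space = toupper(rows$space[1] %||% "MNI"),
      paradigm = normalize_paradigm(rows$paradigm[1] %||% NA),
      contrast = as.character(rows$contrast[1] %||% NA))
  })
  corpus(exps, provenance = path, require_foci = require_foci)
}

#' Serialize a corpus back to disk
#'
#' Writing then re-reading a corpus reproduces it exactly (modulo
#' whitespace), which the test suite asserts as a round-trip fixed point.
#'
#' @inheritParams read_corpus_table
#' @param corp corpus to write.
#' @return `path`, invisibly.
#' @export
write_corpus_table <- function(corp, path, dialect = c("sleuth", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(corp, "cbma_corpus"))
  if (dialect == "sleuth") {
    out <- character()
    for (e in corp$experiments) {
      out <- c(out,
               sprintf("// Reference = %s", e$space),
               if (is.na(e$contrast)) sprintf("// %s", e$study_id) else
                 sprintf("// %s; %s", e$study_id, e$contrast),
               sprintf("// Subjects = %d", e$n_subjects),
               apply(e$foci, 1, function(r)
                 paste(trimws(formatC(r, format = "fg", digits = 10)),
                       collapse = " ")),
               "")
    }
    writeLines(out, path)
  } else {
    rows <- lapply(corp$experiments, function(e) {
      nf <- nrow(e$foci)
      data.frame(study_id = e$study_id, n = e$n_subjects, space = e$space,
                 x = if (nf) e$foci[, 1] else NA_real_,
                 y = if (nf) e$foci[, 2] else NA_real_,
                 z = if (nf) e$foci[, 3] else NA_real_,
                 paradigm = e$paradigm, contrast = e$contrast,
                 row.names = NULL)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' Pooled Talairach-to-MNI affine
#'
#' The Lancaster-style pooled transform, stored as the published MNI-to-Tal
#' matrix and inverted, so the conversion is its exact matrix inverse.
#'
#' @return A 4x4 matrix mapping Talairach (x,y,z,1) to MNI (x,y,z,1).
#' @export
tal2icbm_affine <- function() {
  icbm2tal <- matrix(c(
    0.9357,  0.0029, -0.0072, -1.0423,
   -0.0065,  0.9396, -0.0726, -1.3940,
    0.0103,  0.0752,  0.8967,  3.6475,
    0,       0,       0,       1), 4, 4, byrow = TRUE)
  solve(icbm2tal)
}

#' Convert every Talairach experiment in a corpus to MNI
#'
#' Experiments already in MNI pass through bit-identically; Talairach foci
#' are mapped through `affine` (pooled Lancaster transform by default).
#' Idempotent: applying it to its own output changes nothing.
#'
#' @param corp a corpus.
#' @param affine 4x4 Talairach-to-MNI matrix.
#' @return A corpus whose experiments are all in MNI space.
#' @export
convert_tal_to_mni <- function(corp, affine = tal2icbm_affine()) {
  stopifnot(inherits(corp, "cbma_corpus"))
  exps <- lapply(corp$experiments, function(e) {
    if (e$space == "MNI") return(e)
    if (e$space != "TAL") stop_cbma("unknown space tag '%s'", e$space)
    if (nrow(e$foci)) {
      xyz <- cbind(e$foci, 1) %*% t(affine)
      e$foci <- xyz[, 1:3, drop = FALSE]
      colnames(e$foci) <- c("x", "y", "z")
    }
    e$space <- "MNI"
    e
  })
  corpus(exps, provenance = corp$provenance, require_foci = FALSE)
}

#' Bundled transcription of the included-study table
#'
#' Loads the metadata-only study table shipped with the package (23
#' intentional-forgetting fMRI studies: label, sample size, paradigm,
#' stimuli, contrast; peak coordinates are not part of the published table
#' and are absent).
#'
#' @return A metadata-only [corpus()].
#' @export
included_studies <- function() {
  path <- system.file("extdata", "included_studies.csv", package = "cbma",
                      mustWork = TRUE)
  read_corpus_table(path, dialect = "csv", require_foci = FALSE)
}
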