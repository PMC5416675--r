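## File dialect used throughout: UTF-8, tab-separated, '.' decimal, "NA"
## for missing. Numeric values are written with "%.17g" so that every
## reader/writer pair is a lossless round trip for doubles.

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.readTsv <- function(path, sep = "\t") {
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = NA, comment.char = "", quote = "")
}

.readMatrixFile <- function(path, what) {
  df <- .readTsv(path)
  if (ncol(df) < 2L)
    stop(sprintf("%s file '%s' needs an id column and at least one sample", what, path))
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s id(s) in '%s': %s", what, path,
                 paste(dup, collapse = ", ")))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("non-numeric values in %s file '%s'", what, path))
  rownames(m) <- ids
  m
}

#' Read a gene expression matrix
#'
#' Tab-separated text, first column gene ids, header row of sample ids —
#' the layout of quantile-normalised array exports. Values must be
#' non-negative signal intensities (or NA).
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes x samples.
#' @export
#' @seealso [writeMatrixFile()], [readBeta()]
readExpression <- function(path) {
  m <- .readMatrixFile(path, "gene")
  bad <- which(rowSums(m < 0, na.rm = TRUE) > 0)
  if (length(bad))
    stop(sprintf("negative expression values for gene(s): %s",
                 paste(rownames(m)[bad], collapse = ", ")))
  m
}

#' Read a methylation beta-value matrix
#'
#' Tab-separated text, first column probe ids, header row of sample ids.
#' All non-missing values must lie in [0,1].
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, probes x samples, values in [0,1].
#' @export
readBeta <- function(path) {
  m <- .readMatrixFile(path, "probe")
  bad <- which(rowSums(m < 0 | m > 1, na.rm = TRUE) > 0)
  if (length(bad))
    stop(sprintf("beta values outside [0,1] for probe(s): %s",
                 paste(rownames(m)[bad], collapse = ", ")))
  m
}

#' Write a feature x sample matrix as tab-separated text
#'
#' Inverse of [readExpression()] / [readBeta()]; doubles are written so the
#' round trip is exact.
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param idColumn Name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
writeMatrixFile <- function(m, path, idColumn = "feature_id") {
  header <- paste(c(idColumn, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires `sample_id` and `group` columns; any additional numeric columns
#' are treated as continuous covariates (NA allowed).
#'
#' @param path Path to a tab-separated file.
#' @return `data.frame` with validated ids and group labels.
#' @export
readSampleSheet <- function(path) {
  df <- .readTsv(path)
  validateSampleSheet(df)
}

#' Validate a sample sheet
#'
#' @param df `data.frame` with `sample_id` and `group` columns.
#' @return The validated `data.frame` (covariate columns coerced numeric).
#' @export
validateSampleSheet <- function(df) {
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("sample sheet must have 'sample_id' and 'group' columns")
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop(sprintf("duplicate sample id(s): %s", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(df$group), cohortGroups())
  if (length(bad))
    stop(sprintf("unknown group label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(cohortGroups(), collapse = ", ")))
  for (cl in setdiff(colnames(df), c("sample_id", "group")))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Write a sample sheet
#'
#' @param df Sample sheet `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSampleSheet <- function(df, path) writeResultTable(df, path)

#' Read a probe-to-gene annotation table
#'
#' Comma- or tab-separated with columns `probe_id`, `genes`, `chromosome`,
#' `position`. The gene field may hold several ";"-separated symbols; these
#' are deduplicated preserving order. An empty gene field marks an
#' unannotated probe. Positions are 1-based manifest coordinates, carried
#' but unused by the statistics.
#'
#' @param path Path to the annotation file.
#' @return `data.frame` with one row per probe, in file order.
#' @export
readAnnotation <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- .readTsv(path, sep = sep)
  colnames(df) <- trimws(colnames(df))
  need <- c("probe_id", "genes")
  if (!all(need %in% colnames(df)))
    stop("annotation must have 'probe_id' and 'genes' columns")
  df$probe_id <- trimws(as.character(df$probe_id))
  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup))
    stop(sprintf("duplicate probe id(s) in annotation: %s",
                 paste(dup, collapse = ", ")))
  df$genes[is.na(df$genes)] <- ""
  df$genes <- vapply(strsplit(trimws(as.character(df$genes)), ";", fixed = TRUE),
                     function(g) paste(unique(trimws(g[nzchar(trimws(g))])),
                                       collapse = ";"),
                     character(1))
  if (!"chromosome" %in% colnames(df)) df$chromosome <- NA_character_
  df$chromosome <- trimws(as.character(df$chromosome))
  if (!"position" %in% colnames(df)) df$position <- NA_integer_
  df$position <- as.integer(df$position)
  if (any(df$position < 0, na.rm = TRUE))
    stop("annotation positions must be non-negative")
  df[, c("probe_id", "genes", "chromosome", "position")]
}

#' Split annotation gene fields into a per-probe symbol list
#'
#' @param annotation Annotation `data.frame` from [readAnnotation()].
#' @return Named list (by probe id) of character vectors; `character(0)`
#'   for unannotated probes.
#' @export
annotationGeneList <- function(annotation) {
  out <- strsplit(annotation$genes, ";", fixed = TRUE)
  out <- lapply(out, function(g) g[nzchar(g)])
  names(out) <- annotation$probe_id
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Members are deduplicated; duplicate set names are an
#' error.
#'
#' @param path Path to a GMT file.
#' @param universeSize Optional universe size to attach.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path, universeSize = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("GMT file '%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop(sprintf("GMT line(s) %s have fewer than 3 fields",
                 paste(short, collapse = ", ")))
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop(sprintf("duplicate gene-set name(s): %s", paste(dup, collapse = ", ")))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  geneSetCollection(sets, universeSize = universeSize)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [GeneSetCollection-class].
#' @param path Output path.
#' @param descriptions Optional named character of set descriptions.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
  sets <- geneSets(collection)
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a result table as tab-separated text
#'
#' Column order is preserved; numeric columns are written at full double
#' precision so the round trip through [readResultTable()] is exact.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path) {
  out <- df
  for (cl in colnames(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- .fmtNum(out[[cl]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path Path to a tab-separated file with a header row.
#' @return `data.frame`.
#' @export
readResultTable <- function(path) .readTsv(path)

#' Write a simulated cohort to a directory of text artifacts
#'
#' Emits `expression.tsv`, `beta.tsv`, `samples.tsv`, `annotation.tsv` and
#' (when present) `truth.tsv`, all readable by the corresponding readers.
#'
#' @param cohort An [OmicsCohort-class].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMatrixFile(exprValues(cohort), file.path(dir, "expression.tsv"), "gene_id")
  writeMatrixFile(betaValues(cohort), file.path(dir, "beta.tsv"), "probe_id")
  writeResultTable(sampleSheet(cohort), file.path(dir, "samples.tsv"))
  writeResultTable(probeAnnotation(cohort), file.path(dir, "annotation.tsv"))
  if (nrow(truthTable(cohort)))
    writeResultTable(truthTable(cohort), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir Directory holding the cohort text artifacts.
#' @return An [OmicsCohort-class].
#' @export
readCohort <- function(dir) {
  truthPath <- file.path(dir, "truth.tsv")
  OmicsCohort(
    expression = readExpression(file.path(dir, "expression.tsv")),
    methylation = readBeta(file.path(dir, "beta.tsv")),
    samples = readSampleSheet(file.path(dir, "samples.tsv")),
    annotation = readAnnotation(file.path(dir, "annotation.tsv")),
    truth = if (file.exists(truthPath)) readResultTable(truthPath) else emptyTruth()
  )
}
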