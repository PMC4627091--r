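## Delimited-text I/O.  All schemas are tab-separated with explicit headers,
## decimal points and UTF-8; readers validate columns and report the file,
## row and column of a violation.  Readers and writers round-trip.

.checkSchema <- function(df, need, what, file = NULL) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("%s%s: missing column(s) %s", what,
           if (is.null(file)) "" else sprintf(" ('%s')", file),
           paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    .stopf("%s%s: no data rows", what,
           if (is.null(file)) "" else sprintf(" ('%s')", file))
  invisible(df)
}

.checkNumericColumn <- function(df, col, what, file = NULL,
                                allowNA = FALSE) {
  x <- df[[col]]
  if (!is.numeric(x))
    .stopf("%s%s: column '%s' must be numeric", what,
           if (is.null(file)) "" else sprintf(" ('%s')", file), col)
  if (!allowNA && anyNA(x))
    .stopf("%s%s: column '%s' has a missing value at row %d", what,
           if (is.null(file)) "" else sprintf(" ('%s')", file), col,
           which(is.na(x))[1])
  invisible(df)
}

.readTable <- function(file) {
  if (!file.exists(file)) .stopf("file not found: %s", file)
  read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTable <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(file)
}

#' Read / write titration and melt curve tables
#'
#' Tab-separated with headers.  Titration schema: `mutant_id`,
#' `replicate`, `temperature_C`, `conc_uM`, `signal`.  Melt schema:
#' `mutant_id`, `replicate`, `temperature_C`, `signal` (an optional
#' `ligand_uM` column is preserved).
#'
#' @param file path.
#' @param curves data.frame in the corresponding schema.
#' @return the curves data.frame (readers) or the path, invisibly
#'   (writers).
#' @name curve-io
#' @export
readTitrationCurves <- function(file) {
  df <- .readTable(file)
  .checkSchema(df, c("mutant_id", "replicate", "temperature_C", "conc_uM",
                     "signal"), "titration table", file)
  for (cl in c("temperature_C", "conc_uM", "signal"))
    .checkNumericColumn(df, cl, "titration table", file)
  if (any(df$conc_uM <= 0))
    .stopf("titration table ('%s'): non-positive conc_uM at row %d",
           file, which(df$conc_uM <= 0)[1])
  df
}

#' @rdname curve-io
#' @export
writeTitrationCurves <- function(curves, file) {
  .checkSchema(curves, c("mutant_id", "replicate", "temperature_C",
                         "conc_uM", "signal"), "titration table")
  .writeTable(curves, file)
}

#' @rdname curve-io
#' @export
readMeltCurves <- function(file) {
  df <- .readTable(file)
  .checkSchema(df, c("mutant_id", "replicate", "temperature_C", "signal"),
               "melt table", file)
  for (cl in c("temperature_C", "signal"))
    .checkNumericColumn(df, cl, "melt table", file)
  df
}

#' @rdname curve-io
#' @export
writeMeltCurves <- function(curves, file) {
  .checkSchema(curves, c("mutant_id", "replicate", "temperature_C",
                         "signal"), "melt table")
  .writeTable(curves, file)
}

#' Read / write a landscape table
#'
#' One row per mutant: `id`, `position`, `Sm`, `ddG`, `ddH`, `dTm`, the
#' four `*_sigma` errors, `fluorogenic`, `flags`.  The wild-type id and
#' reference temperature are stored in comment-style header lines.
#'
#' @param landscape a [ThermoLandscape].
#' @param file path.
#' @return a [ThermoLandscape] (reader) or the path, invisibly (writer).
#' @name landscape-io
#' @export
writeLandscape <- function(landscape, file) {
  stopifnot(is(landscape, "ThermoLandscape"))
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# wt_id=%s", wtId(landscape)), con)
  writeLines(sprintf("# ref_temperature_K=%.6f",
                     landscape@refTemperature), con)
  df <- as.data.frame(records(landscape))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname landscape-io
#' @export
readLandscape <- function(file) {
  if (!file.exists(file)) .stopf("file not found: %s", file)
  hdr <- readLines(file, n = 2L)
  wt <- sub("^# wt_id=", "", hdr[1])
  refT <- as.numeric(sub("^# ref_temperature_K=", "", hdr[2]))
  if (!nzchar(wt) || !is.finite(refT))
    .stopf("landscape table ('%s'): malformed header", file)
  df <- read.delim(file, skip = 2L, stringsAsFactors = FALSE)
  .checkSchema(df, c("id", "Sm", "ddG", "ddH", "dTm", "fluorogenic"),
               "landscape table", file)
  newThermoLandscape(df, wtId = wt, refTemperature = refT)
}

#' Read / write a chip layout
#'
#' Schema: `cell`, `row`, `col`, `mutant_id`, `replicate`, `control`;
#' `n_cells` and `replicates` are stored in header comment lines.
#'
#' @param layout a [ChipLayout].
#' @param file path.
#' @return a [ChipLayout] (reader) or the path, invisibly (writer).
#' @name layout-io
#' @export
writeLayout <- function(layout, file) {
  stopifnot(is(layout, "ChipLayout"))
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_cells=%d", layout@nCells), con)
  writeLines(sprintf("# replicates=%d", layout@replicates), con)
  write.table(assignment(layout), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname layout-io
#' @export
readLayout <- function(file) {
  if (!file.exists(file)) .stopf("file not found: %s", file)
  hdr <- readLines(file, n = 2L)
  nCells <- as.integer(sub("^# n_cells=", "", hdr[1]))
  reps <- as.integer(sub("^# replicates=", "", hdr[2]))
  df <- read.delim(file, skip = 2L, stringsAsFactors = FALSE)
  .checkSchema(df, c("cell", "row", "col", "mutant_id", "replicate",
                     "control"), "layout table", file)
  new("ChipLayout", nCells = nCells, replicates = reps, assignment = df)
}

#' Read a reference sequence from FASTA
#'
#' @param file FASTA path; the first record is used.
#' @return an [Biostrings::RNAString] (DNA input is transcribed, T -> U).
#' @export
readReferenceSequence <- function(file) {
  if (!file.exists(file)) .stopf("file not found: %s", file)
  set <- readRNAStringSet(file)
  if (length(set) == 0L) .stopf("no FASTA records in %s", file)
  set[[1]]
}

#' Write mutant specifications as a delimited table
#'
#' Schema: `id`, `substitutions` (comma-joined tokens), `deletions`
#' (comma-joined positions), `is_wt`, `is_control`.
#'
#' @param library a [MutantLibrary].
#' @param file path.
#' @return the path, invisibly.
#' @export
writeMutantTable <- function(library, file) {
  stopifnot(is(library, "MutantLibrary"))
  m <- mutants(library)
  toks <- vapply(seq_len(nrow(m)), function(k) {
    p <- m$pos[[k]]
    if (!length(p)) return("")
    paste(paste0(m$wt[[k]], p, m$alt[[k]]), collapse = ",")
  }, "")
  dels <- vapply(as.list(m$deletions), paste, "", collapse = ",")
  .writeTable(data.frame(id = m$id, substitutions = toks,
                         deletions = dels, is_wt = m$isWT,
                         is_control = m$isControl,
                         stringsAsFactors = FALSE), file)
}
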