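#' @include AllClasses.R
NULL

# all writers go through temp-file + rename so outputs are never half-written
.atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read a scale table from CSV
#'
#' Expected layout: first column the residue ID, remaining columns numeric
#' factor scores with a header row. An optional `name` column is carried as
#' a display attribute but ignored by computation.
#'
#' @param path CSV file path.
#' @return A [ScaleTable-class].
#' @export
readScales <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("scale table needs an ID column plus factor columns")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate residue ID(s): ", paste(unique(dup), collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  display <- NULL
  if ("name" %in% names(df)) {
    display <- df[["name"]]
    df[["name"]] <- NULL
  }
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   bad, names(df)[j]))
    }
    df[[j]] <- v
  }
  st <- ScaleTable(as.matrix(df), ids = ids)
  if (!is.null(display)) attr(st, "displayNames") <- display
  st
}

#' Write a scale table to CSV
#'
#' Round-trips losslessly with [readScales()] to 12 significant digits.
#'
#' @param scales A [ScaleTable-class].
#' @param path Output CSV path.
#' @export
writeScales <- function(scales, path) {
  s <- scoreMatrix(scales)
  df <- data.frame(id = rownames(s),
                   signif(s, 12L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .atomically(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
}

#' Read a peptide dataset from CSV/TSV
#'
#' Expected columns: `id`, `sequence`, and either `activity` (numeric) or
#' `class` (two-level label). Sequences are validated with [parseSequence()].
#'
#' @param path File path; tab- or comma-separated by extension (.tsv = tab).
#' @return Data frame with id, sequence, and activity or class.
#' @export
readPeptideDataset <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty peptide dataset: ", path)
  need <- c("id", "sequence")
  if (!all(need %in% names(df)))
    stop("peptide dataset needs columns id, sequence, and activity or class")
  if (!("activity" %in% names(df)) && !("class" %in% names(df)))
    stop("peptide dataset needs an 'activity' or 'class' column")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ parseSequence(df$sequence[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("unparseable sequence for sample '%s': %s",
                   df$id[i], conditionMessage(ok)))
  }
  if ("activity" %in% names(df)) df$activity <- as.numeric(df$activity)
  df
}

#' Write a peptide dataset to CSV
#'
#' @param dataset Data frame with id, sequence and activity or class.
#' @param path Output path.
#' @export
writePeptideDataset <- function(dataset, path) {
  .atomically(path, function(tmp)
    utils::write.csv(dataset, tmp, row.names = FALSE, quote = FALSE))
}

.matrixToJSON <- function(m) {
  list(rows = rownames(m), cols = colnames(m),
       values = unname(apply(m, 1L, identity, simplify = FALSE)))
}

.matrixFromJSON <- function(x) {
  v <- do.call(rbind, lapply(x$values, as.numeric))
  dimnames(v) <- list(unlist(x$rows), unlist(x$cols))
  v
}

#' Serialize a factor model to JSON
#'
#' All matrices are written row-major with named axes; [readFactorModel()]
#' restores an identical model.
#'
#' @param model A [FactorModel-class].
#' @param path Output JSON path.
#' @export
writeFactorModel <- function(model, path) {
  obj <- list(
    nFactors = model@nFactors,
    center = as.list(model@center), scale = as.list(model@scale),
    eigenvalues = model@eigenvalues,
    unrotated = .matrixToJSON(model@unrotated),
    pattern = .matrixToJSON(model@pattern),
    phi = .matrixToJSON(model@phi),
    communalities = as.list(model@communalities),
    scoreCoefficients = .matrixToJSON(model@scoreCoefficients),
    explainedVariance = model@explainedVariance,
    promaxPower = model@promaxPower,
    scoreMethod = model@scoreMethod)
  .atomically(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
}

#' Restore a factor model written by [writeFactorModel()]
#'
#' @param path JSON path.
#' @return A [FactorModel-class].
#' @export
readFactorModel <- function(path) {
  x <- jsonlite::read_json(path)
  new("FactorModel",
      nFactors = as.integer(x$nFactors),
      center = unlist(x$center), scale = unlist(x$scale),
      eigenvalues = as.numeric(unlist(x$eigenvalues)),
      unrotated = .matrixFromJSON(x$unrotated),
      pattern = .matrixFromJSON(x$pattern),
      phi = .matrixFromJSON(x$phi),
      communalities = unlist(x$communalities),
      scoreCoefficients = .matrixFromJSON(x$scoreCoefficients),
      explainedVariance = as.numeric(x$explainedVariance),
      promaxPower = as.integer(x$promaxPower),
      scoreMethod = as.character(x$scoreMethod))
}
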