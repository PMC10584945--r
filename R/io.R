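# Readers and writers for Bonn-style ASCII records and feature tables.

#' Read a Bonn-format ASCII EEG record
#'
#' Bonn records are plain ASCII files with one amplitude (microvolts) per
#' line; the public distribution stores 4097 samples per record captured at
#' 173.61 Hz. Blank lines and surrounding whitespace are tolerated; any other
#' unparseable line is an error naming the line.
#'
#' @param path path to the record file.
#' @param label class label to attach (`"normal"`, `"interictal"`, `"ictal"`,
#'   or `"unknown"`).
#' @param fs sampling rate in Hz; the Bonn rate by default.
#' @return An [eeg_record].
#' @export
read_bonn_record <- function(path, label = "unknown", fs = 173.61) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- trimmed != ""
  if (!any(keep)) stop_arg("empty record file: %s", path)
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop_arg("cannot parse '%s' as a number at line %d of %s",
             trimmed[keep][is.na(vals)][1L], bad, path)
  }
  eeg_record(vals, fs = fs, label = label,
             record_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a record as a Bonn-format ASCII file
#'
#' One amplitude per line, rounded to integers as in the public distribution.
#'
#' @param record an [eeg_record].
#' @param path output file path.
#' @param digits decimal digits to keep; `0` (default) writes integers.
#' @return `path`, invisibly.
#' @export
write_bonn_record <- function(record, path, digits = 0) {
  stopifnot(inherits(record, "eeg_record"))
  writeLines(formatC(round(record$samples, digits), format = "f",
                     digits = digits), path)
  invisible(path)
}

#' Load a dataset from directories of Bonn-format records
#'
#' @param dir_map named character vector mapping directory paths to class
#'   labels, e.g. `c(A = "normal", D = "interictal", E = "ictal")` where the
#'   names are directories. Records within a directory are read in
#'   lexicographic (locale-independent) filename order.
#' @param fs sampling rate passed to [read_bonn_record()].
#' @return An [eeg_dataset].
#' @export
load_dataset <- function(dir_map, fs = 173.61) {
  if (length(dir_map) == 0L || is.null(names(dir_map)) || any(names(dir_map) == "")) {
    stop_arg("'dir_map' must be a named vector: names are directories, values labels")
  }
  records <- list()
  for (dir in names(dir_map)) {
    label <- unname(dir_map[[dir]])
    if (!dir.exists(dir)) stop_arg("directory not found: %s", dir)
    files <- list.files(dir, full.names = TRUE)
    files <- files[!dir.exists(files)]
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L) stop_arg("no record files in directory: %s", dir)
    parsed <- lapply(files, function(f) tryCatch(read_bonn_record(f, label, fs),
                                                 error = function(e) e))
    failed <- vapply(parsed, inherits, logical(1), "error")
    if (any(failed)) {
      stop_arg("unreadable record files in %s: %s", dir,
               paste(basename(files[failed]), collapse = ", "))
    }
    records <- c(records, parsed)
  }
  class_names <- unique(c(intersect(c("normal", "interictal", "ictal"),
                                    unname(unlist(dir_map))),
                          setdiff(unname(unlist(dir_map)), c("normal", "interictal", "ictal"))))
  eeg_dataset(records, class_names = class_names)
}

#' Write and read feature tables as CSV
#'
#' The on-disk dialect is fixed: comma-separated, UTF-8, `.` decimal, a header
#' row of feature names, and a final `label` column. Numeric values are
#' written with full decimal precision (17 significant digits) so that
#' `read_feature_table(write_feature_table(x))` reproduces the numeric payload
#' bit for bit.
#'
#' @param table a feature table: data frame of numeric feature columns plus a
#'   final `label` column (as produced by [extract_table()]).
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_arg("'table' must be a non-empty data frame")
  }
  if (!"label" %in% names(table)) stop_arg("'table' must have a 'label' column")
  feat <- setdiff(names(table), "label")
  if (length(feat) == 0L) stop_arg("'table' has no feature columns")
  num <- vapply(table[feat], is.numeric, logical(1))
  if (!all(num)) stop_arg("non-numeric feature columns: %s",
                          paste(feat[!num], collapse = ", "))
  cells <- vapply(table[feat], function(col) sprintf("%.17g", col),
                  character(nrow(table)))
  if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(c(feat, "label"), collapse = ","),
             paste(apply(cbind(cells, as.character(table$label)), 1L, paste,
                         collapse = ","), collapse = NULL))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop_arg("feature table %s has no data rows", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[length(header)] != "label") {
    stop_arg("last column of %s must be 'label'", path)
  }
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1L]
    stop_arg("row %d of %s has %d fields, expected %d",
             bad, path, nfield[bad], length(header))
  }
  m <- do.call(rbind, rows)
  feat <- header[-length(header)]
  out <- as.data.frame(apply(m[, -ncol(m), drop = FALSE], 2L, as.numeric,
                             simplify = TRUE))
  if (nrow(m) == 1L) out <- as.data.frame(as.list(as.numeric(m[1L, -ncol(m)])))
  names(out) <- feat
  out$label <- m[, ncol(m)]
  out
}
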