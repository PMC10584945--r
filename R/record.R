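#' EEG record and dataset containers
#'
#' An `eeg_record` holds one single-channel EEG time series together with its
#' sampling rate, class label and identifier. An `eeg_dataset` is an ordered
#' collection of records sharing one sampling rate.
#'
#' @param samples numeric vector of amplitudes (microvolts).
#' @param fs sampling rate in Hz (positive).
#' @param label one of `"normal"`, `"interictal"`, `"ictal"`, `"unknown"`.
#' @param record_id character identifier.
#' @return An object of class `eeg_record`.
#' @examples
#' r <- eeg_record(sin(seq_len(512) / 10), fs = 173.61, label = "normal")
#' r
#' @export
eeg_record <- function(samples, fs = 173.61, label = "unknown", record_id = "record") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_arg("'samples' must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_arg("'fs' must be a single positive number")
  }
  label <- match.arg(label, c("normal", "interictal", "ictal", "unknown"))
  structure(
    list(samples = as.numeric(samples), fs = fs, label = label,
         record_id = as.character(record_id)[1L]),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s'> %d samples @ %.2f Hz, label: %s\n",
              x$record_id, length(x$samples), x$fs, x$label))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)

#' @rdname eeg_record
#' @param records list of `eeg_record` objects (all with the same `fs`).
#' @param class_names ordered character vector of the label set.
#' @export
eeg_dataset <- function(records,
                        class_names = c("normal", "interictal", "ictal")) {
  if (!is.list(records) || length(records) == 0L) {
    stop_arg("'records' must be a non-empty list of eeg_record objects")
  }
  ok <- vapply(records, inherits, logical(1), "eeg_record")
  if (!all(ok)) stop_arg("all elements of 'records' must be eeg_record objects")
  fss <- vapply(records, function(r) r$fs, numeric(1))
  if (length(unique(fss)) != 1L) stop_arg("all records must share one sampling rate")
  labs <- vapply(records, function(r) r$label, character(1))
  bad <- setdiff(unique(labs), class_names)
  if (length(bad)) {
    stop_arg("record labels not in class_names: %s", paste(bad, collapse = ", "))
  }
  structure(list(records = records, class_names = class_names),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- vapply(x$records, function(r) r$label, character(1))
  tab <- table(factor(labs, levels = x$class_names))
  cat(sprintf("<eeg_dataset> %d records @ %.2f Hz\n",
              length(x$records), x$records[[1L]]$fs))
  print(tab)
  invisible(x)
}

#' @export
length.eeg_dataset <- function(x) length(x$records)

dataset_labels <- function(dataset) {
  vapply(dataset$records, function(r) r$label, character(1))
}
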