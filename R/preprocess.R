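# Preprocessing: band-limiting, missing-data checks, amplitude normalization.

#' Zero-phase low-pass filter an EEG record
#'
#' Band-limits the record to `[0, cutoff_hz]` with an order-`order`
#' Butterworth filter applied forward and backward (zero phase), so waveform
#' morphology — and with it the Hjorth descriptors — is not distorted by
#' phase shifts.
#'
#' @param record an [eeg_record].
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param order Butterworth order (per pass).
#' @return the filtered [eeg_record] (same length).
#' @export
lowpass_filter <- function(record, cutoff_hz = 40, order = 4) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= record$fs / 2) {
    stop_arg("cutoff_hz must lie in (0, fs/2) = (0, %.3f)", record$fs / 2)
  }
  bf <- signal::butter(order, cutoff_hz / (record$fs / 2), type = "low")
  # odd-symmetric edge extension before the forward-backward pass suppresses
  # startup transients at the record boundaries
  x <- record$samples
  n <- length(x)
  pad <- min(n - 1L, 3L * (order * 2L + 1L) * 3L)
  if (pad > 0L) {
    left <- 2 * x[1L] - x[seq(pad + 1L, 2L, -1L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad, -1L)]
    ext <- c(left, x, right)
    y <- as.numeric(signal::filtfilt(bf, ext))
    record$samples <- y[(pad + 1L):(pad + n)]
  } else {
    record$samples <- as.numeric(signal::filtfilt(bf, x))
  }
  record
}

#' Check a record for missing samples
#'
#' In strict mode any missing (NA/NaN) sample is an error naming its indices.
#' In lenient mode interior gaps are filled by linear interpolation between
#' the nearest finite neighbours and reported; gaps at either end have no
#' neighbour on one side and are always an error.
#'
#' @param record an [eeg_record].
#' @param mode `"strict"` or `"lenient"`.
#' @return list with `record` (possibly interpolated), `n_missing`, and
#'   `missing_idx`.
#' @export
check_missing <- function(record, mode = c("strict", "lenient")) {
  stopifnot(inherits(record, "eeg_record"))
  mode <- match.arg(mode)
  bad <- which(!is.finite(record$samples))
  if (length(bad) == 0L) {
    return(list(record = record, n_missing = 0L, missing_idx = integer()))
  }
  if (mode == "strict") {
    stop_arg("missing samples at indices: %s",
             paste(utils::head(bad, 10L), collapse = ", "))
  }
  n <- length(record$samples)
  if (1L %in% bad || n %in% bad) {
    stop_arg("missing samples at record boundary (no neighbour to interpolate from)")
  }
  good <- setdiff(seq_len(n), bad)
  record$samples[bad] <- stats::approx(good, record$samples[good], xout = bad)$y
  list(record = record, n_missing = length(bad), missing_idx = bad)
}

#' Normalize a record to the interval [-1, 1]
#'
#' Divides by the maximum absolute amplitude, preserving the zero line and
#' waveform symmetry; any nonzero record attains `max(abs(.)) == 1`, and an
#' all-zero record is returned unchanged. Idempotent.
#'
#' @param record an [eeg_record].
#' @return the normalized [eeg_record].
#' @export
normalize_record <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  if (any(!is.finite(record$samples))) stop_arg("record has non-finite samples")
  m <- max(abs(record$samples))
  if (m > 0) record$samples <- record$samples / m
  record
}

#' Run the full preprocessing chain on one record
#'
#' Missing-data check, zero-phase low-pass to `cutoff_hz`, and (optionally)
#' amplitude normalization to `[-1, 1]`.
#'
#' @param record an [eeg_record].
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param order Butterworth order.
#' @param missing_mode `"strict"` or `"lenient"`.
#' @param normalize whether to rescale to `[-1, 1]` after filtering.
#' @return the preprocessed [eeg_record].
#' @export
preprocess_record <- function(record, cutoff_hz = 40, order = 4,
                              missing_mode = "strict", normalize = TRUE) {
  record <- check_missing(record, missing_mode)$record
  record <- lowpass_filter(record, cutoff_hz, order)
  if (normalize) record <- normalize_record(record)
  record
}
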