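# Per-sub-band descriptors and assembly of the 143-element feature vector.
#
# Eight descriptors are computed on each of the 16 sub-bands (mean absolute
# value, standard deviation, skewness, kurtosis, RMS power, and the Hjorth
# activity/mobility/complexity triple), plus the 15 ratios of mean absolute
# values between frequency-adjacent sub-bands: 16*8 + 15 = 16*9 - 1 = 143.
# All moments use the population divisor M. Degenerate inputs (zero variance,
# zero denominators) return 0 rather than NaN so downstream selection never
# crashes on a constant sub-band; each such case is flagged via a warning
# when `warn = TRUE` on the vector assembler.

#' Sub-band descriptor functions
#'
#' @param y,z numeric coefficient vectors (non-empty, finite).
#' @return a single numeric value.
#' @name subband_features
NULL

#' @rdname subband_features
#' @export
mav <- function(y) {
  if (length(y) == 0L) stop_arg("empty input")
  mean(abs(y))
}

#' @rdname subband_features
#' @export
stdev <- function(y) {
  if (length(y) == 0L) stop_arg("empty input")
  mu <- mean(y)
  sqrt(mean((y - mu)^2))
}

#' @rdname subband_features
#' @param moments `"standard"` for the usual standardized third/fourth
#'   moments; `"as_printed"` wraps them in an outer square root (undefined for
#'   negative skewness, mapped to 0) for auditing against sources that print
#'   that form.
#' @export
skewness <- function(y, moments = c("standard", "as_printed")) {
  moments <- match.arg(moments)
  s <- stdev(y)
  if (s == 0) return(0)
  m3 <- mean(((y - mean(y)) / s)^3)
  if (moments == "as_printed") {
    if (m3 < 0) return(0)
    return(sqrt(m3))
  }
  m3
}

#' @rdname subband_features
#' @export
kurtosis <- function(y, moments = c("standard", "as_printed")) {
  moments <- match.arg(moments)
  s <- stdev(y)
  if (s == 0) return(0)
  m4 <- mean(((y - mean(y)) / s)^4)  # non-excess: Gaussian -> 3
  if (moments == "as_printed") return(sqrt(m4))
  m4
}

#' @rdname subband_features
#' @export
rms <- function(y) {
  if (length(y) == 0L) stop_arg("empty input")
  sqrt(mean(y^2))
}

#' @rdname subband_features
#' @export
mav_ratio <- function(y, z) {
  if (length(y) == 0L || length(z) == 0L) stop_arg("empty input")
  den <- sum(abs(z))
  if (den == 0) return(0)
  sum(abs(y)) / den
}

#' @rdname subband_features
#' @export
hjorth_activity <- function(y) {
  if (length(y) == 0L) stop_arg("empty input")
  stdev(y)^2
}

#' @rdname subband_features
#' @export
hjorth_mobility <- function(y) {
  if (length(y) < 2L) stop_arg("need at least 2 samples")
  v <- hjorth_activity(y)
  if (v == 0) return(0)
  sqrt(hjorth_activity(diff(y)) / v)
}

#' @rdname subband_features
#' @export
hjorth_complexity <- function(y) {
  if (length(y) < 3L) stop_arg("need at least 3 samples")
  m <- hjorth_mobility(y)
  if (m == 0) return(0)
  md <- hjorth_mobility(diff(y))
  md / m
}

#' Names of the 143 features, in canonical order
#'
#' Leaves are numbered `n00`..`n15` in ascending frequency; per-leaf
#' descriptors come first (8 per leaf), then the 15 adjacent-band MAV ratios.
#'
#' @param n_leaves number of sub-bands (16 for the depth-4 packet tree).
#' @return character vector of length `9*n_leaves - 1`.
#' @export
feature_names <- function(n_leaves = 16L) {
  per <- c("mav", "stdev", "skewness", "kurtosis", "rms",
           "activity", "mobility", "complexity")
  leafnm <- sprintf("n%02d", seq_len(n_leaves) - 1L)
  c(as.vector(t(outer(leafnm, per, paste, sep = "."))),
    sprintf("ratio.n%02d_n%02d", 0:(n_leaves - 2L), 1:(n_leaves - 1L)))
}

#' Extract the feature vector from a sub-band decomposition
#'
#' @param subbands a `subband_set` from [swt_packet()].
#' @param label class label carried into the vector.
#' @param moments moment convention, see [skewness()].
#' @param warn warn when a degenerate guard (zero variance / zero
#'   denominator) fires.
#' @return named numeric vector of length `9*n_leaves - 1` (143 for 16
#'   leaves), with attribute `"label"`.
#' @export
extract_vector <- function(subbands, label = "unknown",
                           moments = "standard", warn = FALSE) {
  stopifnot(inherits(subbands, "subband_set"))
  leaves <- subbands$leaves[subbands$freq_order]
  nl <- length(leaves)
  vals <- numeric(0)
  flagged <- FALSE
  for (lf in leaves) {
    s <- stdev(lf)
    if (s == 0) flagged <- TRUE
    vals <- c(vals, mav(lf), s, skewness(lf, moments), kurtosis(lf, moments),
              rms(lf), hjorth_activity(lf), hjorth_mobility(lf),
              hjorth_complexity(lf))
  }
  for (i in seq_len(nl - 1L)) {
    if (sum(abs(leaves[[i + 1L]])) == 0) flagged <- TRUE
    vals <- c(vals, mav_ratio(leaves[[i]], leaves[[i + 1L]]))
  }
  if (warn && flagged) warning("degenerate sub-band: guarded feature set to 0")
  names(vals) <- feature_names(nl)
  attr(vals, "label") <- label
  vals
}

#' Extract a feature table from a whole dataset
#'
#' Applies the preprocessing chain, length preparation, the undecimated
#' packet decomposition, and [extract_vector()] uniformly to every record.
#'
#' @param dataset an [eeg_dataset].
#' @param config a [pipeline_config()]; controls the filter cutoff, the
#'   normalization switch, the wavelet, depth, and tree shape.
#' @return data frame with one row per record: feature columns in
#'   [feature_names()] order plus a final `label` column; record ids as row
#'   names.
#' @export
extract_table <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  rows <- vector("list", length(dataset$records))
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    rows[[i]] <- tryCatch({
      pre <- preprocess_record(rec, cutoff_hz = config$lowpass_cutoff_hz,
                               order = config$lowpass_order,
                               missing_mode = config$missing_mode,
                               normalize = config$normalize_before_features)
      sam <- prepare_length(pre$samples, config$depth)
      sb <- swt_packet(sam, wavelet = config$wavelet, depth = config$depth,
                       tree = config$tree)
      extract_vector(sb, label = rec$label, moments = config$moments)
    }, error = function(e) {
      stop_arg("record '%s': %s", rec$record_id, conditionMessage(e))
    })
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- vapply(dataset$records, function(r) r$label, character(1))
  rownames(out) <- make.unique(vapply(dataset$records,
                                      function(r) r$record_id, character(1)))
  out
}
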