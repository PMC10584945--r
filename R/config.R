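# Pipeline configuration: one flat object mirrored by the YAML/JSON config
# file and overridable from the CLI.

#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with the published
#' defaults: 40 Hz zero-phase low-pass, `[-1, 1]` normalization before
#' decomposition, db4 depth-4 undecimated packet tree (16 sub-bands),
#' dragonfly selection (population 10, 100 iterations, alpha 0.99/beta 0.01,
#' tau 4 -> 0.01, weights s=0.1 a=0.1 c=0.7 f=1 e=1 w=0.85) with 5-NN 10-fold
#' cross-validation fitness, a (10, 10, 10) sigmoid MLP, and an 80/20
#' stratified split.
#'
#' @param wavelet,depth,tree decomposition settings, see [swt_packet()].
#' @param lowpass_cutoff_hz,lowpass_order low-pass filter settings.
#' @param missing_mode `"strict"` or `"lenient"`, see [check_missing()].
#' @param normalize_before_features rescale records to `[-1, 1]` before
#'   decomposition.
#' @param moments moment convention for skewness/kurtosis, see [skewness()].
#' @param bdfa a [bdfa_config()].
#' @param hidden integer vector of hidden-layer sizes for the classifier.
#' @param max_epochs optimizer iteration cap for classifier training.
#' @param split_fraction training fraction of the stratified split.
#' @param seed master seed for the pipeline.
#' @return object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(wavelet = "db4", depth = 4L,
                            tree = "packet16",
                            lowpass_cutoff_hz = 40, lowpass_order = 4,
                            missing_mode = "strict",
                            normalize_before_features = TRUE,
                            moments = "standard",
                            bdfa = bdfa_config(),
                            hidden = c(10L, 10L, 10L),
                            max_epochs = 500L,
                            split_fraction = 0.8,
                            seed = 1L) {
  stopifnot(depth >= 1, split_fraction > 0, split_fraction < 1,
            all(hidden >= 1), length(hidden) >= 1)
  structure(list(wavelet = wavelet, depth = as.integer(depth), tree = tree,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 lowpass_order = lowpass_order,
                 missing_mode = missing_mode,
                 normalize_before_features = isTRUE(normalize_before_features),
                 moments = moments, bdfa = bdfa,
                 hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `bdfa:` mirror [bdfa_config()]. Absent keys keep their defaults.
#'
#' @param path config file (`.yml`/`.yaml`/`.json`).
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  bd <- do.call(bdfa_config, raw$bdfa %||% list())
  raw$bdfa <- NULL
  do.call(pipeline_config, c(raw, list(bdfa = bd)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
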