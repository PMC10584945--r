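# Synthetic three-class EEG generator and planted-feature test tables.
#
# The generator emulates the phenomenology of the three clinical classes as a
# scalp recording would show them: low-amplitude mixed-rhythm background
# (normal), the same background with sporadic high-amplitude biphasic sharp
# transients (interictal), and high-amplitude rhythmic 3-5 Hz spike-and-wave
# discharge (ictal). Record geometry mirrors the Bonn corpus: 173.61 Hz and
# 23.6 s, i.e. 4097 samples.

#' Specification for the synthetic EEG generator
#'
#' @param n_per_class records per class.
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed master seed; per-record seeds are spawned from it by counter.
#' @param sigma_bg Gaussian background standard deviation (microvolts).
#' @param alpha_amp,alpha_freq amplitude (microvolts) and frequency (Hz) of the
#'   posterior alpha rhythm added to every class.
#' @param spike_rate mean rate (per second) of interictal sharp transients.
#' @param spike_amp amplitude of interictal transients (microvolts); kept at
#'   least five background standard deviations so transients stand clear of
#'   the noise floor.
#' @param spike_width_s transient width in seconds (biphasic, ~60 ms).
#' @param ictal_freq_range range (Hz) from which each ictal record draws its
#'   spike-and-wave fundamental.
#' @param ictal_mult peak-amplitude multiplier of the ictal rhythm relative to
#'   the typical normal peak (`alpha_amp + 3*sigma_bg`); must exceed 1.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 100L,
                           duration_s = 23.6,
                           fs = 173.61,
                           seed = 1L,
                           sigma_bg = 20,
                           alpha_amp = 30,
                           alpha_freq = 10,
                           spike_rate = 0.4,
                           spike_amp = 6 * sigma_bg,
                           spike_width_s = 0.06,
                           ictal_freq_range = c(3, 5),
                           ictal_mult = 6) {
  stopifnot(is_count(n_per_class), n_per_class >= 1,
            duration_s > 0, fs > 0,
            sigma_bg >= 0, alpha_amp >= 0, alpha_freq > 0,
            spike_rate >= 0, spike_amp >= 0, spike_width_s > 0,
            length(ictal_freq_range) == 2L,
            ictal_freq_range[1] > 0,
            ictal_freq_range[2] >= ictal_freq_range[1],
            ictal_mult > 1)
  # third harmonic of the fastest ictal fundamental must stay below Nyquist
  if (fs <= 2 * max(3 * ictal_freq_range[2], alpha_freq)) {
    stop_arg("fs must exceed twice the highest generated frequency")
  }
  structure(list(n_per_class = as.integer(n_per_class), duration_s = duration_s,
                 fs = fs, seed = as.integer(seed), sigma_bg = sigma_bg,
                 alpha_amp = alpha_amp, alpha_freq = alpha_freq,
                 spike_rate = spike_rate, spike_amp = spike_amp,
                 spike_width_s = spike_width_s,
                 ictal_freq_range = ictal_freq_range,
                 ictal_mult = ictal_mult),
            class = "synthetic_spec")
}

# biphasic transient template: one positive and one negative lobe within
# `width_s`, windowed so it decays smoothly to zero.
spike_template <- function(fs, width_s) {
  n <- max(3L, round(width_s * fs))
  t <- seq(-1, 1, length.out = n)
  sin(pi * t) * exp(-4 * t^2)
}

#' Generate one synthetic EEG record
#'
#' Deterministic given `(spec$seed, record_seed)`.
#'
#' @param class_label `"normal"`, `"interictal"` or `"ictal"`.
#' @param spec a [synthetic_spec()].
#' @param record_seed integer distinguishing records under one master seed.
#' @return An [eeg_record].
#' @export
generate_record <- function(class_label, spec = synthetic_spec(),
                            record_seed = 1L) {
  if (!class_label %in% c("normal", "interictal", "ictal")) {
    stop_arg("unknown class label: %s", as.character(class_label))
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))  # Bonn geometry: 4097
  tt <- (seq_len(n) - 1L) / spec$fs
  with_seed(spawn_seed(spec$seed, record_seed), {
    x <- stats::rnorm(n, 0, spec$sigma_bg) +
      spec$alpha_amp * sin(2 * pi * spec$alpha_freq * tt + stats::runif(1, 0, 2 * pi))
    if (class_label == "interictal" && spec$spike_rate > 0 && spec$spike_amp > 0) {
      k <- stats::rpois(1L, spec$spike_rate * spec$duration_s)
      if (k > 0) {
        # Poisson placement thinned to a 200 ms refractory spacing so
        # transients stay sporadic rather than rhythmic
        times <- sort(stats::runif(k, 0.1, spec$duration_s - 0.1))
        keep <- c(TRUE, diff(times) >= 0.2)
        times <- times[keep]
        tpl <- spike_template(spec$fs, spec$spike_width_s)
        pol <- sample(c(-1, 1), length(times), replace = TRUE)
        for (i in seq_along(times)) {
          at <- round(times[i] * spec$fs) + 1L
          idx <- at:(at + length(tpl) - 1L)
          ok <- idx <= n
          x[idx[ok]] <- x[idx[ok]] + pol[i] * spec$spike_amp * tpl[ok]
        }
      }
    } else if (class_label == "ictal") {
      f0 <- stats::runif(1, spec$ictal_freq_range[1], spec$ictal_freq_range[2])
      ph <- stats::runif(1, 0, 2 * pi)
      peak_normal <- spec$alpha_amp + 3 * spec$sigma_bg
      # fundamental plus two harmonics gives the sharp "spike" riding the wave
      wave <- sin(2 * pi * f0 * tt + ph) +
        0.5 * sin(2 * pi * 2 * f0 * tt + 2 * ph) +
        0.25 * sin(2 * pi * 3 * f0 * tt + 3 * ph)
      wave <- wave / max(abs(wave))
      x <- x + spec$ictal_mult * peak_normal * wave
    }
    eeg_record(x, fs = spec$fs, label = class_label,
               record_id = sprintf("%s_%04d", class_label, as.integer(record_seed)))
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' Produces `3 * n_per_class` records with per-record seeds spawned
#' deterministically (by counter) from `spec$seed`, so any record's content is
#' independent of generation order.
#'
#' @param spec a [synthetic_spec()].
#' @return An [eeg_dataset].
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  classes <- c("normal", "interictal", "ictal")
  counter <- 0L
  records <- vector("list", 3L * spec$n_per_class)
  for (ci in seq_along(classes)) {
    for (i in seq_len(spec$n_per_class)) {
      counter <- counter + 1L
      records[[counter]] <- generate_record(classes[ci], spec, counter)
    }
  }
  eeg_dataset(records, class_names = classes)
}

#' Generate a two-class feature table with planted informative columns
#'
#' A controlled test bed for wrapper feature selection: `informative_idx`
#' columns separate two balanced classes by `effect_size` (class-mean
#' difference in units of the within-class standard deviation, which is 1);
#' every other column is class-independent standard normal noise.
#'
#' @param n_samples total rows (split evenly over classes "c1", "c2").
#' @param n_features number of feature columns.
#' @param informative_idx integer indices (1-based) of informative columns.
#' @param effect_size class-mean separation of informative columns (>= 0).
#' @param seed integer seed.
#' @return data frame of `n_features` numeric columns named `f001`... plus a
#'   final `label` column.
#' @export
generate_planted_table <- function(n_samples, n_features, informative_idx,
                                   effect_size, seed = 1L) {
  stopifnot(is_count(n_samples), n_samples >= 2,
            is_count(n_features), n_features >= 1, effect_size >= 0)
  informative_idx <- as.integer(informative_idx)
  if (length(informative_idx) &&
      (min(informative_idx) < 1L || max(informative_idx) > n_features)) {
    stop_arg("informative_idx out of range 1..%d", n_features)
  }
  n1 <- floor(n_samples / 2)
  lab <- c(rep("c1", n1), rep("c2", n_samples - n1))
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    shift <- ifelse(lab == "c2", effect_size / 2, -effect_size / 2)
    for (j in informative_idx) m[, j] <- m[, j] + shift
    out <- as.data.frame(m)
    names(out) <- sprintf("f%03d", seq_len(n_features))
    out$label <- lab
    out
  })
}
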