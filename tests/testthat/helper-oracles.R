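# Independent definitional oracles, written as naive loops so they share no
# code path with the package implementations.

oracle_mav <- function(y) {
  s <- 0
  for (v in y) s <- s + abs(v)
  s / length(y)
}

oracle_stdev <- function(y) {
  mu <- sum(y) / length(y)
  s <- 0
  for (v in y) s <- s + (v - mu)^2
  sqrt(s / length(y))
}

oracle_skewness <- function(y) {
  mu <- sum(y) / length(y)
  sg <- oracle_stdev(y)
  s <- 0
  for (v in y) s <- s + ((v - mu) / sg)^3
  s / length(y)
}

oracle_kurtosis <- function(y) {
  mu <- sum(y) / length(y)
  sg <- oracle_stdev(y)
  s <- 0
  for (v in y) s <- s + ((v - mu) / sg)^4
  s / length(y)
}

oracle_rms <- function(y) {
  s <- 0
  for (v in y) s <- s + v^2
  sqrt(s / length(y))
}

oracle_mav_ratio <- function(y, z) sum(abs(y)) / sum(abs(z))

oracle_activity <- function(y) oracle_stdev(y)^2

oracle_mobility <- function(y) {
  d <- y[-1] - y[-length(y)]
  sqrt(oracle_activity(d) / oracle_activity(y))
}

oracle_complexity <- function(y) {
  d <- y[-1] - y[-length(y)]
  oracle_mobility(d) / oracle_mobility(y)
}

# circular correlation of x with an a-trous dilated filter, direct double loop
oracle_atrous <- function(x, f, dilation) {
  L <- length(x)
  y <- numeric(L)
  for (n in seq_len(L)) {
    acc <- 0
    for (k in seq_along(f)) {
      acc <- acc + f[k] * x[((n - 1 + dilation * (k - 1)) %% L) + 1]
    }
    y[n] <- acc
  }
  y
}

# confusion counts by explicit enumeration
oracle_confusion <- function(y_true, y_pred, levels) {
  cm <- matrix(0L, length(levels), length(levels),
               dimnames = list(levels, levels))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

# small separable two-class feature table for classifier tests
make_separable_table <- function(n = 60, n_features = 6, seed = 42) {
  tab <- generate_planted_table(n, n_features, informative_idx = 1:2,
                                effect_size = 8, seed = seed)
  tab
}

write_record_file <- function(lines, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}
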