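# Undecimated (stationary) wavelet-packet decomposition.
#
# The decomposition is a full binary tree of depth `depth`: at level j every
# node is filtered with the analysis low-pass and high-pass pair, each
# upsampled a-trous by 2^(j-1), with *circular* (periodic) boundary handling
# and no decimation. Every node therefore keeps the input length, and for an
# orthonormal filter pair each split exactly doubles energy, giving the tight
# frame identity sum(leaf energies) = 2^depth * signal energy.

# db4 analysis filters (orthonormal, ||l|| = 1, sum(l) = sqrt(2)); high-pass
# is the quadrature mirror g[k] = (-1)^k l[N-1-k].
.db4_lo <- c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
             -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
             0.032883011666885197, -0.010597401785069032)

#' Analysis filter pair for a named wavelet
#'
#' @param wavelet wavelet name; `"db4"` and `"haar"` are built in.
#' @return list with `lo` and `hi` numeric filter taps.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  lo <- switch(wavelet,
               db4 = .db4_lo,
               haar = c(1, 1) / sqrt(2),
               stop_arg("unknown wavelet: %s", wavelet))
  n <- length(lo)
  hi <- (-1)^(0:(n - 1L)) * rev(lo)
  list(lo = lo, hi = hi)
}

#' Truncate a signal to a transform-compatible length
#'
#' The undecimated tree requires the length to be divisible by `2^depth`;
#' the signal is truncated to the largest such multiple (a Bonn record of
#' 4097 samples becomes 4096).
#'
#' @param samples numeric vector.
#' @param depth decomposition depth.
#' @return the truncated vector, with attribute `"truncated"` giving the
#'   number of trailing samples dropped.
#' @export
prepare_length <- function(samples, depth = 4) {
  stopifnot(is.numeric(samples), is_count(depth), depth >= 1)
  block <- 2^depth
  if (length(samples) < block) {
    stop_arg("signal of length %d is too short for depth %d (needs >= %d)",
             length(samples), depth, block)
  }
  keep <- as.integer(block * (length(samples) %/% block))
  out <- as.numeric(samples[seq_len(keep)])
  attr(out, "truncated") <- length(samples) - keep
  out
}

# circular correlation of x with filter f dilated a-trous by `dilation`:
# y[n] = sum_k f[k+1] * x[(n-1 + dilation*k) mod L + 1], vectorized over n.
atrous_filter <- function(x, f, dilation) {
  L <- length(x)
  y <- numeric(L)
  idx <- seq_len(L) - 1L
  for (k in seq_along(f)) {
    y <- y + f[k] * x[((idx + dilation * (k - 1L)) %% L) + 1L]
  }
  y
}

#' Undecimated wavelet-packet decomposition
#'
#' Decomposes `samples` into the `2^depth` terminal sub-bands of a full
#' undecimated wavelet-packet tree (both the approximation and the detail
#' branch are split at every level). Circular boundary handling; every leaf
#' has the input length.
#'
#' @param samples numeric vector with length divisible by `2^depth` (see
#'   [prepare_length()]).
#' @param wavelet wavelet name (see [wavelet_filters()]).
#' @param depth tree depth; 4 gives the 16 sub-bands used by the feature set.
#' @param tree `"packet16"` (full tree, default) or `"swt8"` (plain stationary
#'   wavelet transform: only approximations are split, yielding the `2*depth`
#'   coefficient sets cA1..cA_depth, cD1..cD_depth — 8 at depth 4).
#' @return An object of class `subband_set`: list with `leaves` (list of
#'   coefficient vectors in natural filter-path order), `wavelet`, `depth`,
#'   `tree`, and `freq_order` (permutation of leaf indices into ascending
#'   nominal frequency).
#' @export
swt_packet <- function(samples, wavelet = "db4", depth = 4, tree = c("packet16", "swt8")) {
  tree <- match.arg(tree)
  stopifnot(is.numeric(samples), is_count(depth), depth >= 1)
  flt <- wavelet_filters(wavelet)
  if (length(samples) %% 2^depth != 0L) {
    stop_arg("signal length %d is not divisible by 2^depth = %d; use prepare_length()",
             length(samples), 2^depth)
  }
  nodes <- list(as.numeric(samples))
  if (tree == "packet16") {
    for (j in seq_len(depth)) {
      dil <- 2^(j - 1L)
      nxt <- vector("list", 2L * length(nodes))
      for (i in seq_along(nodes)) {
        nxt[[2L * i - 1L]] <- atrous_filter(nodes[[i]], flt$lo, dil)
        nxt[[2L * i]] <- atrous_filter(nodes[[i]], flt$hi, dil)
      }
      nodes <- nxt
    }
  } else {
    # plain SWT: split only the running approximation, keeping both the
    # approximation and detail at every level: (cA1..cA_depth, cD1..cD_depth)
    approx <- as.numeric(samples)
    approxs <- vector("list", depth)
    details <- vector("list", depth)
    for (j in seq_len(depth)) {
      dil <- 2^(j - 1L)
      details[[j]] <- atrous_filter(approx, flt$hi, dil)
      approx <- atrous_filter(approx, flt$lo, dil)
      approxs[[j]] <- approx
    }
    nodes <- c(approxs, details)
  }
  structure(list(leaves = nodes, wavelet = wavelet, depth = as.integer(depth),
                 tree = tree,
                 freq_order = if (tree == "packet16") leaf_frequency_order(depth)
                              else seq_along(nodes)),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d leaves of length %d (%s, depth %d, %s tree)\n",
              length(x$leaves), length(x$leaves[[1L]]), x$wavelet, x$depth,
              x$tree))
  invisible(x)
}

#' Frequency (sequency) ordering of packet-tree leaves
#'
#' In natural filter-path order (low branch first at every split) the leaves
#' of an undecimated packet tree are not frequency-sorted: the dilated
#' filters' passbands fold so that ascending frequency visits the leaves in
#' Gray-code order. Returns the permutation `p` such that `leaves[p]` is in
#' ascending nominal frequency.
#'
#' @param depth tree depth (or a `subband_set`, whose depth is used).
#' @return integer permutation of `1:2^depth`.
#' @export
leaf_frequency_order <- function(depth) {
  if (inherits(depth, "subband_set")) depth <- depth$depth
  stopifnot(is_count(depth), depth >= 1)
  r <- 0:(2^depth - 1L)
  gray <- bitwXor(r, r %/% 2L)
  gray + 1L
}
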