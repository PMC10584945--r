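# Multilayer perceptron classifier: fully connected, sigmoid hidden layers,
# softmax output, trained by full-batch BFGS on L2-regularized cross-entropy
# with analytic gradients. Small by design (default 3 x 10 hidden neurons);
# inputs are standardized with training-set statistics.

#' Classifier architecture specification
#'
#' @param hidden integer vector of hidden-layer sizes (default three layers
#'   of ten neurons).
#' @param max_epochs optimizer iteration cap.
#' @param decay L2 weight-decay coefficient.
#' @param seed weight-initialization seed.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden = c(10L, 10L, 10L), max_epochs = 500L,
                            decay = 1e-4, seed = 1L) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1), max_epochs >= 1, decay >= 0)
  structure(list(hidden = as.integer(hidden), max_epochs = as.integer(max_epochs),
                 decay = decay, seed = as.integer(seed)),
            class = "classifier_spec")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# pack/unpack the weight list <-> flat parameter vector
mlp_shapes <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) c(sizes[l] + 1L, sizes[l + 1L]))
}

unflatten <- function(theta, shapes) {
  out <- vector("list", length(shapes))
  pos <- 0L
  for (l in seq_along(shapes)) {
    n <- prod(shapes[[l]])
    out[[l]] <- matrix(theta[pos + seq_len(n)], shapes[[l]][1L], shapes[[l]][2L])
    pos <- pos + n
  }
  out
}

mlp_forward <- function(W, x) {
  nlay <- length(W)
  acts <- vector("list", nlay + 1L)
  acts[[1L]] <- x
  for (l in seq_len(nlay)) {
    z <- cbind(1, acts[[l]]) %*% W[[l]]
    acts[[l + 1L]] <- if (l < nlay) sigmoid(z) else z
  }
  # softmax over the output scores
  z <- acts[[nlay + 1L]]
  z <- z - apply(z, 1L, max)
  p <- exp(z)
  acts[[nlay + 1L]] <- p / rowSums(p)
  acts
}

#' Train the MLP classifier on a feature table
#'
#' @param table training feature table (numeric columns + `label`).
#' @param mask 0/1 vector over the feature columns; at least one bit set.
#' @param spec a [classifier_spec()].
#' @return object of class `mlp_net` with the fitted weights, the feature
#'   mask and names, class levels, input standardization, and the initial and
#'   final training loss.
#' @export
train_classifier <- function(table, mask, spec = classifier_spec()) {
  feat <- setdiff(names(table), "label")
  if (length(mask) != length(feat)) {
    stop_arg("mask length %d != feature count %d", length(mask), length(feat))
  }
  if (sum(mask != 0) == 0L) stop_arg("mask selects no features")
  labels <- as.character(table$label)
  levels <- sort(unique(labels))
  if (length(levels) < 2L) stop_arg("training data must contain >= 2 classes")
  x <- as.matrix(table[feat])[, mask != 0, drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  y <- matrix(0, nrow(x), length(levels))
  y[cbind(seq_len(nrow(x)), match(labels, levels))] <- 1

  sizes <- c(ncol(xs), spec$hidden, length(levels))
  shapes <- mlp_shapes(sizes)
  npar <- sum(vapply(shapes, prod, numeric(1)))
  theta0 <- with_seed(spec$seed, {
    unlist(lapply(shapes, function(sh) {
      lim <- sqrt(6 / sum(sh))
      stats::runif(prod(sh), -lim, lim)
    }))
  })

  nlay <- length(shapes)
  n <- nrow(xs)
  loss_fn <- function(theta) {
    W <- unflatten(theta, shapes)
    p <- mlp_forward(W, xs)[[nlay + 1L]]
    -sum(y * log(pmax(p, 1e-12))) / n + spec$decay * sum(theta^2)
  }
  grad_fn <- function(theta) {
    W <- unflatten(theta, shapes)
    acts <- mlp_forward(W, xs)
    delta <- (acts[[nlay + 1L]] - y) / n
    g <- vector("list", nlay)
    for (l in nlay:1) {
      g[[l]] <- crossprod(cbind(1, acts[[l]]), delta)
      if (l > 1L) {
        back <- delta %*% t(W[[l]][-1L, , drop = FALSE])
        delta <- back * acts[[l]] * (1 - acts[[l]])
      }
    }
    unlist(g) + 2 * spec$decay * theta
  }
  loss0 <- loss_fn(theta0)
  fit <- stats::optim(theta0, loss_fn, grad_fn, method = "BFGS",
                      control = list(maxit = spec$max_epochs, reltol = 1e-10))
  structure(list(weights = unflatten(fit$par, shapes), sizes = sizes,
                 mask = mask, feature_names = feat, levels = levels,
                 center = mu, scale = sdv,
                 loss_initial = loss0, loss_final = fit$value,
                 spec = spec),
            class = "mlp_net")
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("<mlp_net> %s network, classes: %s\n",
              paste(x$sizes, collapse = "-"), paste(x$levels, collapse = "/")))
  cat(sprintf("  %d/%d features; training loss %.4f -> %.4f\n",
              sum(x$mask != 0), length(x$mask), x$loss_initial, x$loss_final))
  invisible(x)
}

#' Predict class labels with a trained MLP
#'
#' @param object an `mlp_net` from [train_classifier()].
#' @param newdata feature table (or numeric matrix) with the same feature
#'   columns the model was trained on.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return character vector of labels, or a probability matrix.
#' @export
predict.mlp_net <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    feat <- setdiff(names(newdata), "label")
    if (!identical(feat, object$feature_names)) {
      stop_arg("newdata feature columns do not match the training features")
    }
    x <- as.matrix(newdata[feat])
  } else {
    x <- as.matrix(newdata)
    if (ncol(x) != length(object$mask)) {
      stop_arg("newdata has %d columns, expected %d", ncol(x), length(object$mask))
    }
  }
  x <- x[, object$mask != 0, drop = FALSE]
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  p <- mlp_forward(object$weights, xs)[[length(object$weights) + 1L]]
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  object$levels[max.col(p, ties.method = "first")]
}
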