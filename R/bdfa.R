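# Binary dragonfly algorithm (BDFA) wrapper feature selection.
#
# Each dragonfly carries a binary position (a feature mask) and a real step
# vector. Five swarm behaviors drive the step update — separation, alignment,
# cohesion, attraction to the food source (best solution) and distraction
# from the enemy (worst solution) — and a time-varying V-shaped transfer
# function maps step components to bit probabilities. The wrapper fitness is
# alpha * (10-fold cross-validated KNN error on the masked features) +
# beta * (fraction of features selected).

#' Configuration for the binary dragonfly optimizer
#'
#' Defaults are the published settings: alpha 0.99, beta 0.01, population 10,
#' 100 iterations, tau from 4 down to 0.01, behavior weights s=0.1, a=0.1,
#' c=0.7, f=1, e=1, inertia w=0.85, 5-nearest-neighbour fitness under
#' stratified 10-fold cross-validation.
#'
#' @param population swarm size (>= 2).
#' @param iterations iteration budget T.
#' @param s,a,c,f,e,w separation, alignment, cohesion, food, enemy, and
#'   inertia weights.
#' @param tau_max,tau_min transfer-function temperature schedule endpoints
#'   (`tau_max > tau_min > 0`).
#' @param alpha,beta fitness weights on error rate and subset size
#'   (`alpha + beta` must equal 1).
#' @param knn_k neighbours for the KNN fitness classifier.
#' @param cv_folds cross-validation folds.
#' @param step_clamp componentwise step magnitude cap.
#' @param position_rule `"set"` (bit := 1 with probability T, as the update
#'   rule is printed) or `"flip"` (bit toggles with probability T, the common
#'   binary-swarm variant).
#' @param separation `"standard"` (`-sum(X_i - X_j)`) or `"literal"`
#'   (`-sum(X - X_i)` with the operands as printed).
#' @param inertia `"step"` (inertia on the previous step, the standard
#'   dragonfly recursion) or `"position_literal"` (inertia on the position).
#' @param seed optimizer seed.
#' @return object of class `bdfa_config`.
#' @export
bdfa_config <- function(population = 10L, iterations = 100L,
                        s = 0.1, a = 0.1, c = 0.7, f = 1, e = 1, w = 0.85,
                        tau_max = 4, tau_min = 0.01,
                        alpha = 0.99, beta = 0.01,
                        knn_k = 5L, cv_folds = 10L,
                        step_clamp = 6,
                        position_rule = c("set", "flip"),
                        separation = c("standard", "literal"),
                        inertia = c("step", "position_literal"),
                        seed = 1L) {
  stopifnot(population >= 2, iterations >= 1,
            tau_max > tau_min, tau_min > 0,
            abs(alpha + beta - 1) < 1e-12,
            knn_k >= 1, cv_folds >= 2, step_clamp > 0)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 s = s, a = a, c = c, f = f, e = e, w = w,
                 tau_max = tau_max, tau_min = tau_min,
                 alpha = alpha, beta = beta,
                 knn_k = as.integer(knn_k), cv_folds = as.integer(cv_folds),
                 step_clamp = step_clamp,
                 position_rule = match.arg(position_rule),
                 separation = match.arg(separation),
                 inertia = match.arg(inertia),
                 seed = as.integer(seed)),
            class = "bdfa_config")
}

#' Transfer-function temperature schedule
#'
#' Linear interpolation from `tau_max` at `t = 0` to `tau_min` at `t = T`.
#'
#' @param t current iteration (0..T).
#' @param T_total iteration budget.
#' @param tau_max,tau_min schedule endpoints.
#' @return the temperature at iteration `t`.
#' @export
tau_schedule <- function(t, T_total, tau_max = 4, tau_min = 0.01) {
  if (t < 0 || t > T_total) stop_arg("t must lie in [0, %d]", T_total)
  (1 - t / T_total) * tau_max + (t / T_total) * tau_min
}

#' Time-varying V-shaped transfer function
#'
#' Maps a step component to a bit probability:
#' `1 - 2/(1 + exp(-2x/tau))` for `x <= 0` and `2/(1 + exp(-2x/tau)) - 1`
#' for `x > 0`, which is exactly `|tanh(x/tau)|`. Small `tau` sharpens the
#' map, pushing late iterations toward exploitation.
#'
#' @param x step component(s).
#' @param tau temperature (> 0).
#' @return probabilities in `[0, 1)`.
#' @export
transfer_function <- function(x, tau) {
  if (!is.numeric(tau) || tau <= 0) stop_arg("tau must be positive")
  ifelse(x <= 0, 1 - 2 / (1 + exp(-2 * x / tau)),
         2 / (1 + exp(-2 * x / tau)) - 1)
}

#' Swarm behaviors for one dragonfly
#'
#' Neighborhood is the whole swarm excluding individual `i`. Returns
#' separation `S`, alignment `A`, cohesion `C`, food attraction `F`
#' (`food - X_i`) and enemy distraction `E` (`enemy + X_i`).
#'
#' @param positions population x N binary matrix.
#' @param steps population x N step matrix.
#' @param i individual index.
#' @param food,enemy positions of the best and worst solutions.
#' @param separation orientation of the separation sum (see [bdfa_config()]).
#' @return list with components `S`, `A`, `C`, `F`, `E`.
#' @export
swarm_behaviors <- function(positions, steps, i, food, enemy,
                            separation = "standard") {
  n <- nrow(positions)
  if (n < 2L) stop_arg("population must be >= 2")
  xi <- positions[i, ]
  others <- positions[-i, , drop = FALSE]
  S <- if (separation == "literal") {
    -(colSums(others) - (n - 1L) * xi)      # -sum_j (X_j - X_i)
  } else {
    -((n - 1L) * xi - colSums(others))      # -sum_j (X_i - X_j)
  }
  A <- colMeans(steps[-i, , drop = FALSE])
  C <- colMeans(others) - xi
  list(S = S, A = A, C = C, F = food - xi, E = enemy + xi)
}

#' Step-vector update
#'
#' `step_new = s*S + a*A + c*C + f*F + e*E + w * inertia_term`, componentwise
#' clamped to `[-step_clamp, step_clamp]`.
#'
#' @param behaviors list from [swarm_behaviors()].
#' @param step_old previous step vector.
#' @param position current binary position (used only by the
#'   `inertia = "position_literal"` variant).
#' @param config a [bdfa_config()].
#' @return the new step vector.
#' @export
step_update <- function(behaviors, step_old, position, config) {
  inert <- if (config$inertia == "position_literal") position else step_old
  v <- config$s * behaviors$S + config$a * behaviors$A + config$c * behaviors$C +
    config$f * behaviors$F + config$e * behaviors$E + config$w * inert
  pmin(pmax(v, -config$step_clamp), config$step_clamp)
}

#' Binary position update through the transfer function
#'
#' Per dimension, an independent uniform draw is compared with
#' `transfer_function(step, tau)`: under the `"set"` rule the bit becomes 1
#' iff `rand < T`; under `"flip"` the bit toggles iff `rand < T`.
#'
#' @param step step vector.
#' @param tau temperature.
#' @param position current binary position.
#' @param rule `"set"` or `"flip"`.
#' @return the new binary position (0/1 vector). Uses the current RNG stream.
#' @export
position_update <- function(step, tau, position, rule = "set") {
  p <- transfer_function(step, tau)
  r <- stats::runif(length(step))
  if (rule == "flip") {
    ifelse(r < p, 1 - position, position)
  } else {
    as.numeric(r < p)
  }
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

knn_cv_error <- function(x, labels, k_nn, folds) {
  nerr <- 0L
  for (fd in sort(unique(folds))) {
    tr <- folds != fd
    pred <- class::knn(x[tr, , drop = FALSE], x[!tr, , drop = FALSE],
                       cl = factor(labels[tr]), k = k_nn)
    nerr <- nerr + sum(as.character(pred) != labels[!tr])
  }
  nerr / length(labels)
}

#' Wrapper fitness of a feature mask
#'
#' `fitness = alpha * gamma + beta * |C|/N`, where `gamma` is the mean
#' misclassification rate of a `knn_k`-nearest-neighbour classifier over
#' seeded stratified `cv_folds`-fold cross-validation restricted to the
#' selected columns, and `|C|/N` is the selected-feature fraction. An
#' all-zero mask scores the worst possible fitness, 1, without touching the
#' classifier.
#'
#' @param mask 0/1 vector over the feature columns.
#' @param table feature table (numeric columns + `label`).
#' @param config a [bdfa_config()].
#' @param folds optional precomputed fold assignment (reused across masks
#'   inside [select_features()]); if `NULL`, folds are drawn under
#'   `config$seed`.
#' @return list with `fitness`, `error_rate`, `n_selected`.
#' @export
fitness <- function(mask, table, config = bdfa_config(), folds = NULL) {
  feat <- setdiff(names(table), "label")
  if (length(mask) != length(feat)) {
    stop_arg("mask length %d != feature count %d", length(mask), length(feat))
  }
  labels <- as.character(table$label)
  if (length(unique(labels)) < 2L) stop_arg("table must contain >= 2 classes")
  if (min(table(labels)) < config$cv_folds) {
    stop_arg("every class needs >= cv_folds = %d samples", config$cv_folds)
  }
  n_sel <- sum(mask != 0)
  if (n_sel == 0L) {
    return(list(fitness = 1, error_rate = 1, n_selected = 0L))
  }
  x <- as.matrix(table[feat])[, mask != 0, drop = FALSE]
  if (is.null(folds)) {
    folds <- with_seed(config$seed, stratified_folds(labels, config$cv_folds))
  }
  gam <- with_seed(config$seed + 1L, knn_cv_error(x, labels, config$knn_k, folds))
  list(fitness = config$alpha * gam + config$beta * n_sel / length(mask),
       error_rate = gam, n_selected = n_sel)
}

#' Select features with the binary dragonfly algorithm
#'
#' Runs the swarm for `config$iterations` iterations. The food source is the
#' best solution observed so far (elitist) and the enemy is the worst
#' solution of the current iteration. The returned mask is the food position,
#' repaired to contain at least one selected feature.
#'
#' @param table feature table (numeric columns + `label`).
#' @param config a [bdfa_config()].
#' @param verbose print per-iteration progress.
#' @return object of class `bdfa_result`: list with `mask` (named 0/1
#'   vector), `selected` (feature names), `ratio`, `fitness`, `error_rate`,
#'   `history` (best-so-far fitness per iteration), and `config`.
#' @export
select_features <- function(table, config = bdfa_config(), verbose = FALSE) {
  feat <- setdiff(names(table), "label")
  N <- length(feat)
  labels <- as.character(table$label)
  folds <- with_seed(config$seed, stratified_folds(labels, config$cv_folds))
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- fitness(mask, table, config, folds = folds)
    cache[[key]] <- res
    res
  }
  with_seed(config$seed, {
    pop <- config$population
    positions <- matrix(as.numeric(stats::runif(pop * N) < 0.5), pop, N)
    steps <- matrix(0, pop, N)
    food <- NULL; food_fit <- Inf
    history <- numeric(config$iterations)
    for (t in seq_len(config$iterations)) {
      fits <- numeric(pop)
      for (i in seq_len(pop)) fits[i] <- eval_mask(positions[i, ])$fitness
      if (min(fits) < food_fit) {
        food_fit <- min(fits)
        food <- positions[which.min(fits), ]
      }
      enemy <- positions[which.max(fits), ]
      history[t] <- food_fit
      tau <- tau_schedule(t, config$iterations, config$tau_max, config$tau_min)
      new_positions <- positions
      new_steps <- steps
      for (i in seq_len(pop)) {
        bh <- swarm_behaviors(positions, steps, i, food, enemy,
                              separation = config$separation)
        new_steps[i, ] <- step_update(bh, steps[i, ], positions[i, ], config)
        new_positions[i, ] <- position_update(new_steps[i, ], tau,
                                              positions[i, ],
                                              rule = config$position_rule)
      }
      positions <- new_positions
      steps <- new_steps
      if (verbose && (t %% 10L == 0L || t == 1L)) {
        message(sprintf("iter %3d  best fitness %.5f  tau %.3f", t, food_fit, tau))
      }
    }
    if (sum(food) == 0) food[sample.int(N, 1L)] <- 1  # repair: never empty
    names(food) <- feat
    final <- eval_mask(unname(food))
    structure(list(mask = food, selected = feat[food != 0],
                   ratio = selected_feature_ratio(food),
                   fitness = final$fitness, error_rate = final$error_rate,
                   history = history, config = config),
              class = "bdfa_result")
  })
}

#' @export
print.bdfa_result <- function(x, ...) {
  cat(sprintf("<bdfa_result> %d/%d features selected (ratio %.4f)\n",
              sum(x$mask), length(x$mask), x$ratio))
  cat(sprintf("  fitness %.5f (CV error %.4f) after %d iterations\n",
              x$fitness, x$error_rate, length(x$history)))
  invisible(x)
}

#' @export
plot.bdfa_result <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "s",
                 xlab = "iteration", ylab = "best-so-far fitness",
                 main = "Dragonfly convergence", ...)
  invisible(x)
}

#' Selected-feature ratio
#'
#' Fraction of features selected by a mask, `|C| / N`.
#'
#' @param mask 0/1 vector.
#' @return a number in `[0, 1]`.
#' @export
selected_feature_ratio <- function(mask) {
  if (length(mask) == 0L) stop_arg("empty mask")
  sum(mask != 0) / length(mask)
}
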