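test_that("stratified splitting respects fractions per class", {
  tab <- generate_planted_table(300, 4, 1:2, 3, seed = 71)
  tab$label <- rep(c("normal", "interictal", "ictal"), each = 100)
  parts <- split_train_test(tab, 0.8, seed = 71)
  expect_identical(nrow(parts$train), 240L)
  expect_identical(nrow(parts$test), 60L)
  expect_true(all(table(parts$train$label) == 80L))
  expect_true(all(table(parts$test$label) == 20L))
  expect_length(intersect(rownames(parts$train), rownames(parts$test)), 0L)

  small <- generate_planted_table(4, 3, 1L, 2, seed = 72)
  p2 <- split_train_test(small, 0.5, seed = 1)
  expect_identical(nrow(p2$train), 2L)
  expect_true(all(table(p2$train$label) == 1L))

  pa <- split_train_test(tab, 0.8, seed = 5)
  pb <- split_train_test(tab, 0.8, seed = 5)
  expect_identical(rownames(pa$train), rownames(pb$train))

  one <- generate_planted_table(10, 3, 1L, 2, seed = 73)
  one$label[1] <- "rare"
  expect_error(split_train_test(one, 0.8, 1), ">= 2 samples")
})

test_that("the MLP fits separable data to perfection, deterministically", {
  tab <- make_separable_table(n = 80, n_features = 6, seed = 74)
  mask <- c(1, 1, 0, 0, 0, 0)
  net <- train_classifier(tab, mask, classifier_spec(seed = 74))
  expect_s3_class(net, "mlp_net")
  expect_lt(net$loss_final, net$loss_initial)
  pred <- predict(net, tab)
  expect_identical(pred, tab$label)  # training accuracy 1.0

  net2 <- train_classifier(tab, mask, classifier_spec(seed = 74))
  expect_identical(predict(net2, tab), pred)

  one_class <- tab[tab$label == "c1", ]
  expect_error(train_classifier(one_class, mask), ">= 2 classes")
  expect_error(train_classifier(tab, rep(0, 6)), "no features")
})

test_that("prediction honours its contracts", {
  tab <- make_separable_table(n = 40, seed = 75)
  net <- train_classifier(tab, c(1, 1, 1, 0, 0, 0), classifier_spec(seed = 75))
  expect_length(predict(net, tab[3, , drop = FALSE]), 1L)
  expect_identical(predict(net, tab), predict(net, tab))
  p <- predict(net, tab, type = "prob")
  expect_equal(rowSums(p), rep(1, 40))
  wrong <- tab; names(wrong)[2] <- "renamed"
  expect_error(predict(net, wrong), "do not match")
})

test_that("metrics match hand-computed confusion rates", {
  perfect <- compute_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)

  # TP=50 TN=40 FP=5 FN=5 with positive class "pos"
  y_true <- c(rep("pos", 55), rep("neg", 45))
  y_pred <- c(rep("pos", 50), rep("neg", 5), rep("pos", 5), rep("neg", 40))
  m <- compute_metrics(y_true, y_pred, positive_class = "pos")
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$sensitivity, 0.9091, tolerance = 1e-4)
  expect_equal(m$specificity, 0.8889, tolerance = 1e-4)
  expect_equal(m$f1, 0.9091, tolerance = 1e-4)

  allneg <- compute_metrics(y_true, rep("neg", 100), positive_class = "pos")
  expect_equal(allneg$sensitivity, 0)

  expect_error(compute_metrics(c("a", "b"), "a"), "lengths differ")
})

test_that("metrics agree with a brute-force confusion oracle", {
  set.seed(76)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    levels <- letters[seq_len(k)]
    y_true <- sample(levels, 60, replace = TRUE)
    y_true[seq_len(k)] <- levels  # every class represented
    y_pred <- sample(levels, 60, replace = TRUE)
    m <- compute_metrics(y_true, y_pred, positive_class = levels[1])
    cm <- oracle_confusion(y_true, y_pred, levels)
    expect_true(all(m$confusion == cm))
    expect_equal(m$accuracy, sum(diag(cm)) / 60)
    if (k == 2) {
      tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
      expect_equal(m$sensitivity, tp / (tp + fn))
      expect_equal(m$specificity, tn / (tn + fp))
      # exact binary identity on integer counts
      P <- tp + fn; N <- tn + fp
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    }
  }
})

test_that("the Fisher score follows its between/within definition", {
  # two classes, one feature: means 0 and 1, within-class variance 0.01
  x <- c(rep(-0.1, 25), rep(0.1, 25))  # population variance exactly 0.01
  tab <- data.frame(f1 = c(x, x + 1),
                    label = rep(c("a", "b"), each = 50))
  fr <- fisher_report(tab)
  expect_equal(unname(fr$scores["f1"]), 25)
  expect_equal(fr$f_tot, 25)
  expect_identical(fr$n_selected, 1L)

  # shuffled labels: near-zero separability
  set.seed(77)
  big <- generate_planted_table(500, 6, 1:2, 3, seed = 77)
  big$label <- sample(big$label)
  expect_lt(fisher_report(big)$f_tot, 0.05)

  # subset of one feature: F_tot equals that feature's score
  fr3 <- fisher_report(big, mask = c(1, rep(0, 5)))
  expect_equal(fr3$f_tot, unname(fr3$scores[1]))

  # constant feature guards to zero
  cst <- data.frame(f1 = rep(1, 20), label = rep(c("a", "b"), 10))
  expect_identical(fisher_report(cst)$f_tot, 0)
})
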