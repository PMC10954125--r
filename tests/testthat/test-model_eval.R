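# Splitting, loss, classifier head training, and evaluation statistics.

test_that("stratified split is exact, exhaustive and deterministic", {
  y <- rep("A", 100)
  sp <- split_dataset(y, seed = 1)
  expect_equal(lengths(sp), c(train = 70L, test = 20L, validation = 10L))

  y2 <- rep(c("A", "B", "C"), c(30, 50, 20))
  sp2 <- split_dataset(y2, seed = 2)
  all_idx <- unname(sort(unlist(sp2)))
  expect_equal(all_idx, 1:100)
  expect_equal(length(intersect(sp2$train, sp2$test)), 0)
  expect_equal(length(intersect(sp2$train, sp2$validation)), 0)
  # per-class proportions within one sample of target
  for (cl in c("A", "B", "C")) {
    n_cl <- sum(y2 == cl)
    got <- vapply(sp2, function(ix) sum(y2[ix] == cl), 0)
    expect_true(all(abs(got - n_cl * c(0.7, 0.2, 0.1)) <= 1))
  }
  expect_identical(split_dataset(y2, seed = 2), sp2)
  expect_false(identical(split_dataset(y2, seed = 3), sp2))
  expect_error(split_dataset(c("A", "A", "B")), "at least")
})

test_that("cross entropy matches hand arithmetic", {
  onehot <- diag(4)[c(1, 2, 3, 4), ]
  expect_equal(cross_entropy(onehot, 1:4), 0)

  unif <- matrix(1 / 8, 5, 8)
  expect_equal(cross_entropy(unif, rep(3, 5)), log(8))

  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3))
  expect_equal(cross_entropy(p, c(1, 3)), mean(-log(c(0.7, 0.3))))

  expect_error(cross_entropy(matrix(c(0.5, 0.2), 1), 1), "sum to 1")
})

test_that("the softmax head fits separable data to 100% and trains deterministically", {
  set.seed(6)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  X <- centers[rep(1:4, each = 20), ] + matrix(rnorm(160, 0, 0.3), 80, 2)
  y <- factor(rep(c("a", "b", "c", "d"), each = 20))
  cfg <- train_config(learning_rate = 0.05, seed = 5)  # scaled to the tiny head
  head <- train_head(X, y, hidden = 16, config = cfg)
  expect_true(all(is.finite(head$loss_trace)))
  expect_length(head$loss_trace, 40)
  expect_equal(mean(predict(head, X) == y), 1)
  expect_equal(head$n_params, 2 * 16 + 16 + 16 * 4 + 4)

  head2 <- train_head(X, y, hidden = 16, config = cfg)
  expect_identical(head$W1, head2$W1)
  expect_identical(head$W2, head2$W2)

  P <- predict(head, X, type = "prob")
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_error(predict(head, X[, 1, drop = FALSE]), "width")
})

test_that("confusion matrix counts true-by-predicted", {
  y <- c("A", "A", "B", "B", "C", "C")
  p <- c("A", "B", "B", "B", "C", "A")
  cm <- confusion_matrix(y, p, classes = c("A", "B", "C"))
  expect_equal(unname(cm),
               matrix(c(1, 0, 1, 1, 2, 0, 0, 0, 1), 3, 3))  # cols = predicted A,B,C
  expect_equal(sum(cm), 6)

  perfect <- confusion_matrix(y, y, classes = c("A", "B", "C"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))

  allA <- confusion_matrix(y, rep("A", 6), classes = c("A", "B", "C"))
  expect_equal(sum(allA[, 1]), 6)
  expect_equal(sum(allA[, -1]), 0)

  expect_error(confusion_matrix(y, c(p[-6], "Z"), classes = c("A", "B", "C")),
               "vocabulary")
})

test_that("metrics follow the one-vs-rest confusion formulas", {
  # binary toy: TP=50, FP=10, FN=10, TN=30
  cm <- matrix(c(50, 10, 10, 30), 2, 2, byrow = TRUE)
  rep1 <- metrics_from_confusion(cm)
  expect_equal(rep1$per_class$ACC[1], 0.8)
  expect_equal(rep1$per_class$PREC[1], 50 / 60, tolerance = 1e-6)
  expect_equal(rep1$per_class$REC[1], 50 / 60, tolerance = 1e-6)
  expect_equal(rep1$per_class$F1[1], 50 / 60, tolerance = 1e-6)

  perfect <- metrics_from_confusion(diag(c(5, 3, 2)))
  expect_equal(unname(perfect$macro), rep(1, 4))
  expect_equal(perfect$accuracy, 1)

  set.seed(44)
  for (rep in 1:5) {
    y_true <- sample(1:4, 60, replace = TRUE)
    y_pred <- sample(1:4, 60, replace = TRUE)
    m <- metrics_from_confusion(confusion_matrix(y_true, y_pred, classes = 1:4))
    # brute-force per-sample recomputation
    for (k in 1:4) {
      tp <- sum(y_true == k & y_pred == k)
      fp <- sum(y_true != k & y_pred == k)
      fn <- sum(y_true == k & y_pred != k)
      expect_equal(m$per_class$TP[k], tp)
      if (tp + fn > 0) expect_equal(m$per_class$REC[k], tp / (tp + fn))
      if (tp + fp > 0) expect_equal(m$per_class$PREC[k], tp / (tp + fp))
      pr <- m$per_class$PREC[k] + m$per_class$REC[k]
      if (pr > 0) {
        expect_equal(m$per_class$F1[k],
                     2 * m$per_class$PREC[k] * m$per_class$REC[k] / pr)
      }
    }
    expect_equal(m$accuracy, mean(y_true == y_pred))
  }
})

test_that("one-vs-rest AUC agrees with pair counting and with pROC", {
  scores <- cbind(c(0.9, 0.8, 0.7, 0.3, 0.2), 1 - c(0.9, 0.8, 0.7, 0.3, 0.2))
  colnames(scores) <- c("P", "N")
  y <- c("P", "P", "P", "N", "N")
  expect_equal(auc_ovr(y, scores), 1)
  expect_equal(auc_ovr(rev(y), scores), 0)

  set.seed(17)
  s10 <- runif(10)
  y10 <- sample(c("P", "N"), 10, replace = TRUE, prob = c(0.5, 0.5))
  probs <- cbind(P = s10, N = 1 - s10)
  want <- (naive_auc_binary(s10, y10 == "P") +
           naive_auc_binary(1 - s10, y10 == "N")) / 2
  expect_equal(auc_ovr(y10, probs), want)
  # independent implementation cross-check
  proc_auc <- as.numeric(pROC::auc(pROC::roc(y10 == "P", s10, quiet = TRUE,
                                             direction = "<")))
  expect_equal(naive_auc_binary(s10, y10 == "P"), proc_auc)

  expect_warning(auc_ovr(factor(y10, levels = c("P", "N", "Z")),
                         cbind(probs, Z = runif(10))),
                 "absent")
})

test_that("one-way ANOVA reduces to textbook arithmetic and t^2 for two groups", {
  g_eq <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  expect_lt(anova_oneway(g_eq)$F, 1e-10)

  set.seed(4)
  a <- rnorm(8, 0); b <- rnorm(9, 1)
  res <- anova_oneway(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
  expect_equal(res$p, tt$p.value)

  # 2-group x 3-value hand computation
  g <- list(c(1, 2, 3), c(4, 5, 6))
  grand <- 3.5
  ss_b <- 3 * (2 - grand)^2 + 3 * (5 - grand)^2   # 13.5
  ss_w <- sum((c(1, 2, 3) - 2)^2) + sum((c(4, 5, 6) - 5)^2)  # 4
  f_hand <- (ss_b / 1) / (ss_w / 4)
  res2 <- anova_oneway(g)
  expect_equal(res2$F, f_hand)
  expect_equal(res2$df1, 1)
  expect_equal(res2$df2, 4)

  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "zero within")
  expect_error(anova_oneway(list(1:3)), "2 groups")
})
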