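# Softmax classifier head on the selected features, trained with RMSprop
# and categorical cross-entropy, plus the full evaluation toolkit:
# stratified splitting, confusion matrix, per-class and macro
# accuracy/precision/recall/F1, one-vs-rest macro AUC, and one-way ANOVA
# for comparing model accuracies.

#' Training configuration for the classifier head
#'
#' Defaults follow the standard configuration used throughout the package:
#' learning rate 0.001, batch size 32, 40 epochs, RMSprop-style adaptive
#' steps on categorical cross-entropy.
#'
#' @param learning_rate Positive step size.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training data.
#' @param rho RMSprop decay of the squared-gradient average.
#' @param eps RMSprop stabilizer.
#' @param seed Integer seed for weight init and shuffling.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32, epochs = 40,
                         rho = 0.9, eps = 1e-8, seed = 1) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1) {
    stop_domain("hyperparameters must be positive")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), rho = rho, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/test/validation split
#'
#' Splits sample indices per class (largest-remainder apportionment, so each
#' class's partition sizes are within one sample of the target fractions),
#' deterministically given `seed`. The three parts are disjoint and
#' exhaustive.
#'
#' @param labels Class labels (factor or character).
#' @param fractions Named numeric vector summing to 1; default the 70:20:10
#'   train:test:validation split.
#' @param seed Integer seed.
#' @return Named list of integer index vectors, one per partition.
#' @export
split_dataset <- function(labels,
                          fractions = c(train = 0.7, test = 0.2, validation = 0.1),
                          seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_domain("fractions must sum to 1")
  y <- factor(labels)
  counts <- table(droplevels(y))
  if (any(counts < length(fractions))) {
    stop_domain("every class needs at least ", length(fractions), " samples; too small: ",
                paste(names(counts)[counts < length(fractions)], collapse = ", "))
  }
  parts <- stats::setNames(vector("list", length(fractions)), names(fractions))
  parts[] <- list(integer(0))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      q <- counts[[cl]] * fractions
      base <- floor(q)
      left <- counts[[cl]] - sum(base)
      if (left > 0) {
        give <- order(-(q - base))[seq_len(left)]
        base[give] <- base[give] + 1
      }
      at <- 0L
      for (p in seq_along(fractions)) {
        take <- base[p]
        parts[[p]] <- c(parts[[p]], idx[seq_len(take) + at])
        at <- at + take
      }
    }
  })
  lapply(parts, sort)
}

#' Mean categorical cross-entropy
#'
#' `mean(-log p(true class))` with probabilities clipped to
#' `[1e-12, 1]` (natural log).
#'
#' @param probs `n x C` matrix of predicted class probabilities; rows must
#'   sum to 1 within `1e-6`.
#' @param labels True labels: factor/character matching the columns of
#'   `probs`, or integer class indices.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(probs, labels) {
  probs <- as.matrix(probs)
  li <- label_index(labels, probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop_domain("probability rows must sum to 1")
  }
  p <- pmin(pmax(probs[cbind(seq_len(nrow(probs)), li)], 1e-12), 1)
  mean(-log(p))
}

label_index <- function(labels, probs) {
  if (is.numeric(labels)) {
    li <- as.integer(labels)
  } else {
    lv <- colnames(probs)
    if (is.null(lv)) lv <- levels(factor(labels))
    li <- match(as.character(labels), lv)
  }
  if (length(li) != nrow(probs) || anyNA(li) || any(li < 1 | li > ncol(probs))) {
    stop_domain("labels do not match the probability matrix")
  }
  li
}

#' Train the softmax classifier head
#'
#' A dense head `p -> hidden (ReLU) -> C (softmax)` trained by minibatch
#' RMSprop on categorical cross-entropy, with seeded He-normal
#' initialization and seeded shuffling, so training is deterministic given
#' the configuration seed. The per-epoch full-training-set loss is recorded,
#' together with a final mean-absolute-deviation diagnostic between the
#' one-hot targets and the predicted probabilities.
#'
#' @param X `n x p` training feature matrix.
#' @param y Training labels (factor; its levels define the output classes).
#' @param hidden Hidden layer width.
#' @param config A [train_config()].
#' @return An object of class `"softmax_head"` with the weight matrices,
#'   `levels`, `loss_trace` (length `epochs`), `final_mad`, and `n_params`.
#' @export
train_head <- function(X, y, hidden = 512, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  C <- nlevels(y)
  if (C < 2) stop_domain("need at least 2 classes")
  n <- nrow(X); p <- ncol(X)
  yi <- as.integer(y)
  Yhot <- matrix(0, n, C); Yhot[cbind(seq_len(n), yi)] <- 1

  rms <- function(acc, g, cfg) cfg$rho * acc + (1 - cfg$rho) * g^2
  state <- with_seed(config$seed, list(
    W1 = matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden),
    b1 = numeric(hidden),
    W2 = matrix(rnorm(hidden * C, sd = sqrt(2 / hidden)), hidden, C),
    b2 = numeric(C)
  ))
  acc <- lapply(state, function(w) w * 0)
  forward <- function(Xb) {
    H <- pmax(Xb %*% state$W1 + matrix(state$b1, nrow(Xb), hidden, byrow = TRUE), 0)
    Z <- H %*% state$W2 + matrix(state$b2, nrow(Xb), C, byrow = TRUE)
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    list(H = H, P = E / rowSums(E))
  }
  loss_trace <- numeric(config$epochs)
  with_seed(derive_seed(config$seed, "shuffle"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n)]
        fw <- forward(X[bi, , drop = FALSE])
        m <- length(bi)
        dZ <- (fw$P - Yhot[bi, , drop = FALSE]) / m
        gW2 <- crossprod(fw$H, dZ)
        gb2 <- colSums(dZ)
        dH <- (dZ %*% t(state$W2)) * (fw$H > 0)
        gW1 <- crossprod(X[bi, , drop = FALSE], dH)
        gb1 <- colSums(dH)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        for (nm in names(state)) {
          acc[[nm]] <- rms(acc[[nm]], grads[[nm]], config)
          state[[nm]] <- state[[nm]] -
            config$learning_rate * grads[[nm]] / (sqrt(acc[[nm]]) + config$eps)
        }
      }
      loss_trace[ep] <- cross_entropy(forward(X)$P, yi)
    }
  })
  P <- forward(X)$P
  structure(list(W1 = state$W1, b1 = state$b1, W2 = state$W2, b2 = state$b2,
                 levels = levels(y), hidden = hidden,
                 loss_trace = loss_trace,
                 final_mad = mean(abs(Yhot - P)),
                 n_params = p * hidden + hidden + hidden * C + C,
                 config = config),
            class = "softmax_head")
}

#' @export
print.softmax_head <- function(x, ...) {
  cat(sprintf("Softmax head: %d -> %d -> %d, %s trainable parameters\n",
              nrow(x$W1), x$hidden, length(x$levels),
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  final training loss %.4f (mean abs deviation %.4f)\n",
              x$loss_trace[length(x$loss_trace)], x$final_mad))
  invisible(x)
}

#' Predict classes or probabilities from a trained head
#'
#' @param object A `"softmax_head"`.
#' @param X Feature matrix with the width the head was trained on.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted labels, or an `n x C` probability matrix.
#' @export
predict.softmax_head <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != nrow(object$W1)) stop_domain("feature width mismatch")
  H <- pmax(X %*% object$W1 + matrix(object$b1, nrow(X), object$hidden,
                                     byrow = TRUE), 0)
  Z <- H %*% object$W2 + matrix(object$b2, nrow(X), length(object$levels),
                                byrow = TRUE)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' Confusion matrix of counts
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`.
#'
#' @param y_true,y_pred Labels (factor/character); coerced to the union of
#'   `classes`.
#' @param classes Class vocabulary defining the matrix order; defaults to
#'   the levels of `y_true`.
#' @return `C x C` integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(y_true)) levels(y_true) else sort(unique(as.character(y_true)))
  }
  yt <- factor(as.character(y_true), levels = classes)
  yp <- factor(as.character(y_pred), levels = classes)
  if (anyNA(yt) || anyNA(yp)) stop_domain("labels outside the class vocabulary")
  cm <- table(true = yt, predicted = yp)
  matrix(as.integer(cm), nlevels(yt), nlevels(yt),
         dimnames = list(true = classes, predicted = classes))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest per class: `ACC = (TP + TN) / total`, `REC = TP / (TP + FN)`,
#' `PREC = TP / (TP + FP)`, `F1 = 2 PR / (P + R)`, plus unweighted macro
#' averages and overall accuracy. A zero denominator yields 0 for that
#' metric and sets the class's degenerate flag.
#'
#' @param confusion Square nonnegative count matrix (true x predicted).
#' @return An object of class `"metrics_report"` with `per_class` (data
#'   frame of TP/FP/FN/TN and the four rates), `macro` (named vector),
#'   `accuracy` (overall), `confusion`, and `degenerate` (logical per
#'   class).
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0)) {
    stop_domain("confusion must be a square nonnegative matrix")
  }
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- safe(tp + tn, rep(total, length(tp)))
  rec <- safe(tp, tp + fn)
  prec <- safe(tp, tp + fp)
  f1 <- safe(2 * prec * rec, prec + rec)
  degenerate <- (tp + fn) == 0 | (tp + fp) == 0 | (prec + rec) == 0
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_along(tp))
  structure(list(
    per_class = data.frame(class = classes, TP = tp, FP = fp, FN = fn, TN = tn,
                           ACC = acc, PREC = prec, REC = rec, F1 = f1,
                           row.names = NULL),
    macro = c(ACC = mean(acc), PREC = mean(prec), REC = mean(rec), F1 = mean(f1)),
    accuracy = if (total > 0) sum(tp) / total else 0,
    confusion = confusion, degenerate = degenerate
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  cat("Macro: ", paste(sprintf("%s=%.*f", names(x$macro), digits, x$macro),
                       collapse = "  "), "\n")
  if (!is.null(x$auc_macro)) cat(sprintf("Macro one-vs-rest AUC: %.4f\n", x$auc_macro))
  print(x$per_class, digits = digits)
  invisible(x)
}

#' Macro one-vs-rest AUC
#'
#' Per-class ROC AUC computed by the Mann-Whitney rank statistic with
#' midranks for ties, macro-averaged over the classes present in `y_true`;
#' classes without positive samples are excluded with a warning.
#'
#' @param y_true True labels.
#' @param probs `n x C` score/probability matrix with class columns (column
#'   names matching the label vocabulary, or columns in factor-level order).
#' @return Macro-averaged AUC in `[0, 1]`.
#' @export
auc_ovr <- function(y_true, probs) {
  probs <- as.matrix(probs)
  y <- factor(y_true)
  classes <- colnames(probs)
  if (is.null(classes)) {
    if (ncol(probs) < nlevels(y)) stop_domain("probability matrix too narrow")
    classes <- levels(y)
  }
  aucs <- numeric(0)
  for (ci in seq_along(classes)) {
    pos <- as.character(y) == classes[ci]
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0) {
      warning("class absent from y_true, excluded from AUC: ", classes[ci])
      next
    }
    if (nneg == 0) next
    r <- rank(probs[, ci], ties.method = "average")
    aucs <- c(aucs, (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg))
  }
  mean(aucs)
}

#' One-way ANOVA over groups of accuracies
#'
#' Classical one-way fixed-effects F test (equal-variance), as used to
#' compare mean accuracies of competing models.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop_domain("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop_domain("each group needs >= 2 values")
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (within_ss == 0) stop_domain("zero within-group variance: F undefined")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]))
}
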