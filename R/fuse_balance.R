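# Feature fusion (HOG block first, deep block second), entropy-based
# selection of the top-scoring features, and SMOTE-Tomek rebalancing in
# feature space. Selection and rebalancing are fitted on training rows only.

#' Fuse a HOG descriptor with a deep descriptor
#'
#' Plain concatenation, HOG block first. With the default geometries this
#' yields 3780 + 4096 = 7876 features.
#'
#' @param hog Numeric vector (HOG block).
#' @param deep Numeric vector (deep block).
#' @return Numeric vector with a `blocks` attribute giving the index range
#'   of each block.
#' @export
fuse <- function(hog, deep) {
  if (!is.numeric(hog) || !is.numeric(deep) || !length(hog) || !length(deep)) {
    stop_domain("hog and deep must be nonempty numeric vectors")
  }
  structure(c(as.numeric(hog), as.numeric(deep)),
            blocks = list(hog = c(1L, length(hog)),
                          deep = c(length(hog) + 1L, length(hog) + length(deep))))
}

#' Fuse per-sample HOG and deep feature matrices
#'
#' @param hog_matrix `n x p_hog` matrix (one row per sample).
#' @param deep_matrix `n x p_deep` matrix over the same samples.
#' @return `n x (p_hog + p_deep)` matrix with a `blocks` attribute.
#' @export
fuse_features <- function(hog_matrix, deep_matrix) {
  if (nrow(hog_matrix) != nrow(deep_matrix)) {
    stop_domain("hog and deep matrices must have the same number of rows")
  }
  structure(cbind(hog_matrix, deep_matrix),
            blocks = list(hog = c(1L, ncol(hog_matrix)),
                          deep = c(ncol(hog_matrix) + 1L,
                                   ncol(hog_matrix) + ncol(deep_matrix))))
}

#' Shannon entropy score per feature
#'
#' For each feature (column), the empirical distribution of its training
#' values over `bins` equal-width bins spanning that feature's range is
#' scored by Shannon entropy in bits (`-sum p log2 p`). Constant features
#' score 0.
#'
#' @param train_matrix `n x p` numeric matrix of training samples.
#' @param bins Number of equal-width histogram bins.
#' @return Numeric vector of length `p`, all values `>= 0`.
#' @export
entropy_scores <- function(train_matrix, bins = 256) {
  if (!is.matrix(train_matrix) || nrow(train_matrix) < 2) {
    stop_domain("need a matrix with at least 2 training samples")
  }
  n <- nrow(train_matrix)
  apply(train_matrix, 2, function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(0)
    idx <- pmin(bins, floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L)
    p <- tabulate(idx, nbins = bins) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Select the top-k features by score
#'
#' Indices of the `k` largest scores, ties broken towards the lower index.
#' The selection is fitted on training data only and then applied unchanged
#' to validation/test samples via [apply_selection()].
#'
#' @param scores Per-feature scores (e.g. from [entropy_scores()]).
#' @param k Number of features to keep.
#' @return An object of class `"entropy_selection"` with `selected_idx`
#'   (in decreasing-score order), `scores`, `k`.
#' @export
select_top_k <- function(scores, k = 1186) {
  if (k > length(scores)) stop_domain("k exceeds the number of features")
  if (k < 1) stop_domain("k must be >= 1")
  idx <- order(-scores, seq_along(scores))[seq_len(k)]
  structure(list(selected_idx = idx, scores = scores, k = as.integer(k)),
            class = "entropy_selection")
}

#' @export
print.entropy_selection <- function(x, ...) {
  cat(sprintf("Entropy selection: kept %d of %d features (score range %.3f-%.3f bits)\n",
              x$k, length(x$scores), min(x$scores[x$selected_idx]),
              max(x$scores[x$selected_idx])))
  invisible(x)
}

#' Apply a fitted feature selection to a matrix
#'
#' @param X Feature matrix.
#' @param selection An `"entropy_selection"`.
#' @return `X` restricted to the selected columns.
#' @export
apply_selection <- function(X, selection) {
  stopifnot(inherits(selection, "entropy_selection"))
  X[, selection$selected_idx, drop = FALSE]
}

#' SMOTE minority over-sampling
#'
#' Grows every minority class to the majority count by interpolating
#' synthetic rows `x_new = x + u (x_nn - x)` with `u ~ Uniform(0, 1)`
#' between a class member and one of its `k_neighbors` within-class nearest
#' neighbours (Euclidean). Deterministic given `seed`.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class labels (factor or character).
#' @param k_neighbors Neighbourhood size; capped at class size minus 1.
#' @param seed Integer seed.
#' @return An object of class `"rebalanced_set"`: `X`, `y`, `synthetic`
#'   (logical per row), `removed_pairs` (`NULL` here; filled by
#'   [smote_tomek()]).
#' @export
smote <- function(X, y, k_neighbors = 5, seed = 1) {
  y <- factor(y)
  counts <- table(y)
  if (any(counts < 2)) {
    stop_domain("class of size 1 cannot be over-sampled: ",
                paste(names(counts)[counts < 2], collapse = ", "))
  }
  target <- max(counts)
  new_rows <- list(); new_labs <- character(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      k <- min(k_neighbors, length(idx) - 1L)
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      ord <- apply(D, 1, function(d) order(d)[seq_len(k)])
      nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)
      base <- sample.int(length(idx), need, replace = TRUE)
      pick <- sample.int(k, need, replace = TRUE)
      u <- stats::runif(need)
      for (s in seq_len(need)) {
        a <- Xc[base[s], ]
        b <- Xc[nn[base[s], pick[s]], ]
        new_rows[[length(new_rows) + 1L]] <- a + u[s] * (b - a)
        new_labs <- c(new_labs, cl)
      }
    }
  })
  if (length(new_rows)) {
    Xout <- rbind(X, do.call(rbind, new_rows))
    yout <- factor(c(as.character(y), new_labs), levels = levels(y))
    syn <- c(rep(FALSE, nrow(X)), rep(TRUE, length(new_labs)))
  } else {
    Xout <- X; yout <- y; syn <- rep(FALSE, nrow(X))
  }
  structure(list(X = Xout, y = yout, synthetic = syn, removed_pairs = NULL),
            class = "rebalanced_set")
}

#' Tomek links: mutual nearest-neighbour pairs with different labels
#'
#' A pair `(i, j)` is a Tomek link when `i` is `j`'s single (Euclidean)
#' nearest neighbour and vice versa while their labels differ. Such pairs
#' straddle the class boundary; removing them cleans it. Deterministic
#' (nearest-neighbour ties go to the lower index).
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @return Two-column integer matrix of link pairs (`i < j`); zero rows if
#'   none, including the single-class case.
#' @export
tomek_links <- function(X, y) {
  y <- factor(y)
  n <- nrow(X)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (nlevels(droplevels(y)) < 2 || n < 2) return(empty)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn1 <- apply(D, 1, which.min)
  links <- which(nn1[nn1] == seq_len(n) & nn1 > seq_len(n) &
                   as.integer(y) != as.integer(y[nn1]))
  if (!length(links)) return(empty)
  cbind(i = links, j = nn1[links])
}

#' SMOTE followed by Tomek-link removal
#'
#' Runs [smote()], then finds all Tomek links in the over-sampled set and
#' removes both members of every link.
#'
#' @inheritParams smote
#' @return A `"rebalanced_set"` with `removed_pairs` recording the dropped
#'   link pairs (row indices into the post-SMOTE matrix).
#' @export
smote_tomek <- function(X, y, k_neighbors = 5, seed = 1) {
  sm <- smote(X, y, k_neighbors = k_neighbors, seed = seed)
  links <- tomek_links(sm$X, sm$y)
  if (nrow(links)) {
    drop_idx <- unique(as.integer(links))
    keep <- setdiff(seq_len(nrow(sm$X)), drop_idx)
    sm$X <- sm$X[keep, , drop = FALSE]
    sm$y <- sm$y[keep]
    sm$synthetic <- sm$synthetic[keep]
  }
  sm$removed_pairs <- links
  sm
}

#' @export
print.rebalanced_set <- function(x, ...) {
  cat("Rebalanced set:", nrow(x$X), "rows (", sum(x$synthetic), "synthetic),",
      if (is.null(x$removed_pairs)) 0L else nrow(x$removed_pairs),
      "Tomek links removed\n")
  print(table(x$y))
  invisible(x)
}
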