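# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use plain loops and direct formula
# evaluation, sharing no code path with the package internals.

reflect_idx <- function(i, n) min(max(i, 1L), n)

# straight-loop Perona-Malik step with exponential conduction, reflecting
# borders
naive_diffusion_step <- function(img, kappa = 30, lam = 0.2) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      s <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nb <- img[reflect_idx(i + d[1], H), reflect_idx(j + d[2], W)]
        diff <- nb - img[i, j]
        s <- s + exp(-(diff / kappa)^2) * diff
      }
      out[i, j] <- img[i, j] + lam * s
    }
  }
  out
}

# straight-loop HOG: Sobel gradients, 9 unsigned bins (centers 0,20,...,160,
# wrapping at 180) with linear votes, 8x8 cells, 2x2 blocks at 1-cell
# stride (row-major), L2-hys-free normalization v / sqrt(|v|^2 + k^2)
naive_hog <- function(img, cell = 8, bins = 9, k = 1e-5) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  at <- function(i, j) img[reflect_idx(i, H), reflect_idx(j, W)]
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      gx[i, j] <- (at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
                  (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1))
      gy[i, j] <- (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)) -
                  (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1))
    }
  }
  ncr <- H %/% cell; ncc <- W %/% cell
  hist <- array(0, c(ncr, ncc, bins))
  binw <- 180 / bins
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      mag <- sqrt(gx[i, j]^2 + gy[i, j]^2)
      ang <- (atan2(gy[i, j], gx[i, j]) * 180 / pi) %% 180
      t <- ang / binw
      b0 <- floor(t)
      w_hi <- t - b0
      ci <- (i - 1) %/% cell + 1
      cj <- (j - 1) %/% cell + 1
      hist[ci, cj, b0 + 1] <- hist[ci, cj, b0 + 1] + mag * (1 - w_hi)
      hist[ci, cj, (b0 + 1) %% bins + 1] <- hist[ci, cj, (b0 + 1) %% bins + 1] + mag * w_hi
    }
  }
  out <- numeric(0)
  for (br in seq_len(ncr - 1)) {
    for (bc in seq_len(ncc - 1)) {
      v <- c(hist[br, bc, ], hist[br, bc + 1, ], hist[br + 1, bc, ],
             hist[br + 1, bc + 1, ])
      out <- c(out, v / sqrt(sum(v^2) + k^2))
    }
  }
  out
}

# all-pairs mutual-1-NN search for Tomek links
naive_tomek <- function(X, y) {
  n <- nrow(X)
  y <- factor(y)
  nn <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; at <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d < best) { best <- d; at <- j }
    }
    nn[i] <- at
  }
  links <- NULL
  for (i in seq_len(n)) {
    j <- nn[i]
    if (j > i && nn[j] == i && y[i] != y[j]) links <- rbind(links, c(i, j))
  }
  if (is.null(links)) matrix(integer(0), 0, 2) else links
}

# Mann-Whitney AUC by direct concordant-pair counting (ties count 1/2)
naive_auc_binary <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

# two-region speckled fixture with known clean reference
two_region_fixture <- function(h = 96, w = 96, lo = 100, hi = 200,
                               variance = 0.05, seed = 7) {
  clean <- matrix(lo, h, w)
  clean[, (w %/% 2 + 1):w] <- hi
  list(clean = clean, noisy = add_speckle(clean, variance, seed = seed),
       edge_col = w %/% 2)
}
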